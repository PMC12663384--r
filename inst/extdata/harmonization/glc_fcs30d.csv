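dataset_id,native_code,native_label,harmonized_code,note
glc_fcs30d,10,Rainfed cropland,CULTIVATED,GLC_FCS30D fine classification legend (v2023).
glc_fcs30d,11,Herbaceous cover cropland,CULTIVATED,
glc_fcs30d,12,Tree or shrub cover (orchard) cropland,CULTIVATED,Tree crops included in cropland.
glc_fcs30d,20,Irrigated cropland,CULTIVATED,
glc_fcs30d,51,Open evergreen broadleaved forest,FOREST,
glc_fcs30d,52,Closed evergreen broadleaved forest,FOREST,
glc_fcs30d,61,Open deciduous broadleaved forest,FOREST,
glc_fcs30d,62,Closed deciduous broadleaved forest,FOREST,
glc_fcs30d,71,Open evergreen needle-leaved forest,FOREST,
glc_fcs30d,72,Closed evergreen needle-leaved forest,FOREST,
glc_fcs30d,81,Open deciduous needle-leaved forest,FOREST,
glc_fcs30d,82,Closed deciduous needle-leaved forest,FOREST,
glc_fcs30d,91,Open mixed-leaf forest,FOREST,
glc_fcs30d,92,Closed mixed-leaf forest,FOREST,
glc_fcs30d,120,Shrubland,GRASS_SHRUB,
glc_fcs30d,121,Evergreen shrubland,GRASS_SHRUB,
glc_fcs30d,122,Deciduous shrubland,GRASS_SHRUB,
glc_fcs30d,130,Grassland,GRASS_SHRUB,
glc_fcs30d,140,Lichens and mosses (tundra),OTHER,Tundra kept out of grassland & shrubland; classification standards differ across products.
glc_fcs30d,150,Sparse vegetation,OTHER,
glc_fcs30d,152,Sparse shrubland,OTHER,
glc_fcs30d,153,Sparse herbaceous,OTHER,
glc_fcs30d,181,Swamp,FOREST,Woody wetland counted as forest; conservative for non-forested wetland.
glc_fcs30d,182,Marsh,NONFOREST_WETLAND,
glc_fcs30d,183,Flooded flat,NONFOREST_WETLAND,
glc_fcs30d,184,Saline,NONFOREST_WETLAND,
glc_fcs30d,185,Mangrove,FOREST,Woody wetland counted as forest; conservative for non-forested wetland.
glc_fcs30d,186,Salt marsh,NONFOREST_WETLAND,
glc_fcs30d,187,Tidal flat,NONFOREST_WETLAND,
glc_fcs30d,190,Impervious surface,OTHER,
glc_fcs30d,200,Bare areas,OTHER,
glc_fcs30d,201,Consolidated bare areas,OTHER,
glc_fcs30d,202,Unconsolidated bare areas,OTHER,
glc_fcs30d,210,Water body,OTHER,
glc_fcs30d,220,Permanent ice and snow,OTHER,
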