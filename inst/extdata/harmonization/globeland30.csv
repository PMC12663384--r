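dataset_id,native_code,native_label,harmonized_code,note
globeland30,10,Cultivated land,CULTIVATED,Includes cultivated grassland (pasture); excludes tree crops. GlobeLand30 2020 legend.
globeland30,20,Forestland,FOREST,
globeland30,30,Grassland,GRASS_SHRUB,
globeland30,40,Shrubland,GRASS_SHRUB,
globeland30,50,Wetland,NONFOREST_WETLAND,Entire wetland class treated as non-forested wetland; never counted as forest (no forested/non-forested split available).
globeland30,60,Water bodies,OTHER,
globeland30,70,Tundra,OTHER,Tundra kept out of grassland & shrubland; classification standards differ across products.
globeland30,80,Artificial surfaces,OTHER,
globeland30,90,Bareland,OTHER,
globeland30,100,Permanent snow and ice,OTHER,
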