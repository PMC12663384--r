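dataset_id,native_code,native_label,harmonized_code,note
glcluc,1,Terra firma short vegetation and tree cover < 5 m,GRASS_SHRUB,Tree-height split follows the FAO forest definition (trees taller than 5 m). GLCLUC 2000-2020 aggregate thematic legend.
glcluc,2,Tree cover >= 5 m (incl. forested wetlands),FOREST,
glcluc,3,Wetland short vegetation and tree cover < 5 m,NONFOREST_WETLAND,
glcluc,4,Open surface water present 20-79% of the year,NONFOREST_WETLAND,
glcluc,5,Cropland,CULTIVATED,Herbaceous crops only; excludes tree crops and cultivated grassland.
glcluc,6,Built-up,OTHER,
glcluc,7,Permanent open surface water,OTHER,
glcluc,8,Permanent snow and ice,OTHER,
glcluc,9,Bare ground and sparse vegetation,OTHER,
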