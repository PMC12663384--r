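dataset_id,native_code,native_label,harmonized_code,note
synthetic,1,Cultivated,CULTIVATED,Identity mapping for synthetic landscapes.
synthetic,2,Grassland and shrubland,GRASS_SHRUB,
synthetic,3,Non-forested wetland,NONFOREST_WETLAND,
synthetic,4,Forestland,FOREST,
synthetic,5,Other,OTHER,
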