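class,long_name,emission_factor_ug_per_g_per_h,density_g_per_m2
tropical_evergreen_forest,Tropical evergreen forest/woodland,5.9,11
tropical_deciduous_forest,Tropical deciduous forest/woodland,5.9,8
temperate_broadleaf_evergreen_forest,Temperate broadleaf evergreen forest/woodland,1.77,3
temperate_needleleaf_evergreen_forest,Temperate needleleaf evergreen forest/woodland,1.77,3
temperate_deciduous_forest,Temperate deciduous forest/woodland,1.77,3
boreal_evergreen_forest,Boreal evergreen forest/woodland,1.77,3
boreal_deciduous_forest,Boreal deciduous forest/woodland,1.77,3
mixed_forest,Evergreen/deciduous mixed forest/woodland,1.77,3
savanna,Savanna,5.175,5.78
grassland,Grassland/steppe,1.77,5.2
dense_shrubland,Dense shrubland,5.1,8.43
open_shrubland,Open shrubland,5.25,0.98
tundra,Tundra,0,0
desert,Desert,1,3.1
polar_desert,Polar desert/rock/ice,0,0
cropland,Cropland,3.45,3.815
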