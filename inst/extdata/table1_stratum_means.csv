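direction,stratum,mean,ci_half
cropland to grassland,0-10 cm,21.5,0.4
cropland to grassland,10-30 cm,10.9,0.6
cropland to grassland,30-60 cm,7.7,0.6
cropland to grassland,60-90 cm,4.5,0.4
cropland to grassland,Overall,44.6,1.1
cropland to grassland,Mineral soil,44.6,1.1
grassland to cropland,0-10 cm,-21.2,1.4
grassland to cropland,10-30 cm,-8.9,2.7
grassland to cropland,30-60 cm,-6.0,2.0
grassland to cropland,60-90 cm,-4.6,2.0
grassland to cropland,Overall,-40.7,4.6
grassland to cropland,Mineral soil,-40.7,4.6
cropland to forest,litter,19.7,0.4
cropland to forest,0-10 cm,19.1,0.4
cropland to forest,10-30 cm,-5.2,0.6
cropland to forest,30-60 cm,3.9,0.7
cropland to forest,60-90 cm,2.9,0.5
cropland to forest,Overall,40.4,1.2
cropland to forest,Mineral soil,20.7,1.6
forest to cropland,litter,-20.2,1.1
forest to cropland,0-10 cm,-16.3,0.8
forest to cropland,10-30 cm,6.6,0.9
forest to cropland,30-60 cm,-3.7,0.9
forest to cropland,60-90 cm,-1.3,0.7
forest to cropland,Overall,-34.9,2.2
forest to cropland,Mineral soil,-14.7,1.8
grassland to forest,litter,20.6,1.1
grassland to forest,0-10 cm,-2.2,1.5
grassland to forest,10-30 cm,-15.7,3.6
grassland to forest,30-60 cm,-4.2,3.4
grassland to forest,60-90 cm,-1.2,2.4
grassland to forest,Overall,-2.7,6.4
grassland to forest,Mineral soil,-23.3,6.3
forest to grassland,litter,-19.8,1.0
forest to grassland,0-10 cm,4.3,0.7
forest to grassland,10-30 cm,14.4,1.0
forest to grassland,30-60 cm,4.1,0.9
forest to grassland,60-90 cm,2.2,0.7
forest to grassland,Overall,5.2,2.2
forest to grassland,Mineral soil,25.0,1.9
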