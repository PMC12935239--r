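scenario,ghg,eutrophication,water,arable_land,pasture_land,total_land,biodiversity,colorectal_dalys,diabetes_dalys,ihd_dalys,total_dalys,female_managers,farm_labour_female,female_farm_managers,affordability_ppp,gom_change,employment_change,local_multiplier_change
0%,0.8,4.5,19.9,0.4,1.9,2.3,28.6,0,0,0,0,9140,11110,3950,0.38,0,0,0
25%,0.6,3.5,17.8,0.4,1.4,1.8,22.6,-1.6,-0.4,-3.8,-5.9,9436,11353,4236,0.31,"13,21","−11,99","0,62"
50%,0.4,2.4,15.8,0.3,0.9,1.3,16.5,-3.2,-0.7,-7.2,-11.1,9732,11596,4521,0.24,"26,42","−23,99","1,25"
75%,0.2,1.4,13.7,0.3,0.5,0.8,10.5,-4.6,-1.1,-10,-15.8,10027,11839,4807,0.17,"39,63","−35,98","1,87"
100%,0,0.3,11.7,0.3,0,0.3,4.4,-6,-1.4,-12.6,-20,10323,12082,5092,0.10,"52,84","−47,97","2,50"
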