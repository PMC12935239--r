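scenario,ghg,eutrophication,water,arable_land,pasture_land,total_land,biodiversity,colorectal_dalys,diabetes_dalys,ihd_dalys,total_dalys,female_managers,farm_labour_female,female_farm_managers,affordability_ppp,gom_change,employment_change,local_multiplier_change
0%,1.2,4,33.5,0.8,0.3,1,54.4,0,0,0,0,520,1570,280,1.1,0,0,0
25%,0.9,3.1,29.5,0.7,0.2,0.9,42.4,-5.4,-1.1,-4.1,-10.7,882,2678,456,0.85,"−7,90","−22,26","0,62"
50%,0.6,2.2,25.5,0.6,0.1,0.7,30.5,-10.7,-2.1,-7.9,-20.8,1243,3786,632,0.61,"−15,79","−44,53","1,25"
75%,0.4,1.3,21.4,0.5,0.1,0.5,18.5,-15.9,-3.1,-11.5,-30.5,1605,4894,807,0.36,"−23,69","−66,79","1,87"
100%,0.1,0.5,17.4,0.4,0,0.4,6.6,-20.9,-4.1,-14.7,-39.7,1966,6002,983,0.12,"−31,59","−89,05","2,50"
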