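scenario,profitability,diet_health,biodiversity,climate_change,water_use,land_use,pollution
0%,0,0,54.4,1.2,33.5,1,4
25%,-7.90,-10.7,42.4,0.9,29.5,0.9,3.1
50%,-15.79,-20.8,30.5,0.6,25.5,0.7,2.2
75%,-23.69,-30.5,18.5,0.4,21.4,0.5,1.3
100%,-31.59,-39.7,6.6,0.1,17.4,0.4,0.5
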