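country,scenario,printed
PT,100%,102.37
PT,75%,80.05
PT,50%,57.07
PT,25%,40.89
PT,0%,16.99
DK,100%,97.9
DK,75%,67.8
DK,50%,43
DK,25%,28.7
DK,0%,2.3
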