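B0BN85
D3ZBM7
D4AE41
F1LNJ2
F1LQ48
F1M386
O35346
O35821
P04256
P07153
P10686
P12001
P13471
P20171
P21272
P41123
P48679
P62193
P62243
P62268
P62890
P68255
P84586
P86182
Q4KLM4
Q4VSI4
Q5MJ12
Q62829
Q63009
Q68FS2
Q6AY09
Q6AYK6
Q6RUV5
Q80W83
Q9JJ31
Q9R085
Q9Z269
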