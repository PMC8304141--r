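signature	accession
SHAM_ONLY	P04256
SHAM_ONLY	P12001
SHAM_ONLY	P13471
SHAM_ONLY	P62193
SHAM_ONLY	P68255
SHAM_ONLY	P84586
SHAM_ONLY	P86182
SHAM_ONLY	Q4VSI4
SHAM_ONLY	Q5MJ12
SHAM_ONLY	Q63009
SHAM_ONLY	Q6AY09
SHAM_ONLY	Q6AYK6
SHAM_ONLY	Q80W83
SHAM_ONLY	Q9R085
SHAM_ONLY	Q9Z269
TEM	F1LQ48
TEM	P48679
TEM	P62243
TEM	Q4KLM4
TEM	Q68FS2
SMI	B0BN85
SMI	D4AE41
SMI	F1LNJ2
SMI	F1M386
SMI	O35346
SMI	P07153
SMI	P20171
SMI	P21272
SMI	Q62829
SMI	Q9JJ31
PSM	D3ZBM7
PSM	O35821
PSM	P10686
PSM	P41123
PSM	P62268
PSM	P62890
PSM	Q6RUV5
IMPAIRED	B0BN85
IMPAIRED	D4AE41
IMPAIRED	F1LNJ2
IMPAIRED	F1LQ48
IMPAIRED	F1M386
IMPAIRED	O35346
IMPAIRED	P07153
IMPAIRED	P20171
IMPAIRED	P21272
IMPAIRED	P48679
IMPAIRED	P62243
IMPAIRED	Q4KLM4
IMPAIRED	Q62829
IMPAIRED	Q68FS2
IMPAIRED	Q9JJ31
FUNCTIONAL	D3ZBM7
FUNCTIONAL	F1LQ48
FUNCTIONAL	O35821
FUNCTIONAL	P10686
FUNCTIONAL	P41123
FUNCTIONAL	P48679
FUNCTIONAL	P62243
FUNCTIONAL	P62268
FUNCTIONAL	P62890
FUNCTIONAL	Q4KLM4
FUNCTIONAL	Q68FS2
FUNCTIONAL	Q6RUV5
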