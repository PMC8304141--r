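accession	membership_class	ups_matched
A1A5R8	UNIQUE	FALSE
P11951	UNIQUE	FALSE
P38438	UNIQUE	FALSE
Q4G017	UNIQUE	FALSE
Q6AXV4	UNIQUE	FALSE
Q8K4T4	UNIQUE	FALSE
B0BNE5	UNIQUE	FALSE
P12001	UNIQUE	TRUE
P53678	UNIQUE	FALSE
Q4KLZ4	UNIQUE	FALSE
Q6AY09	UNIQUE	TRUE
Q99MZ4	UNIQUE	FALSE
B2DD29	UNIQUE	FALSE
P13471	UNIQUE	TRUE
P55053	UNIQUE	FALSE
Q4VSI4	UNIQUE	TRUE
Q6AY30	UNIQUE	FALSE
Q99PF5	UNIQUE	FALSE
B2GV54	UNIQUE	FALSE
P15429	UNIQUE	FALSE
P56603	UNIQUE	FALSE
Q5FVQ8	UNIQUE	FALSE
Q6AY41	UNIQUE	FALSE
Q9ESB5	UNIQUE	FALSE
B2RZ37	UNIQUE	FALSE
P15431	UNIQUE	FALSE
P60892	UNIQUE	FALSE
Q5MJ12	UNIQUE	TRUE
Q6AYH5	UNIQUE	FALSE
Q9JHU0	UNIQUE	FALSE
B2RZ78	UNIQUE	FALSE
P15800	UNIQUE	FALSE
P62193	UNIQUE	TRUE
Q5U2Z5	UNIQUE	FALSE
Q6AYK6	UNIQUE	TRUE
Q9QYL8	UNIQUE	FALSE
D3ZEY4	UNIQUE	FALSE
P20069	UNIQUE	FALSE
P62824	UNIQUE	FALSE
Q62656	UNIQUE	FALSE
Q6MG06	UNIQUE	FALSE
Q9R085	UNIQUE	TRUE
D3ZGS3	UNIQUE	FALSE
P22062	UNIQUE	FALSE
P62959	UNIQUE	FALSE
Q62824	UNIQUE	FALSE
Q6MG49	UNIQUE	FALSE
Q9R0I8	UNIQUE	FALSE
D4ABY2	UNIQUE	FALSE
P23576	UNIQUE	FALSE
P68255	UNIQUE	TRUE
Q63009	UNIQUE	TRUE
Q6MG55	UNIQUE	FALSE
Q9R1N3	UNIQUE	FALSE
F1LSG8	UNIQUE	FALSE
P23965	UNIQUE	FALSE
P84586	UNIQUE	TRUE
Q63100	UNIQUE	FALSE
Q6MG60	UNIQUE	FALSE
Q9WU70	UNIQUE	FALSE
O35274	UNIQUE	FALSE
P26817	UNIQUE	FALSE
P86182	UNIQUE	TRUE
Q63633	UNIQUE	FALSE
Q6P7S1	UNIQUE	FALSE
Q9Z1C7	UNIQUE	FALSE
O54701	UNIQUE	FALSE
P29411	UNIQUE	FALSE
Q01066	UNIQUE	FALSE
Q63881	UNIQUE	FALSE
Q78P75	UNIQUE	FALSE
Q9Z269	UNIQUE	TRUE
P00564	UNIQUE	FALSE
P31422	UNIQUE	FALSE
Q02356	UNIQUE	FALSE
Q64232	UNIQUE	FALSE
Q7M6Z5	UNIQUE	FALSE
Q9Z2X5	UNIQUE	FALSE
P01026	UNIQUE	FALSE
P31424	UNIQUE	FALSE
Q1WIM2	UNIQUE	FALSE
Q64640	UNIQUE	FALSE
Q80W83	UNIQUE	TRUE
P04256	UNIQUE	TRUE
P31977	UNIQUE	FALSE
Q4FZT0	UNIQUE	FALSE
Q66H20	UNIQUE	FALSE
Q811X6	UNIQUE	FALSE
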