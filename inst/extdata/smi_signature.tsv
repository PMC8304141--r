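accession	membership_class	ups_matched
B0BN85	UNIQUE	TRUE
P15178	UNIQUE	FALSE
P60901	BOTH	FALSE
Q4KM49	UNIQUE	FALSE
Q6P7Q4	UPREGULATED	FALSE
B0BNF1	UNIQUE	FALSE
P15865	UPREGULATED	FALSE
P61203	UPREGULATED	FALSE
Q4V8I7	UNIQUE	FALSE
Q6QIX3	UPREGULATED	FALSE
D4AE41	UNIQUE	TRUE
P18163	UNIQUE	FALSE
P61227	UPREGULATED	FALSE
Q505J8	UNIQUE	FALSE
Q7TQ94	UPREGULATED	FALSE
F1LNJ2	UNIQUE	TRUE
P20171	UNIQUE	TRUE
P62024	UNIQUE	FALSE
Q569C2	UNIQUE	FALSE
Q80W89	UPREGULATED	FALSE
F1M386	UNIQUE	TRUE
P21272	UNIQUE	TRUE
P62250	UPREGULATED	FALSE
Q5HZA6	UNIQUE	FALSE
Q8VHW5	UNIQUE	FALSE
O35179	UNIQUE	FALSE
P29101	UNIQUE	FALSE
P62914	UPREGULATED	FALSE
Q5U216	UNIQUE	FALSE
Q9JHL4	UPREGULATED	FALSE
O35314	UNIQUE	FALSE
P31647	UPREGULATED	FALSE
P63045	UNIQUE	FALSE
Q5XIE8	UNIQUE	FALSE
Q9JJ31	UNIQUE	TRUE
O35346	UNIQUE	TRUE
P37285	UNIQUE	FALSE
P69682	BOTH	FALSE
Q5XIF3	UPREGULATED	FALSE
Q9JKE3	UNIQUE	FALSE
P02650	UPREGULATED	FALSE
P40307	UPREGULATED	FALSE
P70619	UNIQUE	FALSE
Q5XIG8	UPREGULATED	FALSE
Q9JMJ4	UPREGULATED	FALSE
P04631	UPREGULATED	FALSE
P47863	UPREGULATED	FALSE
P84092	UPREGULATED	FALSE
Q5XIT1	UPREGULATED	FALSE
Q9WV63	UPREGULATED	FALSE
P04785	UPREGULATED	FALSE
P48768	UPREGULATED	FALSE
Q08602	UPREGULATED	FALSE
Q62829	UNIQUE	TRUE
Q9Z0W7	UNIQUE	FALSE
P07153	UNIQUE	TRUE
P51635	UPREGULATED	FALSE
Q32ZG1	UNIQUE	FALSE
Q63635	UNIQUE	FALSE
Q9Z142	UPREGULATED	FALSE
P09895	UPREGULATED	FALSE
P55051	UPREGULATED	FALSE
Q3B8Q0	BOTH	FALSE
Q64591	UNIQUE	FALSE
Q9Z1N1	UNIQUE	FALSE
P0C5X8	UNIQUE	FALSE
P56536	UNIQUE	FALSE
Q499P2	UPREGULATED	FALSE
Q66X93	UNIQUE	FALSE
P11232	UPREGULATED	FALSE
P59215	UPREGULATED	FALSE
Q4FZT2	UPREGULATED	FALSE
Q68FP1	UPREGULATED	FALSE
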