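accession	membership_class	ups_matched
B5DF41	UNIQUE	FALSE
P25093	UPREGULATED	FALSE
P62890	UNIQUE	TRUE
Q3ZB98	UNIQUE	FALSE
Q8K4M9	UNIQUE	FALSE
D3ZBM7	UNIQUE	TRUE
P25809	UNIQUE	FALSE
P63029	UNIQUE	FALSE
Q497B0	UNIQUE	FALSE
Q91Z79	UNIQUE	FALSE
D4A6D8	UNIQUE	FALSE
P40329	BOTH	FALSE
P63088	UNIQUE	FALSE
Q4V882	UNIQUE	FALSE
Q99M64	UNIQUE	FALSE
O08557	UNIQUE	FALSE
P41123	UNIQUE	TRUE
P69735	UNIQUE	FALSE
Q5M7U6	UPREGULATED	FALSE
Q99PE7	UNIQUE	FALSE
O35821	UNIQUE	TRUE
P46101	UNIQUE	FALSE
P83868	UPREGULATED	FALSE
Q5PQN0	UNIQUE	FALSE
Q9ER24	UPREGULATED	FALSE
O54922	UNIQUE	FALSE
P46844	UNIQUE	FALSE
P84087	UPREGULATED	FALSE
Q5U2T3	UNIQUE	FALSE
Q9JLA3	UPREGULATED	FALSE
O55043	UNIQUE	FALSE
P47987	UNIQUE	FALSE
P85970	UNIQUE	FALSE
Q5XHY5	UNIQUE	FALSE
Q9QVC8	UPREGULATED	FALSE
P10686	UNIQUE	TRUE
P61107	UNIQUE	FALSE
P97837	UNIQUE	FALSE
Q62717	UNIQUE	FALSE
Q9WTT2	UNIQUE	FALSE
P13264	UPREGULATED	FALSE
P62268	UNIQUE	TRUE
Q05695	UPREGULATED	FALSE
Q63228	UNIQUE	FALSE
Q9WVK7	UNIQUE	FALSE
P19468	UPREGULATED	FALSE
P62853	UNIQUE	FALSE
Q07205	UNIQUE	FALSE
Q6RUV5	UNIQUE	TRUE
Q9Z0V6	UPREGULATED	FALSE
P20650	UPREGULATED	FALSE
P62859	UNIQUE	FALSE
Q07310	UNIQUE	FALSE
Q812D1	UNIQUE	FALSE
Q9Z270	UPREGULATED	FALSE
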