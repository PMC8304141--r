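accession	membership_class	ups_matched
F1LQ48	UNIQUE	TRUE
P13803	UNIQUE	FALSE
Q07303	UNIQUE	FALSE
Q4KLM4	UNIQUE	TRUE
O35763	UNIQUE	FALSE
P14604	UNIQUE	FALSE
Q02874	UNIQUE	FALSE
Q5M9I5	UNIQUE	FALSE
O70511	UNIQUE	FALSE
P18484	UNIQUE	FALSE
P62243	UNIQUE	TRUE
Q63803	UNIQUE	FALSE
P09330	UNIQUE	FALSE
P21396	UNIQUE	FALSE
P53676	UNIQUE	FALSE
Q68FS2	UNIQUE	TRUE
P13638	UNIQUE	FALSE
P26772	UNIQUE	FALSE
P48679	UNIQUE	TRUE
Q91XU8	UNIQUE	FALSE
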