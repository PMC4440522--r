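gene_id	ES	MCP	CM	SM	EC
POU5F1	850	95	2	3	4
NANOG	400	60	1	2	1
ISL1	2	280	90	70	60
TNNT2	0.5	45	900	30	8
MYH6	0.2	20	500	15	5
CDH5	1	10	5	8	400
GAPDH	1000	1100	950	1050	980
COL1A1	200	120	70	40	25
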