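tracking_id	gene_id	sample	FPKM	FPKM_status
FGFR1.ex3	FGFR1	ES	150	OK
FGFR1.ex3	FGFR1	MCP	120	OK
FGFR1.ex3	FGFR1	CM	10	OK
FGFR1.ex3	FGFR1	SM	12	OK
FGFR1.ex3	FGFR1	EC	9	OK
FGFR1.skip	FGFR1	ES	8	OK
FGFR1.skip	FGFR1	MCP	15	OK
FGFR1.skip	FGFR1	CM	140	OK
FGFR1.skip	FGFR1	SM	130	OK
FGFR1.skip	FGFR1	EC	125	OK
FGFR1.frag	FGFR1	ES	999	LOWDATA
GAPDH.1	GAPDH	ES	900	OK
GAPDH.1	GAPDH	MCP	950	OK
GAPDH.1	GAPDH	CM	880	OK
GAPDH.1	GAPDH	SM	920	OK
GAPDH.1	GAPDH	EC	910	OK
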