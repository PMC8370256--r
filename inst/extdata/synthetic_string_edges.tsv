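VCL	VCL_N01	0.9
VCL	VCL_N02	0.9
VCL	VCL_N03	0.9
VCL	VCL_N04	0.9
VCL	VCL_N05	0.9
VCL	VCL_N06	0.9
VCL	VCL_N07	0.9
VCL	VCL_N08	0.9
VCL	VCL_N09	0.9
VCL	VCL_N10	0.9
VCL	VCL_N11	0.9
VCL	VCL_N12	0.9
VCL	VCL_N13	0.9
VCL	VCL_N14	0.9
VCL	VCL_N15	0.9
VCL	VCL_N16	0.9
VCL	VCL_N17	0.9
CTNNB1	CTNNB1_N01	0.9
CTNNB1	CTNNB1_N02	0.9
CTNNB1	CTNNB1_N03	0.9
CTNNB1	CTNNB1_N04	0.9
CTNNB1	CTNNB1_N05	0.9
CTNNB1	CTNNB1_N06	0.9
CTNNB1	CTNNB1_N07	0.9
CTNNB1	CTNNB1_N08	0.9
CTNNB1	CTNNB1_N09	0.9
CTNNB1	CTNNB1_N10	0.9
CTNNB1	CTNNB1_N11	0.9
CTNNB1	CTNNB1_N12	0.9
CTNNB1	CTNNB1_N13	0.9
CTNNB1	CTNNB1_N14	0.9
MAPK3	MAPK3_N01	0.9
MAPK3	MAPK3_N02	0.9
MAPK3	MAPK3_N03	0.9
MAPK3	MAPK3_N04	0.9
MAPK3	MAPK3_N05	0.9
MAPK3	MAPK3_N06	0.9
MAPK3	MAPK3_N07	0.9
MAPK3	MAPK3_N08	0.9
MAPK3	MAPK3_N09	0.9
MAPK3	MAPK3_N10	0.9
MAPK3	MAPK3_N11	0.9
MAPK3	MAPK3_N12	0.9
CTNNA1	CTNNA1_N01	0.9
CTNNA1	CTNNA1_N02	0.9
CTNNA1	CTNNA1_N03	0.9
CTNNA1	CTNNA1_N04	0.9
CTNNA1	CTNNA1_N05	0.9
CTNNA1	CTNNA1_N06	0.9
CTNNA1	CTNNA1_N07	0.9
CTNNA1	CTNNA1_N08	0.9
CTNNA1	CTNNA1_N09	0.9
CTNNA1	CTNNA1_N10	0.9
CTNNA1	CTNNA1_N11	0.9
CTNNA1	CTNNA1_N12	0.9
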