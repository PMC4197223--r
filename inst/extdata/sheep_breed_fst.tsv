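breed	PIN	COM	SAB	VDB	CHI	CAS	MER	SAW	LAC	LEC
PIN	0	0.025	0.065	0.041	0.086	0.033	0.038	0.046	0.041	0.030
COM	0.025	0	0.080	0.051	0.096	0.045	0.051	0.060	0.054	0.040
SAB	0.065	0.080	0	0.090	0.139	0.078	0.080	0.059	0.083	0.075
VDB	0.041	0.051	0.090	0	0.112	0.059	0.063	0.071	0.066	0.054
CHI	0.086	0.096	0.139	0.112	0	0.096	0.099	0.120	0.103	0.095
CAS	0.033	0.045	0.078	0.059	0.096	0	0.038	0.060	0.044	0.038
MER	0.038	0.051	0.080	0.063	0.099	0.038	0	0.061	0.048	0.043
SAW	0.046	0.060	0.059	0.071	0.120	0.060	0.061	0	0.064	0.054
LAC	0.041	0.054	0.083	0.066	0.103	0.044	0.048	0.064	0	0.047
LEC	0.030	0.040	0.075	0.054	0.095	0.038	0.043	0.054	0.047	0
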