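breed,RHF,FGV,DFV,MWF,BBV,OBV,API,SIC,HRI,HRP,PMT,RMG,HRB,IMB,NDA,Dbar_EST
RHF,,0.166,0.185,0.190,0.220,0.174,0.153,0.134,0.162,0.241,0.120,0.199,0.103,0.119,0.318,0.177
FGV,0.087,,0.077,0.129,0.161,0.109,0.112,0.074,0.117,0.207,0.065,0.156,0.061,0.087,0.273,0.128
DFV,0.097,0.051,,0.125,0.157,0.107,0.119,0.061,0.123,0.213,0.070,0.166,0.065,0.100,0.278,0.132
MWF,0.100,0.074,0.075,,0.167,0.122,0.134,0.104,0.137,0.223,0.092,0.177,0.084,0.111,0.282,0.148
BBV,0.122,0.098,0.099,0.104,,0.114,0.167,0.135,0.163,0.253,0.124,0.200,0.121,0.147,0.312,0.174
OBV,0.093,0.066,0.067,0.073,0.078,,0.115,0.081,0.109,0.205,0.068,0.153,0.058,0.086,0.267,0.126
API,0.080,0.065,0.069,0.075,0.099,0.069,,0.046,0.109,0.199,0.065,0.150,0.055,0.076,0.266,0.126
SIC,0.071,0.047,0.043,0.061,0.082,0.052,0.033,,0.078,0.174,0.033,0.122,0.022,0.045,0.243,0.097
HRI,0.082,0.065,0.069,0.076,0.095,0.064,0.062,0.047,,0.166,0.061,0.102,0.043,0.061,0.240,0.119
HRP,0.131,0.118,0.124,0.128,0.152,0.120,0.113,0.099,0.096,,0.160,0.210,0.137,0.153,0.293,0.202
PMT,0.065,0.043,0.047,0.056,0.077,0.047,0.042,0.028,0.041,0.093,,0.099,0.012,0.024,0.227,0.087
RMG,0.108,0.092,0.099,0.103,0.124,0.094,0.088,0.074,0.065,0.126,0.065,,0.086,0.102,0.256,0.155
HRB,0.055,0.037,0.041,0.048,0.070,0.039,0.035,0.019,0.029,0.077,0.015,0.054,,0.008,0.204,0.076
IMB,0.060,0.048,0.055,0.059,0.081,0.050,0.044,0.030,0.036,0.084,0.022,0.060,0.010,,0.219,0.095
NDA,0.179,0.163,0.170,0.172,0.197,0.165,0.158,0.145,0.145,0.190,0.138,0.167,0.120,0.125,,0.263
Gbar_ST,0.095,0.075,0.079,0.086,0.105,0.077,0.074,0.059,0.069,0.118,0.056,0.094,0.046,0.054,0.160,
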