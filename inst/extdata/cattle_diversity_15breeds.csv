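breed,N,nA,mA,npA,nrA,H_O,H_O_snp,H_E,AR
RHF,50,34474,6.93,465,602,0.709,0.342,0.703,6.050
FGV,49,35178,7.08,319,472,0.713,0.334,0.699,6.160
DFV,50,34674,6.97,238,393,0.700,0.326,0.687,6.018
MWF,46,31627,6.36,227,306,0.717,0.334,0.681,5.594
BBV,50,31006,6.24,158,251,0.660,0.307,0.647,5.355
OBV,35,33344,6.71,251,367,0.701,0.325,0.688,6.082
API,50,37987,7.64,451,676,0.716,0.335,0.706,6.493
SIC,26,34807,7.00,237,422,0.737,0.343,0.718,6.695
HRI,30,36364,7.31,380,603,0.719,0.331,0.711,6.735
HRP,24,26053,5.24,219,299,0.681,0.312,0.642,5.101
PMT,22,36084,7.26,430,526,0.738,0.343,0.721,7.141
RMG,21,30170,6.07,305,368,0.680,0.312,0.667,6.031
HRB,24,40116,8.07,664,847,0.702,0.324,0.746,7.771
IMB,43,44416,8.93,1307,1467,0.743,0.344,0.748,7.620
NDA,,30135,6.06,875,801,0.581,0.237,0.589,5.332
All,477,58632,11.79,6526,4200,0.699,0.323,0.690,6.279
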