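locus,ne1p,ne2p,nePp,neI,neSi
BM1824,0.681,0.507,0.324,0.118,0.415
BM2113,0.670,0.493,0.305,0.112,0.411
ETH10,0.608,0.429,0.245,0.082,0.381
ETH225,0.719,0.542,0.353,0.138,0.439
ETH3,0.641,0.463,0.283,0.096,0.393
INRA023,0.588,0.409,0.221,0.075,0.377
SPS115,0.679,0.502,0.314,0.117,0.417
TGLA122,0.479,0.311,0.140,0.043,0.339
TGLA126,0.741,0.563,0.372,0.152,0.455
TGLA227,0.467,0.302,0.133,0.041,0.336
TGLA53,0.366,0.223,0.078,0.022,0.311
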