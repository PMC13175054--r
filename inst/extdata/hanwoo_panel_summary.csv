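locus,k,N,hObs,hExp,pic,fis
BM1824,11,778544,0.732,0.730,0.684,-0.0038
BM2113,17,778544,0.736,0.733,0.692,-0.0034
ETH10,12,778544,0.780,0.778,0.745,-0.0020
ETH225,11,778544,0.693,0.691,0.649,-0.0022
ETH3,15,778544,0.764,0.763,0.723,-0.0017
INRA023,16,778544,0.788,0.784,0.755,-0.0040
SPS115,15,778544,0.727,0.724,0.683,-0.0040
TGLA122,28,778544,0.846,0.843,0.825,-0.0028
TGLA126,9,778544,0.669,0.665,0.625,-0.0053
TGLA227,19,778544,0.851,0.849,0.831,-0.0024
TGLA53,19,778544,0.891,0.890,0.880,-0.0014
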