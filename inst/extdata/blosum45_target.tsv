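# BLOSUM45 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	1.572232e-02	1.777474e-03	2.407824e-03	2.332575e-03	1.429861e-03	2.532442e-03	2.722906e-03	5.594309e-03	1.065592e-03	4.073583e-03	4.748453e-03	4.303245e-03	1.483517e-03	1.938892e-03	2.473925e-03	6.012915e-03	3.937843e-03	5.335942e-04	1.423602e-03	4.428820e-03
R	1.777474e-03	7.804469e-03	1.653334e-03	1.574745e-03	4.975766e-04	2.201179e-03	1.864797e-03	1.886112e-03	9.236735e-04	1.421060e-03	2.129106e-03	5.883065e-03	8.106189e-04	1.092074e-03	1.075069e-03	2.101689e-03	1.721814e-03	2.996161e-04	9.737044e-04	1.545212e-03
N	2.407824e-03	1.653334e-03	7.463800e-03	3.427720e-03	6.912010e-04	1.929837e-03	2.030005e-03	3.353605e-03	1.273331e-03	1.931903e-03	1.857163e-03	3.239324e-03	7.075672e-04	1.153952e-03	1.214801e-03	3.589304e-03	2.370824e-03	2.124296e-04	8.523241e-04	1.352220e-03
D	2.332575e-03	1.574745e-03	3.427720e-03	1.324210e-02	6.562601e-04	2.218014e-03	3.878077e-03	3.084195e-03	1.191215e-03	1.503067e-03	2.192495e-03	3.781599e-03	6.657715e-04	9.049847e-04	1.778327e-03	3.398262e-03	2.261860e-03	2.443503e-04	9.791887e-04	1.595366e-03
C	1.429861e-03	4.975766e-04	6.912010e-04	6.562601e-04	1.053331e-02	5.564262e-04	6.267629e-04	1.006598e-03	2.985867e-04	9.268395e-04	1.389144e-03	9.769858e-04	4.132954e-04	7.044780e-04	4.522602e-04	1.347995e-03	1.131280e-03	9.705041e-05	3.947043e-04	1.248464e-03
Q	2.532442e-03	2.201179e-03	1.929837e-03	2.218014e-03	5.564262e-04	7.897791e-03	3.343638e-03	2.183626e-03	1.278234e-03	1.968614e-03	2.416754e-03	4.256942e-03	1.138569e-03	7.858542e-04	1.551668e-03	3.008378e-03	1.963534e-03	3.486250e-04	1.105082e-03	1.397630e-03
E	2.722906e-03	1.864797e-03	2.030005e-03	3.878077e-03	6.267629e-04	3.343638e-03	9.224402e-03	2.311755e-03	1.121657e-03	1.722660e-03	2.605647e-03	4.561077e-03	7.953809e-04	1.079573e-03	2.105255e-03	3.196019e-03	2.145705e-03	3.014858e-04	9.607941e-04	1.539045e-03
G	5.594309e-03	1.886112e-03	3.353605e-03	3.084195e-03	1.006598e-03	2.183626e-03	2.311755e-03	3.030348e-02	1.169657e-03	2.260189e-03	3.290434e-03	3.758003e-03	1.284466e-03	1.715699e-03	2.208623e-03	5.247564e-03	2.750976e-03	5.872332e-04	1.227390e-03	2.394818e-03
H	1.065592e-03	9.236735e-04	1.273331e-03	1.191215e-03	2.985867e-04	1.278234e-03	1.121657e-03	1.169657e-03	5.593789e-03	8.504629e-04	1.275433e-03	1.446001e-03	6.134840e-04	6.716585e-04	6.598978e-04	1.260708e-03	8.341717e-04	1.407975e-04	1.146372e-03	7.214126e-04
I	4.073583e-03	1.421060e-03	1.931903e-03	1.503067e-03	9.268395e-04	1.968614e-03	1.722660e-03	2.260189e-03	8.504629e-04	1.661379e-02	9.875171e-03	2.777169e-03	2.949879e-03	3.269644e-03	2.041383e-03	3.032901e-03	3.208094e-03	5.475922e-04	2.230233e-03	9.243659e-03
L	4.748453e-03	2.129106e-03	1.857163e-03	2.192495e-03	1.389144e-03	2.416754e-03	2.605647e-03	3.290434e-03	1.275433e-03	9.875171e-03	2.384448e-02	3.379066e-03	3.697856e-03	4.892968e-03	1.896329e-03	2.955550e-03	3.830143e-03	6.787381e-04	2.629493e-03	6.921328e-03
K	4.303245e-03	5.883065e-03	3.239324e-03	3.781599e-03	9.769858e-04	4.256942e-03	4.561077e-03	3.758003e-03	1.446001e-03	2.777169e-03	3.379066e-03	1.836583e-02	1.552328e-03	1.678638e-03	2.685596e-03	4.170515e-03	3.422532e-03	5.773084e-04	1.851137e-03	2.963212e-03
M	1.483517e-03	8.106189e-04	7.075672e-04	6.657715e-04	4.132954e-04	1.138569e-03	7.953809e-04	1.284466e-03	6.134840e-04	2.949879e-03	3.697856e-03	1.552328e-03	2.766422e-03	1.166407e-03	7.308115e-04	1.124114e-03	1.165177e-03	2.077528e-04	8.250451e-04	2.060647e-03
F	1.938892e-03	1.092074e-03	1.153952e-03	9.049847e-04	7.044780e-04	7.858542e-04	1.079573e-03	1.715699e-03	6.716585e-04	3.269644e-03	4.892968e-03	1.678638e-03	1.166407e-03	1.216459e-02	9.622354e-04	1.859984e-03	1.925748e-03	6.758573e-04	2.796253e-03	2.731844e-03
P	2.473925e-03	1.075069e-03	1.214801e-03	1.778327e-03	4.522602e-04	1.551668e-03	2.105255e-03	2.208623e-03	6.598978e-04	2.041383e-03	1.896329e-03	2.685596e-03	7.308115e-04	9.622354e-04	1.584362e-02	2.365479e-03	2.004015e-03	2.625110e-04	6.954086e-04	1.414302e-03
S	6.012915e-03	2.101689e-03	3.589304e-03	3.398262e-03	1.347995e-03	3.008378e-03	3.196019e-03	5.247564e-03	1.260708e-03	3.032901e-03	2.955550e-03	4.170515e-03	1.124114e-03	1.859984e-03	2.365479e-03	1.145278e-02	5.876569e-03	3.262068e-04	1.335150e-03	3.295003e-03
T	3.937843e-03	1.721814e-03	2.370824e-03	2.261860e-03	1.131280e-03	1.963534e-03	2.145705e-03	2.750976e-03	8.341717e-04	3.208094e-03	3.830143e-03	3.422532e-03	1.165177e-03	1.925748e-03	2.004015e-03	5.876569e-03	9.760205e-03	3.414973e-04	1.351539e-03	3.532932e-03
W	5.335942e-04	2.996161e-04	2.124296e-04	2.443503e-04	9.705041e-05	3.486250e-04	3.014858e-04	5.872332e-04	1.407975e-04	5.475922e-04	6.787381e-04	5.773084e-04	2.077528e-04	6.758573e-04	2.625110e-04	3.262068e-04	3.414973e-04	4.589493e-03	7.315292e-04	3.839230e-04
Y	1.423602e-03	9.737044e-04	8.523241e-04	9.791887e-04	3.947043e-04	1.105082e-03	9.607941e-04	1.227390e-03	1.146372e-03	2.230233e-03	2.629493e-03	1.851137e-03	8.250451e-04	2.796253e-03	6.954086e-04	1.335150e-03	1.351539e-03	7.315292e-04	6.015875e-03	1.541888e-03
V	4.428820e-03	1.545212e-03	1.352220e-03	1.595366e-03	1.248464e-03	1.397630e-03	1.539045e-03	2.394818e-03	7.214126e-04	9.243659e-03	6.921328e-03	2.963212e-03	2.060647e-03	2.731844e-03	1.414302e-03	3.295003e-03	3.532932e-03	3.839230e-04	1.541888e-03	1.214911e-02
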