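# BLOSUM40 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	1.790632e-02	2.794505e-03	3.006611e-03	3.556999e-03	1.441729e-03	2.950586e-03	4.746646e-03	8.692378e-03	1.341786e-03	5.532203e-03	4.625207e-03	4.501866e-03	2.240152e-03	2.356475e-03	2.877160e-03	5.582744e-03	4.118958e-03	6.344147e-04	2.087633e-03	5.232888e-03
R	2.794505e-03	9.912378e-03	1.872529e-03	1.899129e-03	6.347138e-04	2.221211e-03	2.543840e-03	2.357622e-03	1.003037e-03	2.058270e-03	2.427106e-03	4.756409e-03	1.182394e-03	1.479622e-03	1.283367e-03	2.086585e-03	1.555583e-03	4.003416e-04	1.324196e-03	1.963425e-03
N	3.006611e-03	1.872529e-03	6.813433e-03	2.904622e-03	6.933068e-04	1.686329e-03	2.302003e-03	3.591567e-03	1.088260e-03	2.241044e-03	1.858439e-03	2.556746e-03	9.024769e-04	1.136904e-03	1.366949e-03	2.659956e-03	1.977923e-03	2.554452e-04	9.956499e-04	1.496126e-03
D	3.556999e-03	1.899129e-03	2.904622e-03	1.165609e-02	8.054624e-04	1.452390e-03	4.607303e-03	3.036075e-03	1.090919e-03	1.888484e-03	2.226179e-03	3.032144e-03	8.955991e-04	1.121792e-03	1.664570e-03	2.673317e-03	1.986830e-03	2.583976e-04	1.016166e-03	1.781336e-03
C	1.441729e-03	6.347138e-04	6.933068e-04	8.054624e-04	8.817664e-03	4.106661e-04	1.085579e-03	1.196317e-03	2.603832e-04	9.019611e-04	1.251174e-03	8.647704e-04	4.279337e-04	7.462997e-04	4.664434e-04	1.058115e-03	9.428640e-04	1.018647e-04	3.985951e-04	1.016203e-03
Q	2.950586e-03	2.221211e-03	1.686329e-03	1.452390e-03	4.106661e-04	4.743087e-03	3.209596e-03	2.094102e-03	7.655464e-04	1.583781e-03	1.840009e-03	2.535203e-03	8.991360e-04	7.803371e-04	1.166923e-03	2.194683e-03	1.393577e-03	3.536525e-04	9.965033e-04	1.234748e-03
E	4.746646e-03	2.543840e-03	2.302003e-03	4.607303e-03	1.085579e-03	3.209596e-03	1.440759e-02	3.373086e-03	1.434378e-03	2.515193e-03	3.506959e-03	4.815970e-03	1.416753e-03	1.767064e-03	3.060585e-03	3.537602e-03	2.624084e-03	5.642953e-04	1.585742e-03	2.359931e-03
G	8.692378e-03	2.357622e-03	3.591567e-03	3.036075e-03	1.196317e-03	2.094102e-03	3.373086e-03	2.975538e-02	1.337445e-03	3.283517e-03	3.280159e-03	3.763102e-03	1.867285e-03	2.309434e-03	3.323627e-03	4.701568e-03	2.893889e-03	7.451970e-04	1.747061e-03	2.621133e-03
H	1.341786e-03	1.003037e-03	1.088260e-03	1.090919e-03	2.603832e-04	7.655464e-04	1.434378e-03	1.337445e-03	4.597561e-03	9.920129e-04	1.173917e-03	1.141569e-03	7.980650e-04	7.061817e-04	7.330494e-04	1.005412e-03	7.421536e-04	1.154778e-04	1.052678e-03	6.676260e-04
I	5.532203e-03	2.058270e-03	2.241044e-03	1.888484e-03	9.019611e-04	1.583781e-03	2.515193e-03	3.283517e-03	9.920129e-04	1.645938e-02	8.199680e-03	2.807823e-03	2.831639e-03	4.109491e-03	2.532145e-03	2.907033e-03	3.062159e-03	5.650024e-04	2.599438e-03	9.284176e-03
L	4.625207e-03	2.427106e-03	1.858439e-03	2.226179e-03	1.251174e-03	1.840009e-03	3.506959e-03	3.280159e-03	1.173917e-03	8.199680e-03	1.612501e-02	3.248687e-03	3.906135e-03	4.864398e-03	1.779653e-03	2.440282e-03	3.050210e-03	7.751732e-04	2.576150e-03	6.439431e-03
K	4.501866e-03	4.756409e-03	2.556746e-03	3.032144e-03	8.647704e-04	2.535203e-03	4.815970e-03	3.763102e-03	1.141569e-03	2.807823e-03	3.248687e-03	1.076211e-02	1.594316e-03	1.680054e-03	2.443272e-03	3.323289e-03	2.914584e-03	5.388807e-04	1.762991e-03	2.621823e-03
M	2.240152e-03	1.182394e-03	9.024769e-04	8.955991e-04	4.279337e-04	8.991360e-04	1.416753e-03	1.867285e-03	7.980650e-04	2.831639e-03	3.906135e-03	1.594316e-03	3.180082e-03	1.399970e-03	1.000766e-03	1.179265e-03	1.238737e-03	2.711691e-04	1.229174e-03	2.216387e-03
F	2.356475e-03	1.479622e-03	1.136904e-03	1.121792e-03	7.462997e-04	7.803371e-04	1.767064e-03	2.309434e-03	7.061817e-04	4.109491e-03	4.864398e-03	1.680054e-03	1.399970e-03	9.957043e-03	1.068917e-03	1.747858e-03	1.822207e-03	6.667286e-04	3.097010e-03	2.779743e-03
P	2.877160e-03	1.283367e-03	1.366949e-03	1.664570e-03	4.664434e-04	1.166923e-03	3.060585e-03	3.323627e-03	7.330494e-04	2.532145e-03	1.779653e-03	2.443272e-03	1.000766e-03	1.068917e-03	1.478227e-02	2.119086e-03	2.211849e-03	2.872592e-04	9.445368e-04	1.673456e-03
S	5.582744e-03	2.086585e-03	2.659956e-03	2.673317e-03	1.058115e-03	2.194683e-03	3.537602e-03	4.701568e-03	1.005412e-03	2.907033e-03	2.440282e-03	3.323289e-03	1.179265e-03	1.747858e-03	2.119086e-03	6.983654e-03	3.688328e-03	2.851731e-04	1.313970e-03	2.756732e-03
T	4.118958e-03	1.555583e-03	1.977923e-03	1.986830e-03	9.428640e-04	1.393577e-03	2.624084e-03	2.893889e-03	7.421536e-04	3.062159e-03	3.050210e-03	2.914584e-03	1.238737e-03	1.822207e-03	2.211849e-03	3.688328e-03	6.406239e-03	2.967167e-04	1.354349e-03	3.411808e-03
W	6.344147e-04	4.003416e-04	2.554452e-04	2.583976e-04	1.018647e-04	3.536525e-04	5.642953e-04	7.451970e-04	1.154778e-04	5.650024e-04	7.751732e-04	5.388807e-04	2.711691e-04	6.667286e-04	2.872592e-04	2.851731e-04	2.967167e-04	3.987157e-03	7.058321e-04	4.425409e-04
Y	2.087633e-03	1.324196e-03	9.956499e-04	1.016166e-03	3.985951e-04	9.965033e-04	1.585742e-03	1.747061e-03	1.052678e-03	2.599438e-03	2.576150e-03	1.762991e-03	1.229174e-03	3.097010e-03	9.445368e-04	1.313970e-03	1.354349e-03	7.058321e-04	5.550768e-03	1.747772e-03
V	5.232888e-03	1.963425e-03	1.496126e-03	1.781336e-03	1.016203e-03	1.234748e-03	2.359931e-03	2.621133e-03	6.676260e-04	9.284176e-03	6.439431e-03	2.621823e-03	2.216387e-03	2.779743e-03	1.673456e-03	2.756732e-03	3.411808e-03	4.425409e-04	1.747772e-03	8.843863e-03
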