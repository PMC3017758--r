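# BLOSUM65 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	2.929333e-02	2.769404e-03	1.905738e-03	2.306415e-03	1.835228e-03	1.875582e-03	3.250258e-03	5.749320e-03	1.017100e-03	3.373816e-03	4.661537e-03	3.720213e-03	1.631604e-03	2.167757e-03	2.122356e-03	7.427886e-03	4.687818e-03	4.835920e-04	1.317864e-03	5.539325e-03
R	2.769404e-03	1.738951e-02	1.935002e-03	1.306591e-03	2.804160e-04	2.059648e-03	2.556206e-03	1.537750e-03	1.116918e-03	9.862856e-04	2.349585e-03	5.824508e-03	6.687949e-04	8.879106e-04	8.187530e-04	2.042398e-03	1.870291e-03	2.748166e-04	7.321497e-04	1.134040e-03
N	1.905738e-03	1.935002e-03	1.461379e-02	3.262836e-03	3.479197e-04	1.318664e-03	2.257786e-03	2.178611e-03	1.359036e-03	8.464890e-04	1.173531e-03	2.599308e-03	5.581437e-04	7.620299e-04	7.373505e-04	3.500013e-03	2.340180e-03	1.726455e-04	6.484416e-04	9.812348e-04
D	2.306415e-03	1.306591e-03	3.262836e-03	2.237274e-02	3.085194e-04	1.581841e-03	5.370652e-03	2.397283e-03	8.744511e-04	1.054533e-03	1.390905e-03	2.260367e-03	4.867205e-04	7.175204e-04	9.668982e-04	3.133227e-03	2.061892e-03	1.607483e-04	5.540338e-04	1.158893e-03
C	1.835228e-03	2.804160e-04	3.479197e-04	3.085194e-04	1.094509e-02	2.416020e-04	3.018192e-04	5.427389e-04	1.749315e-04	9.126984e-04	1.525101e-03	4.532935e-04	3.106667e-04	5.640947e-04	2.704089e-04	9.433463e-04	8.564303e-04	1.670925e-04	3.198507e-04	1.014901e-03
Q	1.875582e-03	2.059648e-03	1.318664e-03	1.581841e-03	2.416020e-04	7.135407e-03	3.238929e-03	1.049399e-03	9.885035e-04	6.362951e-04	1.552924e-03	2.703571e-03	8.191317e-04	5.582672e-04	7.292383e-04	1.843042e-03	1.202197e-03	2.503655e-04	5.014861e-04	9.901578e-04
E	3.250258e-03	2.556206e-03	2.257786e-03	5.370652e-03	3.018192e-04	3.238929e-03	1.600960e-02	1.745205e-03	1.221785e-03	1.056808e-03	1.887407e-03	4.535930e-03	7.026274e-04	9.370950e-04	1.296562e-03	3.175655e-03	2.062098e-03	2.948195e-04	7.862894e-04	1.295430e-03
G	5.749320e-03	1.537750e-03	2.178611e-03	2.397283e-03	5.427389e-04	1.049399e-03	1.745205e-03	3.600238e-02	7.933346e-04	9.948423e-04	1.731601e-03	2.107023e-03	6.546712e-04	1.175589e-03	1.097243e-03	3.887652e-03	1.861357e-03	3.995081e-04	6.939310e-04	1.473642e-03
H	1.017100e-03	1.116918e-03	1.359036e-03	8.744511e-04	1.749315e-04	9.885035e-04	1.221785e-03	7.933346e-04	8.424180e-03	4.612303e-04	8.594525e-04	1.036086e-03	3.163722e-04	8.546661e-04	3.980976e-04	9.967866e-04	6.452904e-04	1.869832e-04	1.394485e-03	5.248176e-04
I	3.373816e-03	9.862856e-04	8.464890e-04	1.054533e-03	9.126984e-04	6.362951e-04	1.056808e-03	9.948423e-04	4.612303e-04	1.379000e-02	1.168452e-02	1.251395e-03	2.240903e-03	3.004702e-03	7.221697e-04	1.673801e-03	2.264147e-03	4.372963e-04	1.226436e-03	1.065396e-02
L	4.661537e-03	2.349585e-03	1.173531e-03	1.390905e-03	1.525101e-03	1.552924e-03	1.887407e-03	1.731601e-03	8.594525e-04	1.168452e-02	4.261184e-02	2.343372e-03	5.526081e-03	5.398371e-03	1.253448e-03	2.331084e-03	3.769300e-03	8.133495e-04	2.204618e-03	9.307760e-03
K	3.720213e-03	5.824508e-03	2.599308e-03	2.260367e-03	4.532935e-04	2.703571e-03	4.535930e-03	2.107023e-03	1.036086e-03	1.251395e-03	2.343372e-03	2.002985e-02	8.460244e-04	1.086909e-03	1.487325e-03	3.649168e-03	2.350859e-03	3.349893e-04	9.208989e-04	1.863157e-03
M	1.631604e-03	6.687949e-04	5.581437e-04	4.867205e-04	3.106667e-04	8.191317e-04	7.026274e-04	6.546712e-04	3.163722e-04	2.240903e-03	5.526081e-03	8.460244e-04	5.405361e-03	1.381461e-03	3.428940e-04	8.449661e-04	1.036799e-03	2.260154e-04	5.590560e-04	2.414977e-03
F	2.167757e-03	8.879106e-04	7.620299e-04	7.175204e-04	5.640947e-04	5.582672e-04	9.370950e-04	1.175589e-03	8.546661e-04	3.004702e-03	5.398371e-03	1.086909e-03	1.381461e-03	2.162794e-02	4.461562e-04	1.479278e-03	1.385741e-03	1.179762e-03	4.415808e-03	2.352851e-03
P	2.122356e-03	8.187530e-04	7.373505e-04	9.668982e-04	2.704089e-04	7.292383e-04	1.296562e-03	1.097243e-03	3.980976e-04	7.221697e-04	1.253448e-03	1.487325e-03	3.428940e-04	4.461562e-04	1.784252e-02	1.470945e-03	1.325395e-03	1.358908e-04	3.615899e-04	1.066649e-03
S	7.427886e-03	2.042398e-03	3.500013e-03	3.133227e-03	9.433463e-04	1.843042e-03	3.175655e-03	3.887652e-03	9.967866e-04	1.673801e-03	2.331084e-03	3.649168e-03	8.449661e-04	1.479278e-03	1.470945e-03	1.457902e-02	4.699852e-03	3.405507e-04	9.241763e-04	1.950385e-03
T	4.687818e-03	1.870291e-03	2.340180e-03	2.061892e-03	8.564303e-04	1.202197e-03	2.062098e-03	1.861357e-03	6.452904e-04	2.264147e-03	3.769300e-03	2.350859e-03	1.036799e-03	1.385741e-03	1.325395e-03	4.699852e-03	1.619067e-02	3.293391e-04	8.304136e-04	3.512706e-03
W	4.835920e-04	2.748166e-04	1.726455e-04	1.607483e-04	1.670925e-04	2.503655e-04	2.948195e-04	3.995081e-04	1.869832e-04	4.372963e-04	8.133495e-04	3.349893e-04	2.260154e-04	1.179762e-03	1.358908e-04	3.405507e-04	3.293391e-04	8.694882e-03	9.666288e-04	3.640346e-04
Y	1.317864e-03	7.321497e-04	6.484416e-04	5.540338e-04	3.198507e-04	5.014861e-04	7.862894e-04	6.939310e-04	1.394485e-03	1.226436e-03	2.204618e-03	9.208989e-04	5.590560e-04	4.415808e-03	3.615899e-04	9.241763e-04	8.304136e-04	9.666288e-04	1.001288e-02	1.313626e-03
V	5.539325e-03	1.134040e-03	9.812348e-04	1.158893e-03	1.014901e-03	9.901578e-04	1.295430e-03	1.473642e-03	5.248176e-04	1.065396e-02	9.307760e-03	1.863157e-03	2.414977e-03	2.352851e-03	1.066649e-03	1.950385e-03	3.512706e-03	3.640346e-04	1.313626e-03	1.651613e-02
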