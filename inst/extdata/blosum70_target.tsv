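# BLOSUM70 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	2.918515e-02	2.282169e-03	1.926049e-03	2.367588e-03	1.522708e-03	1.771369e-03	3.335726e-03	5.946521e-03	9.624325e-04	2.979317e-03	4.532896e-03	3.391965e-03	1.455283e-03	2.097691e-03	2.048100e-03	7.943281e-03	4.365883e-03	3.727914e-04	1.306029e-03	5.057028e-03
R	2.282169e-03	2.013894e-02	1.737640e-03	1.441075e-03	3.113574e-04	2.133850e-03	2.825007e-03	1.344117e-03	1.159402e-03	1.190954e-03	1.984714e-03	5.709298e-03	6.417010e-04	9.169683e-04	8.642878e-04	2.312154e-03	1.842950e-03	2.252533e-04	7.766460e-04	1.110922e-03
N	1.926049e-03	1.737640e-03	1.659137e-02	3.601593e-03	3.781760e-04	1.356519e-03	2.458325e-03	2.350411e-03	1.112814e-03	7.921059e-04	1.209032e-03	2.543482e-03	5.281807e-04	7.827111e-04	7.369048e-04	3.176575e-03	2.335799e-03	1.398526e-04	6.825990e-04	9.555933e-04
D	2.367588e-03	1.441075e-03	3.601593e-03	2.538531e-02	3.342659e-04	1.260219e-03	4.757239e-03	2.058357e-03	8.898669e-04	9.737705e-04	1.424414e-03	2.177462e-03	4.570990e-04	7.480386e-04	9.760922e-04	3.491121e-03	2.020115e-03	1.280205e-04	4.601370e-04	8.954343e-04
C	1.522708e-03	3.113574e-04	3.781760e-04	3.342659e-04	1.258846e-02	2.464556e-04	3.233124e-04	5.800129e-04	1.395607e-04	1.120245e-03	1.300446e-03	3.482274e-04	2.995931e-04	5.961909e-04	2.715200e-04	1.082207e-03	8.572344e-04	1.131984e-04	2.772794e-04	1.008279e-03
Q	1.771369e-03	2.133850e-03	1.356519e-03	1.260219e-03	2.464556e-04	6.925590e-03	3.388576e-03	1.033222e-03	9.369600e-04	6.947202e-04	1.481313e-03	2.409338e-03	7.171505e-04	5.310319e-04	5.371211e-04	1.921182e-03	1.101933e-03	1.856513e-04	4.890661e-04	8.944633e-04
E	3.335726e-03	2.825007e-03	2.458325e-03	4.757239e-03	3.233124e-04	3.388576e-03	1.827888e-02	1.899235e-03	1.285400e-03	9.948083e-04	1.946410e-03	4.466556e-03	6.727899e-04	7.688159e-04	1.338974e-03	3.639566e-03	2.031875e-03	1.899256e-04	6.593150e-04	1.262911e-03
G	5.946521e-03	1.344117e-03	2.350411e-03	2.058357e-03	5.800129e-04	1.033222e-03	1.899235e-03	3.974897e-02	7.868240e-04	1.135515e-03	1.765086e-03	2.000920e-03	6.101044e-04	9.622295e-04	8.762812e-04	3.453138e-03	1.817861e-03	3.170704e-04	5.816364e-04	1.128708e-03
H	9.624325e-04	1.159402e-03	1.112814e-03	8.898669e-04	1.395607e-04	9.369600e-04	1.285400e-03	7.868240e-04	8.284742e-03	4.022927e-04	8.260606e-04	9.145677e-04	2.748952e-04	8.118652e-04	3.772715e-04	1.044394e-03	5.862421e-04	1.426463e-04	1.446893e-03	4.725864e-04
I	2.979317e-03	1.190954e-03	7.921059e-04	9.737705e-04	1.120245e-03	6.947202e-04	9.948083e-04	1.135515e-03	4.022927e-04	1.835585e-02	1.339571e-02	1.308442e-03	2.334817e-03	3.407501e-03	7.919018e-04	1.639884e-03	2.410805e-03	3.099241e-04	1.410133e-03	1.141619e-02
L	4.532896e-03	1.984714e-03	1.209032e-03	1.424414e-03	1.300446e-03	1.481313e-03	1.946410e-03	1.765086e-03	8.260606e-04	1.339571e-02	4.316464e-02	2.151350e-03	5.092288e-03	5.343382e-03	1.231182e-03	2.494185e-03	2.812797e-03	6.423728e-04	2.280901e-03	8.867361e-03
K	3.391965e-03	5.709298e-03	2.543482e-03	2.177462e-03	3.482274e-04	2.409338e-03	4.466556e-03	2.000920e-03	9.145677e-04	1.308442e-03	2.151350e-03	1.775342e-02	7.088352e-04	9.919670e-04	1.338502e-03	3.616478e-03	2.066132e-03	2.384162e-04	8.629028e-04	1.281427e-03
M	1.455283e-03	6.417010e-04	5.281807e-04	4.570990e-04	2.995931e-04	7.171505e-04	6.727899e-04	6.101044e-04	2.748952e-04	2.334817e-03	5.092288e-03	7.088352e-04	4.649140e-03	1.271602e-03	3.051624e-04	8.248517e-04	8.996758e-04	1.599417e-04	5.127293e-04	2.090566e-03
F	2.097691e-03	9.169683e-04	7.827111e-04	7.480386e-04	5.961909e-04	5.310319e-04	7.688159e-04	9.622295e-04	8.118652e-04	3.407501e-03	5.343382e-03	9.919670e-04	1.271602e-03	2.189753e-02	4.306800e-04	1.266509e-03	1.295269e-03	9.123827e-04	4.568028e-03	2.194926e-03
P	2.048100e-03	8.642878e-04	7.369048e-04	9.760922e-04	2.715200e-04	5.371211e-04	1.338974e-03	8.762812e-04	3.772715e-04	7.919018e-04	1.231182e-03	1.338502e-03	3.051624e-04	4.306800e-04	1.786792e-02	1.552683e-03	1.204011e-03	1.020234e-04	3.554922e-04	7.760867e-04
S	7.943281e-03	2.312154e-03	3.176575e-03	3.491121e-03	1.082207e-03	1.921182e-03	3.639566e-03	3.453138e-03	1.044394e-03	1.639884e-03	2.494185e-03	3.616478e-03	8.248517e-04	1.266509e-03	1.552683e-03	1.772919e-02	4.790774e-03	2.845555e-04	1.026190e-03	1.959382e-03
T	4.365883e-03	1.842950e-03	2.335799e-03	2.020115e-03	8.572344e-04	1.101933e-03	2.031875e-03	1.817861e-03	5.862421e-04	2.410805e-03	2.812797e-03	2.066132e-03	8.996758e-04	1.295269e-03	1.204011e-03	4.790774e-03	1.505464e-02	2.385671e-04	8.041199e-04	3.147595e-03
W	3.727914e-04	2.252533e-04	1.398526e-04	1.280205e-04	1.131984e-04	1.856513e-04	1.899256e-04	3.170704e-04	1.426463e-04	3.099241e-04	6.423728e-04	2.384162e-04	1.599417e-04	9.123827e-04	1.020234e-04	2.845555e-04	2.385671e-04	6.952452e-03	8.022791e-04	2.661969e-04
Y	1.306029e-03	7.766460e-04	6.825990e-04	4.601370e-04	2.772794e-04	4.890661e-04	6.593150e-04	5.816364e-04	1.446893e-03	1.410133e-03	2.280901e-03	8.629028e-04	5.127293e-04	4.568028e-03	3.554922e-04	1.026190e-03	8.041199e-04	8.022791e-04	1.116850e-02	1.007021e-03
V	5.057028e-03	1.110922e-03	9.555933e-04	8.954343e-04	1.008279e-03	8.944633e-04	1.262911e-03	1.128708e-03	4.725864e-04	1.141619e-02	8.867361e-03	1.281427e-03	2.090566e-03	2.194926e-03	7.760867e-04	1.959382e-03	3.147595e-03	2.661969e-04	1.007021e-03	1.496391e-02
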