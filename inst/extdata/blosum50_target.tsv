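# BLOSUM50 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	2.138694e-02	3.081442e-03	2.804864e-03	2.495622e-03	1.359186e-03	2.001813e-03	4.218724e-03	5.632991e-03	1.285704e-03	4.417233e-03	5.356383e-03	3.408765e-03	1.103632e-03	2.028893e-03	2.597165e-03	6.095291e-03	4.983602e-03	5.461823e-04	1.788933e-03	5.163976e-03
R	3.081442e-03	1.811448e-02	2.132368e-03	1.841728e-03	4.934602e-04	2.305043e-03	3.836905e-03	2.050671e-03	1.483292e-03	1.655503e-03	3.109941e-03	6.246948e-03	6.526889e-04	1.468073e-03	1.210164e-03	2.742218e-03	2.859647e-03	3.976997e-04	1.586585e-03	1.910248e-03
N	2.804864e-03	2.132368e-03	9.767019e-03	3.350144e-03	5.586675e-04	1.366049e-03	2.839349e-03	2.995448e-03	1.393766e-03	1.511235e-03	1.818315e-03	2.305482e-03	4.635046e-04	8.747076e-04	1.119340e-03	3.238709e-03	2.667299e-03	2.304127e-04	9.565714e-04	1.364520e-03
D	2.495622e-03	1.841728e-03	3.350144e-03	1.461094e-02	4.058539e-04	1.471787e-03	5.026695e-03	2.551417e-03	9.784804e-04	1.326152e-03	1.962871e-03	2.043182e-03	3.339831e-04	7.658778e-04	1.515307e-03	2.808216e-03	2.332888e-03	2.040479e-04	8.333916e-04	1.236023e-03
C	1.359186e-03	4.934602e-04	5.586675e-04	4.058539e-04	8.452184e-03	3.070652e-04	6.580296e-04	7.034675e-04	2.523752e-04	8.671808e-04	1.324879e-03	5.344177e-04	2.196255e-04	6.238807e-04	3.302719e-04	9.502331e-04	9.981935e-04	8.656173e-05	3.550723e-04	1.022901e-03
Q	2.001813e-03	2.305043e-03	1.366049e-03	1.471787e-03	3.070652e-04	4.680280e-03	3.178328e-03	1.312419e-03	9.531294e-04	1.050065e-03	1.952126e-03	2.504270e-03	5.197743e-04	5.940806e-04	9.735644e-04	1.810905e-03	1.480821e-03	3.131157e-04	8.389347e-04	9.732049e-04
E	4.218724e-03	3.836905e-03	2.839349e-03	5.026695e-03	6.580296e-04	3.178328e-03	1.730829e-02	2.247451e-03	1.603580e-03	1.804247e-03	3.341806e-03	4.299907e-03	6.886346e-04	1.575537e-03	2.117452e-03	3.117229e-03	3.161699e-03	4.333263e-04	1.413741e-03	2.072299e-03
G	5.632991e-03	2.050671e-03	2.995448e-03	2.551417e-03	7.034675e-04	1.312419e-03	2.247451e-03	2.888108e-02	1.071129e-03	1.823958e-03	2.735962e-03	2.254233e-03	5.936576e-04	1.349046e-03	1.722170e-03	3.981810e-03	2.609927e-03	4.572871e-04	1.158068e-03	1.731664e-03
H	1.285704e-03	1.483292e-03	1.393766e-03	9.784804e-04	2.523752e-04	9.531294e-04	1.603580e-03	1.071129e-03	6.397462e-03	6.948056e-04	1.291134e-03	1.280288e-03	3.406541e-04	9.500890e-04	6.207810e-04	1.152517e-03	9.565408e-04	1.636721e-04	1.370039e-03	6.327318e-04
I	4.417233e-03	1.655503e-03	1.511235e-03	1.326152e-03	8.671808e-04	1.050065e-03	1.804247e-03	1.823958e-03	6.948056e-04	1.526896e-02	1.120955e-02	1.778494e-03	1.842228e-03	3.396293e-03	1.418889e-03	2.047187e-03	3.316478e-03	4.637292e-04	1.919972e-03	1.081044e-02
L	5.356383e-03	3.109941e-03	1.818315e-03	1.962871e-03	1.324879e-03	1.952126e-03	3.341806e-03	2.735962e-03	1.291134e-03	1.120955e-02	3.397618e-02	2.720627e-03	3.453365e-03	6.300441e-03	1.659879e-03	2.989967e-03	4.893569e-03	8.531179e-04	2.811609e-03	8.246886e-03
K	3.408765e-03	6.246948e-03	2.305482e-03	2.043182e-03	5.344177e-04	2.504270e-03	4.299907e-03	2.254233e-03	1.280288e-03	1.778494e-03	2.720627e-03	1.091785e-02	5.737258e-04	1.036246e-03	1.673209e-03	3.027294e-03	2.569230e-03	3.508919e-04	1.157143e-03	1.700858e-03
M	1.103632e-03	6.526889e-04	4.635046e-04	3.339831e-04	2.196255e-04	5.197743e-04	6.886346e-04	5.936576e-04	3.406541e-04	1.842228e-03	3.453365e-03	5.737258e-04	1.460388e-03	8.392744e-04	3.546515e-04	6.315687e-04	8.240835e-04	1.757850e-04	5.844744e-04	1.365978e-03
F	2.028893e-03	1.468073e-03	8.747076e-04	7.658778e-04	6.238807e-04	5.940806e-04	1.575537e-03	1.349046e-03	9.500890e-04	3.396293e-03	6.300441e-03	1.036246e-03	8.392744e-04	1.524581e-02	7.789583e-04	1.454179e-03	1.892232e-03	8.246881e-04	4.179308e-03	2.487130e-03
P	2.597165e-03	1.210164e-03	1.119340e-03	1.515307e-03	3.302719e-04	9.735644e-04	2.117452e-03	1.722170e-03	6.207810e-04	1.418889e-03	1.659879e-03	1.673209e-03	3.546515e-04	7.789583e-04	1.617178e-02	1.863106e-03	1.968347e-03	2.108154e-04	6.828111e-04	1.288989e-03
S	6.095291e-03	2.742218e-03	3.238709e-03	2.808216e-03	9.502331e-04	1.810905e-03	3.117229e-03	3.981810e-03	1.152517e-03	2.047187e-03	2.989967e-03	3.027294e-03	6.315687e-04	1.454179e-03	1.863106e-03	1.065515e-02	5.615645e-03	3.042677e-04	1.262177e-03	2.358947e-03
T	4.983602e-03	2.859647e-03	2.667299e-03	2.332888e-03	9.981935e-04	1.480821e-03	3.161699e-03	2.609927e-03	9.565408e-04	3.316478e-03	4.893569e-03	2.569230e-03	8.240835e-04	1.892232e-03	1.968347e-03	5.615645e-03	1.206371e-02	4.059006e-04	1.341374e-03	3.884834e-03
W	5.461823e-04	3.976997e-04	2.304127e-04	2.040479e-04	8.656173e-05	3.131157e-04	4.333263e-04	4.572871e-04	1.636721e-04	4.637292e-04	8.531179e-04	3.508919e-04	1.757850e-04	8.246881e-04	2.108154e-04	3.042677e-04	4.059006e-04	5.632024e-03	7.410223e-04	4.133344e-04
Y	1.788933e-03	1.586585e-03	9.565714e-04	8.333916e-04	3.550723e-04	8.389347e-04	1.413741e-03	1.158068e-03	1.370039e-03	1.919972e-03	2.811609e-03	1.157143e-03	5.844744e-04	4.179308e-03	6.828111e-04	1.262177e-03	1.341374e-03	7.410223e-04	7.615320e-03	1.698698e-03
V	5.163976e-03	1.910248e-03	1.364520e-03	1.236023e-03	1.022901e-03	9.732049e-04	2.072299e-03	1.731664e-03	6.327318e-04	1.081044e-02	8.246886e-03	1.700858e-03	1.365978e-03	2.487130e-03	1.288989e-03	2.358947e-03	3.884834e-03	4.133344e-04	1.698698e-03	1.266387e-02
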