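# BLOSUM55 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	2.332969e-02	2.625179e-03	2.266199e-03	2.919534e-03	1.764182e-03	2.594129e-03	3.557182e-03	6.205078e-03	1.211575e-03	3.146444e-03	4.953889e-03	4.160268e-03	1.480441e-03	1.892575e-03	2.863913e-03	6.075845e-03	4.994866e-03	4.888158e-04	1.816694e-03	6.869403e-03
R	2.625179e-03	1.498858e-02	1.670292e-03	1.713825e-03	4.076750e-04	2.412240e-03	2.609135e-03	1.785885e-03	1.130331e-03	1.112929e-03	2.263700e-03	6.155084e-03	6.893684e-04	1.064929e-03	1.052244e-03	1.784941e-03	2.274034e-03	3.397315e-04	1.063688e-03	1.958316e-03
N	2.266199e-03	1.670292e-03	1.104248e-02	3.679091e-03	4.446598e-04	1.632263e-03	2.233577e-03	3.022041e-03	1.226873e-03	9.666841e-04	1.510940e-03	2.615576e-03	4.731031e-04	7.385511e-04	1.117366e-03	2.468709e-03	2.462573e-03	1.882631e-04	8.976376e-04	1.356335e-03
D	2.919534e-03	1.713825e-03	3.679091e-03	1.983895e-02	4.656375e-04	2.156244e-03	4.779472e-03	2.612439e-03	1.019183e-03	1.250653e-03	1.635052e-03	2.761265e-03	4.907191e-04	7.816182e-04	1.529141e-03	2.581266e-03	2.577609e-03	2.433639e-04	9.361390e-04	1.775449e-03
C	1.764182e-03	4.076750e-04	4.446598e-04	4.656375e-04	9.119736e-03	3.289251e-04	4.443276e-04	7.616390e-04	1.962023e-04	7.622013e-04	1.231414e-03	5.302310e-04	2.970726e-04	4.819506e-04	4.350990e-04	7.771195e-04	9.850366e-04	1.174847e-04	3.661492e-04	1.351176e-03
Q	2.594129e-03	2.412240e-03	1.632263e-03	2.156244e-03	3.289251e-04	7.693598e-03	3.339702e-03	1.754506e-03	1.129552e-03	8.991557e-04	1.823554e-03	3.806169e-03	8.650044e-04	6.766950e-04	1.303450e-03	1.810346e-03	1.794848e-03	3.464421e-04	1.044480e-03	1.571341e-03
E	3.557182e-03	2.609135e-03	2.233577e-03	4.779472e-03	4.443276e-04	3.339702e-03	1.421022e-02	1.948763e-03	1.008694e-03	1.206336e-03	1.979628e-03	4.222612e-03	6.036819e-04	9.495932e-04	1.813591e-03	2.438810e-03	2.475959e-03	3.678691e-04	1.134952e-03	2.134305e-03
G	6.205078e-03	1.785885e-03	3.022041e-03	2.612439e-03	7.616390e-04	1.754506e-03	1.948763e-03	3.410049e-02	1.041301e-03	1.323852e-03	2.124413e-03	2.833360e-03	8.027738e-04	1.279344e-03	1.596002e-03	3.363414e-03	2.658413e-03	5.141637e-04	1.003975e-03	2.326642e-03
H	1.211575e-03	1.130331e-03	1.226873e-03	1.019183e-03	1.962023e-04	1.129552e-03	1.008694e-03	1.041301e-03	6.674210e-03	5.221772e-04	1.040356e-03	1.398721e-03	3.293786e-04	8.005242e-04	5.008750e-04	8.396611e-04	8.404889e-04	1.629750e-04	1.287315e-03	7.379188e-04
I	3.146444e-03	1.112929e-03	9.666841e-04	1.250653e-03	7.622013e-04	8.991557e-04	1.206336e-03	1.323852e-03	5.221772e-04	1.294282e-02	8.523633e-03	1.433906e-03	2.011414e-03	2.551234e-03	1.212143e-03	1.334171e-03	2.656968e-03	4.053244e-04	1.573573e-03	1.172357e-02
L	4.953889e-03	2.263700e-03	1.510940e-03	1.635052e-03	1.231414e-03	1.823554e-03	1.979628e-03	2.124413e-03	1.040356e-03	8.523633e-03	3.340609e-02	2.848143e-03	4.071185e-03	5.064868e-03	1.559991e-03	2.104473e-03	3.493876e-03	6.660843e-04	2.502432e-03	9.478538e-03
K	4.160268e-03	6.155084e-03	2.615576e-03	2.761265e-03	5.302310e-04	3.806169e-03	4.222612e-03	2.833360e-03	1.398721e-03	1.433906e-03	2.848143e-03	1.582705e-02	8.770658e-04	1.091701e-03	2.101461e-03	2.871606e-03	2.900884e-03	3.583065e-04	1.345395e-03	2.543714e-03
M	1.480441e-03	6.893684e-04	4.731031e-04	4.907191e-04	2.970726e-04	8.650044e-04	6.036819e-04	8.027738e-04	3.293786e-04	2.011414e-03	4.071185e-03	8.770658e-04	3.072821e-03	9.902144e-04	4.799700e-04	6.480615e-04	1.027834e-03	2.008090e-04	6.200391e-04	2.292765e-03
F	1.892575e-03	1.064929e-03	7.385511e-04	7.816182e-04	4.819506e-04	6.766950e-04	9.495932e-04	1.279344e-03	8.005242e-04	2.551234e-03	5.064868e-03	1.091701e-03	9.902144e-04	1.547821e-02	6.067478e-04	1.029915e-03	1.345701e-03	9.742733e-04	3.869284e-03	2.842348e-03
P	2.863913e-03	1.052244e-03	1.117366e-03	1.529141e-03	4.350990e-04	1.303450e-03	1.813591e-03	1.596002e-03	5.008750e-04	1.212143e-03	1.559991e-03	2.101461e-03	4.799700e-04	6.067478e-04	1.882124e-02	1.568725e-03	1.993761e-03	1.941297e-04	5.933664e-04	1.736327e-03
S	6.075845e-03	1.784941e-03	2.468709e-03	2.581266e-03	7.771195e-04	1.810346e-03	2.438810e-03	3.363414e-03	8.396611e-04	1.334171e-03	2.104473e-03	2.871606e-03	6.480615e-04	1.029915e-03	1.568725e-03	6.891160e-03	4.301113e-03	2.565475e-04	9.867539e-04	2.343262e-03
T	4.994866e-03	2.274034e-03	2.462573e-03	2.577609e-03	9.850366e-04	1.794848e-03	2.475959e-03	2.658413e-03	8.404889e-04	2.656968e-03	3.493876e-03	2.900884e-03	1.027834e-03	1.345701e-03	1.993761e-03	4.301113e-03	1.387782e-02	4.142098e-04	1.269943e-03	4.769679e-03
W	4.888158e-04	3.397315e-04	1.882631e-04	2.433639e-04	1.174847e-04	3.464421e-04	3.678691e-04	5.141637e-04	1.629750e-04	4.053244e-04	6.660843e-04	3.583065e-04	2.008090e-04	9.742733e-04	1.941297e-04	2.565475e-04	4.142098e-04	6.582343e-03	9.638045e-04	4.606677e-04
Y	1.816694e-03	1.063688e-03	8.976376e-04	9.361390e-04	3.661492e-04	1.044480e-03	1.134952e-03	1.003975e-03	1.287315e-03	1.573573e-03	2.502432e-03	1.345395e-03	6.200391e-04	3.869284e-03	5.933664e-04	9.867539e-04	1.269943e-03	9.638045e-04	9.480533e-03	1.794663e-03
V	6.869403e-03	1.958316e-03	1.356335e-03	1.775449e-03	1.351176e-03	1.571341e-03	2.134305e-03	2.326642e-03	7.379188e-04	1.172357e-02	9.478538e-03	2.543714e-03	2.292765e-03	2.842348e-03	1.736327e-03	2.343262e-03	4.769679e-03	4.606677e-04	1.794663e-03	2.116450e-02
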