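# BLOSUM62 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	2.630831e-02	3.401414e-03	1.713634e-03	2.167005e-03	1.727146e-03	2.350569e-03	2.910570e-03	5.397553e-03	9.918227e-04	3.586313e-03	5.018869e-03	3.119676e-03	1.747962e-03	2.098820e-03	2.536316e-03	6.684051e-03	4.539546e-03	3.644251e-04	1.272304e-03	5.115869e-03
R	3.401414e-03	2.242239e-02	2.297086e-03	1.653346e-03	4.483894e-04	3.422668e-03	3.062436e-03	1.968708e-03	1.446148e-03	1.391997e-03	2.717323e-03	6.565221e-03	1.207283e-03	1.163500e-03	1.305125e-03	2.499167e-03	2.451782e-03	2.776386e-04	9.579681e-04	1.420625e-03
N	1.713634e-03	2.297086e-03	1.224395e-02	2.971774e-03	3.227521e-04	1.589085e-03	1.967300e-03	2.515807e-03	1.277336e-03	8.847652e-04	1.234562e-03	2.110161e-03	5.861561e-04	7.229496e-04	8.680271e-04	3.088654e-03	2.198283e-03	1.263798e-04	6.117793e-04	8.877246e-04
D	2.167005e-03	1.653346e-03	2.971774e-03	2.104638e-02	3.779642e-04	2.054204e-03	4.900101e-03	2.357723e-03	8.722059e-04	1.155028e-03	1.240875e-03	1.964615e-03	5.415484e-04	8.873086e-04	1.497383e-03	2.934924e-03	2.060720e-03	1.569012e-04	5.626793e-04	1.115249e-03
C	1.727146e-03	4.483894e-04	3.227521e-04	3.779642e-04	1.047551e-02	3.142813e-04	2.846040e-04	5.353428e-04	1.797244e-04	9.728304e-04	1.344446e-03	4.014918e-04	4.303787e-04	5.632164e-04	3.372793e-04	8.845262e-04	8.582777e-04	1.261859e-04	3.190338e-04	9.700199e-04
Q	2.350569e-03	3.422668e-03	1.589085e-03	2.054204e-03	3.142813e-04	9.534286e-03	3.892584e-03	1.371608e-03	1.037480e-03	9.276535e-04	1.840302e-03	3.112071e-03	1.205693e-03	7.398551e-04	1.214735e-03	2.286125e-03	1.597881e-03	2.586007e-04	8.345936e-04	1.249341e-03
E	2.910570e-03	3.062436e-03	1.967300e-03	4.900101e-03	2.846040e-04	3.892584e-03	1.369467e-02	1.618761e-03	1.143525e-03	1.103853e-03	1.610323e-03	3.685239e-03	7.391322e-04	9.016433e-04	1.517682e-03	2.789795e-03	1.966561e-03	2.192172e-04	7.519530e-04	1.470051e-03
G	5.397553e-03	1.968708e-03	2.515807e-03	2.357723e-03	5.353428e-04	1.371608e-03	1.618761e-03	3.462200e-02	8.023985e-04	1.103185e-03	1.564273e-03	1.839860e-03	7.336824e-04	1.188345e-03	1.380706e-03	3.679982e-03	1.882366e-03	3.891972e-04	7.017886e-04	1.433860e-03
H	9.918227e-04	1.446148e-03	1.277336e-03	8.722059e-04	1.797244e-04	1.037480e-03	1.143525e-03	8.023985e-04	8.450552e-03	5.221654e-04	7.914131e-04	9.324303e-04	3.658434e-04	8.774295e-04	5.063800e-04	9.618380e-04	6.701368e-04	1.472395e-04	1.391950e-03	5.198853e-04
I	3.586313e-03	1.391997e-03	8.847652e-04	1.155028e-03	9.728304e-04	9.276535e-04	1.103853e-03	1.103185e-03	5.221654e-04	1.640134e-02	1.139504e-02	1.220238e-03	2.767422e-03	3.310540e-03	1.005320e-03	1.761944e-03	2.542115e-03	3.017557e-04	1.370207e-03	1.120712e-02
L	5.018869e-03	2.717323e-03	1.234562e-03	1.240875e-03	1.344446e-03	1.840302e-03	1.610323e-03	1.564273e-03	7.914131e-04	1.139504e-02	3.374762e-02	2.313222e-03	5.495401e-03	4.895578e-03	1.404476e-03	2.489334e-03	3.469678e-03	5.667464e-04	1.982002e-03	7.951804e-03
K	3.119676e-03	6.565221e-03	2.110161e-03	1.964615e-03	4.014918e-04	3.112071e-03	3.685239e-03	1.839860e-03	9.324303e-04	1.220238e-03	2.313222e-03	1.517023e-02	1.047534e-03	9.681078e-04	1.635059e-03	3.029803e-03	2.096413e-03	2.334211e-04	8.214939e-04	1.599428e-03
M	1.747962e-03	1.207283e-03	5.861561e-04	5.415484e-04	4.303787e-04	1.205693e-03	7.391322e-04	7.336824e-04	3.658434e-04	2.767422e-03	5.495401e-03	1.047534e-03	5.325935e-03	1.547561e-03	6.052311e-04	1.127133e-03	1.179154e-03	2.477331e-04	6.410053e-04	2.591335e-03
F	2.098820e-03	1.163500e-03	7.229496e-04	8.873086e-04	5.632164e-04	7.398551e-04	9.016433e-04	1.188345e-03	8.774295e-04	3.310540e-03	4.895578e-03	9.681078e-04	1.547561e-03	2.167558e-02	5.725167e-04	1.426010e-03	1.433239e-03	9.229802e-04	4.410037e-03	2.301840e-03
P	2.536316e-03	1.305125e-03	8.680271e-04	1.497383e-03	3.372793e-04	1.214735e-03	1.517682e-03	1.380706e-03	5.063800e-04	1.005320e-03	1.404476e-03	1.635059e-03	6.052311e-04	5.725167e-04	2.173325e-02	1.751874e-03	1.693031e-03	1.358645e-04	4.617138e-04	1.297477e-03
S	6.684051e-03	2.499167e-03	3.088654e-03	2.934924e-03	8.845262e-04	2.286125e-03	2.789795e-03	3.679982e-03	9.618380e-04	1.761944e-03	2.489334e-03	3.029803e-03	1.127133e-03	1.426010e-03	1.751874e-03	1.280840e-02	4.550477e-03	2.524877e-04	8.827293e-04	1.811068e-03
T	4.539546e-03	2.451782e-03	2.198283e-03	2.060720e-03	8.582777e-04	1.597881e-03	1.966561e-03	1.882366e-03	6.701368e-04	2.542115e-03	3.469678e-03	2.096413e-03	1.179154e-03	1.433239e-03	1.693031e-03	4.550477e-03	1.631227e-02	3.289018e-04	8.554220e-04	3.428936e-03
W	3.644251e-04	2.776386e-04	1.263798e-04	1.569012e-04	1.261859e-04	2.586007e-04	2.192172e-04	3.891972e-04	1.472395e-04	3.017557e-04	5.667464e-04	2.334211e-04	2.477331e-04	9.229802e-04	1.358645e-04	2.524877e-04	3.289018e-04	6.489626e-03	7.447273e-04	2.767663e-04
Y	1.272304e-03	9.579681e-04	6.117793e-04	5.626793e-04	3.190338e-04	8.345936e-04	7.519530e-04	7.017886e-04	1.391950e-03	1.370207e-03	1.982002e-03	8.214939e-04	6.410053e-04	4.410037e-03	4.617138e-04	8.827293e-04	8.554220e-04	7.447273e-04	9.771540e-03	1.284975e-03
V	5.115869e-03	1.420625e-03	8.877246e-04	1.115249e-03	9.700199e-04	1.249341e-03	1.470051e-03	1.433860e-03	5.198853e-04	1.120712e-02	7.951804e-03	1.599428e-03	2.591335e-03	2.301840e-03	1.297477e-03	1.811068e-03	3.428936e-03	2.767663e-04	1.284975e-03	1.520441e-02
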