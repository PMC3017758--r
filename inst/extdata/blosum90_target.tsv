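# BLOSUM90 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	2.596716e-02	1.993109e-03	1.268047e-03	1.249963e-03	1.375963e-03	1.377268e-03	2.633263e-03	5.365148e-03	9.672609e-04	2.194441e-03	3.167749e-03	2.276358e-03	9.183486e-04	1.070028e-03	1.902532e-03	6.239349e-03	3.304112e-03	2.597317e-04	7.686994e-04	3.253597e-03
R	1.993109e-03	2.911213e-02	1.624031e-03	1.107232e-03	3.240029e-04	2.391826e-03	2.420234e-03	1.680748e-03	1.713623e-03	9.959795e-04	1.986317e-03	5.659009e-03	7.816328e-04	6.908579e-04	8.898617e-04	2.610190e-03	1.521830e-03	2.165210e-04	6.809233e-04	1.438451e-03
N	1.268047e-03	1.624031e-03	1.635242e-02	2.706693e-03	2.888801e-04	1.121892e-03	1.561007e-03	2.232198e-03	1.164290e-03	6.272704e-04	9.054857e-04	1.786714e-03	3.601526e-04	4.204544e-04	5.326402e-04	2.577807e-03	1.888929e-03	9.804579e-05	4.391834e-04	6.627578e-04
D	1.249963e-03	1.107232e-03	2.706693e-03	2.727133e-02	2.486518e-04	1.039381e-03	4.143925e-03	1.951253e-03	7.369539e-04	5.737254e-04	8.289989e-04	1.575285e-03	3.113835e-04	4.223696e-04	7.355302e-04	2.238605e-03	1.231406e-03	8.946816e-05	3.916510e-04	6.383323e-04
C	1.375963e-03	3.240029e-04	2.888801e-04	2.486518e-04	1.873944e-02	2.141531e-04	2.248115e-04	5.646686e-04	1.470300e-04	9.862195e-04	1.323746e-03	3.262430e-04	3.785959e-04	4.695956e-04	2.696873e-04	9.555359e-04	7.371215e-04	1.040937e-04	2.481851e-04	1.057074e-03
Q	1.377268e-03	2.391826e-03	1.121892e-03	1.039381e-03	2.141531e-04	9.437717e-03	3.386430e-03	8.470840e-04	1.202146e-03	5.084104e-04	1.000463e-03	2.057787e-03	7.426995e-04	3.447969e-04	5.735955e-04	1.352501e-03	1.041476e-03	1.517343e-04	3.720259e-04	7.196467e-04
E	2.633263e-03	2.420234e-03	1.561007e-03	4.143925e-03	2.248115e-04	3.386430e-03	2.712740e-02	1.616478e-03	1.236741e-03	9.467077e-04	1.341220e-03	2.804243e-03	5.439002e-04	4.947715e-04	1.146455e-03	2.637994e-03	1.961302e-03	1.585025e-04	4.691267e-04	1.431056e-03
G	5.365148e-03	1.680748e-03	2.232198e-03	1.951253e-03	5.646686e-04	8.470840e-04	1.616478e-03	5.305465e-02	8.174706e-04	9.334747e-04	1.368466e-03	1.851361e-03	5.432937e-04	6.935213e-04	1.079858e-03	3.744788e-03	1.536835e-03	2.848996e-04	4.789879e-04	1.053724e-03
H	9.672609e-04	1.713623e-03	1.164290e-03	7.369539e-04	1.470300e-04	1.202146e-03	1.236741e-03	8.174706e-04	1.409976e-02	4.784792e-04	7.472790e-04	9.711180e-04	2.748946e-04	6.650470e-04	4.065497e-04	1.009597e-03	7.204335e-04	1.495778e-04	1.444847e-03	5.052302e-04
I	2.194441e-03	9.959795e-04	6.272704e-04	5.737254e-04	9.862195e-04	5.084104e-04	9.467077e-04	9.334747e-04	4.784792e-04	2.578660e-02	9.215126e-03	8.417147e-04	2.563890e-03	2.133936e-03	6.620483e-04	1.542783e-03	2.265204e-03	2.573899e-04	1.052356e-03	1.275110e-02
L	3.167749e-03	1.986317e-03	9.054857e-04	8.289989e-04	1.323746e-03	1.000463e-03	1.341220e-03	1.368466e-03	7.472790e-04	9.215126e-03	4.923053e-02	1.590168e-03	5.160191e-03	4.382332e-03	9.495723e-04	2.179273e-03	2.344297e-03	4.902541e-04	1.565922e-03	6.774812e-03
K	2.276358e-03	5.659009e-03	1.786714e-03	1.575285e-03	3.262430e-04	2.057787e-03	2.804243e-03	1.851361e-03	9.711180e-04	8.417147e-04	1.590168e-03	1.808604e-02	6.216569e-04	5.491200e-04	9.568516e-04	2.153979e-03	1.658644e-03	1.228675e-04	5.415595e-04	1.160704e-03
M	9.183486e-04	7.816328e-04	3.601526e-04	3.113835e-04	3.785959e-04	7.426995e-04	5.439002e-04	5.432937e-04	2.748946e-04	2.563890e-03	5.160191e-03	6.216569e-04	8.111734e-03	9.031524e-04	3.784244e-04	8.519603e-04	9.581530e-04	1.911593e-04	4.126874e-04	1.887155e-03
F	1.070028e-03	6.908579e-04	4.204544e-04	4.223696e-04	4.695956e-04	3.447969e-04	4.947715e-04	6.935213e-04	6.650470e-04	2.133936e-03	4.382332e-03	5.491200e-04	9.031524e-04	2.374983e-02	4.415994e-04	1.046943e-03	7.974748e-04	6.510433e-04	4.088734e-03	1.666071e-03
P	1.902532e-03	8.898617e-04	5.326402e-04	7.355302e-04	2.696873e-04	5.735955e-04	1.146455e-03	1.079858e-03	4.065497e-04	6.620483e-04	9.495723e-04	9.568516e-04	3.784244e-04	4.415994e-04	2.517205e-02	1.363200e-03	9.544712e-04	1.009201e-04	3.109058e-04	9.491496e-04
S	6.239349e-03	2.610190e-03	2.577807e-03	2.238605e-03	9.555359e-04	1.352501e-03	2.637994e-03	3.744788e-03	1.009597e-03	1.542783e-03	2.179273e-03	2.153979e-03	8.519603e-04	1.046943e-03	1.363200e-03	2.474196e-02	4.748252e-03	2.276115e-04	7.997440e-04	2.200406e-03
T	3.304112e-03	1.521830e-03	1.888929e-03	1.231406e-03	7.371215e-04	1.041476e-03	1.961302e-03	1.536835e-03	7.204335e-04	2.265204e-03	2.344297e-03	1.658644e-03	9.581530e-04	7.974748e-04	9.544712e-04	4.748252e-03	1.902384e-02	1.819079e-04	7.857193e-04	2.652649e-03
W	2.597317e-04	2.165210e-04	9.804579e-05	8.946816e-05	1.040937e-04	1.517343e-04	1.585025e-04	2.848996e-04	1.495778e-04	2.573899e-04	4.902541e-04	1.228675e-04	1.911593e-04	6.510433e-04	1.009201e-04	2.276115e-04	1.819079e-04	9.618948e-03	9.331723e-04	3.465033e-04
Y	7.686994e-04	6.809233e-04	4.391834e-04	3.916510e-04	2.481851e-04	3.720259e-04	4.691267e-04	4.789879e-04	1.444847e-03	1.052356e-03	1.565922e-03	5.415595e-04	4.126874e-04	4.088734e-03	3.109058e-04	7.997440e-04	7.857193e-04	9.331723e-04	1.616640e-02	8.460042e-04
V	3.253597e-03	1.438451e-03	6.627578e-04	6.383323e-04	1.057074e-03	7.196467e-04	1.431056e-03	1.053724e-03	5.052302e-04	1.275110e-02	6.774812e-03	1.160704e-03	1.887155e-03	1.666071e-03	9.491496e-04	2.200406e-03	2.652649e-03	3.465033e-04	8.460042e-04	2.741351e-02
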