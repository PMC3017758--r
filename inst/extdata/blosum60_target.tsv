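# BLOSUM60 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	2.410636e-02	2.870745e-03	1.898480e-03	2.003868e-03	1.591420e-03	2.069454e-03	2.688849e-03	4.992426e-03	1.131721e-03	3.479216e-03	4.765494e-03	3.917191e-03	1.560819e-03	1.901448e-03	2.416351e-03	5.821884e-03	5.758635e-03	4.262818e-04	1.526999e-03	4.583294e-03
R	2.870745e-03	1.700498e-02	1.836178e-03	1.749434e-03	3.831069e-04	2.722314e-03	2.566754e-03	1.672639e-03	1.493873e-03	1.225584e-03	2.354601e-03	7.512964e-03	9.869483e-04	9.667776e-04	1.131281e-03	2.001781e-03	2.844983e-03	2.950010e-04	1.054413e-03	1.466116e-03
N	1.898480e-03	1.836178e-03	9.954445e-03	2.591097e-03	3.573001e-04	1.315908e-03	1.717172e-03	2.214092e-03	1.370522e-03	8.207287e-04	1.116162e-03	2.501303e-03	4.987304e-04	6.239101e-04	7.887426e-04	2.565276e-03	2.636462e-03	1.394525e-04	6.977096e-04	7.586257e-04
D	2.003868e-03	1.749434e-03	2.591097e-03	1.896144e-02	3.526950e-04	1.801055e-03	4.469275e-03	2.188023e-03	9.881461e-04	1.112659e-03	1.474109e-03	2.472119e-03	4.853753e-04	7.981542e-04	1.428112e-03	2.564269e-03	2.605634e-03	1.831739e-04	6.811382e-04	1.005836e-03
C	1.591420e-03	3.831069e-04	3.573001e-04	3.526950e-04	9.564347e-03	2.771000e-04	3.337698e-04	6.237659e-04	2.071894e-04	9.219819e-04	1.265538e-03	5.112787e-04	3.850840e-04	5.112541e-04	3.217000e-04	7.768993e-04	1.089471e-03	1.439008e-04	3.831832e-04	8.698036e-04
Q	2.069454e-03	2.722314e-03	1.315908e-03	1.801055e-03	2.771000e-04	7.784650e-03	3.364361e-03	1.211128e-03	1.404412e-03	8.548676e-04	1.660473e-03	3.702385e-03	1.020319e-03	6.357931e-04	1.104007e-03	1.900103e-03	1.924159e-03	2.858119e-04	9.552489e-04	1.060689e-03
E	2.688849e-03	2.566754e-03	1.717172e-03	4.469275e-03	3.337698e-04	3.364361e-03	1.239619e-02	1.496411e-03	1.287095e-03	1.068834e-03	1.535635e-03	4.575029e-03	6.603639e-04	8.236994e-04	1.444612e-03	2.419905e-03	2.493474e-03	2.560682e-04	9.048237e-04	1.318409e-03
G	4.992426e-03	1.672639e-03	2.214092e-03	2.188023e-03	6.237659e-04	1.211128e-03	1.496411e-03	3.162112e-02	9.154996e-04	1.344451e-03	1.496687e-03	2.903730e-03	8.270557e-04	1.086521e-03	1.334445e-03	3.236031e-03	2.404594e-03	4.542539e-04	8.506889e-04	1.302045e-03
H	1.131721e-03	1.493873e-03	1.370522e-03	9.881461e-04	2.071894e-04	1.404412e-03	1.287095e-03	9.154996e-04	9.253663e-03	6.235753e-04	9.262371e-04	1.443118e-03	5.083873e-04	9.721591e-04	5.928298e-04	1.035620e-03	1.049489e-03	2.077105e-04	2.021705e-03	5.765945e-04
I	3.479216e-03	1.225584e-03	8.207287e-04	1.112659e-03	9.219819e-04	8.548676e-04	1.068834e-03	1.344451e-03	6.235753e-04	1.620813e-02	1.107795e-02	1.604227e-03	2.566885e-03	3.093223e-03	1.003635e-03	1.617057e-03	3.362764e-03	4.566100e-04	1.717030e-03	1.033287e-02
L	4.765494e-03	2.354601e-03	1.116162e-03	1.474109e-03	1.265538e-03	1.660473e-03	1.535635e-03	1.496687e-03	9.262371e-04	1.107795e-02	3.212665e-02	2.977178e-03	4.962525e-03	4.520411e-03	1.365887e-03	2.232976e-03	4.524277e-03	6.691747e-04	2.423388e-03	7.212393e-03
K	3.917191e-03	7.512964e-03	2.501303e-03	2.472119e-03	5.112787e-04	3.702385e-03	4.575029e-03	2.903730e-03	1.443118e-03	1.604227e-03	2.977178e-03	2.037459e-02	1.275212e-03	1.191316e-03	2.110784e-03	3.582939e-03	3.618385e-03	3.710046e-04	1.344920e-03	1.963931e-03
M	1.560819e-03	9.869483e-04	4.987304e-04	4.853753e-04	3.850840e-04	1.020319e-03	6.603639e-04	8.270557e-04	5.083873e-04	2.566885e-03	4.962525e-03	1.275212e-03	4.514796e-03	1.341119e-03	5.617814e-04	9.544399e-04	1.443948e-03	2.765445e-04	7.499912e-04	2.226309e-03
F	1.901448e-03	9.667776e-04	6.239101e-04	7.981542e-04	5.112541e-04	6.357931e-04	8.236994e-04	1.086521e-03	9.721591e-04	3.093223e-03	4.520411e-03	1.191316e-03	1.341119e-03	1.887556e-02	5.393115e-04	1.226311e-03	1.792806e-03	1.034303e-03	5.089513e-03	2.021201e-03
P	2.416351e-03	1.131281e-03	7.887426e-04	1.428112e-03	3.217000e-04	1.104007e-03	1.444612e-03	1.334445e-03	5.928298e-04	1.003635e-03	1.365887e-03	2.110784e-03	5.617814e-04	5.393115e-04	2.085346e-02	1.584822e-03	2.218997e-03	1.646060e-04	5.748102e-04	1.201979e-03
S	5.821884e-03	2.001781e-03	2.565276e-03	2.564269e-03	7.768993e-04	1.900103e-03	2.419905e-03	3.236031e-03	1.035620e-03	1.617057e-03	2.232976e-03	3.582939e-03	9.544399e-04	1.226311e-03	1.584822e-03	1.045149e-02	5.482051e-03	2.756580e-04	1.001834e-03	1.552918e-03
T	5.758635e-03	2.844983e-03	2.636462e-03	2.605634e-03	1.089471e-03	1.924159e-03	2.493474e-03	2.404594e-03	1.049489e-03	3.362764e-03	4.524277e-03	3.618385e-03	1.443948e-03	1.792806e-03	2.218997e-03	5.482051e-03	2.233014e-02	5.240028e-04	1.418211e-03	4.211081e-03
W	4.262818e-04	2.950010e-04	1.394525e-04	1.831739e-04	1.439008e-04	2.858119e-04	2.560682e-04	4.542539e-04	2.077105e-04	4.566100e-04	6.691747e-04	3.710046e-04	2.765445e-04	1.034303e-03	1.646060e-04	2.756580e-04	5.240028e-04	7.424650e-03	1.102873e-03	3.123256e-04
Y	1.526999e-03	1.054413e-03	6.977096e-04	6.811382e-04	3.831832e-04	9.552489e-04	9.048237e-04	8.506889e-04	2.021705e-03	1.717030e-03	2.423388e-03	1.344920e-03	7.499912e-04	5.089513e-03	5.748102e-04	1.001834e-03	1.418211e-03	1.102873e-03	1.181295e-02	1.497617e-03
V	4.583294e-03	1.466116e-03	7.586257e-04	1.005836e-03	8.698036e-04	1.060689e-03	1.318409e-03	1.302045e-03	5.765945e-04	1.033287e-02	7.212393e-03	1.963931e-03	2.226309e-03	2.021201e-03	1.201979e-03	1.552918e-03	4.211081e-03	3.123256e-04	1.497617e-03	1.306824e-02
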