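# BLOSUM30 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	1.123189e-03	1.103543e-03	1.311058e-03	1.218552e-03	4.181121e-04	1.345775e-03	1.261577e-03	2.129642e-03	5.623616e-04	3.005987e-04	2.340195e-03	1.876576e-03	8.007962e-04	7.440969e-04	1.034328e-03	2.961304e-03	8.671009e-04	1.874913e-04	2.820214e-04	3.328106e-03
R	1.103543e-03	7.504754e-03	1.956105e-03	2.085093e-03	9.255188e-04	3.498310e-03	2.167838e-03	3.213427e-03	1.254600e-03	3.917499e-04	4.051895e-03	4.167598e-03	1.375798e-03	1.689010e-03	2.051940e-03	4.390171e-03	9.890824e-04	7.362468e-04	9.448721e-04	5.040567e-03
N	1.311058e-03	1.956105e-03	8.387588e-03	2.895078e-03	1.154611e-03	2.177312e-03	2.297353e-03	4.576163e-03	1.371350e-03	6.320421e-04	4.352545e-03	3.858173e-03	1.446673e-03	1.798864e-03	1.666281e-03	5.278863e-03	1.806638e-03	3.024997e-04	5.771139e-04	4.651385e-03
D	1.218552e-03	2.085093e-03	2.895078e-03	8.191747e-03	7.871322e-04	1.959293e-03	2.840688e-03	3.539501e-03	1.096528e-03	3.421186e-04	4.563761e-03	3.473605e-03	8.733234e-04	9.613317e-04	2.028071e-03	4.833091e-03	1.272734e-03	4.139682e-04	7.923046e-04	4.287975e-03
C	4.181121e-04	9.255188e-04	1.154611e-03	7.871322e-04	6.629903e-03	8.785650e-04	1.444218e-03	1.228826e-03	3.669962e-04	2.239451e-04	2.662338e-03	1.229387e-03	5.036035e-04	6.172383e-04	7.873317e-04	1.864542e-03	5.751061e-04	2.705438e-04	2.020736e-04	2.178426e-03
Q	1.345775e-03	3.498310e-03	2.177312e-03	1.959293e-03	8.785650e-04	6.572170e-03	3.109092e-03	3.003311e-03	1.339842e-03	4.259331e-04	3.811499e-03	3.388966e-03	1.109219e-03	1.178517e-03	2.274288e-03	4.123083e-03	1.424477e-03	5.918837e-04	7.806647e-04	3.548676e-03
E	1.261577e-03	2.167838e-03	2.297353e-03	2.840688e-03	1.444218e-03	3.109092e-03	5.844276e-03	3.267369e-03	1.451298e-03	4.021138e-04	4.787535e-03	4.849991e-03	1.191126e-03	1.126076e-03	2.733041e-03	5.126325e-03	1.161112e-03	6.481905e-04	7.348871e-04	3.925580e-03
G	2.129642e-03	3.213427e-03	4.576163e-03	3.539501e-03	1.228826e-03	3.003311e-03	3.267369e-03	2.186194e-02	1.666130e-03	8.863327e-04	6.938930e-03	5.509620e-03	1.802303e-03	2.163959e-03	3.465765e-03	8.855339e-03	1.942938e-03	1.409919e-03	1.076493e-03	6.519384e-03
H	5.623616e-04	1.254600e-03	1.371350e-03	1.096528e-03	3.669962e-04	1.339842e-03	1.451298e-03	1.666130e-03	6.031286e-03	2.651738e-04	2.742539e-03	1.620321e-03	1.057308e-03	7.448232e-04	1.605109e-03	2.607141e-03	6.720011e-04	2.159697e-04	5.415675e-04	2.206294e-03
I	3.005987e-04	3.917499e-04	6.320421e-04	3.421186e-04	2.239451e-04	4.259331e-04	4.021138e-04	8.863327e-04	2.651738e-04	3.307290e-04	1.728435e-03	6.761237e-04	3.792891e-04	4.736548e-04	3.885285e-04	1.052838e-03	3.602500e-04	1.190239e-04	1.985474e-04	2.459213e-03
L	2.340195e-03	4.051895e-03	4.352545e-03	4.563761e-03	2.662338e-03	3.811499e-03	4.787535e-03	6.938930e-03	2.742539e-03	1.728435e-03	2.061111e-02	6.043072e-03	4.005543e-03	5.583367e-03	3.423146e-03	8.457689e-03	3.304390e-03	1.227165e-03	3.017676e-03	1.461963e-02
K	1.876576e-03	4.167598e-03	3.858173e-03	3.473605e-03	1.229387e-03	3.388966e-03	4.849991e-03	5.509620e-03	1.620321e-03	6.761237e-04	6.043072e-03	9.449358e-03	2.641858e-03	2.529370e-03	4.046236e-03	7.528478e-03	1.949653e-03	8.333688e-04	1.197545e-03	6.396179e-03
M	8.007962e-04	1.375798e-03	1.446673e-03	8.733234e-04	5.036035e-04	1.109219e-03	1.191126e-03	1.802303e-03	1.057308e-03	3.792891e-04	4.005543e-03	2.641858e-03	1.740943e-03	8.203928e-04	7.439876e-04	2.160759e-03	8.396250e-04	2.821393e-04	4.487953e-04	3.208954e-03
F	7.440969e-04	1.689010e-03	1.798864e-03	9.613317e-04	6.172383e-04	1.178517e-03	1.126076e-03	2.163959e-03	7.448232e-04	4.736548e-04	5.583367e-03	2.529370e-03	8.203928e-04	5.930985e-03	1.047597e-03	3.463670e-03	8.861629e-04	6.495994e-04	1.105443e-03	5.209229e-03
P	1.034328e-03	2.051940e-03	1.666281e-03	2.028071e-03	7.873317e-04	2.274288e-03	2.733041e-03	3.465765e-03	1.605109e-03	3.885285e-04	3.423146e-03	4.046236e-03	7.439876e-04	1.047597e-03	1.048184e-02	4.135651e-03	1.445611e-03	4.474235e-04	6.725053e-04	3.189992e-03
S	2.961304e-03	4.390171e-03	5.278863e-03	4.833091e-03	1.864542e-03	4.123083e-03	5.126325e-03	8.855339e-03	2.607141e-03	1.052838e-03	8.457689e-03	7.528478e-03	2.160759e-03	3.463670e-03	4.135651e-03	1.800285e-02	4.056644e-03	1.010026e-03	1.482161e-03	1.019774e-02
T	8.671009e-04	9.890824e-04	1.806638e-03	1.272734e-03	5.751061e-04	1.424477e-03	1.161112e-03	1.942938e-03	6.720011e-04	3.602500e-04	3.304390e-03	1.949653e-03	8.396250e-04	8.861629e-04	1.445611e-03	4.056644e-03	1.816078e-03	2.271972e-04	4.822125e-04	4.029764e-03
W	1.874913e-04	7.362468e-04	3.024997e-04	4.139682e-04	2.705438e-04	5.918837e-04	6.481905e-04	1.409919e-03	2.159697e-04	1.190239e-04	1.227165e-03	8.333688e-04	2.821393e-04	6.495994e-04	4.474235e-04	1.010026e-03	2.271972e-04	3.260753e-03	5.396905e-04	1.127039e-03
Y	2.820214e-04	9.448721e-04	5.771139e-04	7.923046e-04	2.020736e-04	7.806647e-04	7.348871e-04	1.076493e-03	5.415675e-04	1.985474e-04	3.017676e-03	1.197545e-03	4.487953e-04	1.105443e-03	6.725053e-04	1.482161e-03	4.822125e-04	5.396905e-04	1.228765e-03	2.511790e-03
V	3.328106e-03	5.040567e-03	4.651385e-03	4.287975e-03	2.178426e-03	3.548676e-03	3.925580e-03	6.519384e-03	2.206294e-03	2.459213e-03	1.461963e-02	6.396179e-03	3.208954e-03	5.209229e-03	3.189992e-03	1.019774e-02	4.029764e-03	1.127039e-03	2.511790e-03	2.692755e-02
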