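# BLOSUM35 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	1.579890e-02	3.652088e-03	2.123235e-03	4.048424e-03	1.659156e-03	2.802777e-03	4.163607e-03	7.429975e-03	1.826500e-03	8.301330e-03	4.873247e-03	4.601948e-03	9.625980e-04	2.540188e-03	2.727785e-03	6.217957e-03	5.019885e-03	6.251762e-04	2.396148e-03	1.016498e-10
R	3.652088e-03	1.138504e-02	1.381057e-03	2.634058e-03	9.229783e-04	2.579816e-03	2.705635e-03	3.390063e-03	1.427903e-03	3.815262e-03	3.156266e-03	4.290634e-03	6.251385e-04	1.966537e-03	1.765783e-03	2.879386e-03	2.299020e-03	5.781073e-04	1.890599e-03	5.509397e-11
N	2.123235e-03	1.381057e-03	3.141820e-03	2.142273e-03	7.342201e-04	1.221028e-03	1.546672e-03	3.221579e-03	1.128941e-03	3.074070e-03	1.788316e-03	1.731451e-03	3.026746e-04	1.117430e-03	1.004245e-03	1.972517e-03	1.872064e-03	2.287201e-04	7.625000e-04	2.652085e-11
D	4.048424e-03	2.634058e-03	2.142273e-03	1.368989e-02	1.010949e-03	1.679740e-03	4.922996e-03	3.763018e-03	1.821442e-03	4.105462e-03	3.446417e-03	2.833494e-03	4.115730e-04	1.505509e-03	2.281977e-03	3.194155e-03	2.998311e-03	3.755224e-04	1.475558e-03	5.071586e-11
C	1.659156e-03	9.229783e-04	7.342201e-04	1.010949e-03	1.108513e-02	5.844065e-04	1.456031e-03	1.534789e-03	4.530828e-04	1.743148e-03	1.713259e-03	1.139671e-03	1.736172e-04	6.503526e-04	6.708268e-04	1.121919e-03	1.466128e-03	1.343431e-04	4.346531e-04	2.517752e-11
Q	2.802777e-03	2.579816e-03	1.221028e-03	1.679740e-03	5.844065e-04	3.915156e-03	2.885417e-03	2.174175e-03	9.167305e-04	2.874427e-03	2.012748e-03	1.945768e-03	3.386672e-04	7.569127e-04	1.563970e-03	2.183520e-03	2.057479e-03	3.147349e-04	1.195905e-03	2.506212e-11
E	4.163607e-03	2.705635e-03	1.546672e-03	4.922996e-03	1.456031e-03	2.885417e-03	1.018368e-02	3.806585e-03	1.614327e-03	4.253320e-03	4.181830e-03	4.062581e-03	5.049644e-04	1.569685e-03	2.819684e-03	3.838723e-03	3.061161e-03	5.493126e-04	1.773479e-03	5.169319e-11
G	7.429975e-03	3.390063e-03	3.221579e-03	3.763018e-03	1.534789e-03	2.174175e-03	3.806585e-03	2.738196e-02	1.995668e-03	6.440371e-03	4.478467e-03	4.254624e-03	8.817009e-04	2.366746e-03	3.017474e-03	6.745823e-03	3.887462e-03	8.355435e-04	2.242742e-03	6.586673e-11
H	1.826500e-03	1.427903e-03	1.128941e-03	1.821442e-03	4.530828e-04	9.167305e-04	1.614327e-03	1.995668e-03	7.926003e-03	2.257360e-03	1.868845e-03	1.272945e-03	4.436057e-04	8.317233e-04	1.239500e-03	1.694196e-03	1.358046e-03	1.715279e-04	1.139421e-03	1.965166e-11
I	8.301330e-03	3.815262e-03	3.074070e-03	4.105462e-03	1.743148e-03	2.874427e-03	4.253320e-03	6.440371e-03	2.257360e-03	3.417082e-02	1.403044e-02	4.763586e-03	1.676984e-03	6.201158e-03	4.607474e-03	5.454990e-03	6.163054e-03	1.077929e-03	4.238175e-03	2.926421e-10
L	4.873247e-03	3.156266e-03	1.788316e-03	3.446417e-03	1.713259e-03	2.012748e-03	4.181830e-03	4.478467e-03	1.868845e-03	1.403044e-02	1.638967e-02	3.334100e-03	1.630339e-03	5.162583e-03	2.301433e-03	3.737947e-03	5.032823e-03	8.964232e-04	3.017446e-03	1.438032e-10
K	4.601948e-03	4.290634e-03	1.731451e-03	2.833494e-03	1.139671e-03	1.945768e-03	4.062581e-03	4.254624e-03	1.272945e-03	4.763586e-03	3.334100e-03	7.600086e-03	6.701576e-04	2.065203e-03	2.633684e-03	3.612894e-03	3.426949e-03	6.074526e-04	1.701528e-03	4.959676e-11
M	9.625980e-04	6.251385e-04	3.026746e-04	4.115730e-04	1.736172e-04	3.386672e-04	5.049644e-04	8.817009e-04	4.436057e-04	1.676984e-03	1.630339e-03	6.701576e-04	3.922817e-04	5.129666e-04	3.293659e-04	6.254165e-04	7.117323e-04	1.475628e-04	4.212514e-04	1.717457e-11
F	2.540188e-03	1.966537e-03	1.117430e-03	1.505509e-03	6.503526e-04	7.569127e-04	1.569685e-03	2.366746e-03	8.317233e-04	6.201158e-03	5.162583e-03	2.065203e-03	5.129666e-04	7.817705e-03	1.036031e-03	2.352231e-03	2.251992e-03	5.734336e-04	2.642189e-03	6.403607e-11
P	2.727785e-03	1.765783e-03	1.004245e-03	2.281977e-03	6.708268e-04	1.563970e-03	2.819684e-03	3.017474e-03	1.239500e-03	4.607474e-03	2.301433e-03	2.633684e-03	3.293659e-04	1.036031e-03	1.229907e-02	2.144868e-03	2.836058e-03	2.600272e-04	9.976755e-04	3.410741e-11
S	6.217957e-03	2.879386e-03	1.972517e-03	3.194155e-03	1.121919e-03	2.183520e-03	3.838723e-03	6.745823e-03	1.694196e-03	5.454990e-03	3.737947e-03	3.612894e-03	6.254165e-04	2.352231e-03	2.144868e-03	8.199926e-03	5.503871e-03	4.836859e-04	1.890574e-03	6.657234e-11
T	5.019885e-03	2.299020e-03	1.872064e-03	2.998311e-03	1.466128e-03	2.057479e-03	3.061161e-03	3.887462e-03	1.358046e-03	6.163054e-03	5.032823e-03	3.426949e-03	7.117323e-04	2.251992e-03	2.836058e-03	5.503871e-03	8.831023e-03	4.596527e-04	1.561902e-03	8.911991e-11
W	6.251762e-04	5.781073e-04	2.287201e-04	3.755224e-04	1.343431e-04	3.147349e-04	5.493126e-04	8.355435e-04	1.715279e-04	1.077929e-03	8.964232e-04	6.074526e-04	1.475628e-04	5.734336e-04	2.600272e-04	4.836859e-04	4.596527e-04	1.981453e-03	6.631243e-04	9.482247e-12
Y	2.396148e-03	1.890599e-03	7.625000e-04	1.475558e-03	4.346531e-04	1.195905e-03	1.773479e-03	2.242742e-03	1.139421e-03	4.238175e-03	3.017446e-03	1.701528e-03	4.212514e-04	2.642189e-03	9.976755e-04	1.890574e-03	1.561902e-03	6.631243e-04	5.087235e-03	4.384546e-11
V	1.016498e-10	5.509397e-11	2.652085e-11	5.071586e-11	2.517752e-11	2.506212e-11	5.169319e-11	6.586673e-11	1.965166e-11	2.926421e-10	1.438032e-10	4.959676e-11	1.717457e-11	6.403607e-11	3.410741e-11	6.657234e-11	8.911991e-11	9.482247e-12	4.384546e-11	3.601227e-18
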