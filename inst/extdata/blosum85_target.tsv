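# BLOSUM85 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	2.397941e-02	1.832631e-03	1.269859e-03	1.502314e-03	1.297062e-03	1.660150e-03	2.599003e-03	5.159478e-03	8.506891e-04	2.095702e-03	4.063802e-03	2.215755e-03	7.724877e-04	9.852775e-04	1.767751e-03	5.835104e-03	3.827742e-03	3.065222e-04	9.144425e-04	2.869759e-03
R	1.832631e-03	2.569881e-02	1.553278e-03	1.277474e-03	3.713487e-04	2.817161e-03	2.346446e-03	1.564387e-03	1.450931e-03	9.529122e-04	2.484899e-03	5.242770e-03	6.182115e-04	6.187175e-04	1.005997e-03	2.369755e-03	1.724849e-03	2.044405e-04	7.798340e-04	1.203414e-03
N	1.269859e-03	1.553278e-03	1.595576e-02	2.646851e-03	2.823004e-04	1.406751e-03	1.588410e-03	2.179943e-03	1.035881e-03	6.159821e-04	1.194459e-03	1.797389e-03	3.083486e-04	3.995977e-04	5.145006e-04	2.451203e-03	2.250149e-03	9.789133e-05	5.279029e-04	6.071549e-04
D	1.502314e-03	1.277474e-03	2.646851e-03	2.451575e-02	2.356607e-04	1.226209e-03	3.879434e-03	1.824068e-03	6.443849e-04	5.489465e-04	1.069809e-03	1.512665e-03	2.580377e-04	4.723953e-04	8.392558e-04	2.070746e-03	1.443064e-03	8.527453e-05	4.424318e-04	6.724678e-04
C	1.297062e-03	3.713487e-04	2.823004e-04	2.356607e-04	1.694913e-02	2.634543e-04	2.724280e-04	5.428795e-04	1.283803e-04	9.398632e-04	1.683455e-03	3.140327e-04	3.034710e-04	4.221264e-04	2.514612e-04	8.905510e-04	8.467030e-04	9.911101e-05	3.485468e-04	1.105675e-03
Q	1.660150e-03	2.817161e-03	1.406751e-03	1.226209e-03	2.634543e-04	1.112858e-02	4.158122e-03	1.040804e-03	1.309945e-03	6.198071e-04	1.623538e-03	2.459493e-03	7.706206e-04	3.939942e-04	6.643148e-04	1.624290e-03	1.523578e-03	1.838880e-04	6.664644e-04	7.922518e-04
E	2.599003e-03	2.346446e-03	1.588410e-03	3.879434e-03	2.724280e-04	4.158122e-03	2.514550e-02	1.599789e-03	1.121897e-03	9.103706e-04	1.762501e-03	2.807274e-03	4.640482e-04	5.699309e-04	1.114686e-03	2.555845e-03	2.295349e-03	1.891901e-04	5.647620e-04	1.226195e-03
G	5.159478e-03	1.564387e-03	2.179943e-03	1.824068e-03	5.428795e-04	1.040804e-03	1.599789e-03	4.939832e-02	7.361993e-04	8.997092e-04	1.782217e-03	1.804553e-03	4.563898e-04	7.809234e-04	9.895204e-04	3.426174e-03	2.203564e-03	2.713485e-04	5.592539e-04	1.116849e-03
H	8.506891e-04	1.450931e-03	1.035881e-03	6.443849e-04	1.283803e-04	1.309945e-03	1.121897e-03	7.361993e-04	1.083497e-02	4.113387e-04	1.081787e-03	8.652625e-04	2.090321e-04	5.574316e-04	3.498552e-04	1.062850e-03	7.512989e-04	1.307392e-04	1.900549e-03	3.986095e-04
I	2.095702e-03	9.529122e-04	6.159821e-04	5.489465e-04	9.398632e-04	6.198071e-04	9.103706e-04	8.997092e-04	4.113387e-04	2.304567e-02	1.159157e-02	1.007907e-03	2.077221e-03	1.967139e-03	6.288965e-04	1.410749e-03	2.590034e-03	2.984436e-04	1.214750e-03	1.068401e-02
L	4.063802e-03	2.484899e-03	1.194459e-03	1.069809e-03	1.683455e-03	1.623538e-03	1.762501e-03	1.782217e-03	1.081787e-03	1.159157e-02	6.477609e-02	2.066718e-03	5.558274e-03	5.220296e-03	1.213035e-03	2.721310e-03	3.569977e-03	6.297601e-04	2.489266e-03	7.848056e-03
K	2.215755e-03	5.242770e-03	1.797389e-03	1.512665e-03	3.140327e-04	2.459493e-03	2.807274e-03	1.804553e-03	8.652625e-04	1.007907e-03	2.066718e-03	1.662636e-02	5.114040e-04	5.034019e-04	9.093021e-04	2.075337e-03	1.946658e-03	1.210785e-04	6.451032e-04	9.903231e-04
M	7.724877e-04	6.182115e-04	3.083486e-04	2.580377e-04	3.034710e-04	7.706206e-04	4.640482e-04	4.563898e-04	2.090321e-04	2.077221e-03	5.558274e-03	5.114040e-04	5.310299e-03	7.057970e-04	2.956936e-04	6.733811e-04	9.356622e-04	1.524687e-04	4.157876e-04	1.399977e-03
F	9.852775e-04	6.187175e-04	3.995977e-04	4.723953e-04	4.221264e-04	3.939942e-04	5.699309e-04	7.809234e-04	5.574316e-04	1.967139e-03	5.220296e-03	5.034019e-04	7.057970e-04	1.925285e-02	3.863903e-04	9.117751e-04	8.860768e-04	5.856400e-04	4.400612e-03	1.673459e-03
P	1.767751e-03	1.005997e-03	5.145006e-04	8.392558e-04	2.514612e-04	6.643148e-04	1.114686e-03	9.895204e-04	3.498552e-04	6.288965e-04	1.213035e-03	9.093021e-04	2.956936e-04	3.863903e-04	2.226897e-02	1.523856e-03	1.086436e-03	9.204005e-05	3.487012e-04	7.858958e-04
S	5.835104e-03	2.369755e-03	2.451203e-03	2.070746e-03	8.905510e-04	1.624290e-03	2.555845e-03	3.426174e-03	1.062850e-03	1.410749e-03	2.721310e-03	2.075337e-03	6.733811e-04	9.117751e-04	1.523856e-03	2.118140e-02	5.180081e-03	2.135106e-04	1.124317e-03	1.824063e-03
T	3.827742e-03	1.724849e-03	2.250149e-03	1.443064e-03	8.467030e-04	1.523578e-03	2.295349e-03	2.203564e-03	7.512989e-04	2.590034e-03	3.569977e-03	1.946658e-03	9.356622e-04	8.860768e-04	1.086436e-03	5.180081e-03	2.037471e-02	2.101403e-04	1.099384e-03	3.371171e-03
W	3.065222e-04	2.044405e-04	9.789133e-05	8.527453e-05	9.911101e-05	1.838880e-04	1.891901e-04	2.713485e-04	1.307392e-04	2.984436e-04	6.297601e-04	1.210785e-04	1.524687e-04	5.856400e-04	9.204005e-05	2.135106e-04	2.101403e-04	8.629534e-03	1.052836e-03	2.865222e-04
Y	9.144425e-04	7.798340e-04	5.279029e-04	4.424318e-04	3.485468e-04	6.664644e-04	5.647620e-04	5.592539e-04	1.900549e-03	1.214750e-03	2.489266e-03	6.451032e-04	4.157876e-04	4.400612e-03	3.487012e-04	1.124317e-03	1.099384e-03	1.052836e-03	1.742280e-02	1.083577e-03
V	2.869759e-03	1.203414e-03	6.071549e-04	6.724678e-04	1.105675e-03	7.922518e-04	1.226195e-03	1.116849e-03	3.986095e-04	1.068401e-02	7.848056e-03	9.903231e-04	1.399977e-03	1.673459e-03	7.858958e-04	1.824063e-03	3.371171e-03	2.865222e-04	1.083577e-03	1.968961e-02
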