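# BLOSUM75 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	3.136788e-02	2.215895e-03	2.104422e-03	2.387399e-03	1.556366e-03	1.830660e-03	3.742229e-03	6.226218e-03	9.918547e-04	3.810740e-03	4.913284e-03	3.375619e-03	1.352058e-03	1.671546e-03	2.086537e-03	6.364428e-03	4.472719e-03	3.771171e-04	1.334008e-03	3.786812e-03
R	2.215895e-03	1.974619e-02	1.802389e-03	1.387048e-03	3.066926e-04	2.137272e-03	2.974451e-03	1.324783e-03	1.153579e-03	1.474071e-03	2.071324e-03	5.427255e-03	5.773835e-04	8.740955e-04	8.432298e-04	1.776808e-03	1.764154e-03	2.149677e-04	7.686569e-04	8.224954e-04
N	2.104422e-03	1.802389e-03	1.931679e-02	3.869822e-03	4.036094e-04	1.491681e-03	2.277057e-03	2.533325e-03	1.186612e-03	1.066329e-03	1.374587e-03	2.656121e-03	4.170703e-04	6.554291e-04	6.121626e-04	2.633946e-03	2.519178e-03	1.456779e-04	5.902949e-04	7.633031e-04
D	2.387399e-03	1.387048e-03	3.869822e-03	2.576051e-02	3.236757e-04	1.243711e-03	5.077375e-03	2.038264e-03	8.721976e-04	1.158441e-03	1.481229e-03	2.093381e-03	3.316863e-04	7.210155e-04	9.397537e-04	2.125662e-03	1.960885e-03	1.200948e-04	4.555500e-04	6.479257e-04
C	1.556366e-03	3.066926e-04	4.036094e-04	3.236757e-04	1.321714e-02	2.550455e-04	2.828132e-04	5.824824e-04	1.364659e-04	1.442086e-03	1.413305e-03	3.392096e-04	2.816992e-04	5.963679e-04	2.144439e-04	8.529756e-04	8.607120e-04	1.093875e-04	2.815702e-04	7.738701e-04
Q	1.830660e-03	2.137272e-03	1.491681e-03	1.243711e-03	2.550455e-04	7.389327e-03	3.832929e-03	1.043152e-03	9.710046e-04	8.949078e-04	1.285064e-03	2.374099e-03	6.778544e-04	4.210755e-04	5.247758e-04	1.493920e-03	1.134584e-03	1.826151e-04	4.963269e-04	6.684117e-04
E	3.742229e-03	2.974451e-03	2.277057e-03	5.077375e-03	2.828132e-04	3.832929e-03	2.251587e-02	1.682651e-03	1.422339e-03	1.364968e-03	1.821234e-03	4.658506e-03	6.777305e-04	8.162306e-04	1.436044e-03	3.050372e-03	2.231072e-03	1.993082e-04	7.060702e-04	1.029895e-03
G	6.226218e-03	1.324783e-03	2.533325e-03	2.038264e-03	5.824824e-04	1.043152e-03	1.682651e-03	4.144933e-02	7.892197e-04	1.158209e-03	1.912211e-03	1.962760e-03	5.626460e-04	9.450801e-04	8.593134e-04	2.700379e-03	1.846510e-03	3.036048e-04	5.856285e-04	8.405599e-04
H	9.918547e-04	1.153579e-03	1.186612e-03	8.721976e-04	1.364659e-04	9.710046e-04	1.422339e-03	7.892197e-04	8.471081e-03	5.054052e-04	8.910771e-04	8.961147e-04	2.507386e-04	6.367088e-04	3.693876e-04	8.167124e-04	5.913317e-04	1.388496e-04	1.508476e-03	2.831463e-04
I	3.810740e-03	1.474071e-03	1.066329e-03	1.158441e-03	1.442086e-03	8.949078e-04	1.364968e-03	1.158209e-03	5.054052e-04	3.080895e-02	1.451718e-02	1.615398e-03	2.814007e-03	4.226207e-03	9.852682e-04	1.614864e-03	3.080661e-03	3.815539e-04	1.456075e-03	1.095685e-02
L	4.913284e-03	2.071324e-03	1.374587e-03	1.481229e-03	1.413305e-03	1.285064e-03	1.821234e-03	1.912211e-03	8.910771e-04	1.451718e-02	5.020860e-02	2.218598e-03	5.119048e-03	5.726093e-03	1.296076e-03	2.085300e-03	2.969987e-03	6.750850e-04	2.499554e-03	7.072544e-03
K	3.375619e-03	5.427255e-03	2.656121e-03	2.093381e-03	3.392096e-04	2.374099e-03	4.658506e-03	1.962760e-03	8.961147e-04	1.615398e-03	2.218598e-03	1.718217e-02	6.282631e-04	7.497765e-04	1.251052e-03	2.660107e-03	2.020266e-03	1.766961e-04	8.385527e-04	9.151190e-04
M	1.352058e-03	5.773835e-04	4.170703e-04	3.316863e-04	2.816992e-04	6.778544e-04	6.777305e-04	5.626460e-04	2.507386e-04	2.814007e-03	5.119048e-03	6.282631e-04	4.159238e-03	1.157670e-03	2.779196e-04	5.905156e-04	8.450866e-04	1.451495e-04	3.875132e-04	1.438710e-03
F	1.671546e-03	8.740955e-04	6.554291e-04	7.210155e-04	5.963679e-04	4.210755e-04	8.162306e-04	9.450801e-04	6.367088e-04	4.226207e-03	5.726093e-03	7.497765e-04	1.157670e-03	2.209886e-02	4.290402e-04	9.670910e-04	1.265801e-03	8.624840e-04	4.650026e-03	1.632151e-03
P	2.086537e-03	8.432298e-04	6.121626e-04	9.397537e-04	2.144439e-04	5.247758e-04	1.436044e-03	8.593134e-04	3.693876e-04	9.852682e-04	1.296076e-03	1.251052e-03	2.779196e-04	4.290402e-04	1.800004e-02	1.192202e-03	1.154542e-03	7.896320e-05	2.842310e-04	5.676326e-04
S	6.364428e-03	1.776808e-03	2.633946e-03	2.125662e-03	8.529756e-04	1.493920e-03	3.050372e-03	2.700379e-03	8.167124e-04	1.614864e-03	2.085300e-03	2.660107e-03	5.905156e-04	9.670910e-04	1.192202e-03	1.389388e-02	3.768527e-03	2.144665e-04	8.261167e-04	1.164004e-03
T	4.472719e-03	1.764154e-03	2.519178e-03	1.960885e-03	8.607120e-04	1.134584e-03	2.231072e-03	1.846510e-03	5.913317e-04	3.080661e-03	2.969987e-03	2.020266e-03	8.450866e-04	1.265801e-03	1.154542e-03	3.768527e-03	1.534703e-02	2.252887e-04	8.356409e-04	2.358977e-03
W	3.771171e-04	2.149677e-04	1.456779e-04	1.200948e-04	1.093875e-04	1.826151e-04	1.993082e-04	3.036048e-04	1.388496e-04	3.815539e-04	6.750850e-04	1.766961e-04	1.451495e-04	8.624840e-04	7.896320e-05	2.144665e-04	2.252887e-04	6.950488e-03	8.213333e-04	1.990918e-04
Y	1.334008e-03	7.686569e-04	5.902949e-04	4.555500e-04	2.815702e-04	4.963269e-04	7.060702e-04	5.856285e-04	1.508476e-03	1.456075e-03	2.499554e-03	8.385527e-04	3.875132e-04	4.650026e-03	2.842310e-04	8.261167e-04	8.356409e-04	8.213333e-04	1.212222e-02	7.615637e-04
V	3.786812e-03	8.224954e-04	7.633031e-04	6.479257e-04	7.738701e-04	6.684117e-04	1.029895e-03	8.405599e-04	2.831463e-04	1.095685e-02	7.072544e-03	9.151190e-04	1.438710e-03	1.632151e-03	5.676326e-04	1.164004e-03	2.358977e-03	1.990918e-04	7.615637e-04	8.768036e-03
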