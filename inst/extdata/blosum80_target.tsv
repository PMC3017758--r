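# BLOSUM80 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	2.496697e-02	1.882960e-03	1.630475e-03	1.659677e-03	1.570730e-03	1.532777e-03	2.871567e-03	5.323188e-03	8.462856e-04	2.452482e-03	4.124387e-03	2.772611e-03	1.104980e-03	1.276947e-03	1.951965e-03	6.478559e-03	3.528769e-03	3.343423e-04	9.558259e-04	3.345483e-03
R	1.882960e-03	2.276353e-02	1.923156e-03	1.249007e-03	3.746351e-04	2.320550e-03	2.702427e-03	1.563840e-03	1.278665e-03	1.154292e-03	2.433269e-03	5.361221e-03	6.661453e-04	7.604172e-04	9.364687e-04	2.012774e-03	1.656520e-03	2.476827e-04	7.205727e-04	1.223686e-03
N	1.630475e-03	1.923156e-03	1.753716e-02	3.416173e-03	4.085437e-04	1.565609e-03	2.302469e-03	2.696326e-03	1.346333e-03	7.997822e-04	1.345013e-03	2.329242e-03	4.561983e-04	5.353462e-04	6.436664e-04	3.304929e-03	2.306375e-03	1.377218e-04	6.139221e-04	8.523336e-04
D	1.659677e-03	1.249007e-03	3.416173e-03	2.250974e-02	2.694174e-04	1.249388e-03	4.670696e-03	1.784326e-03	7.083313e-04	6.569727e-04	1.107431e-03	1.532643e-03	3.009257e-04	5.368167e-04	8.297376e-04	2.196689e-03	1.476952e-03	1.097290e-04	3.993873e-04	6.921503e-04
C	1.570730e-03	3.746351e-04	4.085437e-04	2.694174e-04	1.667422e-02	3.014066e-04	3.497343e-04	5.486685e-04	1.365401e-04	1.234674e-03	1.673043e-03	3.591746e-04	3.563178e-04	5.228142e-04	2.552946e-04	1.045464e-03	8.860641e-04	1.329846e-04	3.056616e-04	1.068052e-03
Q	1.532777e-03	2.320550e-03	1.565609e-03	1.249388e-03	3.014066e-04	9.270330e-03	4.292289e-03	1.016872e-03	1.040426e-03	7.306533e-04	1.558101e-03	2.646374e-03	6.980257e-04	4.754011e-04	5.984625e-04	1.594010e-03	1.315831e-03	2.015511e-04	5.619687e-04	7.999962e-04
E	2.871567e-03	2.702427e-03	2.302469e-03	4.670696e-03	3.497343e-04	4.292289e-03	2.554692e-02	1.876207e-03	1.479175e-03	1.094052e-03	1.868377e-03	3.976374e-03	6.350203e-04	7.167713e-04	1.399917e-03	2.979921e-03	2.023134e-03	2.324713e-04	6.659659e-04	1.447875e-03
G	5.323188e-03	1.563840e-03	2.696326e-03	1.784326e-03	5.486685e-04	1.016872e-03	1.876207e-03	4.525367e-02	7.216190e-04	1.023994e-03	1.758043e-03	1.890712e-03	5.862484e-04	8.520441e-04	8.546348e-04	3.441422e-03	1.853016e-03	2.865651e-04	6.175858e-04	1.096858e-03
H	8.462856e-04	1.278665e-03	1.346333e-03	7.083313e-04	1.365401e-04	1.040426e-03	1.479175e-03	7.216190e-04	9.184418e-03	4.143860e-04	8.869641e-04	9.390502e-04	2.396033e-04	6.746254e-04	3.400679e-04	8.935896e-04	5.962421e-04	1.430096e-04	1.608246e-03	4.342310e-04
I	2.452482e-03	1.154292e-03	7.997822e-04	6.569727e-04	1.234674e-03	7.306533e-04	1.094052e-03	1.023994e-03	4.143860e-04	2.391375e-02	1.276512e-02	1.106366e-03	2.705090e-03	2.546016e-03	7.653980e-04	1.586149e-03	2.216880e-03	3.274993e-04	1.183003e-03	1.050060e-02
L	4.124387e-03	2.433269e-03	1.345013e-03	1.107431e-03	1.673043e-03	1.558101e-03	1.868377e-03	1.758043e-03	8.869641e-04	1.276512e-02	5.508106e-02	2.288451e-03	5.855841e-03	5.345329e-03	1.294648e-03	2.673629e-03	2.916575e-03	6.983568e-04	2.469643e-03	8.624880e-03
K	2.772611e-03	5.361221e-03	2.329242e-03	1.532643e-03	3.591746e-04	2.646374e-03	3.976374e-03	1.890712e-03	9.390502e-04	1.106366e-03	2.288451e-03	1.624182e-02	6.287242e-04	7.072801e-04	1.111618e-03	2.371495e-03	1.957633e-03	1.843118e-04	6.800942e-04	1.156301e-03
M	1.104980e-03	6.661453e-04	4.561983e-04	3.009257e-04	3.563178e-04	6.980257e-04	6.350203e-04	5.862484e-04	2.396033e-04	2.705090e-03	5.855841e-03	6.287242e-04	5.152016e-03	1.117449e-03	3.444431e-04	7.345472e-04	9.726733e-04	1.861414e-04	4.287563e-04	1.847837e-03
F	1.276947e-03	7.604172e-04	5.353462e-04	5.368167e-04	5.228142e-04	4.754011e-04	7.167713e-04	8.520441e-04	6.746254e-04	2.546016e-03	5.345329e-03	7.072801e-04	1.117449e-03	2.093505e-02	4.057036e-04	1.049403e-03	9.154748e-04	7.002559e-04	3.977970e-03	1.716776e-03
P	1.951965e-03	9.364687e-04	6.436664e-04	8.297376e-04	2.552946e-04	5.984625e-04	1.399917e-03	8.546348e-04	3.400679e-04	7.653980e-04	1.294648e-03	1.111618e-03	3.444431e-04	4.057036e-04	2.018822e-02	1.321817e-03	9.068237e-04	1.037283e-04	3.024396e-04	8.158100e-04
S	6.478559e-03	2.012774e-03	3.304929e-03	2.196689e-03	1.045464e-03	1.594010e-03	2.979921e-03	3.441422e-03	8.935896e-04	1.586149e-03	2.673629e-03	2.371495e-03	7.345472e-04	1.049403e-03	1.321817e-03	1.751750e-02	4.554674e-03	2.249763e-04	9.828671e-04	1.733418e-03
T	3.528769e-03	1.656520e-03	2.306375e-03	1.476952e-03	8.860641e-04	1.315831e-03	2.023134e-03	1.853016e-03	5.962421e-04	2.216880e-03	2.916575e-03	1.957633e-03	9.726733e-04	9.154748e-04	9.068237e-04	4.554674e-03	1.568133e-02	2.310175e-04	8.431046e-04	2.909176e-03
W	3.343423e-04	2.476827e-04	1.377218e-04	1.097290e-04	1.329846e-04	2.015511e-04	2.324713e-04	2.865651e-04	1.430096e-04	3.274993e-04	6.983568e-04	1.843118e-04	1.861414e-04	7.002559e-04	1.037283e-04	2.249763e-04	2.310175e-04	9.102390e-03	1.008200e-03	2.816695e-04
Y	9.558259e-04	7.205727e-04	6.139221e-04	3.993873e-04	3.056616e-04	5.619687e-04	6.659659e-04	6.175858e-04	1.608246e-03	1.183003e-03	2.469643e-03	6.800942e-04	4.287563e-04	3.977970e-03	3.024396e-04	9.828671e-04	8.431046e-04	1.008200e-03	1.442292e-02	9.882176e-04
V	3.345483e-03	1.223686e-03	8.523336e-04	6.921503e-04	1.068052e-03	7.999962e-04	1.447875e-03	1.096858e-03	4.342310e-04	1.050060e-02	8.624880e-03	1.156301e-03	1.847837e-03	1.716776e-03	8.158100e-04	1.733418e-03	2.909176e-03	2.816695e-04	9.882176e-04	1.738279e-02
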