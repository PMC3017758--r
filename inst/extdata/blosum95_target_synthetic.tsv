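# BLOSUM95 target (joint substitution) frequencies, reconstructed.
# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.
# SYNTHETIC: no integer BLOSUM95 matrix exists in the NCBI set; this table is the cross-family trend evaluated at eta=95.
# See data-raw/make_blosum_targets.R for the full derivation.
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	2.957807e-02	2.029387e-03	1.153518e-03	1.288547e-03	1.321150e-03	1.514761e-03	2.204344e-03	5.280660e-03	8.846743e-04	2.046159e-03	2.960258e-03	2.122004e-03	8.378372e-04	9.867276e-04	1.936905e-03	5.542232e-03	3.483120e-03	2.615064e-04	7.910604e-04	3.064091e-03
R	2.029387e-03	3.083644e-02	1.480370e-03	1.094931e-03	2.959067e-04	2.303389e-03	2.042288e-03	1.515936e-03	1.503487e-03	8.481133e-04	1.699621e-03	5.337357e-03	6.529721e-04	6.153240e-04	8.676430e-04	2.064677e-03	1.613527e-03	1.839743e-04	6.721961e-04	1.218435e-03
N	1.153518e-03	1.480370e-03	1.689205e-02	2.638901e-03	2.877042e-04	1.104968e-03	1.334993e-03	2.152568e-03	1.089285e-03	5.522663e-04	7.989852e-04	1.516897e-03	3.081403e-04	3.526769e-04	5.142676e-04	2.259193e-03	1.880216e-03	8.648560e-05	4.393979e-04	5.587881e-04
D	1.288547e-03	1.094931e-03	2.638901e-03	3.036161e-02	2.391462e-04	1.170709e-03	4.255988e-03	1.999711e-03	7.305396e-04	5.593844e-04	8.092832e-04	1.409180e-03	2.561332e-04	4.004802e-04	7.733281e-04	2.064598e-03	1.286784e-03	8.198794e-05	4.149510e-04	6.398302e-04
C	1.321150e-03	2.959067e-04	2.877042e-04	2.391462e-04	1.895425e-02	2.043694e-04	2.015083e-04	5.166517e-04	1.307231e-04	9.132673e-04	1.084285e-03	2.573184e-04	3.145687e-04	4.387209e-04	2.310492e-04	8.189432e-04	7.773149e-04	8.862946e-05	2.642801e-04	1.023662e-03
Q	1.514761e-03	2.303389e-03	1.104968e-03	1.170709e-03	2.043694e-04	1.230484e-02	3.189068e-03	9.129462e-04	1.254215e-03	5.342638e-04	1.053236e-03	2.271770e-03	6.454230e-04	3.568796e-04	6.142483e-04	1.268856e-03	1.127197e-03	1.534722e-04	4.669946e-04	7.337815e-04
E	2.204344e-03	2.042288e-03	1.334993e-03	4.255988e-03	2.015083e-04	3.189068e-03	2.656319e-02	1.367066e-03	1.015370e-03	7.969531e-04	1.134213e-03	2.386665e-03	4.321391e-04	4.119035e-04	9.746091e-04	2.063671e-03	1.796522e-03	1.376392e-04	4.163603e-04	1.248339e-03
G	5.280660e-03	1.515936e-03	2.152568e-03	1.999711e-03	5.166517e-04	9.129462e-04	1.367066e-03	5.833701e-02	7.060817e-04	8.402145e-04	1.320275e-03	1.553340e-03	4.631368e-04	6.533485e-04	1.049210e-03	3.423951e-03	1.713236e-03	2.621489e-04	4.987102e-04	1.043827e-03
H	8.846743e-04	1.503487e-03	1.089285e-03	7.305396e-04	1.307231e-04	1.254215e-03	1.015370e-03	7.060817e-04	1.463921e-02	4.235526e-04	7.220498e-04	7.860517e-04	2.296668e-04	5.520286e-04	3.833000e-04	8.950820e-04	7.210020e-04	1.326578e-04	1.444713e-03	4.409763e-04
I	2.046159e-03	8.481133e-04	5.522663e-04	5.593844e-04	9.132673e-04	5.342638e-04	7.969531e-04	8.402145e-04	4.235526e-04	2.711926e-02	9.413211e-03	7.926480e-04	2.222551e-03	1.836420e-03	5.990059e-04	1.326718e-03	2.208325e-03	2.504011e-04	1.032151e-03	1.202977e-02
L	2.960258e-03	1.699621e-03	7.989852e-04	8.092832e-04	1.084285e-03	1.053236e-03	1.134213e-03	1.320275e-03	7.220498e-04	9.413211e-03	5.146882e-02	1.315126e-03	4.758889e-03	4.113045e-03	8.666052e-04	1.717417e-03	2.412585e-03	4.438935e-04	1.480881e-03	6.410698e-03
K	2.122004e-03	5.337357e-03	1.516897e-03	1.409180e-03	2.573184e-04	2.271770e-03	2.386665e-03	1.553340e-03	7.860517e-04	7.926480e-04	1.315126e-03	1.892502e-02	5.052539e-04	4.899234e-04	9.193940e-04	1.741881e-03	1.547413e-03	1.057483e-04	5.201290e-04	1.053685e-03
M	8.378372e-04	6.529721e-04	3.081403e-04	2.561332e-04	3.145687e-04	6.454230e-04	4.321391e-04	4.631368e-04	2.296668e-04	2.222551e-03	4.758889e-03	5.052539e-04	8.378050e-03	7.865564e-04	3.482581e-04	6.598089e-04	9.458469e-04	1.596120e-04	3.468320e-04	1.664118e-03
F	9.867276e-04	6.153240e-04	3.526769e-04	4.004802e-04	4.387209e-04	3.568796e-04	4.119035e-04	6.533485e-04	5.520286e-04	1.836420e-03	4.113045e-03	4.899234e-04	7.865564e-04	2.285711e-02	3.985930e-04	8.612624e-04	7.815219e-04	5.895750e-04	4.032294e-03	1.554391e-03
P	1.936905e-03	8.676430e-04	5.142676e-04	7.733281e-04	2.310492e-04	6.142483e-04	9.746091e-04	1.049210e-03	3.833000e-04	5.990059e-04	8.666052e-04	9.193940e-04	3.482581e-04	3.985930e-04	2.752679e-02	1.297563e-03	9.992276e-04	9.894124e-05	3.234617e-04	8.605569e-04
S	5.542232e-03	2.064677e-03	2.259193e-03	2.064598e-03	8.189432e-04	1.268856e-03	2.063671e-03	3.423951e-03	8.950820e-04	1.326718e-03	1.717417e-03	1.741881e-03	6.598089e-04	8.612624e-04	1.297563e-03	2.368500e-02	5.048135e-03	1.821734e-04	7.490892e-04	1.822173e-03
T	3.483120e-03	1.613527e-03	1.880216e-03	1.286784e-03	7.773149e-04	1.127197e-03	1.796522e-03	1.713236e-03	7.210020e-04	2.208325e-03	2.412585e-03	1.547413e-03	9.458469e-04	7.815219e-04	9.992276e-04	5.048135e-03	2.407289e-02	1.764510e-04	7.990569e-04	3.077952e-03
W	2.615064e-04	1.839743e-04	8.648560e-05	8.198794e-05	8.862946e-05	1.534722e-04	1.376392e-04	2.621489e-04	1.326578e-04	2.504011e-04	4.438935e-04	1.057483e-04	1.596120e-04	5.895750e-04	9.894124e-05	1.821734e-04	1.764510e-04	9.759709e-03	9.104060e-04	3.261901e-04
Y	7.910604e-04	6.721961e-04	4.393979e-04	4.149510e-04	2.642801e-04	4.669946e-04	4.163603e-04	4.987102e-04	1.444713e-03	1.032151e-03	1.480881e-03	5.201290e-04	3.468320e-04	4.032294e-03	3.234617e-04	7.490892e-04	7.990569e-04	9.104060e-04	1.905974e-02	8.663992e-04
V	3.064091e-03	1.218435e-03	5.587881e-04	6.398302e-04	1.023662e-03	7.337815e-04	1.248339e-03	1.043827e-03	4.409763e-04	1.202977e-02	6.410698e-03	1.053685e-03	1.664118e-03	1.554391e-03	8.605569e-04	1.822173e-03	3.077952e-03	3.261901e-04	8.663992e-04	2.917149e-02
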