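# squared molecular form factor per gram: air
# columns: x_invA  F2_per_g  (x = sin(theta/2)/lambda)
# provenance: Thomas-Fermi-style analytic form factor, independent-atom mixture rule; format_version: 1
0.000000e+00 2.212357e+24
1.000000e-03 2.212342e+24
1.076870e-03 2.212340e+24
1.159648e-03 2.212337e+24
1.248790e-03 2.212334e+24
1.344784e-03 2.212330e+24
1.448158e-03 2.212326e+24
1.559477e-03 2.212321e+24
1.679354e-03 2.212315e+24
1.808445e-03 2.212309e+24
1.947460e-03 2.212301e+24
2.097160e-03 2.212292e+24
2.258369e-03 2.212282e+24
2.431969e-03 2.212270e+24
2.618914e-03 2.212256e+24
2.820229e-03 2.212240e+24
3.037019e-03 2.212221e+24
3.270474e-03 2.212200e+24
3.521874e-03 2.212175e+24
3.792599e-03 2.212146e+24
4.084136e-03 2.212112e+24
4.398082e-03 2.212073e+24
4.736161e-03 2.212028e+24
5.100229e-03 2.211975e+24
5.492282e-03 2.211914e+24
5.914472e-03 2.211843e+24
6.369116e-03 2.211762e+24
6.858708e-03 2.211667e+24
7.385935e-03 2.211556e+24
7.953690e-03 2.211429e+24
8.565088e-03 2.211281e+24
9.223483e-03 2.211109e+24
9.932490e-03 2.210910e+24
1.069600e-02 2.210679e+24
1.151820e-02 2.210411e+24
1.240360e-02 2.210101e+24
1.335706e-02 2.209741e+24
1.438381e-02 2.209324e+24
1.548949e-02 2.208840e+24
1.668016e-02 2.208280e+24
1.796236e-02 2.207630e+24
1.934312e-02 2.206876e+24
2.083003e-02 2.206003e+24
2.243122e-02 2.204991e+24
2.415551e-02 2.203817e+24
2.601233e-02 2.202458e+24
2.801189e-02 2.200883e+24
3.016516e-02 2.199058e+24
3.248395e-02 2.196944e+24
3.498098e-02 2.194496e+24
3.766996e-02 2.191662e+24
4.056564e-02 2.188381e+24
4.368390e-02 2.184583e+24
4.704187e-02 2.180190e+24
5.065797e-02 2.175109e+24
5.455203e-02 2.169236e+24
5.874543e-02 2.162450e+24
6.326118e-02 2.154615e+24
6.812405e-02 2.145573e+24
7.336072e-02 2.135147e+24
7.899994e-02 2.123136e+24
8.507265e-02 2.109315e+24
9.161216e-02 2.093428e+24
9.865436e-02 2.075193e+24
1.062379e-01 2.054297e+24
1.144044e-01 2.030395e+24
1.231986e-01 2.003114e+24
1.326688e-01 1.972054e+24
1.428671e-01 1.936790e+24
1.538492e-01 1.896884e+24
1.656756e-01 1.851895e+24
1.784110e-01 1.801392e+24
1.921254e-01 1.744978e+24
2.068940e-01 1.682315e+24
2.227979e-01 1.613152e+24
2.399243e-01 1.537370e+24
2.583672e-01 1.455013e+24
2.782278e-01 1.366341e+24
2.996151e-01 1.271860e+24
3.226465e-01 1.172359e+24
3.474482e-01 1.068927e+24
3.741565e-01 9.629508e+23
4.029178e-01 8.560786e+23
4.338899e-01 7.501617e+23
4.672429e-01 6.471565e+23
5.031598e-01 5.490029e+23
5.418375e-01 4.574872e+23
5.834884e-01 3.741064e+23
6.283410e-01 2.999546e+23
6.766414e-01 2.356486e+23
7.286547e-01 1.813058e+23
7.846661e-01 1.365763e+23
8.449832e-01 1.007233e+23
9.099368e-01 7.273501e+22
9.798834e-01 5.144875e+22
1.055207e+00 3.566678e+22
1.136320e+00 2.425058e+22
1.223669e+00 1.618527e+22
1.317732e+00 1.061386e+22
1.419026e+00 6.845925e+21
1.528106e+00 4.347773e+21
1.645571e+00 2.721817e+21
1.772065e+00 1.681478e+21
1.908284e+00 1.026219e+21
2.054973e+00 6.193964e+20
2.212938e+00 3.701034e+20
2.383046e+00 2.191425e+20
2.566230e+00 1.287000e+20
2.763495e+00 7.503278e+19
2.975924e+00 4.345987e+19
3.204683e+00 2.502691e+19
3.451026e+00 1.433824e+19
3.716305e+00 8.177411e+18
4.001977e+00 4.645183e+18
4.309608e+00 2.629468e+18
4.640886e+00 1.483883e+18
4.997630e+00 8.351518e+17
5.381796e+00 4.689357e+17
5.795493e+00 2.627690e+17
6.240991e+00 1.469816e+17
6.720734e+00 8.208814e+16
7.237355e+00 4.578414e+16
7.793689e+00 2.550610e+16
8.392787e+00 1.419497e+16
9.037939e+00 7.893061e+15
9.732682e+00 4.385585e+15
1.048083e+01 2.435146e+15
1.128649e+01 1.351377e+15
1.215408e+01 7.495754e+14
1.308836e+01 4.155949e+14
1.409446e+01 2.303384e+14
1.517790e+01 1.276219e+14
1.634462e+01 7.069125e+13
1.760102e+01 3.914748e+13
1.895401e+01 2.167472e+13
2.041100e+01 1.199851e+13
2.197998e+01 6.641022e+12
2.366958e+01 3.675242e+12
2.548905e+01 2.033705e+12
2.744839e+01 1.125247e+12
2.955834e+01 6.225457e+11
3.183048e+01 3.444000e+11
3.427728e+01 1.905144e+11
3.691217e+01 1.053827e+11
3.974959e+01 5.828952e+10
4.280513e+01 3.223994e+10
4.609555e+01 1.783130e+10
4.963891e+01 9.861861e+09
5.345463e+01 5.454106e+09
5.756368e+01 3.016328e+09
6.198858e+01 1.668112e+09
6.675363e+01 9.224968e+08
7.188496e+01 5.101504e+08
7.741074e+01 2.821151e+08
8.336128e+01 1.560090e+08
8.976923e+01 8.627187e+07
9.666977e+01 4.770735e+07
1.041007e+02 2.638144e+07
1.121029e+02 1.458845e+07
1.207203e+02 8.067100e+06
1.300000e+02 4.460915e+06
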