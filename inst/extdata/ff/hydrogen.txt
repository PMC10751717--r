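# squared molecular form factor per gram: hydrogen
# columns: x_invA  F2_per_g  (x = sin(theta/2)/lambda)
# provenance: Thomas-Fermi-style analytic form factor, independent-atom mixture rule; format_version: 1
0.000000e+00 5.974346e+23
1.000000e-03 5.974196e+23
1.076870e-03 5.974172e+23
1.159648e-03 5.974144e+23
1.248790e-03 5.974112e+23
1.344784e-03 5.974074e+23
1.448158e-03 5.974031e+23
1.559477e-03 5.973981e+23
1.679354e-03 5.973922e+23
1.808445e-03 5.973855e+23
1.947460e-03 5.973776e+23
2.097160e-03 5.973686e+23
2.258369e-03 5.973580e+23
2.431969e-03 5.973458e+23
2.618914e-03 5.973316e+23
2.820229e-03 5.973152e+23
3.037019e-03 5.972961e+23
3.270474e-03 5.972740e+23
3.521874e-03 5.972484e+23
3.792599e-03 5.972186e+23
4.084136e-03 5.971842e+23
4.398082e-03 5.971442e+23
4.736161e-03 5.970978e+23
5.100229e-03 5.970441e+23
5.492282e-03 5.969818e+23
5.914472e-03 5.969095e+23
6.369116e-03 5.968258e+23
6.858708e-03 5.967286e+23
7.385935e-03 5.966160e+23
7.953690e-03 5.964855e+23
8.565088e-03 5.963341e+23
9.223483e-03 5.961587e+23
9.932490e-03 5.959553e+23
1.069600e-02 5.957195e+23
1.151820e-02 5.954463e+23
1.240360e-02 5.951296e+23
1.335706e-02 5.947627e+23
1.438381e-02 5.943375e+23
1.548949e-02 5.938449e+23
1.668016e-02 5.932743e+23
1.796236e-02 5.926135e+23
1.934312e-02 5.918483e+23
2.083003e-02 5.909626e+23
2.243122e-02 5.899374e+23
2.415551e-02 5.887514e+23
2.601233e-02 5.873798e+23
2.801189e-02 5.857942e+23
3.016516e-02 5.839622e+23
3.248395e-02 5.818467e+23
3.498098e-02 5.794053e+23
3.766996e-02 5.765903e+23
4.056564e-02 5.733472e+23
4.368390e-02 5.696148e+23
4.704187e-02 5.653245e+23
5.065797e-02 5.603998e+23
5.455203e-02 5.547557e+23
5.874543e-02 5.482993e+23
6.326118e-02 5.409293e+23
6.812405e-02 5.325371e+23
7.336072e-02 5.230078e+23
7.899994e-02 5.122226e+23
8.507265e-02 5.000612e+23
9.161216e-02 4.864068e+23
9.865436e-02 4.711508e+23
1.062379e-01 4.542005e+23
1.144044e-01 4.354874e+23
1.231986e-01 4.149773e+23
1.326688e-01 3.926816e+23
1.428671e-01 3.686687e+23
1.538492e-01 3.430749e+23
1.656756e-01 3.161135e+23
1.784110e-01 2.880800e+23
1.921254e-01 2.593508e+23
2.068940e-01 2.303756e+23
2.227979e-01 2.016596e+23
2.399243e-01 1.737382e+23
2.583672e-01 1.471429e+23
2.782278e-01 1.223636e+23
2.996151e-01 9.981124e+22
3.226465e-01 7.978566e+22
3.474482e-01 6.245482e+22
3.741565e-01 4.784832e+22
4.029178e-01 3.586635e+22
4.338899e-01 2.630204e+22
4.672429e-01 1.887294e+22
5.031598e-01 1.325574e+22
5.418375e-01 9.118914e+21
5.834884e-01 6.148950e+21
6.283410e-01 4.068093e+21
6.766414e-01 2.643510e+21
7.286547e-01 1.689192e+21
7.846661e-01 1.062713e+21
8.449832e-01 6.590725e+20
9.099368e-01 4.034313e+20
9.798834e-01 2.440344e+20
1.055207e+00 1.460435e+20
1.136320e+00 8.656482e+19
1.223669e+00 5.087157e+19
1.317732e+00 2.966857e+19
1.419026e+00 1.718639e+19
1.528106e+00 9.896531e+18
1.645571e+00 5.668948e+18
1.772065e+00 3.232374e+18
1.908284e+00 1.835646e+18
2.054973e+00 1.038785e+18
2.212938e+00 5.860388e+17
2.383046e+00 3.297341e+17
2.566230e+00 1.850927e+17
2.763495e+00 1.036897e+17
2.975924e+00 5.798538e+16
3.204683e+00 3.237722e+16
3.451026e+00 1.805456e+16
3.716305e+00 1.005629e+16
4.001977e+00 5.595755e+15
4.309608e+00 3.111055e+15
4.640886e+00 1.728364e+15
4.997630e+00 9.595877e+14
5.381796e+00 5.324686e+14
5.795493e+00 2.953221e+14
6.240991e+00 1.637264e+14
6.720734e+00 9.073746e+13
7.237355e+00 5.027141e+13
7.793689e+00 2.784455e+13
8.392787e+00 1.541913e+13
9.037939e+00 8.536772e+12
9.732682e+00 4.725561e+12
1.048083e+01 2.615467e+12
1.128649e+01 1.447404e+12
1.215408e+01 8.009085e+11
1.308836e+01 4.431339e+11
1.409446e+01 2.451611e+11
1.517790e+01 1.356244e+11
1.634462e+01 7.502352e+10
1.760102e+01 4.149870e+10
1.895401e+01 2.295366e+10
2.041100e+01 1.269558e+10
2.197998e+01 7.021639e+09
2.366958e+01 3.883398e+09
2.548905e+01 2.147704e+09
2.744839e+01 1.187757e+09
2.955834e+01 6.568601e+08
3.183048e+01 3.632546e+08
3.427728e+01 2.008831e+08
3.691217e+01 1.110888e+08
3.974959e+01 6.143177e+07
4.280513e+01 3.397127e+07
4.609555e+01 1.878569e+07
4.963891e+01 1.038819e+07
5.345463e+01 5.744469e+06
5.756368e+01 3.176566e+06
6.198858e+01 1.756564e+06
6.675363e+01 9.713341e+05
7.188496e+01 5.371207e+05
7.741074e+01 2.970119e+05
8.336128e+01 1.642385e+05
8.976923e+01 9.081866e+04
9.666977e+01 5.021974e+04
1.041007e+02 2.776983e+04
1.121029e+02 1.535576e+04
1.207203e+02 8.491201e+03
1.300000e+02 4.695333e+03
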