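# squared molecular form factor per gram: water
# columns: x_invA  F2_per_g  (x = sin(theta/2)/lambda)
# provenance: Thomas-Fermi-style analytic form factor, independent-atom mixture rule; format_version: 1
0.000000e+00 2.206303e+24
1.000000e-03 2.206288e+24
1.076870e-03 2.206285e+24
1.159648e-03 2.206282e+24
1.248790e-03 2.206279e+24
1.344784e-03 2.206275e+24
1.448158e-03 2.206271e+24
1.559477e-03 2.206266e+24
1.679354e-03 2.206260e+24
1.808445e-03 2.206253e+24
1.947460e-03 2.206245e+24
2.097160e-03 2.206236e+24
2.258369e-03 2.206226e+24
2.431969e-03 2.206213e+24
2.618914e-03 2.206199e+24
2.820229e-03 2.206182e+24
3.037019e-03 2.206163e+24
3.270474e-03 2.206141e+24
3.521874e-03 2.206115e+24
3.792599e-03 2.206085e+24
4.084136e-03 2.206051e+24
4.398082e-03 2.206010e+24
4.736161e-03 2.205964e+24
5.100229e-03 2.205909e+24
5.492282e-03 2.205847e+24
5.914472e-03 2.205774e+24
6.369116e-03 2.205689e+24
6.858708e-03 2.205591e+24
7.385935e-03 2.205478e+24
7.953690e-03 2.205346e+24
8.565088e-03 2.205194e+24
9.223483e-03 2.205017e+24
9.932490e-03 2.204811e+24
1.069600e-02 2.204573e+24
1.151820e-02 2.204297e+24
1.240360e-02 2.203978e+24
1.335706e-02 2.203607e+24
1.438381e-02 2.203177e+24
1.548949e-02 2.202678e+24
1.668016e-02 2.202101e+24
1.796236e-02 2.201431e+24
1.934312e-02 2.200654e+24
2.083003e-02 2.199755e+24
2.243122e-02 2.198712e+24
2.415551e-02 2.197504e+24
2.601233e-02 2.196104e+24
2.801189e-02 2.194483e+24
3.016516e-02 2.192605e+24
3.248395e-02 2.190430e+24
3.498098e-02 2.187912e+24
3.766996e-02 2.184997e+24
4.056564e-02 2.181625e+24
4.368390e-02 2.177724e+24
4.704187e-02 2.173213e+24
5.065797e-02 2.168000e+24
5.455203e-02 2.161979e+24
5.874543e-02 2.155027e+24
6.326118e-02 2.147008e+24
6.812405e-02 2.137764e+24
7.336072e-02 2.127120e+24
7.899994e-02 2.114874e+24
8.507265e-02 2.100804e+24
9.161216e-02 2.084661e+24
9.865436e-02 2.066168e+24
1.062379e-01 2.045022e+24
1.144044e-01 2.020893e+24
1.231986e-01 1.993426e+24
1.326688e-01 1.962240e+24
1.428671e-01 1.926940e+24
1.538492e-01 1.887120e+24
1.656756e-01 1.842373e+24
1.784110e-01 1.792308e+24
1.921254e-01 1.736564e+24
2.068940e-01 1.674836e+24
2.227979e-01 1.606900e+24
2.399243e-01 1.532646e+24
2.583672e-01 1.452110e+24
2.782278e-01 1.365513e+24
2.996151e-01 1.273298e+24
3.226465e-01 1.176161e+24
3.474482e-01 1.075072e+24
3.741565e-01 9.712792e+23
4.029178e-01 8.662934e+23
4.338899e-01 7.618382e+23
4.672429e-01 6.597730e+23
5.031598e-01 5.619851e+23
5.418375e-01 4.702613e+23
5.834884e-01 3.861544e+23
6.283410e-01 3.108610e+23
6.766414e-01 2.451320e+23
7.286547e-01 1.892296e+23
7.846661e-01 1.429403e+23
8.449832e-01 1.056375e+23
9.099368e-01 7.638450e+22
9.798834e-01 5.405612e+22
1.055207e+00 3.745958e+22
1.136320e+00 2.543742e+22
1.223669e+00 1.694198e+22
1.317732e+00 1.107862e+22
1.419026e+00 7.120846e+21
1.528106e+00 4.504290e+21
1.645571e+00 2.807426e+21
1.772065e+00 1.726308e+21
1.908284e+00 1.048546e+21
2.054973e+00 6.298379e+20
2.212938e+00 3.745678e+20
2.383046e+00 2.207753e+20
2.566230e+00 1.290965e+20
2.763495e+00 7.495712e+19
2.975924e+00 4.325164e+19
3.204683e+00 2.482023e+19
3.451026e+00 1.417465e+19
3.716305e+00 8.060860e+18
4.001977e+00 4.567129e+18
4.309608e+00 2.579303e+18
4.640886e+00 1.452576e+18
4.997630e+00 8.160396e+17
5.381796e+00 4.574659e+17
5.795493e+00 2.559783e+17
6.240991e+00 1.430049e+17
6.720734e+00 7.978012e+16
7.237355e+00 4.445448e+16
7.793689e+00 2.474478e+16
8.392787e+00 1.376131e+16
9.037939e+00 7.647110e+15
9.732682e+00 4.246606e+15
1.048083e+01 2.356858e+15
1.128649e+01 1.307394e+15
1.215408e+01 7.249204e+14
1.308836e+01 4.018012e+14
1.409446e+01 2.226340e+14
1.517790e+01 1.233247e+14
1.634462e+01 6.829732e+13
1.760102e+01 3.781524e+13
1.895401e+01 2.093398e+13
2.041100e+01 1.158696e+13
2.197998e+01 6.412525e+12
2.366958e+01 3.548448e+12
2.548905e+01 1.963380e+12
2.744839e+01 1.086259e+12
2.955834e+01 6.009381e+11
3.183048e+01 3.324287e+11
3.427728e+01 1.838837e+11
3.691217e+01 1.017109e+11
3.974959e+01 5.625664e+10
4.280513e+01 3.111464e+10
4.609555e+01 1.720848e+10
4.963891e+01 9.517191e+09
5.345463e+01 5.263386e+09
5.756368e+01 2.910805e+09
6.198858e+01 1.609733e+09
6.675363e+01 8.902009e+08
7.188496e+01 4.922853e+08
7.741074e+01 2.722331e+08
8.336128e+01 1.505432e+08
8.976923e+01 8.324873e+07
9.666977e+01 4.603532e+07
1.041007e+02 2.545670e+07
1.121029e+02 1.407702e+07
1.207203e+02 7.784266e+06
1.300000e+02 4.304501e+06
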