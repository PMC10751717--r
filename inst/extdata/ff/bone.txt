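# squared molecular form factor per gram: bone
# columns: x_invA  F2_per_g  (x = sin(theta/2)/lambda)
# provenance: Thomas-Fermi-style analytic form factor, independent-atom mixture rule; format_version: 1
0.000000e+00 3.264143e+24
1.000000e-03 3.264126e+24
1.076870e-03 3.264124e+24
1.159648e-03 3.264121e+24
1.248790e-03 3.264117e+24
1.344784e-03 3.264113e+24
1.448158e-03 3.264108e+24
1.559477e-03 3.264103e+24
1.679354e-03 3.264096e+24
1.808445e-03 3.264089e+24
1.947460e-03 3.264080e+24
2.097160e-03 3.264070e+24
2.258369e-03 3.264059e+24
2.431969e-03 3.264046e+24
2.618914e-03 3.264030e+24
2.820229e-03 3.264012e+24
3.037019e-03 3.263991e+24
3.270474e-03 3.263967e+24
3.521874e-03 3.263939e+24
3.792599e-03 3.263907e+24
4.084136e-03 3.263869e+24
4.398082e-03 3.263825e+24
4.736161e-03 3.263774e+24
5.100229e-03 3.263716e+24
5.492282e-03 3.263648e+24
5.914472e-03 3.263568e+24
6.369116e-03 3.263477e+24
6.858708e-03 3.263371e+24
7.385935e-03 3.263247e+24
7.953690e-03 3.263104e+24
8.565088e-03 3.262939e+24
9.223483e-03 3.262746e+24
9.932490e-03 3.262524e+24
1.069600e-02 3.262265e+24
1.151820e-02 3.261966e+24
1.240360e-02 3.261618e+24
1.335706e-02 3.261216e+24
1.438381e-02 3.260749e+24
1.548949e-02 3.260207e+24
1.668016e-02 3.259580e+24
1.796236e-02 3.258852e+24
1.934312e-02 3.258009e+24
2.083003e-02 3.257031e+24
2.243122e-02 3.255898e+24
2.415551e-02 3.254584e+24
2.601233e-02 3.253062e+24
2.801189e-02 3.251298e+24
3.016516e-02 3.249255e+24
3.248395e-02 3.246887e+24
3.498098e-02 3.244145e+24
3.766996e-02 3.240969e+24
4.056564e-02 3.237292e+24
4.368390e-02 3.233036e+24
4.704187e-02 3.228111e+24
5.065797e-02 3.222413e+24
5.455203e-02 3.215824e+24
5.874543e-02 3.208209e+24
6.326118e-02 3.199411e+24
6.812405e-02 3.189253e+24
7.336072e-02 3.177532e+24
7.899994e-02 3.164020e+24
8.507265e-02 3.148456e+24
9.161216e-02 3.130547e+24
9.865436e-02 3.109966e+24
1.062379e-01 3.086345e+24
1.144044e-01 3.059278e+24
1.231986e-01 3.028320e+24
1.326688e-01 2.992983e+24
1.428671e-01 2.952744e+24
1.538492e-01 2.907045e+24
1.656756e-01 2.855304e+24
1.784110e-01 2.796928e+24
1.921254e-01 2.731323e+24
2.068940e-01 2.657924e+24
2.227979e-01 2.576221e+24
2.399243e-01 2.485789e+24
2.583672e-01 2.386336e+24
2.782278e-01 2.277748e+24
2.996151e-01 2.160136e+24
3.226465e-01 2.033889e+24
3.474482e-01 1.899718e+24
3.741565e-01 1.758690e+24
4.029178e-01 1.612239e+24
4.338899e-01 1.462162e+24
4.672429e-01 1.310571e+24
5.031598e-01 1.159818e+24
5.418375e-01 1.012389e+24
5.834884e-01 8.707624e+23
6.283410e-01 7.372669e+23
6.766414e-01 6.139272e+23
7.286547e-01 5.023374e+23
7.846661e-01 4.035644e+23
8.449832e-01 3.180997e+23
9.099368e-01 2.458628e+23
9.798834e-01 1.862556e+23
1.055207e+00 1.382579e+23
1.136320e+00 1.005521e+23
1.223669e+00 7.165561e+22
1.317732e+00 5.004834e+22
1.419026e+00 3.427788e+22
1.528106e+00 2.303582e+22
1.645571e+00 1.520222e+22
1.772065e+00 9.861177e+21
1.908284e+00 6.293847e+21
2.054973e+00 3.956828e+21
2.212938e+00 2.453103e+21
2.383046e+00 1.501486e+21
2.566230e+00 9.083569e+20
2.763495e+00 5.437511e+20
2.975924e+00 3.224106e+20
3.204683e+00 1.895461e+20
3.451026e+00 1.105905e+20
3.716305e+00 6.408978e+19
4.001977e+00 3.692032e+19
4.309608e+00 2.115702e+19
4.640886e+00 1.206791e+19
4.997630e+00 6.855599e+18
5.381796e+00 3.880743e+18
5.795493e+00 2.189959e+18
6.240991e+00 1.232484e+18
6.720734e+00 6.919944e+17
7.237355e+00 3.877340e+17
7.793689e+00 2.168663e+17
8.392787e+00 1.211098e+17
9.037939e+00 6.754368e+16
9.732682e+00 3.762585e+16
1.048083e+01 2.093879e+16
1.128649e+01 1.164231e+16
1.215408e+01 6.468453e+15
1.308836e+01 3.591527e+15
1.409446e+01 1.993030e+15
1.517790e+01 1.105447e+15
1.634462e+01 6.128860e+14
1.760102e+01 3.396755e+14
1.895401e+01 1.881971e+14
2.041100e+01 1.042424e+14
2.197998e+01 5.772646e+13
2.366958e+01 3.196083e+13
2.548905e+01 1.769236e+13
2.744839e+01 9.792384e+12
2.955834e+01 5.419199e+12
3.183048e+01 2.998702e+12
3.427728e+01 1.659166e+12
3.691217e+01 9.179315e+11
3.974959e+01 5.078082e+11
4.280513e+01 2.809068e+11
4.609555e+01 1.553824e+11
4.963891e+01 8.594515e+10
5.345463e+01 4.753613e+10
5.756368e+01 2.629126e+10
6.198858e+01 1.454073e+10
6.675363e+01 8.041738e+09
7.188496e+01 4.447379e+09
7.741074e+01 2.459519e+09
8.336128e+01 1.360158e+09
8.976923e+01 7.521805e+08
9.666977e+01 4.159582e+08
1.041007e+02 2.300238e+08
1.121029e+02 1.272014e+08
1.207203e+02 7.034088e+07
1.300000e+02 3.889741e+07
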