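# squared molecular form factor per gram: steel316
# columns: x_invA  F2_per_g  (x = sin(theta/2)/lambda)
# provenance: Thomas-Fermi-style analytic form factor, independent-atom mixture rule; format_version: 1
0.000000e+00 7.330030e+24
1.000000e-03 7.330009e+24
1.076870e-03 7.330006e+24
1.159648e-03 7.330002e+24
1.248790e-03 7.329998e+24
1.344784e-03 7.329993e+24
1.448158e-03 7.329987e+24
1.559477e-03 7.329980e+24
1.679354e-03 7.329971e+24
1.808445e-03 7.329962e+24
1.947460e-03 7.329951e+24
2.097160e-03 7.329938e+24
2.258369e-03 7.329924e+24
2.431969e-03 7.329907e+24
2.618914e-03 7.329887e+24
2.820229e-03 7.329864e+24
3.037019e-03 7.329838e+24
3.270474e-03 7.329807e+24
3.521874e-03 7.329771e+24
3.792599e-03 7.329730e+24
4.084136e-03 7.329682e+24
4.398082e-03 7.329626e+24
4.736161e-03 7.329562e+24
5.100229e-03 7.329487e+24
5.492282e-03 7.329400e+24
5.914472e-03 7.329299e+24
6.369116e-03 7.329183e+24
6.858708e-03 7.329047e+24
7.385935e-03 7.328891e+24
7.953690e-03 7.328709e+24
8.565088e-03 7.328498e+24
9.223483e-03 7.328253e+24
9.932490e-03 7.327969e+24
1.069600e-02 7.327640e+24
1.151820e-02 7.327259e+24
1.240360e-02 7.326817e+24
1.335706e-02 7.326304e+24
1.438381e-02 7.325709e+24
1.548949e-02 7.325019e+24
1.668016e-02 7.324220e+24
1.796236e-02 7.323293e+24
1.934312e-02 7.322218e+24
2.083003e-02 7.320971e+24
2.243122e-02 7.319526e+24
2.415551e-02 7.317851e+24
2.601233e-02 7.315909e+24
2.801189e-02 7.313658e+24
3.016516e-02 7.311048e+24
3.248395e-02 7.308024e+24
3.498098e-02 7.304518e+24
3.766996e-02 7.300455e+24
4.056564e-02 7.295748e+24
4.368390e-02 7.290293e+24
4.704187e-02 7.283974e+24
5.065797e-02 7.276655e+24
5.455203e-02 7.268179e+24
5.874543e-02 7.258366e+24
6.326118e-02 7.247006e+24
6.812405e-02 7.233861e+24
7.336072e-02 7.218655e+24
7.899994e-02 7.201071e+24
8.507265e-02 7.180748e+24
9.161216e-02 7.157270e+24
9.865436e-02 7.130164e+24
1.062379e-01 7.098893e+24
1.144044e-01 7.062844e+24
1.231986e-01 7.021328e+24
1.326688e-01 6.973567e+24
1.428671e-01 6.918690e+24
1.538492e-01 6.855731e+24
1.656756e-01 6.783618e+24
1.784110e-01 6.701182e+24
1.921254e-01 6.607155e+24
2.068940e-01 6.500181e+24
2.227979e-01 6.378839e+24
2.399243e-01 6.241665e+24
2.583672e-01 6.087197e+24
2.782278e-01 5.914030e+24
2.996151e-01 5.720891e+24
3.226465e-01 5.506727e+24
3.474482e-01 5.270820e+24
3.741565e-01 5.012914e+24
4.029178e-01 4.733349e+24
4.338899e-01 4.433206e+24
4.672429e-01 4.114432e+24
5.031598e-01 3.779933e+24
5.418375e-01 3.433620e+24
5.834884e-01 3.080371e+24
6.283410e-01 2.725895e+24
6.766414e-01 2.376495e+24
7.286547e-01 2.038720e+24
7.846661e-01 1.718937e+24
8.449832e-01 1.422871e+24
9.099368e-01 1.155160e+24
9.798834e-01 9.190107e+23
1.055207e+00 7.159896e+23
1.136320e+00 5.460012e+23
1.223669e+00 4.074453e+23
1.317732e+00 2.975238e+23
1.419026e+00 2.126367e+23
1.528106e+00 1.487999e+23
1.645571e+00 1.020203e+23
1.772065e+00 6.858670e+22
1.908284e+00 4.525600e+22
2.054973e+00 2.933994e+22
2.212938e+00 1.871064e+22
2.383046e+00 1.175127e+22
2.566230e+00 7.277406e+21
2.763495e+00 4.449276e+21
2.975924e+00 2.688658e+21
3.204683e+00 1.607710e+21
3.451026e+00 9.522960e+20
3.716305e+00 5.593253e+20
4.001977e+00 3.260538e+20
4.309608e+00 1.888065e+20
4.640886e+00 1.086889e+20
4.997630e+00 6.224418e+19
5.381796e+00 3.548393e+19
5.795493e+00 2.014786e+19
6.240991e+00 1.140008e+19
6.720734e+00 6.430755e+18
7.237355e+00 3.617936e+18
7.793689e+00 2.030741e+18
8.392787e+00 1.137561e+18
9.037939e+00 6.361152e+17
9.732682e+00 3.551720e+17
1.048083e+01 1.980483e+17
1.128649e+01 1.103086e+17
1.215408e+01 6.137896e+16
1.308836e+01 3.412398e+16
1.409446e+01 1.895743e+16
1.517790e+01 1.052501e+16
1.634462e+01 5.840186e+15
1.760102e+01 3.239097e+15
1.895401e+01 1.795737e+15
2.041100e+01 9.951933e+14
2.197998e+01 5.513648e+14
2.366958e+01 3.053907e+14
2.548905e+01 1.691116e+14
2.744839e+01 9.362792e+13
2.955834e+01 5.182789e+13
3.183048e+01 2.868521e+13
3.427728e+01 1.587441e+13
3.691217e+01 8.783946e+12
3.974959e+01 4.860052e+12
4.280513e+01 2.688789e+12
4.609555e+01 1.487450e+12
4.963891e+01 8.228137e+11
5.345463e+01 4.551328e+11
5.756368e+01 2.517417e+11
6.198858e+01 1.392372e+11
6.675363e+01 7.700893e+10
7.188496e+01 4.259065e+10
7.741074e+01 2.355465e+10
8.336128e+01 1.302656e+10
8.976923e+01 7.204016e+09
9.666977e+01 3.983940e+09
1.041007e+02 2.203154e+09
1.121029e+02 1.218349e+09
1.207203e+02 6.737431e+08
1.300000e+02 3.725744e+08
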