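# squared molecular form factor per gram: oxygen
# columns: x_invA  F2_per_g  (x = sin(theta/2)/lambda)
# provenance: Thomas-Fermi-style analytic form factor, independent-atom mixture rule; format_version: 1
0.000000e+00 2.409007e+24
1.000000e-03 2.408992e+24
1.076870e-03 2.408989e+24
1.159648e-03 2.408987e+24
1.248790e-03 2.408983e+24
1.344784e-03 2.408979e+24
1.448158e-03 2.408975e+24
1.559477e-03 2.408970e+24
1.679354e-03 2.408964e+24
1.808445e-03 2.408957e+24
1.947460e-03 2.408949e+24
2.097160e-03 2.408940e+24
2.258369e-03 2.408930e+24
2.431969e-03 2.408917e+24
2.618914e-03 2.408903e+24
2.820229e-03 2.408886e+24
3.037019e-03 2.408867e+24
3.270474e-03 2.408845e+24
3.521874e-03 2.408819e+24
3.792599e-03 2.408789e+24
4.084136e-03 2.408754e+24
4.398082e-03 2.408714e+24
4.736161e-03 2.408667e+24
5.100229e-03 2.408613e+24
5.492282e-03 2.408550e+24
5.914472e-03 2.408477e+24
6.369116e-03 2.408393e+24
6.858708e-03 2.408295e+24
7.385935e-03 2.408181e+24
7.953690e-03 2.408049e+24
8.565088e-03 2.407897e+24
9.223483e-03 2.407719e+24
9.932490e-03 2.407514e+24
1.069600e-02 2.407276e+24
1.151820e-02 2.406999e+24
1.240360e-02 2.406679e+24
1.335706e-02 2.406308e+24
1.438381e-02 2.405877e+24
1.548949e-02 2.405378e+24
1.668016e-02 2.404799e+24
1.796236e-02 2.404128e+24
1.934312e-02 2.403351e+24
2.083003e-02 2.402449e+24
2.243122e-02 2.401404e+24
2.415551e-02 2.400194e+24
2.601233e-02 2.398790e+24
2.801189e-02 2.397164e+24
3.016516e-02 2.395280e+24
3.248395e-02 2.393098e+24
3.498098e-02 2.390570e+24
3.766996e-02 2.387643e+24
4.056564e-02 2.384254e+24
4.368390e-02 2.380332e+24
4.704187e-02 2.375794e+24
5.065797e-02 2.370545e+24
5.455203e-02 2.364475e+24
5.874543e-02 2.357462e+24
6.326118e-02 2.349361e+24
6.812405e-02 2.340010e+24
7.336072e-02 2.329224e+24
7.899994e-02 2.316795e+24
8.507265e-02 2.302484e+24
9.161216e-02 2.286027e+24
9.865436e-02 2.267127e+24
1.062379e-01 2.245453e+24
1.144044e-01 2.220641e+24
1.231986e-01 2.192297e+24
1.326688e-01 2.159991e+24
1.428671e-01 2.123269e+24
1.538492e-01 2.081657e+24
1.656756e-01 2.034669e+24
1.784110e-01 1.981828e+24
1.921254e-01 1.922680e+24
2.068940e-01 1.856826e+24
2.227979e-01 1.783949e+24
2.399243e-01 1.703857e+24
2.583672e-01 1.616525e+24
2.782278e-01 1.522139e+24
2.996151e-01 1.421148e+24
3.226465e-01 1.314296e+24
3.474482e-01 1.202653e+24
3.741565e-01 1.087624e+24
4.029178e-01 9.709203e+23
4.338899e-01 8.545097e+23
4.672429e-01 7.405211e+23
5.031598e-01 6.311204e+23
5.418375e-01 5.283614e+23
5.834884e-01 4.340320e+23
6.283410e-01 3.495144e+23
6.766414e-01 2.756835e+23
7.286547e-01 2.128582e+23
7.846661e-01 1.608157e+23
8.449832e-01 1.188639e+23
9.099368e-01 8.595749e+22
9.798834e-01 6.083600e+22
1.055207e+00 4.216078e+22
1.136320e+00 2.863142e+22
1.223669e+00 1.907012e+22
1.317732e+00 1.247069e+22
1.419026e+00 8.015848e+21
1.528106e+00 5.070546e+21
1.645571e+00 3.160424e+21
1.772065e+00 1.943401e+21
1.908284e+00 1.180423e+21
2.054973e+00 7.090614e+20
2.212938e+00 4.216864e+20
2.383046e+00 2.485496e+20
2.566230e+00 1.453382e+20
2.763495e+00 8.438804e+19
2.975924e+00 4.869369e+19
3.204683e+00 2.794329e+19
3.451026e+00 1.595826e+19
3.716305e+00 9.075195e+18
4.001977e+00 5.141845e+18
4.309608e+00 2.903882e+18
4.640886e+00 1.635371e+18
4.997630e+00 9.187329e+17
5.381796e+00 5.150357e+17
5.795493e+00 2.881922e+17
6.240991e+00 1.610017e+17
6.720734e+00 8.982033e+16
7.237355e+00 5.004904e+16
7.793689e+00 2.785891e+16
8.392787e+00 1.549318e+16
9.037939e+00 8.609507e+15
9.732682e+00 4.781048e+15
1.048083e+01 2.653473e+15
1.128649e+01 1.471932e+15
1.215408e+01 8.161535e+14
1.308836e+01 4.523690e+14
1.409446e+01 2.506531e+14
1.517790e+01 1.388455e+14
1.634462e+01 7.689277e+13
1.760102e+01 4.257442e+13
1.895401e+01 2.356860e+13
2.041100e+01 1.304522e+13
2.197998e+01 7.219565e+12
2.366958e+01 3.995033e+12
2.548905e+01 2.210480e+12
2.744839e+01 1.222968e+12
2.955834e+01 6.765686e+11
3.183048e+01 3.742662e+11
3.427728e+01 2.070263e+11
3.691217e+01 1.145116e+11
3.974959e+01 6.333677e+10
4.280513e+01 3.503055e+10
4.609555e+01 1.937424e+10
4.963891e+01 1.071497e+10
5.345463e+01 5.925805e+09
5.756368e+01 3.277142e+09
6.198858e+01 1.812324e+09
6.675363e+01 1.002236e+09
7.188496e+01 5.542415e+08
7.741074e+01 3.064948e+08
8.336128e+01 1.694897e+08
8.976923e+01 9.372594e+07
9.666977e+01 5.182907e+07
1.041007e+02 2.866054e+07
1.121029e+02 1.584868e+07
1.207203e+02 8.763949e+06
1.300000e+02 4.846241e+06
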