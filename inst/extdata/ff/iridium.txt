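# squared molecular form factor per gram: iridium
# columns: x_invA  F2_per_g  (x = sin(theta/2)/lambda)
# provenance: Thomas-Fermi-style analytic form factor, independent-atom mixture rule; format_version: 1
0.000000e+00 1.857550e+25
1.000000e-03 1.857548e+25
1.076870e-03 1.857547e+25
1.159648e-03 1.857547e+25
1.248790e-03 1.857546e+25
1.344784e-03 1.857546e+25
1.448158e-03 1.857545e+25
1.559477e-03 1.857544e+25
1.679354e-03 1.857543e+25
1.808445e-03 1.857542e+25
1.947460e-03 1.857540e+25
2.097160e-03 1.857539e+25
2.258369e-03 1.857537e+25
2.431969e-03 1.857535e+25
2.618914e-03 1.857532e+25
2.820229e-03 1.857530e+25
3.037019e-03 1.857526e+25
3.270474e-03 1.857523e+25
3.521874e-03 1.857518e+25
3.792599e-03 1.857513e+25
4.084136e-03 1.857507e+25
4.398082e-03 1.857500e+25
4.736161e-03 1.857492e+25
5.100229e-03 1.857483e+25
5.492282e-03 1.857472e+25
5.914472e-03 1.857460e+25
6.369116e-03 1.857446e+25
6.858708e-03 1.857429e+25
7.385935e-03 1.857409e+25
7.953690e-03 1.857387e+25
8.565088e-03 1.857361e+25
9.223483e-03 1.857331e+25
9.932490e-03 1.857296e+25
1.069600e-02 1.857255e+25
1.151820e-02 1.857208e+25
1.240360e-02 1.857153e+25
1.335706e-02 1.857090e+25
1.438381e-02 1.857017e+25
1.548949e-02 1.856931e+25
1.668016e-02 1.856833e+25
1.796236e-02 1.856718e+25
1.934312e-02 1.856585e+25
2.083003e-02 1.856431e+25
2.243122e-02 1.856253e+25
2.415551e-02 1.856046e+25
2.601233e-02 1.855806e+25
2.801189e-02 1.855527e+25
3.016516e-02 1.855204e+25
3.248395e-02 1.854830e+25
3.498098e-02 1.854397e+25
3.766996e-02 1.853894e+25
4.056564e-02 1.853311e+25
4.368390e-02 1.852635e+25
4.704187e-02 1.851852e+25
5.065797e-02 1.850944e+25
5.455203e-02 1.849892e+25
5.874543e-02 1.848673e+25
6.326118e-02 1.847261e+25
6.812405e-02 1.845625e+25
7.336072e-02 1.843730e+25
7.899994e-02 1.841536e+25
8.507265e-02 1.838995e+25
9.161216e-02 1.836054e+25
9.865436e-02 1.832651e+25
1.062379e-01 1.828715e+25
1.144044e-01 1.824164e+25
1.231986e-01 1.818903e+25
1.326688e-01 1.812826e+25
1.428671e-01 1.805812e+25
1.538492e-01 1.797719e+25
1.656756e-01 1.788391e+25
1.784110e-01 1.777650e+25
1.921254e-01 1.765295e+25
2.068940e-01 1.751101e+25
2.227979e-01 1.734820e+25
2.399243e-01 1.716175e+25
2.583672e-01 1.694866e+25
2.782278e-01 1.670568e+25
2.996151e-01 1.642934e+25
3.226465e-01 1.611599e+25
3.474482e-01 1.576191e+25
3.741565e-01 1.536340e+25
4.029178e-01 1.491690e+25
4.338899e-01 1.441924e+25
4.672429e-01 1.386783e+25
5.031598e-01 1.326098e+25
5.418375e-01 1.259823e+25
5.834884e-01 1.188066e+25
6.283410e-01 1.111133e+25
6.766414e-01 1.029552e+25
7.286547e-01 9.440981e+24
7.846661e-01 8.558061e+24
8.449832e-01 7.659529e+24
9.099368e-01 6.760224e+24
9.798834e-01 5.876393e+24
1.055207e+00 5.024764e+24
1.136320e+00 4.221434e+24
1.223669e+00 3.480672e+24
1.317732e+00 2.813808e+24
1.419026e+00 2.228380e+24
1.528106e+00 1.727677e+24
1.645571e+00 1.310752e+24
1.772065e+00 9.728999e+23
1.908284e+00 7.065038e+23
2.054973e+00 5.020780e+23
2.212938e+00 3.493398e+23
2.383046e+00 2.381467e+23
2.566230e+00 1.591979e+23
2.763495e+00 1.044640e+23
2.975924e+00 6.736276e+22
3.204683e+00 4.273830e+22
3.451026e+00 2.671137e+22
3.716305e+00 1.646638e+22
4.001977e+00 1.002437e+22
4.309608e+00 6.033800e+21
4.640886e+00 3.594948e+21
4.997630e+00 2.122398e+21
5.381796e+00 1.242868e+21
5.795493e+00 7.225791e+20
6.240991e+00 4.174176e+20
6.720734e+00 2.397784e+20
7.237355e+00 1.370564e+20
7.793689e+00 7.800156e+19
8.392787e+00 4.422400e+19
9.037939e+00 2.499035e+19
9.732682e+00 1.408093e+19
1.048083e+01 7.914018e+18
1.128649e+01 4.438258e+18
1.215408e+01 2.484293e+18
1.308836e+01 1.388280e+18
1.409446e+01 7.746944e+17
1.517790e+01 4.317637e+17
1.634462e+01 2.403789e+17
1.760102e+01 1.337038e+17
1.895401e+01 7.430919e+16
2.041100e+01 4.127055e+16
2.197998e+01 2.290750e+16
2.366958e+01 1.270838e+16
2.548905e+01 7.047066e+15
2.744839e+01 3.906239e+15
2.955834e+01 2.164534e+15
3.183048e+01 1.199071e+15
3.427728e+01 6.640759e+14
3.691217e+01 3.677031e+14
3.974959e+01 2.035619e+14
4.280513e+01 1.126747e+14
4.609555e+01 6.235861e+13
4.963891e+01 3.450761e+13
5.345463e+01 1.909364e+13
5.756368e+01 1.056390e+13
6.198858e+01 5.844221e+12
6.675363e+01 3.232961e+12
7.188496e+01 1.788338e+12
7.741074e+01 9.891848e+11
8.336128e+01 5.471256e+11
8.976923e+01 3.026083e+11
9.666977e+01 1.673636e+11
1.041007e+02 9.256126e+10
1.121029e+02 5.119027e+10
1.207203e+02 2.830981e+10
1.300000e+02 1.565593e+10
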