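# photon interaction coefficients: hydrogen
# density_g_cm3: 8.375e-05
# composition: H:1.0
# columns: E_keV mu_pe mu_co mu_ra mu_tot muen  (cm^2/g)
# provenance: constructed 2026-09 from free-electron Klein-Nishina incoherent
#   cross sections, a Thomas-Fermi-style analytic form-factor coherent model,
#   and photoelectric cross sections obtained as residuals against standard
#   published (NIST-grid) attenuation totals for water/air/Fe/Pb with
#   power-law Z interpolation (explicit K edge for Ir at 76.111 keV).
#   muen for water and dry air transcribed from the standard NIST mass
#   energy-absorption tables; other materials use the energy-transfer
#   approximation (no fluorescence escape, no radiative correction).
#   Photoelectric tabulation variant (Pratt renormalization etc.): not
#   applicable, residual-based construction.
# format_version: 1
1.000000e+00 1.362727e+02 3.958932e-01 3.671285e-01 1.370357e+02 1.362735e+02
1.500000e+00 4.455919e+01 3.951252e-01 3.345946e-01 4.528891e+01 4.456035e+01
2.000000e+00 1.961360e+01 3.943611e-01 2.969484e-01 2.030491e+01 1.961513e+01
3.000000e+00 5.959780e+00 3.928444e-01 2.229025e-01 6.575527e+00 5.962057e+00
4.000000e+00 2.968104e+00 3.913428e-01 1.640456e-01 3.523492e+00 2.971115e+00
5.000000e+00 1.519259e+00 3.898562e-01 1.223130e-01 2.031428e+00 1.522994e+00
6.000000e+00 8.713886e-01 3.883842e-01 9.355578e-02 1.353329e+00 8.758342e-01
8.000000e+00 6.297286e-02 3.854835e-01 5.915059e-02 5.076070e-01 6.880727e-02
1.000000e+01 2.509518e-02 3.826391e-01 4.056387e-02 4.482981e-01 3.227487e-02
1.500000e+01 4.556022e-03 3.757638e-01 1.967317e-02 3.999930e-01 1.491949e-02
2.000000e+01 1.295726e-03 3.692068e-01 1.149064e-02 3.819932e-01 1.460575e-02
3.000000e+01 1.882910e-04 3.569635e-01 5.263546e-03 3.624154e-01 1.876430e-02
4.000000e+01 3.837015e-05 3.457582e-01 2.996222e-03 3.487928e-01 2.316320e-02
5.000000e+01 1.027799e-05 3.354636e-01 1.930767e-03 3.374047e-01 2.708481e-02
6.000000e+01 5.429673e-06 3.259721e-01 1.348495e-03 3.273261e-01 3.052595e-02
8.000000e+01 1.983755e-06 3.090442e-01 7.695374e-04 3.098157e-01 3.619985e-02
1.000000e+02 9.084542e-07 2.943850e-01 5.048308e-04 2.948907e-01 4.062702e-02
1.500000e+02 2.197777e-07 2.650252e-01 2.576497e-04 2.652831e-01 4.811839e-02
2.000000e+02 8.029677e-08 2.428467e-01 1.866329e-04 2.430334e-01 5.254049e-02
3.000000e+02 1.942579e-08 2.111634e-01 1.545315e-04 2.113179e-01 5.694114e-02
4.000000e+02 7.097299e-09 1.891953e-01 1.500645e-04 1.893454e-01 5.857991e-02
5.000000e+02 3.250185e-09 1.727579e-01 1.492797e-04 1.729072e-01 5.897378e-02
6.000000e+02 1.717013e-09 1.598121e-01 1.491079e-04 1.599612e-01 5.873338e-02
8.000000e+02 6.273185e-10 1.403731e-01 1.490486e-04 1.405221e-01 5.736489e-02
1.000000e+03 2.872784e-10 1.261829e-01 1.490419e-04 1.263319e-01 5.552584e-02
1.250000e+03 1.315582e-10 1.128072e-01 1.490406e-04 1.129563e-01 5.308451e-02
1.500000e+03 6.949981e-11 1.025056e-01 1.490404e-04 1.026547e-01 5.070780e-02
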