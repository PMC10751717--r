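# photon interaction coefficients: bone
# density_g_cm3: 1.92
# composition: H:0.034 C:0.155 N:0.042 O:0.435 Na:0.001 Mg:0.002 P:0.103 S:0.003 Ca:0.225
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
1.000000e+00 5.099942e+03 2.054311e-01 2.136528e+00 5.102284e+03 5.097182e+03
1.500000e+00 1.779936e+03 2.050326e-01 2.094462e+00 1.782236e+03 1.779937e+03
2.000000e+00 8.155213e+02 2.046361e-01 2.038331e+00 8.177643e+02 8.155221e+02
3.000000e+00 2.622920e+02 2.038490e-01 1.893426e+00 2.643893e+02 2.622932e+02
4.000000e+00 1.164463e+02 2.030699e-01 1.721812e+00 1.183712e+02 1.164479e+02
5.000000e+00 6.059254e+01 2.022984e-01 1.541554e+00 6.233639e+01 6.059448e+01
6.000000e+00 3.522712e+01 2.015346e-01 1.366041e+00 3.679470e+01 3.522943e+01
8.000000e+00 4.703458e+01 2.000294e-01 1.057939e+00 4.829254e+01 4.703760e+01
1.000000e+01 2.497050e+01 1.985535e-01 8.199555e-01 2.598901e+01 2.497423e+01
1.500000e+01 7.626101e+00 1.949858e-01 4.637750e-01 8.284861e+00 7.631478e+00
2.000000e+01 3.186749e+00 1.915834e-01 2.923121e-01 3.670645e+00 3.193656e+00
3.000000e+01 8.907372e-01 1.852303e-01 1.450621e-01 1.221030e+00 9.003764e-01
4.000000e+01 3.448593e-01 1.794158e-01 8.583255e-02 6.101076e-01 3.568589e-01
5.000000e+01 1.584502e-01 1.740739e-01 5.642661e-02 3.889507e-01 1.724993e-01
6.000000e+01 8.828157e-02 1.691487e-01 3.980696e-02 2.972372e-01 1.041188e-01
8.000000e+01 3.477060e-02 1.603647e-01 2.277175e-02 2.179070e-01 5.355386e-02
1.000000e+02 1.675255e-02 1.527579e-01 1.470279e-02 1.842133e-01 3.783366e-02
1.500000e+02 4.370797e-03 1.375230e-01 6.626947e-03 1.485207e-01 2.933957e-02
2.000000e+02 1.664430e-03 1.260144e-01 3.797332e-03 1.314762e-01 2.892793e-02
3.000000e+02 4.147546e-04 1.095738e-01 1.836460e-03 1.118250e-01 2.996180e-02
4.000000e+02 1.559878e-04 9.817445e-02 1.223251e-03 9.955369e-02 3.055341e-02
5.000000e+02 7.305987e-05 8.964501e-02 9.906241e-04 9.070870e-02 3.067487e-02
6.000000e+02 3.931308e-05 8.292734e-02 8.942677e-04 8.386093e-02 3.051637e-02
8.000000e+02 1.478686e-05 7.284033e-02 8.329663e-04 7.368808e-02 2.978173e-02
1.000000e+03 6.926185e-06 6.547697e-02 8.193860e-04 6.630328e-02 2.881958e-02
1.250000e+03 3.244303e-06 5.853627e-02 8.155137e-04 5.935503e-02 2.754908e-02
1.500000e+03 1.745867e-06 5.319071e-02 8.146458e-04 5.400710e-02 2.631429e-02
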