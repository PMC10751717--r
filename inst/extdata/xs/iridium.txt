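# photon interaction coefficients: iridium
# density_g_cm3: 22.42
# composition: Ir:1.0
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
1.000000e+00 5.375610e+03 1.598592e-01 1.230167e+01 5.388072e+03 5.375610e+03
1.500000e+00 2.398788e+03 1.595490e-01 1.223278e+01 2.411181e+03 2.398789e+03
2.000000e+00 1.293263e+03 1.592405e-01 1.213746e+01 1.305560e+03 1.293264e+03
3.000000e+00 1.827910e+03 1.586281e-01 1.187218e+01 1.839941e+03 1.827911e+03
4.000000e+00 1.138998e+03 1.580217e-01 1.151753e+01 1.150673e+03 1.138999e+03
5.000000e+00 6.579698e+02 1.574214e-01 1.108827e+01 6.692155e+02 6.579713e+02
6.000000e+00 4.160335e+02 1.568271e-01 1.060092e+01 4.267913e+02 4.160353e+02
8.000000e+00 2.230849e+02 1.556558e-01 9.519003e+00 2.327595e+02 2.230872e+02
1.000000e+01 1.240723e+02 1.545072e-01 8.394093e+00 1.326209e+02 1.240752e+02
1.500000e+01 1.018251e+02 1.517310e-01 5.897561e+00 1.078744e+02 1.018293e+02
2.000000e+01 7.676937e+01 1.490834e-01 4.141760e+00 8.106021e+01 7.677474e+01
3.000000e+01 2.589326e+01 1.441396e-01 2.258686e+00 2.829608e+01 2.590076e+01
4.000000e+01 1.180401e+01 1.396150e-01 1.402004e+00 1.334563e+01 1.181335e+01
5.000000e+01 6.364592e+00 1.354581e-01 9.505970e-01 7.450647e+00 6.375525e+00
6.000000e+01 3.826084e+00 1.316255e-01 6.847513e-01 4.642460e+00 3.838408e+00
7.600000e+01 1.969542e+00 1.260772e-01 4.421156e-01 2.537735e+00 1.983746e+00
7.630000e+01 8.871964e+00 1.259794e-01 4.388592e-01 9.436803e+00 8.886199e+00
8.000000e+01 7.817820e+00 1.247901e-01 4.014497e-01 8.344060e+00 7.832437e+00
9.000000e+01 5.707526e+00 1.217282e-01 3.210914e-01 6.150346e+00 5.723090e+00
1.000000e+02 4.298333e+00 1.188708e-01 2.624496e-01 4.679653e+00 4.314737e+00
1.500000e+02 1.464877e+00 1.070155e-01 1.193510e-01 1.691244e+00 1.484307e+00
2.000000e+02 6.749533e-01 9.805994e-02 6.778467e-02 8.407979e-01 6.961688e-01
3.000000e+02 2.288510e-01 8.526642e-02 3.055845e-02 3.446759e-01 2.518435e-01
4.000000e+02 1.088972e-01 7.639586e-02 1.759945e-02 2.028925e-01 1.325514e-01
5.000000e+02 6.235133e-02 6.975856e-02 1.176366e-02 1.438736e-01 8.616457e-02
6.000000e+02 3.995283e-02 6.453111e-02 8.759085e-03 1.132430e-01 6.366900e-02
8.000000e+02 1.993326e-02 5.668175e-02 6.129874e-03 8.274488e-02 4.309683e-02
1.000000e+03 1.142333e-02 5.095185e-02 5.213074e-03 6.758825e-02 3.384431e-02
1.250000e+03 6.466493e-03 4.555085e-02 4.824901e-03 5.684224e-02 2.790168e-02
1.500000e+03 4.679142e-03 4.139112e-02 4.702500e-03 5.077276e-02 2.515463e-02
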