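# photon interaction coefficients: oxygen
# density_g_cm3: 0.001332
# composition: O:1.0
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
1.000000e+00 4.589928e+03 1.995426e-01 1.570400e+00 4.591698e+03 4.587106e+03
1.500000e+00 1.547542e+03 1.991556e-01 1.531738e+00 1.549273e+03 1.547542e+03
2.000000e+00 6.933085e+02 1.987704e-01 1.480355e+00 6.949876e+02 6.933092e+02
3.000000e+00 2.155790e+02 1.980060e-01 1.349170e+00 2.171262e+02 2.155802e+02
4.000000e+00 9.174500e+01 1.972491e-01 1.197371e+00 9.313962e+01 9.174652e+01
5.000000e+00 4.664060e+01 1.964998e-01 1.043099e+00 4.788020e+01 4.664248e+01
6.000000e+00 2.658916e+01 1.957579e-01 8.987989e-01 2.768372e+01 2.659140e+01
8.000000e+00 1.076474e+01 1.942958e-01 6.614733e-01 1.162051e+01 1.076769e+01
1.000000e+01 5.261031e+00 1.928622e-01 4.931967e-01 5.947090e+00 5.264650e+00
1.500000e+01 1.379416e+00 1.893968e-01 2.651493e-01 1.833962e+00 1.384640e+00
2.000000e+01 5.139826e-01 1.860919e-01 1.635637e-01 8.636382e-01 5.206912e-01
3.000000e+01 1.180368e-01 1.799209e-01 7.932717e-02 3.772849e-01 1.273997e-01
4.000000e+01 3.755724e-02 1.742730e-01 4.633315e-02 2.581634e-01 4.921288e-02
5.000000e+01 1.366734e-02 1.690842e-01 3.022703e-02 2.129786e-01 2.731376e-02
6.000000e+01 7.220209e-03 1.643002e-01 2.122394e-02 1.927444e-01 2.260351e-02
8.000000e+01 2.637936e-03 1.557680e-01 1.208152e-02 1.704875e-01 2.088280e-02
1.000000e+02 1.208034e-03 1.483793e-01 7.785340e-03 1.573727e-01 2.168487e-02
1.500000e+02 2.922535e-04 1.335811e-01 3.515302e-03 1.373886e-01 2.454533e-02
2.000000e+02 1.067761e-04 1.224024e-01 2.035605e-03 1.245448e-01 2.658880e-02
3.000000e+02 2.583181e-05 1.064330e-01 1.038908e-03 1.074977e-01 2.872595e-02
4.000000e+02 9.437765e-06 9.536040e-02 7.525510e-04 9.612239e-02 2.953555e-02
5.000000e+02 4.321994e-06 8.707545e-02 6.571520e-04 8.773692e-02 2.972896e-02
6.000000e+02 2.283231e-06 8.055033e-02 6.231098e-04 8.117573e-02 2.960576e-02
8.000000e+02 8.341885e-07 7.075245e-02 6.050979e-04 7.135838e-02 2.891454e-02
1.000000e+03 3.820139e-07 6.360015e-02 6.019333e-04 6.420246e-02 2.798716e-02
1.250000e+03 1.749420e-07 5.685840e-02 6.011719e-04 5.745975e-02 2.675644e-02
1.500000e+03 9.241868e-08 5.166606e-02 6.010222e-04 5.226717e-02 2.555842e-02
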