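# photon interaction coefficients: steel316
# density_g_cm3: 8.02
# composition: Si:0.01 Cr:0.17 Mn:0.02 Fe:0.655 Ni:0.12 Mo:0.025
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
1.000000e+00 8.909221e+03 1.858404e-01 4.831426e+00 8.914239e+03 8.905325e+03
1.500000e+00 3.335373e+03 1.854799e-01 4.776381e+00 3.340335e+03 3.335373e+03
2.000000e+00 1.595108e+03 1.851212e-01 4.701154e+00 1.599995e+03 1.595109e+03
3.000000e+00 5.611878e+02 1.844093e-01 4.497363e+00 5.658696e+02 5.611889e+02
4.000000e+00 2.581280e+02 1.837044e-01 4.237249e+00 2.625490e+02 2.581294e+02
5.000000e+00 1.390285e+02 1.830065e-01 3.940237e+00 1.431517e+02 1.390302e+02
6.000000e+00 8.313859e+01 1.823156e-01 3.625103e+00 8.694600e+01 8.314067e+01
8.000000e+00 2.878050e+02 1.809539e-01 3.000840e+00 2.909868e+02 2.878078e+02
1.000000e+01 1.596430e+02 1.796187e-01 2.446843e+00 1.622695e+02 1.596464e+02
1.500000e+01 5.367881e+01 1.763913e-01 1.483307e+00 5.533850e+01 5.368367e+01
2.000000e+01 2.402443e+01 1.733133e-01 9.624280e-01 2.516017e+01 2.403068e+01
3.000000e+01 7.359828e+00 1.675660e-01 4.910752e-01 8.018469e+00 7.368548e+00
4.000000e+01 3.104878e+00 1.623060e-01 2.950954e-01 3.562280e+00 3.115733e+00
5.000000e+01 1.569687e+00 1.574735e-01 1.958341e-01 1.922995e+00 1.582396e+00
6.000000e+01 8.944003e-01 1.530180e-01 1.389773e-01 1.186396e+00 9.087272e-01
8.000000e+01 3.636731e-01 1.450717e-01 8.001646e-02 5.887612e-01 3.806651e-01
1.000000e+02 1.911227e-01 1.381904e-01 5.180953e-02 3.811226e-01 2.101935e-01
1.500000e+02 5.197741e-02 1.244083e-01 2.334543e-02 1.997311e-01 7.456507e-02
2.000000e+02 2.030841e-02 1.139972e-01 1.326322e-02 1.475689e-01 4.497196e-02
3.000000e+02 5.213335e-03 9.912443e-02 6.111449e-03 1.104492e-01 3.194267e-02
4.000000e+02 2.012589e-03 8.881218e-02 3.726399e-03 9.455117e-02 2.951120e-02
5.000000e+02 9.639938e-04 8.109614e-02 2.733452e-03 8.479359e-02 2.864750e-02
6.000000e+02 5.290874e-04 7.501909e-02 2.277916e-03 7.782610e-02 2.809975e-02
8.000000e+02 2.057375e-04 6.589401e-02 1.949667e-03 6.804942e-02 2.713400e-02
1.000000e+03 9.886110e-05 5.923285e-02 1.865061e-03 6.119677e-02 2.616384e-02
1.250000e+03 4.749867e-05 5.295404e-02 1.838072e-03 5.483961e-02 2.496646e-02
1.500000e+03 2.650363e-05 4.811825e-02 1.831469e-03 4.997622e-02 2.382979e-02
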