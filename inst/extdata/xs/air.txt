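# photon interaction coefficients: air
# density_g_cm3: 0.0012048
# composition: C:0.000124 N:0.755268 O:0.231781 Ar:0.012827
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
1.000000e+00 3.693769e+03 1.992048e-01 1.440611e+00 3.695409e+03 3.599000e+03
1.500000e+00 1.221749e+03 1.988184e-01 1.403279e+00 1.223352e+03 1.188000e+03
2.000000e+00 5.414916e+02 1.984339e-01 1.353819e+00 5.430438e+02 5.262000e+02
3.000000e+00 1.660911e+02 1.976707e-01 1.228356e+00 1.675171e+02 1.614000e+02
4.000000e+00 7.883918e+01 1.969151e-01 1.084644e+00 8.012074e+01 7.636000e+01
5.000000e+00 4.031768e+01 1.961671e-01 9.402179e-01 4.145406e+01 3.931000e+01
6.000000e+00 2.310496e+01 1.954264e-01 8.066091e-01 2.410699e+01 2.270000e+01
8.000000e+00 1.043480e+01 1.939669e-01 5.898880e-01 1.121866e+01 9.446000e+00
1.000000e+01 5.181727e+00 1.925356e-01 4.382882e-01 5.812551e+00 4.742000e+00
1.500000e+01 1.403048e+00 1.890761e-01 2.348362e-01 1.826960e+00 1.334000e+00
2.000000e+01 5.367482e-01 1.857768e-01 1.446376e-01 8.671627e-01 5.389000e-01
3.000000e+01 1.291600e-01 1.796162e-01 7.001928e-02 3.787955e-01 1.537000e-01
4.000000e+01 4.332062e-02 1.739780e-01 4.086089e-02 2.581595e-01 6.833000e-02
5.000000e+01 1.696771e-02 1.687980e-01 2.664531e-02 2.124110e-01 4.098000e-02
6.000000e+01 9.086566e-03 1.640220e-01 1.870463e-02 1.918132e-01 3.041000e-02
8.000000e+01 3.386967e-03 1.555043e-01 1.064547e-02 1.695367e-01 2.407000e-02
1.000000e+02 1.573051e-03 1.481281e-01 6.860180e-03 1.565613e-01 2.325000e-02
1.500000e+02 3.889421e-04 1.333549e-01 3.100384e-03 1.368442e-01 2.496000e-02
2.000000e+02 1.438724e-04 1.221951e-01 1.799832e-03 1.241388e-01 2.672000e-02
3.000000e+02 3.512213e-05 1.062528e-01 9.283235e-04 1.072162e-01 2.872000e-02
4.000000e+02 1.294811e-05 9.519894e-02 6.809834e-04 9.589287e-02 2.949000e-02
5.000000e+02 5.971794e-06 8.692802e-02 5.995628e-04 8.753355e-02 2.966000e-02
6.000000e+02 3.173385e-06 8.041395e-02 5.707090e-04 8.098783e-02 2.953000e-02
8.000000e+02 1.170374e-06 7.063266e-02 5.554522e-04 7.118928e-02 2.882000e-02
1.000000e+03 5.399594e-07 6.349247e-02 5.527487e-04 6.404575e-02 2.789000e-02
1.250000e+03 2.491395e-07 5.676213e-02 5.520898e-04 5.731447e-02 2.666000e-02
1.500000e+03 1.324375e-07 5.157858e-02 5.519584e-04 5.213067e-02 2.547000e-02
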