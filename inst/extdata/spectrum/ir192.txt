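# Ir-192 photon emission spectrum (gamma + K X-ray lines)
# columns: E_keV  intensity_photons_per_decay
# provenance: transcribed 2026-09 from standard nuclear data compilations (DDEP/NNDC style); lines >= 0.05%
# total_yield_per_decay: 2.299741
# intensity_weighted_mean_keV: 354.674
# format_version: 1
61.486 1.200000e-02
63.000 2.050000e-02
65.122 2.630000e-02
66.831 4.460000e-02
71.079 6.900000e-03
73.363 1.800000e-03
75.749 1.530000e-02
77.831 4.000000e-03
136.343 1.990000e-03
201.311 4.730000e-03
205.794 3.340000e-02
283.267 2.660000e-03
295.957 2.871000e-01
308.455 2.970000e-01
316.506 8.286000e-01
374.485 7.260000e-03
416.469 6.700000e-03
468.069 4.784000e-01
484.575 3.189000e-02
489.060 4.380000e-03
588.581 4.522000e-02
604.411 8.216000e-02
612.462 5.340000e-02
884.537 2.920000e-03
1061.480 5.310000e-04
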