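---
title: "Collisional-kerma Monte Carlo for HDR Ir-192: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collisional-kerma Monte Carlo for HDR Ir-192: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`hdrkerma` computes absorbed dose around high-dose-rate (HDR) Ir-192
brachytherapy sources by scoring *collisional kerma* with a photon-only
Monte Carlo engine. The central approximation is charged-particle
equilibrium (CPE): secondary electrons set in motion by photon interactions
deposit their energy locally, so the absorbed dose equals the collisional
kerma

$$ D \approx K_{\mathrm{coll}} = \int \Phi_E \, E \,
   \frac{\mu_{en}}{\rho}(E) \, dE
   = \frac{1}{V} \sum_i l_i \, E_i \, \frac{\mu_{en}}{\rho}(E_i), $$

where $\Phi_E$ is the photon fluence, $\mu_{en}/\rho$ the mass
energy-absorption coefficient of the local material, $V$ the scoring voxel
volume and $l_i$ the track length of a photon of energy $E_i$ inside the
voxel. For Ir-192 (mean photon energy about 355 keV, CSDA ranges of the
secondaries well under a millimetre in water) the approximation holds to
about 1% beyond roughly 2 mm from a source. The package therefore tracks no
electrons: photoelectric absorption deposits the full photon energy at the
interaction site, incoherent (Compton) scattering deposits $E - E'$, and
coherent (Rayleigh) scattering deposits nothing. Results within 2 mm of a
source should be read with the CPE caveat in mind; dose-grid files carry
that note in their headers.

The right-hand sum above is the *track-length kerma estimator* (TLKE):
every photon flight contributes to **all** voxels it traverses, not only to
the voxel where it happens to interact. The package also provides the
analogue event-by-event scorer (energy transferred at interaction sites,
divided by voxel mass) — it estimates the same quantity, at far higher
variance, and serves as the built-in cross-check of the TLKE.

# Photon interaction data

The shipped coefficient tables (`inst/extdata/xs/*.txt`) cover 1–1500 keV
for water, dry air, ICRU-44-style cortical bone, AISI 316 stainless steel,
iridium, and elemental hydrogen and oxygen. They are constructed, not
downloaded (each file header records this):

* **incoherent**: free-electron Klein–Nishina cross section per electron
  times electrons per gram;
* **coherent**: Thomson cross section modulated by a Thomas–Fermi-style
  analytic atomic form factor $F(x, Z) = Z\,(1 + (c x / Z^{1/3})^2)^{-2}$,
  with the scale $c$ calibrated against the standard water coherent value
  near 60 keV;
* **photoelectric**: the residual (total − incoherent − coherent) against
  transcribed standard NIST-grid attenuation totals at four anchor
  materials (water, dry air, iron, lead), extended to the other elements by
  piecewise power-law interpolation in $Z$ and extended beyond ~60–100 keV,
  where the residual falls below transcription noise, by a fitted
  $\sim E^{-3}$ tail. Iridium gets an explicit K edge at 76.111 keV with an
  above-edge extrapolation fitted on 100–300 keV.
* **$\mu_{en}/\rho$**: transcribed from the standard NIST mass
  energy-absorption tables for water and dry air (these two drive every
  quantitative result of the package); for the other materials it is the
  energy-transfer coefficient $\mu_{tr}$ (no fluorescence escape, no
  radiative-loss correction), which only affects kerma reported *inside*
  bone/steel/iridium.

Because compound totals are sums of the element partials, the
sum-consistency invariant (partials = total) holds exactly; the loader
additionally enforces positivity, a strictly increasing grid spanning
[1, 1400] keV, and $\mu_{en} \le \mu_{tot}$. Interpolation is log–log
linear — standard for photon coefficients, exact at the nodes, and easy to
test. The reconstruction error of the water total against the transcribed
standard values is below 0.5% above 100 keV and below 1.3% everywhere at or
above 10 keV; errors below 10 keV are irrelevant at Ir-192 energies because
such photons are absorbed within micrometres of where they are produced.

The Ir-192 emission spectrum (gamma plus K X-ray lines at or above 0.05%
intensity, 2.2997 photons per decay, intensity-weighted mean 354.7 keV) is
transcribed from standard nuclear-data compilations into a two-column text
file.

# Transport

Photons start in the source capsule core (position uniform in the core
cylinder, isotropic direction, line-sampled energy) and are tracked
analytically through the nested capsule cylinders (core, steel shell,
cable stub). In a voxel phantom the engine switches to Woodcock delta
tracking: free paths are sampled against a majorant
$\Sigma_{maj} = \max_m \rho_{max,m}\,(\mu/\rho)_m(E)$ (times a 1.01 safety
margin) and tentative collisions are accepted with probability
$\Sigma(\mathbf{r})/\Sigma_{maj}$. Two special worlds avoid needless voxel
grids: a homogeneous sphere (the TG-43 full-scatter water sphere) with
analytic boundaries, and vacuum (the air-kerma-strength geometry). The
capsule clips every world step, so photons re-entering the capsule are
attenuated correctly.

Sampling models, recorded in every run log:

* **Compton**: free-electron Klein–Nishina via Kahn's rejection method.
  Binding and Doppler corrections are omitted; at Ir-192 energies their
  effect on water kerma is far below the package's statistical targets.
* **Rayleigh**: angle sampled from the tabulated squared molecular form
  factor, piecewise linear in $x^2$, by exact inversion of its trapezoid
  cumulative plus a $(1+\cos^2\theta)/2$ rejection. The sampled
  distribution therefore matches the tabulated $\mu_{ra}$ exactly.
* **Fluorescence**: characteristic X-rays and Auger electrons are not
  re-emitted; the photoelectric event absorbs the full photon energy. For
  low-Z media every relaxation falls below the 1 keV cut-off anyway; for
  steel and iridium this slightly overestimates local absorption in the
  capsule (and is part of what the simplified capsule model absorbs into
  its 2% tolerance). Pair production is omitted (threshold 1022 keV; the
  yield above it in the Ir-192 spectrum is negligible).
* **Cut-off**: 1 keV in all materials; photons falling below it are
  absorbed on the spot.

Energy bookkeeping closes per history (emitted = escaped + transferred) to
better than $10^{-9}$ relative and is asserted by the engine.

# Tallies and uncertainties

Voxel traversal uses an exact Siddon walk with half-open voxel ownership
(a crossing exactly on a shared plane belongs to the next voxel; zero-length
corner grazes are dropped), so segment lengths sum to the chord length to
machine precision. Cylindrical scoring cells get analytic segment–annulus
chords.

Variance is accumulated history by history: all contributions of one
primary history (including all split clones of a phase-space record, which
are correlated) are summed into a per-voxel buffer and flushed as a single
statistical unit. The relative Type A uncertainty is
$s/(\sqrt{N}\,\bar{x})$, reported at $k=1$ with $k=2$ available. A
batch-based estimator was the alternative; history-by-history was chosen
because it is unbiased, needs no batch-size tuning, and groups splitting
progeny with their parent naturally.

One inherent, deliberate inconsistency deserves note: the TLKE scores with
the *transcribed* $\mu_{en}/\rho$, while the analogue scorer deposits
*sampled* Klein–Nishina transfers. The transcribed tables include physics
(binding, radiative corrections) the sampler does not, so the two
estimators differ systematically by about 1.5% in water at Ir-192 energies.
The estimator-equivalence tests are therefore run at statistical
resolutions coarser than this, and the package treats the TLKE (anchored to
the standard $\mu_{en}/\rho$) as the authoritative estimator.

# TG-43 characterization

Air-kerma strength: capsule in vacuum, air collision kerma scored in a
cell of 0.1 cm radial width and 0.1 cm height at $r = 10$ cm on the
transverse axis; $S_K = \dot{K}_{air} d^2$ in U/Bq. The stated cell
"width of 0.1 cm" is read as radial extent $10 \pm 0.05$ cm — the only
reading consistent with a cell located *at* $r = 10$ cm. Dose-rate
constant: capsule at the centre of a 40 cm-radius water sphere, water
kerma per decay in a cell of 0.5 mm radial thickness and 1 mm height at
1 cm; $\Lambda = \dot{D}(1\,\mathrm{cm})/S_K$. Both cells are azimuthally
extended into full rings: by the cylindrical symmetry of both scenes this
is an exact variance reduction, not an approximation. With photon-only
transport in vacuum no detector-style electron filtering or scatter
correction applies to the $S_K$ run; the report file says so.

The capsule geometries are *simplified* models assembled from published
source descriptions: a pure-iridium core of 0.6 mm diameter and 3.5 mm
length in a steel capsule of 1.0 mm outer diameter (generic working-group
source), and a 0.65 mm x 3.6 mm core in a 0.9 mm capsule (microSelectron
v2 style), both with right-cylinder ends and a short steel cable stub.
End-weld and tip details are not modelled; the 2% tolerance on
$S_K$/$\Lambda$ reproduction is the binding requirement, and the package
meets it with margin to spare (the dose-rate constant, in which capsule
attenuation largely cancels between numerator and denominator, reproduces
the reference value to about 0.1–0.6% depending on seed).

The uncertainty budget table ships the standard component values
(Monte Carlo physics, phantom composition, cross sections, $\mu_{en}/\rho$,
volume averaging, tally statistics); quadrature combination is
root-sum-square within Type A and Type B and then across the two, with
$k=2$ doubling the total.

# Plan sources, phase space, splitting

A phase-space file (PSF) records photons crossing the capsule surface
(energy, position, direction in the capsule frame, weight) behind a
versioned binary header. The plan source replays records: each record is
split into $n$ clones of weight $1/n$ (default 10), and each clone is
independently assigned a dwell position with probability proportional to
its dwell time, then rigidly transformed by that dwell's frame. Dwell
orientations come from catheter tangents (central differences, one-sided at
the ends) mapped from the capsule axis by the minimal-rotation convention
(rotation about the mutual normal), which removes the roll ambiguity that a
tangent alone leaves open. When a run requests more histories than the PSF
holds, the stream restarts from the beginning while the per-history random
streams continue independently — recorded in the run metadata, and a
deviation to keep in mind if results are ever compared against engines that
stop at PSF exhaustion.

Absolute normalization: per-history kerma grids are scaled so the
prescription point receives the prescription dose (an exact arithmetic
identity at that voxel, and the route a clinical comparison of relative
dose distributions needs). The TG-43 bridge ($S_K$ per history times the
plan's total reference air kerma) is available through `compute_sk()` when
an absolute per-Bq normalization is wanted.

# Benchmark metrics and scenes

Local and global dose-difference ratios and the inverse-square-weighted
relative dose map are computed per unmasked voxel at voxel centres.
Voxels geometrically overlapping the capsule (tested on a 3x3x3 lattice of
points per candidate voxel) are masked from every metric; unmasked voxels
with zero reference dose are auto-masked and counted. Difference
histograms use 0.05% bins for local and 0.005% bins for global ratios; the
distribution mode and sigma come from a Gaussian fit (quadratic in log
counts) over the central bins above 20% of the peak. All unmasked voxels
of the scoring mesh enter the histograms — no sub-volume selection.

The scene builders reproduce the water/air cube benchmark geometry: a
51.1 cm water cube with a central source (case 1), a 20.1 cm water cube in
a 51.1 cm air cube (case 2), the same with the source displaced +7 cm in x
(case 3), and a 20.1 cm / 1 mm$^3$ centred scoring mesh — all scalable for
desk-size runs. The detailed shielded-applicator case is out of scope (its
geometry lives in an external reference); `shielded_scene()` provides a
configurable cylindrical high-Z shell as a structural stand-in. The
package ships no third-party reference datasets (they are not
redistributable); `read_dose_grid()` ingests any congruent external grid
for format-level comparison.

# Clinical pipeline

Structure membership is point-in-polygon at voxel centres
(`mgcv::in.out`), slice by slice, with no partial-volume weighting —
matching voxel-level DVH granularity; thin structures relative to the grid
will show discretization in their DVH curves. Material assignment applies
rules in order (first claim wins): structure membership plus an optional
intensity range, e.g. cortical bone above a threshold inside the body
contour. The bone threshold is a required configuration parameter with no
claimed default — reference values for it vary by scanner and protocol.
A configurable water shell (default 20 cm) pads the phantom for full
scatter; the saturation property (enlarging 20 to 30 cm moves target D90
by less than its Type A uncertainty) is part of the test surface.

DVH curves are cumulative at 0.01 Gy resolution; $V_x$ reads the curve at
$x\%$ of prescription, $D_y$ inverts it with linear interpolation, and
D2cc is flagged undefined for structures under 2 cm$^3$.

# The synthetic-data generators

The fixtures emulate the *scale and topology* of the benchmark scenarios:
17 catheters / 111 dwells / 15 Gy for the prostate-like plan (9 inner
catheters of 7 dwells, 8 outer of 6, on rings of 1.1 and 2.0 cm), a single
19-dwell curved endobronchial catheter at 5 Gy for the lung-like plan,
dwell steps of 0.5 cm, and seeded dwell times uniform on 5–25 s
(prostate) / 8–20 s (lung) — values a planner would recognize as
realistic for a single HDR fraction. Structures are analytic solids
(elliptic-cylinder body, ellipsoidal target and bladder, tubular urethra,
rectum and bronchus, two lung ellipsoids). What they do **not** emulate:
real CT texture and noise, heterogeneous tissue compositions, contour
irregularity, applicator hardware, or inter-patient variability. Passing
tests on these fixtures demonstrates that the pipeline machinery
(segmentation, transport, scoring, DVH arithmetic) is correct at clinical
scale — not that any specific patient dose distribution is reproduced.

# Numerical choices and problem sizes

* RNG: PCG32 with one stream per history (stream selector = history
  index), seeded from the user seed through SplitMix64. Runs are
  bit-reproducible and independent of any batch decomposition.
* Boundary crossings advance the photon by a 1 nm nudge past the surface;
  the induced track-length bias is below $10^{-6}$ relative.
* The Woodcock majorant carries a 1.01 margin; a real attenuation above
  the majorant is an internal-consistency error, not a warning.
* Default problem sizes (chosen so a laptop-class single core finishes the
  whole suite in minutes): the efficiency comparison runs $2 \times 10^6$
  histories on a 20.1 cm water cube with a 4.1 cm / 1 mm$^3$ scoring mesh;
  $S_K$ runs $10^7$ and $\Lambda$ runs $2\text{–}3 \times 10^6$ histories,
  giving Type A uncertainties of 0.5–0.6% — an order of magnitude below
  the 2% acceptance tolerance they are checked against.

# Known limitations

* No electron transport: dose within ~2 mm of a source (or tight against a
  high-Z interface) is kerma, not dose; flagged, not masked.
* Free-electron Compton and analytic form factors: sub-percent effects on
  water kerma at Ir-192 energies, but do not use the tables below ~30 keV
  for precision work in high-Z media.
* Simplified capsule geometry: headline TG-43 parameters reproduce
  reference values within 2%; fine anisotropy near the capsule ends is not
  faithful.
* $\mu_{en}$-vs-sampled-transfer inconsistency of ~1.5% between the two
  estimators (see above); the TLKE is the authoritative one.
* Single-threaded by design; throughput is about $10^5$ histories per
  second per core on the benchmark scenes, which covers desk-scale studies
  but not the $5\times10^{10}$-history runs of production benchmarks.
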