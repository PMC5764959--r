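---
title: "Connectivity phasing and ligand-response models for a membrane ammonium sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity phasing and ligand-response models for a membrane ammonium sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amtkit)
```

## What the package models

The package reimplements, as tested reusable code, the two bespoke
computational strands of a study on a fused ammonium-sensor membrane
protein: an Amt-family transporter domain coupled to a cytoplasmic
histidine-kinase (HK) domain.

1. **Ab initio phasing of very-low-resolution diffraction data.** The
   full-length protein crystallized in the polar hexagonal space group
   P6~3~ and diffracted to only 8 Å. With no molecular-replacement
   solution for the full assembly, phases were recovered from the
   amplitudes alone by a connectivity argument: a correct map, contoured
   to enclose a fixed fraction of the cell volume, must decompose into
   one large connected region per molecule, while maps computed with
   wrong phases fragment or fuse. Random phase sets are therefore
   generated in bulk, filtered by the connectivity of their Fourier
   syntheses, brought to a common origin and enantiomorph, and averaged
   into a centroid whose per-reflection figure of merit (FOM) both
   weights the final synthesis and focuses the next round of sampling,
   while the resolution is extended stepwise from 16 Å to 8 Å.

2. **Ligand-response and binding models.** The sensor's biophysics is
   quantified by a small family of nonlinear models: a Hill saturation
   curve for peak transport currents (half-saturation in the tens of
   millimolar, Hill exponent below one), a single-protonation logistic
   in pH, single-site binding isotherms for thermophoresis data, the
   single-binding-site mass-balance model for calorimetric injection
   heats, and a model-free summary (peak current and half-maximum decay
   time τ~1/2~) for solid-supported-membrane transients, whose
   invariance across lipid-to-protein ratios distinguishes mere charge
   displacement from transmembrane transport.

Because the study's raw low-resolution amplitudes and titration traces
are not publicly deposited, a synthetic-data layer stands in for them:
every stage can be exercised against known ground truth.

## The synthetic crystal

`make_two_domain_phantom()` builds one protomer per asymmetric unit from
Gaussian pseudo-atoms: a compact, well-ordered "Amt" cluster (radius
16 Å) and a smaller "HK" cluster (radius 12 Å) hanging ~29 Å below it.
The cluster centers sit next to the three-fold axis at (1/3, 2/3), so
the P6~3~ operators assemble two trimers per cell, one per
screw-related axis — the packing of the real crystal, whose molecule is
a trimer. Design choices, made once:

* **Cell 105 × 105 × 95 Å (γ = 120°).** The study's low-resolution cell
  is unpublished; this one is chosen so the 16 Å and 8 Å shells hold
  ~90 and ~660 unique reflections, the same information content per
  cycle as the reported 89 and 639. The phasing problem posed to the
  driver therefore has the original's dimensionality.
* **Gaussian widths b = 300 Å² (Amt) and 550 Å² (HK).** At 8 Å only the
  envelope matters and the width plays the B-factor role. A crystal
  whose pattern fades at resolution *d* has a Wilson B of roughly
  4*d*² ≈ 250–400 Å², hence the 300 Å² base; the +250 Å² inflation of
  the HK cluster models the disorder of the cytoplasmic domain as width,
  not occupancy, reproducing its washed-out density at fixed resolution.
* **Amplitude noise 3 %** (multiplicative Gaussian, clipped at zero) —
  typical merged-data quality for a weakly diffracting crystal.
* The defaults produce a top-25 %-volume mask that decomposes into
  exactly two large regions (one per trimer) at every resolution between
  16 and 8 Å. This was verified over phantom seeds 1–5; it is a property
  of the packing, not of any phasing run.

What the phantom does **not** emulate: atomic detail, solvent
contribution, anisotropy, measurement-error models beyond multiplicative
Gaussian noise, and lattice disorder. Passing the recovery tests shows
the *procedure* extracts the envelope information present in ideal-ish
amplitudes; it does not certify performance on pathological real data.

## The phasing driver

`run_phasing()` implements the candidate–filter–average loop.

**Candidate evaluation.** A candidate phase set is synthesized over one
cell (`rho = (1/V) Σ m F exp(-2πi h·x)`, Hermitian full-sphere expansion
of the symmetry-unique list), the top α = 0.25 of voxels are selected —
a volume-based cutoff rather than a σ-level one, because the constraint
semantics ("one region per molecule") need the selected volume to be
identical across candidates — and the selection is labeled into
6-connected components with wrap-around on all axes. Face connectivity
is the strictest standard choice, giving the fewest spurious bridges at
these resolutions. A candidate is *suitable* if the number of large
regions (≥ 10 % of the selected volume) equals the expected count, two
here. In the first cycle a candidate also qualifies via a second, tight
contour (α = 0.10 with at most six regions): the true map at α = 0.10
is exactly two clean blobs, and demanding cleanliness at the tight
contour admits a differently-enriched population.

**First-cycle consensus.** Suitable random sets from the 16 Å shell
(~90 reflections; acceptance ≈ 15–18 % with the dual filter) are
aligned to a common origin and enantiomorph and averaged. Alignment
searches the allowed origin classes of the group ({(0,0), (1/3,2/3),
(2/3,1/3)} × continuous z in P6~3~), with a 64-point FFT scan plus
golden-section refinement (tolerance 10⁻⁴ fractional) on each
continuous axis and the phase flip φ → −φ for the enantiomorph,
maximizing |F|²-weighted phase agreement. Plain averaging of hundreds
of weakly consistent sets converges to a self-consistent attractor that
is not always the right one: the iteration is therefore multi-started
from several reference sets, each basin is scored by the share of the
top eigenvalue of the pairwise agreement matrix (a measure of how much
of the ensemble's coherence a single cluster explains), and the most
coherent basin wins; its eigenvector supplies per-set weights for the
final average. In validation runs the eigenvalue share separated true
from false basins cleanly (≈ 0.36–0.37 vs ≈ 0.30–0.34).

**Reliability calibration.** The raw FOM of an averaged centroid — the
modulus of the mean unit phasor — measures per-set scatter, not the
centroid's own accuracy, and with hundreds of weakly coherent sets it
badly understates the latter. The centroid's reliability is instead
estimated by split-half coherence: the ensemble is halved, each half is
averaged, and the mean cosine between the two half-averages (whose
square root estimates the full average's agreement with truth) scales
the per-reflection phasor moduli into the reported FOMs. These
calibrated FOMs are what weight the final synthesis and set the
concentration of focused resampling.

**Resolution extension.** Cycles 2–4 extend from 16 Å to 8 Å
geometrically in 1/d, each cycle internally split into three sub-steps
so new reflections arrive in batches of a few dozen — small steps keep
the acceptance test informative about the newcomers. Within a sub-step,
candidates are drawn focused around the running centroid: previously
phased reflections from a von Mises distribution whose concentration
κ(m) solves the mean-resultant-length identity (Best–Fisher inverse,
capped at κ_max = 100, and at a sampling merit of 0.7 so the core keeps
wobbling enough for the filter to bite), newcomers uniformly — with
centric phases always restricted to their two allowed values. The
accepted ensemble's mean phasor phases each new shell; previously
phased reflections below merit 0.5 receive the bias-subtracted
selection signal (ensemble mean minus the proposal's expected phasor)
with unit gain, and reflections above it are held fixed. Because the
constraint is blind to translations along the polar axis, per-step
updates would otherwise random-walk the origin and scramble the
relative registration of shells phased at different times; every
updated centroid is therefore re-aligned to its predecessor before it
is accepted (origin pinning).

**Scale.** The standard demonstration uses 10⁴ candidates in cycle 1
and 3 × 3300 in each extension cycle, grids sampled at d_min/2.5 for
the loop (the `grid_dims()` default is d_min/3), and completes in two to
three minutes per seed on one core. The study itself varied its candidate
counts from 30 to 3 × 10⁶; the config reaches such counts, but the
tests run at the demonstration scale.

**What the driver achieves.** On the standard phantom the first-cycle
centroid typically reaches an |F|²-weighted phase agreement of ~0.75
with truth on the 16 Å shell, and the full run a weighted map
correlation above 0.6 (unweighted ≈ 0.46–0.48) after alignment — with
the weighted synthesis always ahead of the unweighted one, the same
ordering the study reported (73 % vs 59 %). The random-phase baseline —
the expected map correlation of a single random phase set, estimated by
averaging twenty draws because any single draw is dominated by a few
strong centric terms — sits near zero. The constraint's information
content caps the first-cycle agreement near 0.75–0.78: the selection
"two clean trimer-shaped regions on the special axes" pins the envelope
but not its internal detail, and averaging cannot manufacture
information the filter never sees. Connectivity at stricter contours,
more candidates, or (as in the original work) orders of magnitude more
sampling push that ceiling up.

## The ligand-response models

All closed forms live in plain functions (`hill_response()`,
`titration_response()`, `binding_isotherm()`, `itc_injection_heats()`,
`ammonium_speciation()`), `generate_dataset()` simulates designs with
Gaussian noise, and `fit_model()` wraps Levenberg–Marquardt weighted
least squares (minpack.lm) with data-derived starting values and
asymptotic standard errors. Choices worth noting:

* **pH titration.** The study cites a "titration function" without its
  form; a single-protonation logistic with free slope *n* (default 1),
  rising with pH, is adopted. Slope and direction are free parameters,
  so a falling response simply fits with I_min > I_max.
* **MST isotherm.** Ligand depletion is neglected: the labeled protein
  is at 0.1–0.25 µM against ligand from 1.5 µM up, so free ≈ total
  ligand everywhere that matters.
* **ITC.** Concentrations follow the standard displacement-dilution
  bookkeeping for a perfusion cell (`P_i = P0 (1−v/V0)^i`); the bound
  complex is the root of the single-site mass-balance quadratic with
  stoichiometry N; the heat of injection *i* is the change in cell heat
  content with the half-displaced-volume correction, per mole of
  injectant. An independent bisection solver for the free-ligand
  equilibrium reproduces the heats to 10⁻⁸ in the tests.
* **Transients.** τ~1/2~ extraction is model-free (first interpolated
  half-amplitude crossing after the signed peak; an instantaneous drop
  counts as a crossing at the drop sample). Biexponential traces are
  used only to *synthesize* fixtures. `classify_electrogenicity()`
  calls "translocation" when mean τ~1/2~ grows by more than 25 % from
  the lowest to the highest lipid-to-protein ratio *and* the increase
  is significant by a one-sided Welch test; the study's criterion is
  qualitative ("unchanged"), so the 25 % threshold is a package
  default, exposed as an argument.
* **Units.** Transport concentrations in mM, binding in µM, time in ms,
  heats in kcal/mol; conversions are the caller's responsibility and
  the interfaces say which unit they expect.

Simulated-recovery behavior at the published designs: with 8 points and
5 % noise the Hill K~0.5~ carries a standard error of roughly a third
of its value — the acceptance checks therefore use the two-standard-
error criterion rather than a fixed percentage. Over 200 replicates the
median K~0.5~ estimate is within 5 % of truth and 1-SE interval
coverage sits in the 55–80 % band expected where asymptotic normality
is only approximate at n = 8.

## Numerical conventions

Fractional coordinates; 0-based grid indices, x fastest; phases in
degrees in [0, 360); the symmetry-unique representative of a reflection
class is the lexicographically greatest mate (Friedel included), making
merging deterministic; systematic absences are dropped at construction;
ties in the volume-fraction threshold break by grid order; maps are
written as CCP4/MRC mode-2 volumes. Supported space groups are a
built-in catalog (P1, P2~1~, P6~3~) with explicit operators and
origin-shift tables — the study needs only P6~3~; the others serve the
tests. MTZ files, anomalous data, general space-group machinery,
density modification and skeletonization are out of scope.

## Known limitations

* The deposited-structure checks (RMSD vs the homolog, ammonium
  coordination distances) require the PDB entries on disk; the package
  does not redistribute or download them.
* The connectivity filter carries little information about reflections
  much weaker than the shell average; the highest-resolution shells of
  the demonstration end with honest but small figures of merit, and the
  unweighted map correlation suffers accordingly — as it did in the
  original study.
* Acceptance of a candidate is binary; the volume-concentration score
  ranks accepted sets but adds little beyond the constraint itself in
  our experiments (it is kept for its diagnostic value and because
  score-weighted averaging is a documented variant).
* The phantom's two-region topology is a designed property of its
  packing. A phantom with touching molecules percolates at α = 0.25 and
  would need a different constraint catalog; the constraint per cycle
  is config, not code.
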