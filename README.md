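# amtkit

Tools for the quantitative analyses behind a trimeric ammonium-sensor
membrane protein: ab initio phasing of very-low-resolution (8–16 Å)
crystallographic amplitude data by connectivity selection of random phase
sets, and the nonlinear ligand-response models of the sensor's biophysics
(transport saturation, pH titration, equilibrium binding, titration
calorimetry, transient-current summaries). It is written for structural
biologists and biophysicists who want these bespoke computations as
tested, reusable, scriptable functions rather than one-off lab code.

## The two core methods

**Connectivity-based ab initio phasing.** A crystal of a two-domain
sensor (membrane Amt domain + disordered cytoplasmic histidine-kinase
domain) in polar space group P6₃ diffracts to only 8 Å. Phases are
recovered from amplitudes alone by exploiting a topological prior: a map
synthesized with correct phases,

ρ(x) = (1/V) Σ_h m(h) |F(h)| exp[iφ(h)] exp(−2πi h·x),

and contoured to enclose the top α = 0.25 of the cell volume, must
decompose into one large 6-connected region per molecule (two trimers
per cell here), while wrong phases fragment or fuse the density. The
driver generates random phase sets (centrics restricted to their two
allowed values), keeps the "suitable" ones, factors out the allowed
origin shifts and the enantiomorph flip, averages them into a centroid
with per-reflection figures of merit m = |⟨exp iφ⟩|, and iterates with
von-Mises-focused resampling (κ solving A₁(κ) = m) while extending
resolution from 16 Å to 8 Å over four cycles. Synthetic crystals with
known ground truth (`make_two_domain_phantom()`) make the whole loop
testable: recovery is scored by the map correlation coefficient between
the recovered and true syntheses after alignment.

**Ligand-response models.** Hill saturation
I = I_max·c^h/(K₀.₅^h + c^h); single-protonation pH titration
I = I_min + (I_max−I_min)/(1+10^{n(pK_app−pH)}); single-site isotherm
F = F_free + (F_bound−F_free)·L/(K_d+L); the single-binding-site
mass-balance model for per-injection calorimetric heats in a perfusion
cell; NH₄⁺/NH₃ speciation at pKa 9.25; and model-free peak/τ½ summaries
of solid-supported-membrane transients, whose invariance across
lipid-to-protein ratios classifies an event as charge displacement
rather than transport. `generate_dataset()` simulates any of these
designs with Gaussian noise and `fit_model()` fits them by weighted
Levenberg–Marquardt least squares with asymptotic standard errors.

## Worked example

Simulate the standard phantom's amplitude-only data and phase it
(`Rscript analysis/02_phase_phantom.R` runs exactly this and prints):

```r
library(amtkit)
out <- run_phasing_demo(seed = 1)
#> weighted map CC vs truth:   0.613
#> unweighted map CC vs truth: 0.461
#> random-phase baseline CC:   0.024
#> |F|^2-weighted phase error: 51.0 deg
```

The weighted map correlation with the withheld truth (0.61 here) exceeds
the unweighted one (0.46) — the same ordering the original analysis
reported for its figure-of-merit-weighted versus unweighted syntheses —
and both are far above the random-phase baseline (≈ 0). The per-step
history (`out$result$history`) shows candidate counts, acceptance and
mean figures of merit per resolution step.

Fit a saturation curve simulated from the published constants
(K₀.₅ = 22.9 mM, h = 0.75, 8 points, 5 % noise):

```r
dat <- generate_dataset("hill", list(i_max = 1, k05 = 22.9, h = 0.75),
                        x = exp(seq(log(1), log(300), length.out = 8)),
                        noise = 0.05, seed = 11)
fit_model(dat)
#> fit_result (hill): converged
#>       estimate std.error
#> i_max  1.02410   0.11262
#> k05   26.07400   9.37950
#> h      0.86311   0.16117
```

Both parameters land within two standard errors of the truth; at this
published design (8 points, 5 % noise) the K₀.₅ standard error is
intrinsically large.

The numbered scripts under `analysis/` run the full workflow — phantom
simulation, phasing, evaluation, response-model fits, structure checks —
and write their tables under `results/`.

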