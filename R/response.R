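# Quantitative ligand-response models of the sensor's biophysics:
# saturation of transport-assay peak currents, pH titration, equilibrium
# binding isotherms, calorimetric injection heats and transient-current
# summaries.

#' Hill saturation response
#'
#' `I = I_max * c^h / (K0.5^h + c^h)`: half-saturating concentration
#' `K0.5` and Hill exponent `h`. The transport-assay peak currents
#' saturate with `K0.5` in the tens of millimolar and `h < 1`.
#'
#' @param c Ligand concentration (mM), `>= 0`.
#' @param i_max Saturating response.
#' @param k05 Half-saturating concentration (mM), `> 0`.
#' @param h Hill exponent, `> 0`.
#' @return Response at `c`.
#' @examples
#' hill_response(22.9, 1, 22.9, 0.75)  # half-maximum at c = K0.5
#' @export
hill_response <- function(c, i_max, k05, h) {
  if (k05 <= 0 || h <= 0) stop("K0.5 and h must be > 0")
  ifelse(c <= 0, 0, i_max * c^h / (k05^h + c^h))
}

#' pH titration response
#'
#' Single-protonation logistic in pH with apparent pK and slope `n`:
#' `I = I_min + (I_max - I_min) / (1 + 10^(n (pK_app - pH)))`.
#' The response rises with pH and crosses the midpoint at `pH = pK_app`.
#'
#' @param pH pH values.
#' @param i_min,i_max Plateau responses at low/high pH.
#' @param pk_app Apparent pK.
#' @param n Slope (`> 0`).
#' @return Response at `pH`.
#' @export
titration_response <- function(pH, i_min, i_max, pk_app, n = 1) {
  if (n <= 0) stop("slope n must be > 0")
  i_min + (i_max - i_min) / (1 + 10^(n * (pk_app - pH)))
}

#' Ammonium fraction of total ammonium/ammonia
#'
#' `NH4+ <-> NH3 + H+` with pKa 9.25: `f(NH4+) = 1 / (1 + 10^(pH - pKa))`.
#' Below neutral pH virtually all of the substrate is the cation.
#'
#' @param pH pH values.
#' @param pKa Acid constant (default 9.25).
#' @return Fraction of the protonated (ionic) species.
#' @export
ammonium_speciation <- function(pH, pKa = 9.25) {
  1 / (1 + 10^(pH - pKa))
}

#' Single-site binding isotherm
#'
#' Signal of a labeled species as a function of free ligand, with no
#' ligand depletion (ligand in large excess over the labeled protein, the
#' regime of the thermophoresis assay):
#' `F = F_free + (F_bound - F_free) * L / (K_d + L)`.
#'
#' @param L Ligand concentration (same units as `k_d`), `>= 0`.
#' @param f_free,f_bound Signal of the free and bound states.
#' @param k_d Dissociation constant, `> 0`.
#' @return Signal at `L`.
#' @export
binding_isotherm <- function(L, f_free, f_bound, k_d) {
  if (k_d <= 0) stop("K_d must be > 0")
  f_free + (f_bound - f_free) * L / (k_d + L)
}

#' Single-binding-site ITC injection heats
#'
#' Per-injection heats (kcal per mole of injectant) of an isothermal
#' titration with `n_inj` identical injections of volume `inj_vol` from a
#' syringe at `syringe_conc` into a perfusion cell of volume `cell_vol`
#' initially holding `cell_conc` protein. Total concentrations follow the
#' standard displacement-dilution bookkeeping
#' (`P_i = P0 (1 - v/V0)^i`, `L_i = Ls (1 - (1 - v/V0)^i)`); the bound
#' complex comes from the single-site mass-balance quadratic with
#' stoichiometry `N`, and the heat of injection `i` is the change in cell
#' heat content corrected for the displaced volume.
#'
#' @param n Stoichiometry `N` (sites per protein), `> 0`.
#' @param k_d Dissociation constant in micromolar, `> 0`.
#' @param dh Binding enthalpy (kcal/mol).
#' @param cell_conc Protein concentration in the cell (micromolar).
#' @param cell_vol Cell volume (mL).
#' @param inj_vol Injection volume (microliter).
#' @param syringe_conc Ligand concentration in the syringe (micromolar).
#' @param n_inj Number of injections.
#' @return Numeric vector of `n_inj` heats (kcal/mol of injectant).
#' @examples
#' # the study's geometry: 28 x 10 uL of 1.3 mM ATP into 100 uM protein
#' q <- itc_injection_heats(1, 11.16, -10, 100, 1.437, 10, 1300, 28)
#' @export
itc_injection_heats <- function(n, k_d, dh, cell_conc, cell_vol,
                                inj_vol, syringe_conc, n_inj) {
  if (n <= 0 || k_d <= 0) stop("N and K_D must be > 0")
  if (cell_conc <= 0 || cell_vol <= 0 || inj_vol <= 0 || syringe_conc <= 0)
    stop("concentrations and volumes must be > 0")
  v <- inj_vol * 1e-3                       # mL
  dil <- 1 - v / cell_vol
  i <- seq_len(n_inj)
  pt <- cell_conc * dil^i                   # uM total protein in cell
  lt <- syringe_conc * (1 - dil^i)          # uM total ligand in cell
  sites <- n * pt
  b <- sites + lt + k_d
  pl <- (b - sqrt(b^2 - 4 * sites * lt)) / 2   # uM bound ligand
  q <- dh * pl * 1e-6 * (cell_vol * 1e-3)      # kcal in cell after inj i
  q_prev <- c(0, q[-n_inj])
  dq <- q - q_prev + (v / cell_vol) * (q + q_prev) / 2
  mol_inj <- syringe_conc * 1e-6 * v * 1e-3    # moles injected each time
  dq / mol_inj
}

#' Summarize a transient current trace
#'
#' Peak current (signed extremum) and half-maximum decay time: the time
#' after the peak at which the absolute current first falls to half the
#' absolute peak, linearly interpolated between samples. An instantaneous
#' drop counts as a crossing at the drop sample. The summary is
#' model-free: no functional form is assumed for the transient.
#'
#' @param t Time points (ms), uniformly spaced, `>= 10` samples.
#' @param current Current samples (nA), same length.
#' @return Object of class `transient_summary`: `peak` (nA, signed),
#'   `t_peak` (ms), `tau_half` (ms).
#' @export
transient_summary <- function(t, current) {
  if (length(t) < 10 || length(t) != length(current))
    stop("need >= 10 uniformly spaced samples")
  if (all(current == 0)) stop("all-zero trace")
  ipk <- which.max(abs(current))
  peak <- current[ipk]
  half <- abs(peak) / 2
  a <- abs(current)
  after <- seq(ipk, length(t))
  below <- after[a[after] <= half]
  if (length(below) == 0) stop("decay incomplete: no half-maximum crossing before trace end")
  j <- below[1]
  if (j == ipk) return(structure(list(peak = peak, t_peak = t[ipk],
                                      tau_half = 0), class = "transient_summary"))
  # linear interpolation between samples j-1 and j
  f <- (a[j - 1] - half) / (a[j - 1] - a[j])
  t_cross <- t[j - 1] + f * (t[j] - t[j - 1])
  structure(list(peak = peak, t_peak = t[ipk], tau_half = t_cross - t[ipk]),
            class = "transient_summary")
}

#' @export
print.transient_summary <- function(x, ...) {
  cat(sprintf("transient_summary: peak %.3g nA at %.3g ms, tau_1/2 = %.3g ms\n",
              x$peak, x$t_peak, x$tau_half))
  invisible(x)
}

#' Classify electrogenic events from decay times across reconstitutions
#'
#' In solid-supported-membrane recordings, translocation of an ionic
#' species across the proteoliposome membrane slows the current decay as
#' the lipid-to-protein ratio (LPR) increases, whereas a mere binding /
#' charge-displacement event leaves the half-maximum decay time
#' unchanged. The verdict is `"translocation"` when the relative increase
#' in mean decay time from the lowest to the highest LPR exceeds
#' `threshold` and is significant by Welch's t-test, else
#' `"displacement"`.
#'
#' @param lpr Numeric LPR condition per replicate (>= 2 distinct values,
#'   >= 3 replicates each).
#' @param tau_half Decay time (ms) per replicate.
#' @param peak Optional peak currents per replicate, summarized but not
#'   used for the verdict.
#' @param threshold Minimum relative increase counted as translocation.
#' @param alpha Significance level of the one-sided Welch test.
#' @return Object of class `electrogenicity`: `verdict`, `rel_change`,
#'   `p_value`, per-condition means, and the relative peak-current change
#'   when `peak` is given.
#' @export
classify_electrogenicity <- function(lpr, tau_half, peak = NULL,
                                     threshold = 0.25, alpha = 0.05) {
  if (length(unique(lpr)) < 2) stop("need at least two LPR conditions")
  if (any(table(lpr) < 3)) stop("need at least three replicates per LPR condition")
  lo <- min(lpr); hi <- max(lpr)
  x_lo <- tau_half[lpr == lo]; x_hi <- tau_half[lpr == hi]
  rel <- (mean(x_hi) - mean(x_lo)) / mean(x_lo)
  p <- if (stats::sd(x_lo) == 0 && stats::sd(x_hi) == 0) {
    if (mean(x_hi) > mean(x_lo)) 0 else 1
  } else stats::t.test(x_hi, x_lo, alternative = "greater")$p.value
  verdict <- if (rel > threshold && p < alpha) "translocation" else "displacement"
  peak_change <- if (!is.null(peak))
    (mean(peak[lpr == hi]) - mean(peak[lpr == lo])) / mean(peak[lpr == lo])
  else NA_real_
  structure(list(verdict = verdict, rel_change = rel, p_value = p,
                 mean_tau = tapply(tau_half, lpr, mean),
                 peak_change = peak_change, threshold = threshold),
            class = "electrogenicity")
}

#' @export
print.electrogenicity <- function(x, ...) {
  cat(sprintf("electrogenicity: %s (tau_1/2 change %+.1f%%, p = %.3g)\n",
              x$verdict, 100 * x$rel_change, x$p_value))
  invisible(x)
}
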