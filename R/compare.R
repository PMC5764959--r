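# Quantitative agreement between maps and between phase sets.

#' Map correlation coefficient
#'
#' Pearson correlation of two density maps over all voxels of the unit
#' cell (no mask).
#'
#' @param map1,map2 [density_map()]s on identical grids.
#' @return Correlation in `[-1, 1]`.
#' @export
map_cc <- function(map1, map2) {
  if (!identical(dim(map1$grid), dim(map2$grid)))
    stop("map_cc: grid dimensions differ")
  if (!cells_equal(map1$cell, map2$cell))
    stop("map_cc: unit cells differ")
  v1 <- as.vector(map1$grid); v2 <- as.vector(map2$grid)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("map_cc: zero-variance map")
  stats::cor(v1, v2)
}

#' Phase-set comparison report
#'
#' Compares a candidate phase set against a reference (typically the
#' ground truth of a synthetic crystal): mean minimal angular phase error
#' (unweighted and `|F|^2`-weighted) and the map correlation coefficients
#' of the corresponding syntheses, both unweighted and weighted by the
#' candidate's figures of merit. With `align = TRUE` the best allowed
#' origin shift / enantiomorph flip is factored out first - phasing from
#' amplitudes alone can only ever determine the structure up to that
#' ambiguity, so alignment must precede any scoring.
#'
#' @param candidate A [phase_set()] (foms required for the weighted CC).
#' @param truth Reference [phase_set()].
#' @param rs The companion [reflection_set()].
#' @param align Factor out origin shift and enantiomorph first.
#' @param dims Grid dimensions for the synthesis CCs.
#' @return Object of class `comparison_report`: `cc_weighted`,
#'   `cc_unweighted`, `phase_error_mean`, `phase_error_weighted` (degrees),
#'   `shift`, `flipped`, `agreement`.
#' @export
phase_metrics <- function(candidate, truth, rs, align = TRUE,
                          dims = grid_dims(rs)) {
  if (nrow(candidate$hkl) != nrow(rs$data) || nrow(truth$hkl) != nrow(rs$data))
    stop("phase sets do not match the reflection list")
  shift <- c(0, 0, 0); flipped <- FALSE; agreement <- NA_real_
  if (align) {
    al <- align_phase_set(candidate, truth, rs)
    candidate <- al$aligned
    shift <- al$shift; flipped <- al$flipped; agreement <- al$agreement
  }
  dphi <- abs(((candidate$phase - truth$phase + 180) %% 360) - 180)
  w <- rs$data$f^2
  plan <- synthesis_plan(rs, dims)
  rho_true <- density_map(synth_from_plan(plan, rs$data$f, truth$phase), rs$cell)
  rho_cand <- density_map(synth_from_plan(plan, rs$data$f, candidate$phase), rs$cell)
  cc_u <- map_cc(rho_cand, rho_true)
  cc_w <- if (!is.null(candidate$fom)) {
    rho_w <- density_map(synth_from_plan(plan, rs$data$f, candidate$phase,
                                         fom = candidate$fom), rs$cell)
    map_cc(rho_w, rho_true)
  } else NA_real_
  structure(list(cc_weighted = cc_w, cc_unweighted = cc_u,
                 phase_error_mean = mean(dphi),
                 phase_error_weighted = sum(w * dphi) / sum(w),
                 shift = shift, flipped = flipped, agreement = agreement),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: CC %.3f weighted / %.3f unweighted; phase error %.1f deg (%.1f weighted); shift (%.3f %.3f %.3f)%s\n",
              x$cc_weighted, x$cc_unweighted, x$phase_error_mean,
              x$phase_error_weighted, x$shift[1], x$shift[2], x$shift[3],
              if (isTRUE(x$flipped)) ", enantiomorph flipped" else ""))
  invisible(x)
}
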