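# Fourier synthesis of density maps from unique reflection sets. The map
# convention is rho(x) = (1/V) sum_h m F(h) exp(-2 pi i h.x) over the full
# sphere, realised by placing Hermitian coefficient pairs on the FFT grid.

next_fft_size <- function(n) {
  n <- as.integer(max(n, 2L))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Default grid dimensions for a synthesis
#'
#' Grid step at most `d_min * spacing` along each cell edge (default
#' `d_min/3`, a margin past Shannon's `d_min/2`), rounded up to FFT-friendly
#' sizes and never smaller than the index range demands.
#'
#' @param rs A [reflection_set()].
#' @param spacing Maximum grid step as a fraction of `d_min`.
#' @return Integer vector of three grid dimensions.
#' @export
grid_dims <- function(rs, spacing = 1/3) {
  d <- rs$data
  if (nrow(d) == 0) return(c(8L, 8L, 8L))
  d_min <- min(d$d)
  ex <- expand_full_sphere(rs$sg, as.matrix(d[, c("h", "k", "l")]))
  hmax <- c(max(abs(ex$h)), max(abs(ex$k)), max(abs(ex$l)))
  len <- c(rs$cell$a, rs$cell$b, rs$cell$c)
  vapply(1:3, function(i)
    next_fft_size(max(ceiling(len[i] / (d_min * spacing)), 2L * hmax[i] + 2L)),
    integer(1))
}

# Precomputed scatter plan: grid positions and unit phase factors for the
# full-sphere expansion of a fixed reflection list. Reused across the many
# candidate syntheses of the phasing loop.
synthesis_plan <- function(rs, dims = grid_dims(rs)) {
  d <- rs$data
  ex <- expand_full_sphere(rs$sg, as.matrix(d[, c("h", "k", "l")]))
  ix <- ex$h %% dims[1]; iy <- ex$k %% dims[2]; iz <- ex$l %% dims[3]
  idx <- 1 + ix + dims[1] * (iy + dims[2] * iz)
  if (anyDuplicated(idx)) stop("grid too small for the reflection index range")
  list(dims = dims, idx = idx, src = ex$src,
       unit = exp(1i * ex$shift_deg * pi / 180),
       conj = ex$sign < 0, cell = rs$cell, n_unique = nrow(d))
}

synth_from_plan <- function(plan, f, phi_deg, fom = NULL) {
  z <- f * exp(1i * phi_deg * pi / 180)
  if (!is.null(fom)) z <- z * fom
  zv <- z[plan$src]
  zv[plan$conj] <- Conj(zv[plan$conj])
  cgrid <- array(0i, dim = plan$dims)
  cgrid[plan$idx] <- zv * plan$unit
  Re(stats::fft(cgrid)) / plan$cell$volume
}

#' Fourier synthesis
#'
#' Computes `rho(x) = (1/V) sum m F exp(-2 pi i h.x)` over the full sphere
#' by Hermitian expansion of the symmetry-unique set (`m = 1` unweighted;
#' the reflection figures of merit when `weighted = TRUE`). With no `F(000)`
#' term the map mean is zero.
#'
#' @param rs A [reflection_set()] with phases.
#' @param dims Grid dimensions, default [grid_dims()].
#' @param weighted Weight each coefficient by its figure of merit.
#' @return A [density_map()].
#' @export
fourier_synthesis <- function(rs, dims = grid_dims(rs), weighted = FALSE) {
  d <- rs$data
  if (nrow(d) == 0)
    return(density_map(array(0, dim = dims), rs$cell))
  if (anyNA(d$phi)) {
    bad <- which(is.na(d$phi))[1]
    stop(sprintf("reflection (%d %d %d) has no phase", d$h[bad], d$k[bad], d$l[bad]))
  }
  fom <- NULL
  if (weighted) {
    if (anyNA(d$fom)) stop("weighted synthesis requires a figure of merit on every reflection")
    fom <- d$fom
  }
  plan <- synthesis_plan(rs, dims)
  density_map(synth_from_plan(plan, d$f, d$phi, fom), rs$cell)
}

#' Difference Fourier synthesis (Fo - Fc)
#'
#' Synthesizes coefficients `(|F_o| - |F_c|) exp(i phi_c)`: observed
#' amplitudes, model phases. Density present in the observations but not in
#' the model appears as positive peaks.
#'
#' @param rs_obs Amplitude [reflection_set()] (phases ignored).
#' @param rs_model Phased [reflection_set()] of the partial model, same
#'   indexing.
#' @param dims Grid dimensions, default from the model set.
#' @return A [density_map()].
#' @export
difference_synthesis <- function(rs_obs, rs_model, dims = grid_dims(rs_model)) {
  ko <- paste(rs_obs$data$h, rs_obs$data$k, rs_obs$data$l)
  km <- paste(rs_model$data$h, rs_model$data$k, rs_model$data$l)
  pos <- match(km, ko)
  if (anyNA(pos)) {
    miss <- km[is.na(pos)]
    stop("observed set lacks reflections present in the model set: ",
         paste(utils::head(miss, 5), collapse = "; "),
         if (length(miss) > 5) " ...")
  }
  if (anyNA(rs_model$data$phi)) stop("model set must be fully phased")
  dF <- rs_obs$data$f[pos] - rs_model$data$f
  phi <- ifelse(dF < 0, (rs_model$data$phi + 180) %% 360, rs_model$data$phi)
  rs_d <- rs_model
  rs_d$data$f <- abs(dF)
  rs_d$data$phi <- phi
  fourier_synthesis(rs_d, dims)
}
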