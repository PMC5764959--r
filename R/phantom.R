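# Synthetic crystals with known ground truth. Gaussian pseudo-atoms stand
# in for a low-resolution structure: at 8-16 A only the molecular envelope
# matters, and the Gaussian width b (A^2) plays the B-factor role.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

#' Pseudo-atom model
#'
#' @param xyz Fractional coordinates, matrix with 3 columns; wrapped into
#'   `[0, 1)`.
#' @param w Positive scattering weights.
#' @param b Gaussian widths in Angstrom^2 (`>= 0`), the B-factor analogue.
#' @param cell A [unit_cell()].
#' @param sg A [spacegroup()]; atoms describe one asymmetric unit.
#' @param label Per-atom domain tag (e.g. `"Amt"`, `"HK"`).
#' @return Object of class `pseudo_atom_model`.
#' @export
pseudo_atom_model <- function(xyz, w, b, cell, sg, label = "atom") {
  xyz <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (n < 1) stop("model must contain at least one atom")
  w <- rep_len(w, n); b <- rep_len(b, n); label <- rep_len(label, n)
  if (any(w <= 0)) stop("atom weights must be > 0")
  if (any(b < 0)) stop("Gaussian widths must be >= 0")
  structure(list(xyz = xyz %% 1, w = w, b = b, label = label,
                 cell = cell, sg = sg),
            class = "pseudo_atom_model")
}

#' @export
print.pseudo_atom_model <- function(x, ...) {
  cat(sprintf("pseudo_atom_model: %d atoms (%s), %s\n", nrow(x$xyz),
              paste(sprintf("%s: %d", names(table(x$label)), table(x$label)),
                    collapse = ", "), x$sg$name))
  invisible(x)
}

# uniform points in a ball of given radius (Angstrom), returned as
# fractional offsets via the inverse orthogonalization matrix
ball_cloud <- function(n, radius, cell) {
  p <- matrix(stats::rnorm(3 * n), ncol = 3)
  p <- p / sqrt(rowSums(p^2)) * radius * stats::runif(n)^(1 / 3)
  p %*% t(solve(cell$orth))
}

#' Two-domain phantom emulating the sensor crystal
#'
#' Builds one protomer per asymmetric unit as two compact pseudo-atom
#' clusters: a well-ordered membrane-domain cluster ("Amt") and a second
#' cluster hanging below it ("HK") whose Gaussian widths are inflated by
#' `hk_disorder_b`, emulating a disordered cytoplasmic domain whose
#' density deteriorates at fixed resolution. The default cluster centers
#' sit next to the three-fold axis at `(1/3, 2/3)`, so the space-group
#' symmetry assembles two trimers per hexagonal cell (one per screw-
#' related axis) - the packing of the crystallized sensor. The default
#' cell reproduces the reflection counts of the study's low-resolution
#' data (about 90 unique reflections to 16 Angstrom and 660 to 8), and
#' the default widths give a Wilson-like fall-off that fades around the
#' 8 Angstrom diffraction limit.
#'
#' @param cell A [unit_cell()]; default hexagonal `105 x 105 x 95` A.
#' @param sg A [spacegroup()], typically `P63`.
#' @param n_amt,n_hk Atoms per cluster (`>= 1`).
#' @param hk_disorder_b Extra Gaussian width (A^2) added to the HK cluster.
#' @param seed Integer seed; the model is deterministic given it.
#' @param amt_center,hk_center Fractional cluster centers.
#' @param amt_radius,hk_radius Cluster radii in Angstrom.
#' @param b0 Base Gaussian width (A^2) of every atom.
#' @return A [pseudo_atom_model()] with labels `"Amt"` and `"HK"`.
#' @export
make_two_domain_phantom <- function(cell = unit_cell(105, 105, 95, 90, 90, 120),
                                    sg = spacegroup("P63"),
                                    n_amt = 60, n_hk = 30,
                                    hk_disorder_b = 250, seed = 1,
                                    amt_center = c(0.5238095, 0.6666667, 0.62),
                                    hk_center = c(0.4791372, 0.7106553, 0.38),
                                    amt_radius = 16, hk_radius = 12,
                                    b0 = 300) {
  if (n_amt < 1 || n_hk < 1) stop("need at least one atom per domain")
  if (hk_disorder_b < 0) stop("hk_disorder_b must be >= 0")
  if (2 * max(amt_radius, hk_radius) > min(cell$a, cell$b, cell$c))
    stop("cluster radius exceeds half the shortest cell edge")
  with_seed(seed, {
    amt <- matrix(amt_center, n_amt, 3, byrow = TRUE) +
      ball_cloud(n_amt, amt_radius, cell)
    hk <- matrix(hk_center, n_hk, 3, byrow = TRUE) +
      ball_cloud(n_hk, hk_radius, cell)
    pseudo_atom_model(rbind(amt, hk), w = 1,
                      b = c(rep(b0, n_amt), rep(b0 + hk_disorder_b, n_hk)),
                      cell = cell, sg = sg,
                      label = rep(c("Amt", "HK"), c(n_amt, n_hk)))
  })
}

# enumerate symmetry-unique Miller indices to d >= d_min
enumerate_unique_hkl <- function(cell, sg, d_min) {
  lim <- floor(1 / (d_min * sqrt(diag(cell$gstar)))) + 1
  g <- as.matrix(expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2],
                             l = -lim[3]:lim[3]))
  dimnames(g) <- NULL
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g <- g[d_spacing(cell, g) >= d_min, , drop = FALSE]
  rep_h <- map_to_asu(sg, g)$rep
  uni <- rep_h[!duplicated(paste(rep_h[, 1], rep_h[, 2], rep_h[, 3])), ,
               drop = FALSE]
  uni[!is_absent(sg, uni), , drop = FALSE]
}

#' Structure factors of a pseudo-atom model
#'
#' Direct summation over atoms and symmetry operators:
#' `F(h) = sum_ops sum_j w_j exp(-b_j s^2 / 4) exp(2 pi i h . (R x_j + t))`
#' with `s = 1/d(h)`. Returns the complete symmetry-unique set to `d_min`
#' with true phases; systematic absences are excluded by construction.
#'
#' @param model A [pseudo_atom_model()].
#' @param d_min Resolution limit in Angstrom.
#' @return A [reflection_set()] with `phi` filled in.
#' @export
compute_structure_factors <- function(model, d_min) {
  stopifnot(inherits(model, "pseudo_atom_model"))
  cell <- model$cell; sg <- model$sg
  hkl <- enumerate_unique_hkl(cell, sg, d_min)
  if (nrow(hkl) == 0) stop("no reflections to the requested resolution")
  s2 <- 1 / d_spacing(cell, hkl)^2
  # n_h x n_atoms attenuation and per-op phase accumulation
  att <- exp(-outer(s2, model$b) / 4) *
    matrix(model$w, nrow(hkl), length(model$w), byrow = TRUE)
  f <- complex(real = numeric(nrow(hkl)), imaginary = numeric(nrow(hkl)))
  for (op in sg$ops) {
    arg <- 2 * pi * ((hkl %*% op$R) %*% t(model$xyz) +
                       drop(hkl %*% op$t))
    f <- f + rowSums(exp(1i * arg) * att)
  }
  reflection_set(cell, sg, hkl, Mod(f), phi = (Arg(f) * 180 / pi) %% 360)
}

#' Simulate an amplitude-only diffraction dataset
#'
#' Computes structure factors of a phantom, perturbs the amplitudes by
#' multiplicative Gaussian noise `N(1, amp_noise_frac)` (clipped at zero),
#' withholds the phases from the public set and retains them in a truth
#' record for recovery scoring.
#'
#' @param model A [pseudo_atom_model()].
#' @param d_min Resolution limit in Angstrom.
#' @param amp_noise_frac Relative amplitude noise (`>= 0`).
#' @param seed Integer seed.
#' @return List with `rs` (amplitude-only [reflection_set()]) and `truth`
#'   (class `truth_record`: the model, the phased set `rs_true`, the noise
#'   level and seed).
#' @export
simulate_dataset <- function(model, d_min, amp_noise_frac = 0, seed = 1) {
  if (amp_noise_frac < 0) stop("amp_noise_frac must be >= 0")
  rs_true <- compute_structure_factors(model, d_min)
  f_noisy <- with_seed(seed, {
    pmax(0, rs_true$data$f *
           stats::rnorm(nrow(rs_true$data), 1, amp_noise_frac))
  })
  rs <- rs_true
  rs$data$f <- f_noisy
  rs$data$phi <- NA_real_
  truth <- structure(list(model = model, rs_true = rs_true,
                          amp_noise_frac = amp_noise_frac, seed = seed),
                     class = "truth_record")
  list(rs = rs, truth = truth)
}
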