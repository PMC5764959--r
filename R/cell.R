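#' Unit cell
#'
#' Construct a crystallographic unit cell from edge lengths (Angstrom) and
#' angles (degrees). The reciprocal metric tensor is precomputed and cached;
#' it must be positive definite, which rules out degenerate geometries.
#'
#' @param a,b,c Cell edges in Angstrom, all `> 0`.
#' @param alpha,beta,gamma Cell angles in degrees, each in `(0, 180)`.
#' @return An object of class `unit_cell` with fields `a, b, c, alpha, beta,
#'   gamma`, the cell volume `volume` (Angstrom^3), the orthogonalization
#'   matrix `orth` (fractional -> Cartesian) and the reciprocal metric
#'   `gstar` used for resolution calculations.
#' @examples
#' uc <- unit_cell(140, 140, 120, 90, 90, 120)  # hexagonal setting
#' d_spacing(uc, c(0, 0, 2))                    # c/2 = 60 Angstrom
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be finite and > 0")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  # standard PDB orthogonalization: a along x, b in the xy plane
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop("degenerate unit cell: angles are inconsistent")
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * sqrt(vfac) / sg), nrow = 3, byrow = TRUE)
  g <- crossprod(orth)           # real-space metric tensor
  gstar <- solve(g)              # reciprocal metric tensor
  ev <- eigen(gstar, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("reciprocal metric tensor is not positive definite")
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, volume = a * b * c * sqrt(vfac),
                 orth = orth, gstar = gstar),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.0f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Resolution of reflections
#'
#' d-spacing `d(h)` in Angstrom for Miller indices under a given cell,
#' from the reciprocal metric: `1/d^2 = h' G* h`.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer vector `c(h, k, l)` or a matrix with three columns.
#' @return Numeric vector of d-spacings (Angstrom); `Inf` for `(0,0,0)`.
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  inv_d2 <- rowSums((h %*% cell$gstar) * h)
  ifelse(inv_d2 > 0, 1 / sqrt(inv_d2), Inf)
}

cells_equal <- function(c1, c2, tol = 1e-6) {
  all(abs(c(c1$a - c2$a, c1$b - c2$b, c1$c - c2$c,
            c1$alpha - c2$alpha, c1$beta - c2$beta,
            c1$gamma - c2$gamma)) < tol)
}
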