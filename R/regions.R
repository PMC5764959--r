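# Contouring and periodic connectivity analysis of density maps: the
# per-candidate evaluation machinery of the phasing loop.

#' Sigma-level contour mask
#'
#' Selects voxels with `(rho - mean) / sd >= level`, the convention used to
#' display maps "contoured at the n sigma level".
#'
#' @param map A [density_map()].
#' @param level Contour level in map sigmas.
#' @return Logical array of the map's dimensions.
#' @export
sigma_contour <- function(map, level) {
  g <- map$grid
  s <- stats::sd(as.vector(g))
  if (s == 0) stop("sigma_contour: map has zero variance")
  (g - mean(g)) / s >= level
}

#' Top volume-fraction mask
#'
#' Selects the `ceiling(alpha * N)` highest-valued voxels; ties are broken
#' by grid order (x fastest). This volume-based cutoff defines the
#' "high-density region" tested for connectivity: unlike a sigma cutoff it
#' fixes the selected volume across candidate maps, which the region-count
#' constraint semantics require.
#'
#' @param map A [density_map()] or numeric 3D array.
#' @param alpha Volume fraction in `(0, 1]`.
#' @return Logical array.
#' @export
threshold_by_volume_fraction <- function(map, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  g <- if (inherits(map, "density_map")) map$grid else map
  n <- length(g)
  kcount <- as.integer(ceiling(alpha * n))
  thr <- -sort(-as.vector(g), partial = kcount)[kcount]
  mask <- g > thr
  short <- kcount - sum(mask)
  if (short > 0) {            # admit tied voxels in grid order
    at <- which(g == thr)
    mask[at[seq_len(short)]] <- TRUE
  }
  mask
}

#' Periodic connected-component labeling
#'
#' Face-connected (6-neighbor) components of a boolean grid with
#' wrap-around on all three axes, so a blob straddling the cell boundary is
#' a single region. Labels are renumbered in decreasing size order
#' (label 1 = largest).
#'
#' @param mask Logical 3D array.
#' @return Object of class `region_labels`: `labels` (integer array, 0 =
#'   background), `sizes` (voxel counts, descending) and `n_selected`.
#' @export
label_periodic <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  raw <- .label_periodic_cpp(as.vector(mask), dim(mask))
  k <- attr(raw, "n_regions")
  if (k == 0) {
    labels <- array(0L, dim = dim(mask))
    return(structure(list(labels = labels, sizes = integer(0), n_selected = 0L),
                     class = "region_labels"))
  }
  sizes <- tabulate(raw, nbins = k)
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  labels <- array(0L, dim = dim(mask))
  sel <- raw > 0L
  labels[sel] <- remap[raw[sel]]
  structure(list(labels = labels, sizes = sizes[ord],
                 n_selected = sum(sizes)),
            class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  cat(sprintf("region_labels: %d region(s) over %d voxels; sizes: %s\n",
              length(x$sizes), x$n_selected,
              paste(utils::head(x$sizes, 8), collapse = ", ")))
  invisible(x)
}

#' Connectivity constraint
#'
#' Encodes the acceptance rule for a candidate map: the number of "large"
#' connected regions the high-density mask must form (one per molecule, or
#' one per ordered domain), whether small "drops" are tolerated and a cap
#' on the total region count.
#'
#' @param n_large_expected Required number of large regions (`>= 1`).
#' @param min_large_fraction Fraction of the selected volume a region must
#'   hold to count as large, in `(0, 1]`.
#' @param max_total_regions Cap on the total number of regions.
#' @param allow_drops Tolerate small regions below the large cutoff.
#' @return Object of class `connectivity_constraint`.
#' @export
connectivity_constraint <- function(n_large_expected,
                                    min_large_fraction = 0.1,
                                    max_total_regions = Inf,
                                    allow_drops = TRUE) {
  if (n_large_expected < 1) stop("n_large_expected must be >= 1")
  if (min_large_fraction <= 0 || min_large_fraction > 1)
    stop("min_large_fraction must lie in (0, 1]")
  if (n_large_expected > max_total_regions)
    stop("n_large_expected exceeds max_total_regions")
  structure(list(n_large_expected = as.integer(n_large_expected),
                 min_large_fraction = min_large_fraction,
                 max_total_regions = max_total_regions,
                 allow_drops = allow_drops),
            class = "connectivity_constraint")
}

#' Test a labeling against a connectivity constraint
#'
#' Accepts when the number of large regions (size at least
#' `min_large_fraction` of the selected volume) equals `n_large_expected`,
#' the total region count does not exceed `max_total_regions`, and small
#' drops occur only if allowed. The score - the fraction of selected volume
#' inside the `n_large_expected` largest regions - ranks accepted
#' candidates.
#'
#' @param labels A [label_periodic()] result.
#' @param constraint A [connectivity_constraint()].
#' @return List `(accept, score)`.
#' @export
check_connectivity <- function(labels, constraint) {
  sizes <- labels$sizes
  nsel <- labels$n_selected
  if (nsel == 0) return(list(accept = FALSE, score = 0))
  n_large <- sum(sizes >= constraint$min_large_fraction * nsel)
  accept <- n_large == constraint$n_large_expected &&
    length(sizes) <= constraint$max_total_regions &&
    (constraint$allow_drops || length(sizes) == n_large)
  score <- sum(utils::head(sizes, constraint$n_large_expected)) / nsel
  list(accept = accept, score = score)
}
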