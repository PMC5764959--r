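#' Reflection sets
#'
#' A `reflection_set` holds symmetry-unique reflection records for one
#' crystal: Miller index, amplitude, optional phase (degrees, `[0, 360)`)
#' and figure of merit, plus the centric flag and d-spacing. Construction
#' merges symmetry and Friedel mates onto a deterministic representative
#' (the lexicographically greatest mate), drops systematic absences and
#' `(0,0,0)`, and refuses conflicting duplicate amplitudes.
#'
#' @param cell A [unit_cell()].
#' @param sg A [spacegroup()].
#' @param hkl Integer matrix of Miller indices (rows).
#' @param f Non-negative amplitudes, one per row of `hkl`.
#' @param phi Optional phases in degrees.
#' @param fom Optional figures of merit in `[0, 1]`.
#' @return An object of class `reflection_set` with fields `cell`, `sg` and
#'   `data` (a `data.frame` with columns `h, k, l, f, phi, fom, centric,
#'   d`). Dropped absent reflections are recorded in `attr(, "dropped")`.
#' @export
reflection_set <- function(cell, sg, hkl, f, phi = NULL, fom = NULL) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "spacegroup"))
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  storage.mode(h) <- "double"
  if (nrow(h) != length(f)) stop("hkl and f lengths differ")
  if (any(!is.finite(f)) || any(f < 0)) stop("amplitudes must be finite and >= 0")
  if (!is.null(phi) && length(phi) != nrow(h)) stop("phi length mismatch")
  if (!is.null(fom)) {
    if (length(fom) != nrow(h)) stop("fom length mismatch")
    if (any(fom < -1e-9 | fom > 1 + 1e-9, na.rm = TRUE))
      stop("figures of merit must lie in [0, 1]")
  }
  nonzero <- rowSums(abs(h)) > 0
  h <- h[nonzero, , drop = FALSE]
  f <- f[nonzero]
  phi <- if (!is.null(phi)) phi[nonzero]
  fom <- if (!is.null(fom)) fom[nonzero]

  absent <- is_absent(sg, h)
  dropped <- h[absent, , drop = FALSE]
  h <- h[!absent, , drop = FALSE]
  f <- f[!absent]
  phi <- if (!is.null(phi)) phi[!absent]
  fom <- if (!is.null(fom)) fom[!absent]

  asu <- map_to_asu(sg, h)
  rep_h <- asu$rep
  phi_rep <- if (!is.null(phi)) (asu$sign * (phi + asu$shift_deg)) %% 360

  key <- paste(rep_h[, 1], rep_h[, 2], rep_h[, 3])
  first <- !duplicated(key)
  idx_first <- match(key, key[first])
  # conflict check: all mates of a class must agree in amplitude
  f_ref <- f[first][idx_first]
  bad <- abs(f - f_ref) > 1e-6 * pmax(1, abs(f_ref))
  if (any(bad)) {
    b <- which(bad)[1]
    stop(sprintf("conflicting amplitudes for symmetry-equivalent reflection (%d %d %d): %g vs %g",
                 rep_h[b, 1], rep_h[b, 2], rep_h[b, 3], f[b], f_ref[b]))
  }
  hU <- rep_h[first, , drop = FALSE]
  dat <- data.frame(h = as.integer(hU[, 1]), k = as.integer(hU[, 2]),
                    l = as.integer(hU[, 3]), f = f[first],
                    phi = if (!is.null(phi)) phi_rep[first] else
                      rep(NA_real_, nrow(hU)),
                    fom = if (!is.null(fom)) fom[first] else
                      rep(NA_real_, nrow(hU)))
  cen <- is_centric(hU, sg)
  dat$centric <- cen$centric
  dat$phi0 <- cen$phi0
  dat$d <- d_spacing(cell, hU)
  rownames(dat) <- NULL
  structure(list(cell = cell, sg = sg, data = dat),
            class = "reflection_set", dropped = dropped)
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection_set: %d unique reflections (%s), d range %.2f-%.2f A, %d centric, phases: %s\n",
              nrow(x$data), x$sg$name,
              if (nrow(x$data)) min(x$data$d) else NA,
              if (nrow(x$data)) max(x$data$d) else NA,
              sum(x$data$centric),
              if (all(is.na(x$data$phi))) "absent" else "present"))
  invisible(x)
}

#' Read a reflection table
#'
#' Reads a whitespace- or comma-delimited UTF-8 text file with a header
#' line `h k l F [phi] [fom]`; lines starting with `#` are comments.
#' Symmetry merging and absence filtering are applied on construction;
#' dropped absent reflections are reported via [message()] and recorded in
#' the `"dropped"` attribute.
#'
#' @param path File path.
#' @param cell A [unit_cell()].
#' @param sg A [spacegroup()].
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path, cell, sg) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    warning("empty reflection file: ", path)
    return(reflection_set(cell, sg, matrix(0L, 0, 3), numeric(0)))
  }
  toks <- strsplit(trimws(lines), "[,[:space:]]+")
  header <- tolower(toks[[1]])
  cols <- c("h", "k", "l", "f", "phi", "fom")
  if (length(header) < 4 || !identical(header[1:4], cols[1:4]))
    stop("reflection table must start with header 'h k l F [phi] [fom]', got: ",
         paste(header, collapse = " "))
  has_phi <- length(header) >= 5 && header[5] == "phi"
  has_fom <- length(header) >= 6 && header[6] == "fom"
  body <- toks[-1]
  lineno <- lineno[-1]
  nfld <- 4L + has_phi + has_fom
  vals <- matrix(NA_real_, length(body), nfld)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]]))
    if (length(v) != nfld || any(is.na(v)))
      stop(sprintf("malformed reflection line %d: '%s'", lineno[i], lines[-1][i]))
    if (any(v[1:3] != round(v[1:3])))
      stop(sprintf("non-integer Miller index on line %d", lineno[i]))
    vals[i, ] <- v
  }
  rs <- reflection_set(cell, sg, vals[, 1:3, drop = FALSE], vals[, 4],
                       phi = if (has_phi) vals[, 5] %% 360,
                       fom = if (has_fom) vals[, 6])
  dropped <- attr(rs, "dropped")
  if (nrow(dropped) > 0)
    message(sprintf("read_reflections: dropped %d systematically absent reflection(s): %s",
                    nrow(dropped),
                    paste(apply(dropped, 1, paste, collapse = " "),
                          collapse = "; ")))
  rs
}

#' Write a reflection table
#'
#' Inverse of [read_reflections()]: plain text, `#`-comment header,
#' whitespace-delimited columns.
#'
#' @param rs A [reflection_set()].
#' @param path Output path.
#' @param comments Optional character vector written as `#` comment lines.
#' @export
write_reflections <- function(rs, path, comments = NULL) {
  d <- rs$data
  has_phi <- !all(is.na(d$phi))
  has_fom <- !all(is.na(d$fom))
  hdr <- c("h", "k", "l", "F", if (has_phi) "phi", if (has_fom) "fom")
  body <- cbind(d$h, d$k, d$l, signif(d$f, 9),
                if (has_phi) round(d$phi, 5), if (has_fom) round(d$fom, 5))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(hdr, collapse = " "), con)
  writeLines(apply(body, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Select a resolution shell
#'
#' Keeps records with `d_min <= d < d_max` (d in Angstrom).
#'
#' @param rs A [reflection_set()].
#' @param d_min,d_max Shell bounds in Angstrom, `d_min < d_max`.
#' @return A [reflection_set()] restricted to the shell.
#' @export
resolution_shell <- function(rs, d_min, d_max = Inf) {
  if (!(d_min < d_max)) stop("resolution_shell: need d_min < d_max")
  keep <- rs$data$d >= d_min & rs$data$d < d_max
  out <- rs
  out$data <- rs$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}
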