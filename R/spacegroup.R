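#' Space-group operator tables
#'
#' Symmetry support is a built-in catalog of the three groups the package
#' needs: triclinic `P1`, monoclinic `P21` (unique axis b) and hexagonal
#' `P63` (polar, the crystal form of the full-length sensor). Each entry
#' carries the full operator list, the permitted origin shifts (discrete
#' classes plus continuous polar axes) and whether the enantiomorph phase
#' flip is an allowed ambiguity.
#'
#' Operators act on fractional coordinates as `x' = R x + t` (column
#' vectors); reflections transform as row vectors, `h' = h R`.
#'
#' @param name One of `"P1"`, `"P21"`, `"P63"`.
#' @return An object of class `spacegroup`: fields `name`, `ops` (list of
#'   `list(R, t)`), `origin_classes` (matrix of discrete shift
#'   representatives, one row each), `origin_continuous` (logical length 3,
#'   `TRUE` on floating-origin axes) and `enantiomorph_ok`.
#' @examples
#' sg <- spacegroup("P63")
#' length(sg$ops)  # 6
#' @export
spacegroup <- function(name) {
  name <- toupper(gsub("[ _]", "", name))
  name <- switch(name, "P1" = "P1", "P21" = "P21", "P63" = "P63",
                 stop("unsupported space group '", name,
                      "' (supported: P1, P21, P63)"))
  ops <- switch(name,
    P1 = list(list(R = diag(3), t = c(0, 0, 0))),
    P21 = list(
      list(R = diag(3), t = c(0, 0, 0)),
      list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0))),
    P63 = {
      r6 <- matrix(c(1, -1, 0, 1, 0, 0, 0, 0, 1), nrow = 3, byrow = TRUE)
      rk <- diag(3)
      out <- vector("list", 6)
      for (k in 0:5) {
        out[[k + 1]] <- list(R = rk, t = c(0, 0, (k * 0.5) %% 1))
        rk <- r6 %*% rk
      }
      out
    })
  origin <- switch(name,
    P1 = list(classes = matrix(0, 1, 3), continuous = c(TRUE, TRUE, TRUE)),
    P21 = list(classes = as.matrix(expand.grid(x = c(0, .5), y = 0,
                                               z = c(0, .5))),
               continuous = c(FALSE, TRUE, FALSE)),
    P63 = list(classes = matrix(c(0, 0, 0, 1/3, 2/3, 0, 2/3, 1/3, 0),
                                nrow = 3, byrow = TRUE),
               continuous = c(FALSE, FALSE, TRUE)))
  dimnames(origin$classes) <- NULL
  structure(list(name = name, ops = ops,
                 origin_classes = origin$classes,
                 origin_continuous = origin$continuous,
                 enantiomorph_ok = TRUE),
            class = "spacegroup")
}

#' @export
print.spacegroup <- function(x, ...) {
  cat(sprintf("spacegroup %s: %d operator(s), %d origin class(es), continuous axes: %s\n",
              x$name, length(x$ops), nrow(x$origin_classes),
              paste(c("x", "y", "z")[x$origin_continuous], collapse = "") ))
  invisible(x)
}

#' Systematic absences
#'
#' A reflection is systematically absent when some operator fixes its index
#' (`h R = h`) while the screw translation gives a non-integral phase shift
#' `h . t`, forcing `F(h) = 0`. In `P63` this is the `00l, l` odd rule.
#'
#' @param sg A [spacegroup()].
#' @param hkl Integer matrix (rows are reflections) or a single `c(h,k,l)`.
#' @return Logical vector.
#' @export
is_absent <- function(sg, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  out <- rep(FALSE, nrow(h))
  for (op in sg$ops) {
    fixed <- rowSums(abs(h %*% op$R - h)) == 0
    ht <- drop(h %*% op$t)
    out <- out | (fixed & abs(ht - round(ht)) > 1e-9)
  }
  out
}

#' Centric classification and allowed phases
#'
#' A reflection is centric when some operator maps `h` to `-h`; its phase is
#' then restricted to two values 180 degrees apart, `180 * (h . t)` and that
#' value plus 180, where `t` is the translation of the mapping operator.
#'
#' @param hkl A single Miller index `c(h,k,l)` or an integer matrix.
#' @param sg A [spacegroup()].
#' @return For a single index, `list(centric =, allowed =)` with `allowed`
#'   the two phases in degrees (or `NULL` for acentric). For a matrix, a
#'   `data.frame` with columns `centric` and `phi0` (`NA` for acentric).
#' @examples
#' is_centric(c(2, 1, 0), spacegroup("P63"))$centric  # TRUE: l = 0 zone
#' @export
is_centric <- function(hkl, sg) {
  single <- !is.matrix(hkl)
  h <- if (single) matrix(hkl, ncol = 3) else hkl
  centric <- rep(FALSE, nrow(h))
  phi0 <- rep(NA_real_, nrow(h))
  for (op in sg$ops) {
    maps <- rowSums(abs(h %*% op$R + h)) == 0
    new <- maps & !centric
    if (any(new)) {
      centric[new] <- TRUE
      phi0[new] <- (180 * drop(h[new, , drop = FALSE] %*% op$t)) %% 360
    }
  }
  if (single) {
    if (centric[1]) list(centric = TRUE, allowed = c(phi0[1], (phi0[1] + 180) %% 360))
    else list(centric = FALSE, allowed = NULL)
  } else data.frame(centric = centric, phi0 = phi0)
}

# Lexicographic encoding used to pick a deterministic symmetry-unique
# representative: greatest (h, then k, then l) among all mates.
lex_key <- function(h) {
  (h[, 1] + 2048) * 2^24 + (h[, 2] + 2048) * 2^12 + (h[, 3] + 2048)
}

#' Map reflections to their symmetry-unique representatives
#'
#' The representative of a reflection class is the lexicographically
#' greatest index among all symmetry mates `h R` and Friedel mates `-h R`.
#' The returned transform carries the phase bookkeeping: the phase at the
#' representative is `sign * (phase + shift_deg)` for a phase observed at
#' the input index.
#'
#' @param sg A [spacegroup()].
#' @param hkl Integer matrix of Miller indices (rows).
#' @return List with `rep` (matrix of representatives), `shift_deg`
#'   (degrees, `-360 h . t` of the mapping operator) and `sign` (+1, or -1
#'   when the Friedel flip was used).
#' @export
map_to_asu <- function(sg, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  n <- nrow(h)
  best_key <- rep(-Inf, n)
  rep_h <- h
  shift <- numeric(n)
  sgn <- rep(1, n)
  for (op in sg$ops) {
    hm <- h %*% op$R
    dd <- -360 * drop(h %*% op$t)
    for (s in c(1, -1)) {
      cand <- s * hm
      key <- lex_key(cand)
      take <- key > best_key
      if (any(take)) {
        best_key[take] <- key[take]
        rep_h[take, ] <- cand[take, , drop = FALSE]
        shift[take] <- dd[take]
        sgn[take] <- s
      }
    }
  }
  list(rep = rep_h, shift_deg = shift, sign = sgn)
}

# All distinct symmetry + Friedel expansions of unique reflections, for
# full-sphere Fourier synthesis. Returns a data.frame with the source row
# index `src`, expanded indices, the phase offset in degrees and the sign
# (+1 keep phase, -1 conjugate).
expand_full_sphere <- function(sg, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  n <- nrow(h)
  pieces <- vector("list", 2 * length(sg$ops))
  i <- 1
  for (op in sg$ops) {
    hm <- h %*% op$R
    dd <- -360 * drop(h %*% op$t)
    pieces[[i]] <- data.frame(src = seq_len(n), h = hm[, 1], k = hm[, 2],
                              l = hm[, 3], shift_deg = dd, sign = 1)
    pieces[[i + 1]] <- data.frame(src = seq_len(n), h = -hm[, 1], k = -hm[, 2],
                                  l = -hm[, 3], shift_deg = -dd, sign = -1)
    i <- i + 2
  }
  full <- do.call(rbind, pieces)
  # keep one entry per (src, index); duplicates arise for special reflections
  key <- paste(full$src, full$h, full$k, full$l)
  full[!duplicated(key), , drop = FALSE]
}
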