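# Coordinate-level checks against deposited structures: rigid-body
# superposition RMSD and ligand coordination-shell geometry.

#' Read a coordinate set from a PDB file
#'
#' First model only; alternate locations resolved to the highest-occupancy
#' conformer; heteroatoms retained and flagged. Parsing is delegated to
#' bio3d.
#'
#' @param path Path to a PDB file.
#' @return Object of class `coord_set`: data.frame `atoms` with columns
#'   `chain, resno, resid, elety, elesy, x, y, z, hetero`, and `source`.
#' @export
read_structure <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_structure requires the bio3d package")
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e)
                    stop("cannot parse structure file '", path, "': ",
                         conditionMessage(e)))
  a <- pdb$atom
  if (nrow(a) == 0) stop("no atoms in ", path)
  # resolve altlocs: keep the highest-occupancy record per atom key
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  occ <- ifelse(is.na(a$o), 1, a$o)
  ord <- order(key, -occ)
  a <- a[ord, ][!duplicated(key[ord]), ]
  atoms <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                      elety = a$elety, elesy = a$elesy,
                      x = a$x, y = a$y, z = a$z,
                      hetero = a$type == "HETATM",
                      stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$elety), ]
  rownames(atoms) <- NULL
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  structure(list(atoms = atoms, source = path), class = "coord_set")
}

#' Construct a coordinate set from a data frame
#'
#' @param atoms Data frame with columns `chain, resno, resid, elety, x, y,
#'   z` (optional `elesy`, `hetero`).
#' @param source Identifier string.
#' @return A `coord_set`.
#' @export
coord_set <- function(atoms, source = "in-memory") {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms))) stop("missing columns: ",
    paste(setdiff(need, names(atoms)), collapse = ", "))
  if (is.null(atoms$elesy)) atoms$elesy <- substr(atoms$elety, 1, 1)
  if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) stop("duplicate (chain, residue, atom) keys")
  structure(list(atoms = atoms, source = source), class = "coord_set")
}

#' @export
print.coord_set <- function(x, ...) {
  cat(sprintf("coord_set '%s': %d atoms, %d chain(s), residues %d-%d\n",
              x$source, nrow(x$atoms), length(unique(x$atoms$chain)),
              min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' Pair atoms between two structures
#'
#' `common-atoms` mode intersects exact `(chain, residue number, atom
#' name)` keys. `sequence` mode globally aligns the chain sequences
#' (Biostrings, BLOSUM62) and pairs atoms with matching names within
#' aligned residue pairs, so a renumbered but homologous chain still pairs
#' fully.
#'
#' @param A,B `coord_set`s.
#' @param mode `"common-atoms"` or `"sequence"`.
#' @param chain_a,chain_b Restrict to one chain of each structure
#'   (required for `"sequence"`; default: first chain).
#' @param heavy_only Drop hydrogens (default `TRUE`).
#' @return Object of class `atom_pairing`: index vectors `i` (into
#'   `A$atoms`) and `j` (into `B$atoms`), and `method`.
#' @export
pair_by_alignment <- function(A, B, mode = c("common-atoms", "sequence"),
                              chain_a = NULL, chain_b = NULL,
                              heavy_only = TRUE) {
  mode <- match.arg(mode)
  if (nrow(A$atoms) == 0 || nrow(B$atoms) == 0) stop("empty coordinate set")
  a <- A$atoms; b <- B$atoms
  ia0 <- seq_len(nrow(a)); ib0 <- seq_len(nrow(b))
  if (heavy_only) {
    ka <- toupper(a$elesy) != "H"; kb <- toupper(b$elesy) != "H"
    a <- a[ka, ]; b <- b[kb, ]; ia0 <- ia0[ka]; ib0 <- ib0[kb]
  }
  if (mode == "common-atoms") {
    if (!is.null(chain_a)) { k <- a$chain == chain_a; a <- a[k, ]; ia0 <- ia0[k] }
    if (!is.null(chain_b)) { k <- b$chain == chain_b; b <- b[k, ]; ib0 <- ib0[k] }
    ka <- paste(a$chain, a$resno, a$elety)
    kb <- paste(b$chain, b$resno, b$elety)
    pos <- match(ka, kb)
    sel <- !is.na(pos)
    if (!any(sel)) stop("no common atoms between the two structures")
    pairing <- list(i = ia0[sel], j = ib0[pos[sel]])
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("sequence pairing requires the Biostrings package")
    if (is.null(chain_a)) chain_a <- a$chain[1]
    if (is.null(chain_b)) chain_b <- b$chain[1]
    ka <- a$chain == chain_a & !a$hetero
    kb <- b$chain == chain_b & !b$hetero
    a <- a[ka, ]; b <- b[kb, ]; ia0 <- ia0[ka]; ib0 <- ib0[kb]
    ra <- unique(a$resno); rb <- unique(b$resno)
    sa <- vapply(ra, function(r) aa321(a$resid[a$resno == r][1]), "")
    sb <- vapply(rb, function(r) aa321(b$resid[b$resno == r][1]), "")
    al <- Biostrings::pairwiseAlignment(paste(sa, collapse = ""),
                                        paste(sb, collapse = ""),
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5,
                                        type = "global")
    pa <- as.character(Biostrings::alignedPattern(al))
    ps <- as.character(Biostrings::alignedSubject(al))
    ca <- strsplit(pa, "")[[1]]; cb <- strsplit(ps, "")[[1]]
    ii <- 0; jj <- 0; imatch <- integer(0); jmatch <- integer(0)
    for (k in seq_along(ca)) {
      if (ca[k] != "-") ii <- ii + 1
      if (cb[k] != "-") jj <- jj + 1
      if (ca[k] != "-" && cb[k] != "-" && ca[k] == cb[k]) {
        imatch <- c(imatch, ii); jmatch <- c(jmatch, jj)
      }
    }
    if (length(imatch) == 0) stop("sequence alignment produced no matched residues")
    ilist <- jlist <- integer(0)
    for (k in seq_along(imatch)) {
      sel_a <- which(a$resno == ra[imatch[k]])
      sel_b <- which(b$resno == rb[jmatch[k]])
      pos <- match(a$elety[sel_a], b$elety[sel_b])
      ok <- !is.na(pos)
      ilist <- c(ilist, ia0[sel_a[ok]])
      jlist <- c(jlist, ib0[sel_b[pos[ok]]])
    }
    if (length(ilist) == 0) stop("no atoms paired after sequence alignment")
    pairing <- list(i = ilist, j = jlist)
  }
  structure(list(i = pairing$i, j = pairing$j, method = mode),
            class = "atom_pairing")
}

# three-letter to one-letter amino-acid code
aa321 <- function(res) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
           MSE = "M")
  out <- tab[toupper(res)]
  ifelse(is.na(out), "X", out)
}

#' Least-squares rigid-body superposition
#'
#' Kabsch algorithm: the proper rotation (determinant +1, reflections
#' excluded) and translation minimizing the RMSD over an atom pairing,
#' via singular value decomposition of the cross-covariance of the
#' centered coordinates.
#'
#' @param A,B `coord_set`s (B is superposed onto A).
#' @param pairing An [pair_by_alignment()] result (default: common atoms).
#' @return List: `rotation` (3x3), `translation` (length 3; the transform
#'   is `x_B %*% t(R) + t`), `rmsd` (Angstrom), `n` (pairs used).
#' @export
superpose <- function(A, B, pairing = pair_by_alignment(A, B)) {
  xa <- as.matrix(A$atoms[pairing$i, c("x", "y", "z")])
  xb <- as.matrix(B$atoms[pairing$j, c("x", "y", "z")])
  if (nrow(xa) < 3) stop("need at least 3 atom pairs")
  ca <- colMeans(xa); cb <- colMeans(xb)
  pa <- sweep(xa, 2, ca); pb <- sweep(xb, 2, cb)
  if (any(svd(pa)$d[2] < 1e-9 * nrow(pa)))
    stop("degenerate (collinear) geometry")
  s <- svd(crossprod(pb, pa))       # minimizes |pa - pb R'|
  dsign <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  tvec <- ca - drop(r %*% cb)
  fit <- sweep(xb %*% t(r), 2, tvec, "+")
  rmsd <- sqrt(mean(rowSums((xa - fit)^2)))
  list(rotation = r, translation = tvec, rmsd = rmsd, n = nrow(xa))
}

#' Coordination shell of a site
#'
#' All candidate coordinating atoms within `cutoff` of a center (a
#' Cartesian position or a named ligand atom), sorted by distance. By
#' default partners are restricted to nitrogen, oxygen and water oxygen -
#' the hydrogen-bonding chemistry of an ammonium site - and atoms of the
#' ligand's own residue are excluded.
#'
#' @param S A `coord_set`.
#' @param center Length-3 Cartesian position, or a list
#'   `list(resid =, resno =, chain =)` naming a ligand atom (e.g. the
#'   NH4 nitrogen).
#' @param cutoff Shell radius in Angstrom, `> 0`.
#' @param elements Allowed partner element symbols.
#' @return data.frame of partners with `distance` (ascending); the ligand
#'   count is `nrow()`.
#' @export
coordination_shell <- function(S, center, cutoff = 3.0,
                               elements = c("N", "O")) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- S$atoms
  excl <- rep(FALSE, nrow(a))
  if (is.list(center) && !is.null(center$resid)) {
    sel <- a$resid == center$resid
    if (!is.null(center$resno)) sel <- sel & a$resno == center$resno
    if (!is.null(center$chain)) sel <- sel & a$chain == center$chain
    if (!any(sel)) stop("named ligand '", center$resid, "' not found")
    lig <- a[sel, ][1, ]
    excl <- a$resid == lig$resid & a$resno == lig$resno & a$chain == lig$chain
    center <- c(lig$x, lig$y, lig$z)
  }
  d <- sqrt((a$x - center[1])^2 + (a$y - center[2])^2 + (a$z - center[3])^2)
  keep <- !excl & d <= cutoff & d > 1e-6 &
    toupper(a$elesy) %in% toupper(elements)
  out <- a[keep, c("chain", "resno", "resid", "elety")]
  out$distance <- d[keep]
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  out
}
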