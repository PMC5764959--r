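# shared fixtures, built in code

hex_cell <- function() unit_cell(105, 105, 95, 90, 90, 120)

small_p1_model <- function(seed = 42, n = 10, cell = unit_cell(30, 30, 30)) {
  with_seed <- amtkit:::with_seed
  with_seed(seed, {
    xyz <- matrix(stats::runif(3 * n), ncol = 3)
    pseudo_atom_model(xyz, w = stats::runif(n, 0.5, 2),
                      b = stats::runif(n, 40, 120), cell = cell,
                      sg = spacegroup("P1"))
  })
}

# direct structure-factor oracle: explicit double sum over atoms and ops
sf_oracle <- function(model, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  out <- complex(length.out = nrow(h))
  s2 <- 1 / d_spacing(model$cell, h)^2
  for (r in seq_len(nrow(h))) {
    f <- 0 + 0i
    for (op in model$sg$ops) for (j in seq_len(nrow(model$xyz))) {
      x <- drop(op$R %*% model$xyz[j, ] + op$t)
      f <- f + model$w[j] * exp(-model$b[j] * s2[r] / 4) *
        exp(2i * pi * sum(h[r, ] * x))
    }
    out[r] <- f
  }
  out
}

# brute-force periodic flood fill used as labeling oracle
flood_fill_labels <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ind <- arrayInd(v, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- ind
        nb[ax] <- ((nb[ax] - 1L + s) %% d[ax]) + 1L
        j <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
        if (mask[j] && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  lab
}

# partitions equal up to label permutation
same_partition <- function(lab1, lab2) {
  sel <- lab1 > 0
  if (!identical(sel, lab2 > 0)) return(FALSE)
  key <- paste(lab1[sel], lab2[sel])
  length(unique(key)) == length(unique(lab1[sel])) &&
    length(unique(key)) == length(unique(lab2[sel]))
}

# small unique reflection list for a P1 cell (no Friedel duplicates)
p1_unique_hkl <- function(cell, hmax = 3, n = 20, seed = 2) {
  amtkit:::with_seed(seed, {
    g <- as.matrix(expand.grid(-hmax:hmax, -hmax:hmax, -hmax:hmax))
    rep_h <- map_to_asu(spacegroup("P1"), g)$rep
    uni <- rep_h[!duplicated(paste(rep_h[, 1], rep_h[, 2], rep_h[, 3])), ]
    uni <- uni[rowSums(abs(uni)) > 0, ]
    uni[sample(nrow(uni), n), ]
  })
}

# the standard demonstration runs are expensive; share them across test
# files (test-acceptance.R, which runs first alphabetically, fills the
# cache; the property tests reuse it)
.demo_cache <- new.env(parent = emptyenv())

cached_standard_sim <- function() {
  if (is.null(.demo_cache$sim)) .demo_cache$sim <- standard_dataset()
  .demo_cache$sim
}

cached_demo_run <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.demo_cache[[key]]))
    .demo_cache[[key]] <- run_phasing_demo(seed = seed,
                                           sim = cached_standard_sim())
  .demo_cache[[key]]
}
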