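test_that("a single reflection synthesizes a cosine wave peaking at the origin", {
  cell <- unit_cell(20, 20, 20)
  rs <- reflection_set(cell, spacegroup("P1"), matrix(c(1, 0, 0), 1), 1,
                       phi = 0)
  mp <- fourier_synthesis(rs, dims = c(16L, 8L, 8L))
  expect_identical(which.max(mp$grid[, 1, 1]), 1L)
  profile <- mp$grid[, 1, 1]
  expected <- 2 * cos(2 * pi * (0:15) / 16) / cell$volume
  expect_equal(profile, expected, tolerance = 1e-12)
  # empty set gives a zero map; missing phases are an error
  rs0 <- resolution_shell(rs, 50, 60)
  expect_true(all(fourier_synthesis(rs0, dims = c(8L, 8L, 8L))$grid == 0))
  rs$data$phi <- NA_real_
  expect_error(fourier_synthesis(rs), "phase")
})

test_that("FFT synthesis matches a direct double-loop DFT", {
  cell <- unit_cell(20, 25, 30)
  hkl <- p1_unique_hkl(cell, n = 20, seed = 2)
  amtkit:::with_seed(3, {
    rs <- reflection_set(cell, spacegroup("P1"), hkl,
                         stats::runif(20, 1, 5), phi = stats::runif(20, 0, 360))
  })
  mp <- fourier_synthesis(rs, dims = c(8L, 8L, 8L))
  dft <- array(0, dim = c(8, 8, 8))
  hm <- as.matrix(rs$data[, c("h", "k", "l")])
  for (ix in 0:7) for (iy in 0:7) for (iz in 0:7) {
    x <- c(ix, iy, iz) / 8
    dft[ix + 1, iy + 1, iz + 1] <-
      sum(2 * rs$data$f * cos(rs$data$phi * pi / 180 -
                                2 * pi * drop(hm %*% x))) / cell$volume
  }
  expect_lt(max(abs(mp$grid - dft)), 1e-8 * stats::sd(as.vector(mp$grid)))
})

test_that("synthesis is linear and satisfies Parseval on P1 sets", {
  cell <- unit_cell(20, 25, 30)
  hkl <- p1_unique_hkl(cell, n = 15, seed = 4)
  amtkit:::with_seed(5, {
    f1 <- stats::runif(15, 1, 4); p1 <- stats::runif(15, 0, 360)
    f2 <- stats::runif(15, 1, 4); p2 <- stats::runif(15, 0, 360)
  })
  z1 <- f1 * exp(1i * p1 * pi / 180)
  z2 <- f2 * exp(1i * p2 * pi / 180)
  zs <- 2 * z1 + 3 * z2
  mk <- function(z) fourier_synthesis(
    reflection_set(cell, spacegroup("P1"), hkl, Mod(z),
                   phi = (Arg(z) * 180 / pi) %% 360), dims = c(10L, 10L, 10L))
  ms <- mk(zs)
  lin <- 2 * mk(z1)$grid + 3 * mk(z2)$grid
  expect_lt(max(abs(ms$grid - lin)), 1e-10 * stats::sd(lin))
  # Parseval: mean(rho^2) = sum over the full sphere |F|^2 / V^2
  lhs <- mean(ms$grid^2)
  rhs <- 2 * sum(Mod(zs)^2) / cell$volume^2
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("difference syntheses locate omitted density with positive sign", {
  m <- make_two_domain_phantom(n_amt = 10, n_hk = 5, seed = 8)
  rs_full <- compute_structure_factors(m, 10)
  keep <- m$label == "Amt"
  m_amt <- pseudo_atom_model(m$xyz[keep, ], m$w[keep], m$b[keep],
                             m$cell, m$sg, m$label[keep])
  rs_amt <- compute_structure_factors(m_amt, 10)
  dm <- difference_synthesis(rs_full, rs_amt)
  # identical sets cancel exactly
  zero <- difference_synthesis(rs_amt, rs_amt)
  expect_lt(max(abs(zero$grid)), 1e-12)
  # maximum of the difference map falls inside the omitted HK cluster
  peak <- arrayInd(which.max(dm$grid), dim(dm$grid))
  frac <- (peak - 1) / dim(dm$grid)
  hk_xyz <- m$xyz[!keep, , drop = FALSE]
  # distance to nearest symmetry copy of an HK atom
  mind <- Inf
  for (op in m$sg$ops) {
    xs <- t(op$R %*% t(hk_xyz)) + matrix(op$t, nrow(hk_xyz), 3, byrow = TRUE)
    dfrac <- abs((xs - matrix(frac, nrow(xs), 3, byrow = TRUE) + 0.5) %% 1 - 0.5)
    cart <- dfrac %*% t(m$cell$orth)
    mind <- min(mind, sqrt(min(rowSums(cart^2))))
  }
  expect_lt(mind, 15)
  expect_gt(max(dm$grid), abs(min(dm$grid)))
  # mismatched reflection lists are refused with the missing indices
  expect_error(difference_synthesis(resolution_shell(rs_full, 12, Inf), rs_amt),
               "lacks")
})

test_that("sigma contours select the expected Gaussian tail", {
  cell <- unit_cell(20, 20, 20)
  amtkit:::with_seed(9, {
    g <- array(stats::rnorm(40^3), dim = c(40, 40, 40))
  })
  mp <- density_map(g, cell)
  mask <- sigma_contour(mp, 1)
  expect_equal(mean(mask), pnorm(-1), tolerance = 0.05)
  expect_true(all(sigma_contour(mp, -Inf)))
  expect_false(any(sigma_contour(mp, max(g) + 1)))
  expect_error(sigma_contour(density_map(array(1, c(4, 4, 4)), cell), 1),
               "variance")
})

test_that("volume-fraction thresholds pick exactly the top voxels", {
  cell <- unit_cell(10, 10, 10)
  g <- array(1:8, dim = c(2, 2, 2))
  mask <- threshold_by_volume_fraction(density_map(g, cell), 0.25)
  expect_identical(which(mask), which(g >= 7))
  expect_true(all(threshold_by_volume_fraction(density_map(g, cell), 1)))
  amtkit:::with_seed(10, {
    gr <- array(stats::runif(17^3), dim = c(17, 17, 17))
  })
  for (a in c(0.1, 0.33, 0.5)) {
    k <- sum(threshold_by_volume_fraction(gr, a))
    expect_lte(abs(k - a * length(gr)), 1)
  }
  expect_error(threshold_by_volume_fraction(gr, 0), "alpha")
  expect_error(threshold_by_volume_fraction(gr, 1.2), "alpha")
})

test_that("periodic labeling matches a brute-force flood fill", {
  amtkit:::with_seed(11, {
    for (t in 1:100) {
      mask <- array(stats::runif(512) < stats::runif(1, 0.1, 0.5),
                    dim = c(8, 8, 8))
      lab <- label_periodic(mask)
      oracle <- flood_fill_labels(mask)
      expect_true(same_partition(lab$labels, oracle))
      expect_identical(sort(lab$sizes, decreasing = TRUE), lab$sizes)
      expect_identical(sum(lab$sizes), sum(mask))
    }
  })
})

test_that("labeling respects periodicity and cyclic-shift invariance", {
  mask <- array(FALSE, dim = c(8, 8, 8))
  mask[c(1, 8), 4, 4] <- TRUE       # blob straddling the x boundary
  expect_identical(length(label_periodic(mask)$sizes), 1L)
  mask2 <- array(FALSE, dim = c(8, 8, 8))
  mask2[2, 2, 2] <- TRUE; mask2[6, 6, 6] <- TRUE
  expect_identical(label_periodic(mask2)$sizes, c(1L, 1L))
  amtkit:::with_seed(12, {
    m3 <- array(stats::runif(8^3) < 0.3, dim = c(8, 8, 8))
  })
  sizes0 <- label_periodic(m3)$sizes
  shifted <- m3[c(4:8, 1:3), c(2:8, 1), c(8, 1:7)]
  expect_identical(label_periodic(shifted)$sizes, sizes0)
})

test_that("connectivity constraints accept and score per the stated rule", {
  mk_labels <- function(sizes) structure(
    list(labels = NULL, sizes = as.integer(sizes),
         n_selected = sum(sizes)), class = "region_labels")
  c1 <- connectivity_constraint(1, 0.1)
  expect_true(check_connectivity(mk_labels(1000), c1)$accept)
  expect_equal(check_connectivity(mk_labels(1000), c1)$score, 1.0)
  expect_false(check_connectivity(mk_labels(c(500, 450, 30)), c1)$accept)
  c2 <- connectivity_constraint(2, 0.1, 6, TRUE)
  r <- check_connectivity(mk_labels(c(600, 300, 5, 5)), c2)
  expect_true(r$accept)
  expect_equal(r$score, 900 / 910)
  # drops forbidden
  c3 <- connectivity_constraint(2, 0.1, 6, allow_drops = FALSE)
  expect_false(check_connectivity(mk_labels(c(600, 300, 5)), c3)$accept)
  expect_true(check_connectivity(mk_labels(c(600, 300)), c3)$accept)
  expect_error(connectivity_constraint(3, max_total_regions = 2), "exceeds")
})

test_that("the fused C++ candidate evaluation agrees with the R path", {
  amtkit:::with_seed(13, {
    for (t in 1:20) {
      g <- array(stats::rnorm(10 * 9 * 8), dim = c(10, 9, 8))
      cons <- connectivity_constraint(sample(1:3, 1), 0.2,
                                      sample(c(4, 8, Inf), 1),
                                      sample(c(TRUE, FALSE), 1))
      a <- stats::runif(1, 0.05, 0.5)
      lab <- label_periodic(threshold_by_volume_fraction(g, a))
      rr <- check_connectivity(lab, cons)
      cc <- amtkit:::eval_candidate(as.vector(g), dim(g), a, cons)
      expect_identical(cc$accept, rr$accept)
      expect_equal(cc$score, rr$score, tolerance = 1e-12)
      expect_identical(cc$n_regions, length(lab$sizes))
    }
  })
})
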