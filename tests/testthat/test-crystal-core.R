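test_that("d-spacings match the orthorhombic closed form and hexagonal axes", {
  uc <- unit_cell(10, 20, 30)
  h <- rbind(c(1, 0, 0), c(0, 2, 0), c(1, 2, 3), c(2, -1, 1))
  closed <- 1 / sqrt(h[, 1]^2 / 100 + h[, 2]^2 / 400 + h[, 3]^2 / 900)
  expect_equal(d_spacing(uc, h), closed, tolerance = 1e-12)
  hexc <- hex_cell()
  expect_equal(d_spacing(hexc, c(0, 0, 2)), 95 / 2, tolerance = 1e-12)
  # (100) in a hexagonal cell: d = a * sin(60)
  expect_equal(d_spacing(hexc, c(1, 0, 0)), 105 * sin(pi / 3), tolerance = 1e-9)
  expect_error(unit_cell(-1, 10, 10), "lengths")
  expect_error(unit_cell(10, 10, 10, alpha = 181), "angles")
})

test_that("space-group operator sets are closed under composition", {
  for (nm in c("P1", "P21", "P63")) {
    sg <- spacegroup(nm)
    keyset <- vapply(sg$ops, function(op)
      paste(c(op$R, round(op$t %% 1, 9)), collapse = ","), "")
    for (a in sg$ops) for (b in sg$ops) {
      r <- a$R %*% b$R
      t <- drop(a$R %*% b$t + a$t) %% 1
      expect_true(paste(c(r, round(t, 9)), collapse = ",") %in% keyset,
                  info = nm)
    }
    expect_true(any(vapply(sg$ops, function(op)
      all(op$R == diag(3)) && all(op$t == 0), logical(1))))
  }
})

test_that("systematic absences agree with direct structure-factor summation", {
  model <- make_two_domain_phantom(n_amt = 6, n_hk = 3, seed = 5)
  sg <- model$sg
  # 00l screw absences in P63
  expect_true(is_absent(sg, c(0, 0, 3)))
  expect_false(is_absent(sg, c(0, 0, 2)))
  expect_false(is_absent(sg, c(1, 0, 3)))
  absent_h <- rbind(c(0, 0, 1), c(0, 0, 3), c(0, 0, 5))
  present_h <- rbind(c(0, 0, 2), c(1, 0, 0), c(2, 1, 3))
  f_abs <- Mod(sf_oracle(model, absent_h))
  f_pres <- Mod(sf_oracle(model, present_h))
  expect_lt(max(f_abs), 1e-8 * mean(f_pres))
  # P21: 0k0 with k odd
  sg21 <- spacegroup("P21")
  expect_true(is_absent(sg21, c(0, 1, 0)))
  expect_false(is_absent(sg21, c(0, 2, 0)))
  expect_false(is_absent(sg21, c(1, 1, 0)))
})

test_that("centric classification matches phases of random models", {
  sg <- spacegroup("P63")
  expect_false(is_centric(c(1, 1, 1), spacegroup("P1"))$centric)
  cen <- is_centric(c(2, 1, 0), sg)
  expect_true(cen$centric)
  expect_equal(sort(cen$allowed), c(0, 180))
  expect_false(is_centric(c(0, 0, 2), sg)$centric)
  # direct-summation check: centric phases land on an allowed value
  model <- make_two_domain_phantom(n_amt = 5, n_hk = 3, seed = 9)
  hs <- rbind(c(2, 1, 0), c(3, -1, 0), c(1, 1, 0))
  f <- sf_oracle(model, hs)
  for (i in seq_len(nrow(hs))) {
    allowed <- is_centric(hs[i, ], sg)$allowed
    phi <- (Arg(f[i]) * 180 / pi) %% 360
    expect_lt(min(abs(((phi - allowed + 180) %% 360) - 180)), 1e-6)
  }
})

test_that("symmetry merging is deterministic and idempotent", {
  cell <- hex_cell()
  sg <- spacegroup("P63")
  h0 <- c(3, 1, 2)
  mates <- t(vapply(sg$ops, function(op) drop(h0 %*% op$R), numeric(3)))
  mates <- rbind(mates, -mates)
  rs <- reflection_set(cell, sg, mates, rep(5, nrow(mates)))
  expect_identical(nrow(rs$data), 1L)
  # remerging the merged set changes nothing
  rs2 <- reflection_set(cell, sg, as.matrix(rs$data[, c("h", "k", "l")]),
                        rs$data$f)
  expect_equal(rs2$data$f, rs$data$f)
  expect_equal(rs2$data[, c("h", "k", "l")], rs$data[, c("h", "k", "l")])
  # conflicting amplitudes across a class are refused
  expect_error(reflection_set(cell, sg, mates[c(1, 2), ], c(5, 7)),
               "conflicting")
})

test_that("reflection tables round-trip through text files", {
  cell <- unit_cell(30, 40, 50)
  sg <- spacegroup("P1")
  hkl <- p1_unique_hkl(cell, n = 12)
  rs <- reflection_set(cell, sg, hkl, seq(1, 12), phi = seq(0, 330, 30),
                       fom = seq(0.1, 0.98, length.out = 12))
  path <- withr::local_tempfile(fileext = ".hkl")
  write_reflections(rs, path, comments = "fixture")
  rs2 <- read_reflections(path, cell, sg)
  ord <- order(rs$data$h, rs$data$k, rs$data$l)
  ord2 <- order(rs2$data$h, rs2$data$k, rs2$data$l)
  expect_equal(rs2$data$f[ord2], rs$data$f[ord], tolerance = 1e-6)
  expect_equal(rs2$data$phi[ord2], rs$data$phi[ord], tolerance = 1e-4)
})

test_that("reading merges Friedel mates, drops absences and flags bad lines", {
  cell <- unit_cell(30, 30, 30)
  path <- withr::local_tempfile(fileext = ".hkl")
  writeLines(c("# comment", "h k l F",
               "1 0 0 10.0", "-1 0 0 10.0", "0 2 1 4.5"), path)
  rs <- read_reflections(path, cell, spacegroup("P1"))
  expect_identical(nrow(rs$data), 2L)
  # absence dropped and reported in P63
  path2 <- withr::local_tempfile(fileext = ".hkl")
  writeLines(c("h k l F", "0 0 3 5.0", "0 0 2 6.0"), path2)
  expect_message(rs2 <- read_reflections(path2, hex_cell(), spacegroup("P63")),
                 "absent")
  expect_identical(nrow(rs2$data), 1L)
  expect_identical(nrow(attr(rs2, "dropped")), 1L)
  # malformed line names its position
  path3 <- withr::local_tempfile(fileext = ".hkl")
  writeLines(c("h k l F", "1 0 0 10.0", "2 0 zero 1.0"), path3)
  expect_error(read_reflections(path3, cell, spacegroup("P1")), "line 3")
  # empty file warns and returns an empty set
  path4 <- withr::local_tempfile(fileext = ".hkl")
  writeLines(character(0), path4)
  expect_warning(rs4 <- read_reflections(path4, cell, spacegroup("P1")),
                 "empty")
  expect_identical(nrow(rs4$data), 0L)
})

test_that("resolution shells match brute-force enumeration", {
  cell <- unit_cell(100, 100, 100)
  model <- small_p1_model(n = 4, cell = cell)
  rs <- compute_structure_factors(model, 8)
  # brute-force count of unique (Friedel-merged) triples with d in range
  lim <- 13
  g <- as.matrix(expand.grid(-lim:lim, -lim:lim, -lim:lim))
  g <- g[rowSums(abs(g)) > 0, ]
  rep_h <- map_to_asu(spacegroup("P1"), g)$rep
  uni <- rep_h[!duplicated(paste(rep_h[, 1], rep_h[, 2], rep_h[, 3])), ]
  d <- d_spacing(cell, uni)
  for (bounds in list(c(8, Inf), c(10, 20), c(9, 12.5))) {
    shell <- resolution_shell(rs, bounds[1], bounds[2])
    expect_identical(nrow(shell$data),
                     sum(d >= bounds[1] & d < bounds[2]))
  }
  expect_identical(nrow(resolution_shell(rs, 0, Inf)$data), nrow(rs$data))
  expect_identical(nrow(resolution_shell(rs, 150, 200)$data), 0L)
  expect_error(resolution_shell(rs, 10, 8), "d_min")
})

test_that("density maps round-trip through CCP4 files", {
  cell <- hex_cell()
  amtkit:::with_seed(3, {
    g <- array(stats::rnorm(8 * 8 * 8), dim = c(8, 8, 8))
  })
  mp <- density_map(g, cell)
  path <- withr::local_tempfile(fileext = ".ccp4")
  write_map(mp, path, sg = spacegroup("P63"))
  mp2 <- read_map(path)
  expect_lt(max(abs(mp2$grid - mp$grid)),
            1e-5 * stats::sd(as.vector(mp$grid)))
  expect_equal(mp2$cell$gamma, 120, tolerance = 1e-5)
  expect_error(density_map(array(1, dim = c(1, 4, 4)), cell), ">= 2")
})
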