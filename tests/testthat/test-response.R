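test_that("response model closed forms evaluate correctly", {
  # Hill: midpoint identity, zero limit, direct value
  expect_equal(hill_response(22.9, 1, 22.9, 0.75), 0.5, tolerance = 1e-12)
  expect_equal(hill_response(5, 1, 5, 3.2), 0.5, tolerance = 1e-12)
  expect_identical(hill_response(0, 1, 22.9, 0.75), 0)
  expect_equal(hill_response(300, 1, 22.9, 0.75),
               300^0.75 / (22.9^0.75 + 300^0.75), tolerance = 1e-12)
  expect_equal(hill_response(300, 1, 22.9, 0.75), 0.8732, tolerance = 1e-4)
  # titration: midpoint, high-pH limit, direct value
  expect_equal(titration_response(5.5, 0, 1, 5.5, 1), 0.5, tolerance = 1e-12)
  expect_equal(titration_response(100, 0.2, 1.4, 5.5, 1), 1.4, tolerance = 1e-9)
  expect_equal(titration_response(6.5, 0, 1, 5.5, 1), 1 / (1 + 10^-1),
               tolerance = 1e-12)
  # speciation at the ammonium pKa
  expect_equal(ammonium_speciation(9.25), 0.5, tolerance = 1e-12)
  expect_equal(ammonium_speciation(7.5), 1 / (1 + 10^(-1.75)), tolerance = 1e-12)
  expect_equal(ammonium_speciation(0), 1, tolerance = 1e-9)
  # isotherm: midpoint, intercept, bound fraction 123/(41+123) = 0.75
  expect_equal(binding_isotherm(41, 0, 1, 41), 0.5, tolerance = 1e-12)
  expect_identical(binding_isotherm(0, 0.3, 1, 41), 0.3)
  expect_equal(binding_isotherm(123, 0, 1, 41), 0.75, tolerance = 1e-12)
})

test_that("Hill with unit exponent coincides with the binding isotherm", {
  x <- c(0.5, 2, 10, 41, 100, 1000)
  expect_equal(hill_response(x, 1, 41, 1), binding_isotherm(x, 0, 1, 41),
               tolerance = 1e-12)
})

test_that("ITC heats match an independent bisection equilibrium solver", {
  heats <- itc_injection_heats(1, 11.16, -10, 100, 1.437, 10, 1300, 28)
  oracle <- function(n, kd, dh, p0, v0, v_ul, ls, ninj) {
    v <- v_ul * 1e-3; dil <- 1 - v / v0
    pl <- numeric(ninj)
    for (i in seq_len(ninj)) {
      pt <- p0 * dil^i; lt <- ls * (1 - dil^i); s <- n * pt
      f <- function(lf) lf + s * lf / (kd + lf) - lt
      lo <- 0; hi <- lt
      for (k in 1:200) { mid <- (lo + hi) / 2
        if (f(mid) > 0) hi <- mid else lo <- mid }
      lf <- (lo + hi) / 2
      pl[i] <- s * lf / (kd + lf)
    }
    q <- dh * pl * 1e-6 * (v0 * 1e-3)
    qp <- c(0, q[-ninj])
    (q - qp + (v / v0) * (q + qp) / 2) / (ls * 1e-6 * v * 1e-3)
  }
  expect_lt(max(abs(heats - oracle(1, 11.16, -10, 100, 1.437, 10, 1300, 28))),
            1e-8)
  # zero enthalpy: all heats vanish
  expect_true(all(itc_injection_heats(1, 11.16, 0, 100, 1.437, 10, 1300, 28) == 0))
  # tight-binding limit: heats ~ dH until the equivalence point, then ~ 0
  tight <- itc_injection_heats(1, 1e-6, -10, 100, 1.437, 10, 1300, 28)
  expect_equal(tight[1], -10, tolerance = 0.01)
  expect_gt(abs(tight[5]), 9.9)
  expect_lt(abs(tight[28]), 0.2)
  expect_error(itc_injection_heats(-1, 10, -10, 100, 1.437, 10, 1300, 28),
               "> 0")
})

test_that("ITC total heat approaches N dH x protein moles for saturating ligand", {
  p0 <- 100; v0 <- 1.437; v <- 10; n_inj <- 28
  heats <- itc_injection_heats(1, 11.16, -10, p0, v0, v, 2e5, n_inj)
  mol_inj <- 2e5 * 1e-6 * v * 1e-6 * 1e3
  total <- sum(heats * mol_inj)
  expect_equal(total, -10 * p0 * 1e-6 * v0 * 1e-3, tolerance = 0.02)
})

test_that("transient summaries find the biexponential peak and decay", {
  tt <- seq(0, 80, by = 0.25)
  trace <- 5 * (exp(-tt / 10) - exp(-tt / 1))
  ts <- transient_summary(tt, trace)
  t_star <- 10 * 1 / (10 - 1) * log(10)
  expect_lt(abs(ts$t_peak - t_star), 0.25)
  # dense-grid numerical oracle for tau_1/2
  tg <- seq(0, 80, by = 1e-4)
  yg <- 5 * (exp(-tg / 10) - exp(-tg / 1))
  pk <- which.max(yg)
  cross <- tg[pk + which(yg[(pk + 1):length(yg)] <= yg[pk] / 2)[1]]
  expect_lt(abs(ts$tau_half - (cross - tg[pk])), 0.25)
  # negative-going transients report the signed extremum
  ts_neg <- transient_summary(tt, -trace)
  expect_lt(ts_neg$peak, 0)
  expect_equal(ts_neg$tau_half, ts$tau_half, tolerance = 1e-9)
  # square pulse: the half-maximum crossing sits at the instantaneous
  # drop, so tau_1/2 spans the plateau (peak at sample 6, drop after 15)
  sq <- c(rep(0, 5), rep(4, 10), rep(0, 25))
  tsq <- transient_summary(seq_along(sq), sq)
  expect_gte(tsq$tau_half, 9)
  expect_lte(tsq$tau_half, 10)
  expect_error(transient_summary(tt, 5 * exp(-tt / 1e5)), "incomplete")
  expect_error(transient_summary(tt, rep(0, length(tt))), "zero")
})

test_that("decay-time invariance across LPR classifies charge displacement", {
  lpr <- rep(c(10, 30), each = 4)
  flat <- c(5.1, 4.9, 5.0, 5.2, 5.0, 5.1, 4.9, 5.1)
  v1 <- classify_electrogenicity(lpr, flat)
  expect_identical(v1$verdict, "displacement")
  doubled <- c(5.1, 4.9, 5.0, 5.2, 10.1, 9.8, 10.2, 10.0)
  v2 <- classify_electrogenicity(lpr, doubled)
  expect_identical(v2$verdict, "translocation")
  expect_gt(v2$rel_change, 0.9)
  # borderline 5% change with a 25% threshold stays displacement
  mild <- c(5.0, 5.0, 5.0, 5.0, 5.25, 5.25, 5.25, 5.25)
  expect_identical(classify_electrogenicity(lpr, mild, threshold = 0.25)$verdict,
                   "displacement")
  expect_error(classify_electrogenicity(rep(10, 6), flat[1:6]), "two LPR")
  expect_error(classify_electrogenicity(c(10, 10, 30, 30), flat[1:4]),
               "replicates")
})

test_that("synthetic datasets land on the curve and obey the noise level", {
  x <- exp(seq(log(1), log(300), length.out = 8))
  clean <- generate_dataset("hill", list(i_max = 1, k05 = 22.9, h = 0.75),
                            x, noise = 0, seed = 1)
  expect_equal(clean$y, hill_response(x, 1, 22.9, 0.75), tolerance = 1e-12)
  n1 <- generate_dataset("hill", list(i_max = 1, k05 = 22.9, h = 0.75),
                         x, noise = 0.05, seed = 11)
  n2 <- generate_dataset("hill", list(i_max = 1, k05 = 22.9, h = 0.75),
                         x, noise = 0.05, seed = 11)
  expect_identical(n1$y, n2$y)
  big <- generate_dataset("mst", list(f_free = 0, f_bound = 1, k_d = 41),
                          seq(1, 1e4, length.out = 10000), noise = 0.03,
                          seed = 2)
  resid <- big$y - binding_isotherm(big$x, 0, 1, 41)
  expect_equal(stats::sd(resid), 0.03, tolerance = 0.03)
})

test_that("noiseless fits recover parameters exactly", {
  x <- exp(seq(log(1), log(300), length.out = 8))
  dat <- generate_dataset("hill", list(i_max = 1, k05 = 22.9, h = 0.75),
                          x, noise = 0, seed = 1)
  ft <- fit_model(dat)
  expect_true(ft$converged)
  expect_equal(unname(ft$params["k05"]), 22.9, tolerance = 1e-6)
  expect_equal(unname(ft$params["h"]), 0.75, tolerance = 1e-6)
  expect_lt(sum(ft$residuals^2), 1e-12)
  # titration
  datt <- generate_dataset("titration",
                           list(i_min = 0.1, i_max = 1.2, pk_app = 5.5, n = 1),
                           seq(4, 8, by = 0.5), noise = 0, seed = 1)
  ftt <- fit_model(datt)
  expect_equal(unname(ftt$params["pk_app"]), 5.5, tolerance = 1e-6)
  # degenerate all-equal responses flag non-convergence rather than crash
  bad <- response_dataset(x, rep(1, 8), model = "hill")
  fb <- fit_model(bad)
  expect_false(isTRUE(fb$converged) && all(is.finite(fb$se)))
})

test_that("fits recover simulated parameters within two standard errors", {
  x <- exp(seq(log(1), log(300), length.out = 8))
  dat <- generate_dataset("hill", list(i_max = 1, k05 = 22.9, h = 0.75),
                          x, noise = 0.05, seed = 11)
  ft <- fit_model(dat)
  expect_true(ft$converged)
  expect_lt(abs(ft$params["k05"] - 22.9), 2 * ft$se["k05"])
  expect_lt(abs(ft$params["h"] - 0.75), 2 * ft$se["h"])
  # MST
  dil <- 50000 / 2^(15:0)
  mst <- generate_dataset("mst", list(f_free = 0, f_bound = 1, k_d = 41),
                          dil, noise = 0.03, seed = 17)
  fm <- fit_model(mst)
  expect_lt(abs(fm$params["k_d"] - 41), 2 * fm$se["k_d"])
  # ITC with the study geometry
  meta <- list(cell_conc = 100, cell_vol = 1.437, inj_vol = 10,
               syringe_conc = 1300)
  itc <- generate_dataset("itc", list(n = 1, k_d = 11.16, dh = -10), 1:28,
                          noise = 0.1, seed = 23, meta = meta)
  fi <- fit_model(itc)
  expect_true(fi$converged)
  expect_lt(abs(fi$params["k_d"] - 11.16), 2 * fi$se["k_d"])
})

test_that("recovery is unbiased with near-nominal interval coverage", {
  x <- exp(seq(log(1), log(300), length.out = 8))
  n_sim <- 200
  est <- se <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    dat <- generate_dataset("hill", list(i_max = 1, k05 = 22.9, h = 0.75),
                            x, noise = 0.05, seed = 1000 + i)
    ft <- fit_model(dat)
    est[i] <- ft$params["k05"]; se[i] <- ft$se["k05"]
  }
  ok <- is.finite(est) & is.finite(se)
  expect_lt(abs(stats::median(est[ok]) - 22.9) / 22.9, 0.05)
  cover <- mean(abs(est[ok] - 22.9) < se[ok])
  expect_gte(cover, 0.55)
  expect_lte(cover, 0.80)
})

test_that("response datasets round-trip through delimited text", {
  meta <- list(cell_conc = 100, cell_vol = 1.437, inj_vol = 10,
               syringe_conc = 1300)
  dat <- generate_dataset("itc", list(n = 1, k_d = 11.16, dh = -10), 1:28,
                          noise = 0.1, seed = 23, meta = meta)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_response(dat, path)
  dat2 <- read_response(path)
  expect_identical(dat2$model, "itc")
  expect_equal(dat2$y, dat$y, tolerance = 1e-6)
  expect_equal(dat2$meta$cell_vol, 1.437, tolerance = 1e-9)
  expect_error(fit_model(response_dataset(1:20, stats::rnorm(20),
                                          model = "transient")),
               "transient")
})
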