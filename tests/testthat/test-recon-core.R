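test_that("AICc follows the small-sample-corrected formula", {
  expect_equal(aicc(-100, 3, 31), 200 + 6 + 24 / 27, tolerance = 1e-12)
  expect_equal(aicc(-50, 0, 31), 100)
  for (k in 1:8)  # correction term is strictly positive
    expect_gt(aicc(-10, k, 31), -2 * -10 + 2 * k)
  expect_error(aicc(-10, 30, 31), "insufficient observations")
})

test_that("Horvitz-Thompson inverts the analytic zero class", {
  mix <- parent_mixture(1, 1)
  ht <- horvitz_thompson_missing(mix, 632)
  expect_equal(ht$D_total, 632 / (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(ht$missing, ht$D_total - 632)

  mix2 <- parent_mixture(c(0.5, 0.5), c(1, 4))
  ht2 <- horvitz_thompson_missing(mix2, 807)
  expect_equal(ht2$D_total, 807 / (1 - (0.5 * exp(-1) + 0.5 * exp(-4))),
               tolerance = 1e-12)
  expect_equal(round(ht2$D_total), 1000)

  # full detection limit
  ht3 <- horvitz_thompson_missing(parent_mixture(1, 50), 100)
  expect_equal(ht3$D_total, 100, tolerance = 1e-12)
  expect_error(horvitz_thompson_missing(parent_mixture(1, 1e-15), 10),
               "no detection probability")
})

test_that("conditional likelihood is symmetric under component permutation", {
  obs <- clone_size_distribution(1:6, c(30, 22, 14, 8, 3, 1))
  a <- parent_mixture(c(0.2, 0.5, 0.3), c(0.8, 2.5, 7))
  b <- parent_mixture(c(0.3, 0.2, 0.5), c(7, 0.8, 2.5))
  expect_equal(conditional_loglik(a, obs), conditional_loglik(b, obs),
               tolerance = 1e-12)
})

test_that("conditional likelihood peaks at the generating mean (grid oracle)", {
  # observed spectrum = expected zero-truncated spectrum at m = 2
  m_true <- 2
  sizes <- 1:15
  obs <- clone_size_distribution(sizes, 1e4 * dpois(sizes, m_true))
  grid <- seq(0.5, 5, by = 0.01)
  ll <- vapply(grid, function(m)
    conditional_loglik(parent_mixture(1, m), obs), numeric(1))
  expect_equal(grid[which.max(ll)], m_true, tolerance = 0.011)
})

test_that("single-component fits recover simulated parameters within 2%", {
  D <- 1e4
  parent <- uniform_csd(D, size = 1e5)
  samp <- suppressWarnings(poisson_sample(parent, 2 * D, seed = 5))  # m = 2
  small <- samp[samp$size <= 30, ]
  f <- fit_fixed_k(clone_size_distribution(small$size, small$count), 1)
  expect_equal(f$m, 2, tolerance = 0.02)
  expect_equal(f$D_total, D, tolerance = 0.02)
})

test_that("noise-free fixed point recovers a known mixture", {
  # observed spectrum exactly equal to the expected spectrum of the mixture
  w <- c(0.5, 0.5); m <- c(1, 8); D <- 1e5
  sizes <- 1:30
  counts <- D * (w[1] * dpois(sizes, m[1]) + w[2] * dpois(sizes, m[2]))
  obs <- clone_size_distribution(sizes, counts)
  f <- scan_fit(obs, 2)
  o <- order(f$m)
  expect_equal(f$m[o], m, tolerance = 0.02)
  expect_equal(f$w[o], w, tolerance = 0.02)
  expect_equal(f$D_total, D, tolerance = 0.01)
})

test_that("two-component simulations are recovered within 10%", {
  set.seed(2)
  D <- 2e4
  lam <- rep(c(1, 8), each = D / 2)
  draws <- rpois(D, lam)
  tab <- table(draws[draws > 0 & draws <= 30])
  obs <- clone_size_distribution(as.numeric(names(tab)), as.numeric(tab))
  f <- scan_fit(obs, 2)
  o <- order(f$m)
  expect_equal(f$m[o], c(1, 8), tolerance = 0.1)
  expect_equal(f$D_total, D, tolerance = 0.1)
})

test_that("the scanned fit is at least as good as the mean start", {
  set.seed(3)
  D <- 5e3
  draws <- rpois(D, rep(c(0.8, 6), times = c(0.7, 0.3) * D))
  tab <- table(draws[draws > 0])
  obs <- clone_size_distribution(as.numeric(names(tab)), as.numeric(tab))
  f_scan <- scan_fit(obs, 2)
  f_mean <- fit_fixed_k(obs, 2)
  expect_gte(recondiv:::adjusted_loglik(f_scan, obs),
             recondiv:::adjusted_loglik(f_mean, obs) - 1e-6)
})

test_that("noise guard compares expected new clones with Poisson SD", {
  inc <- parent_mixture(1, 5, D_total = 1000)
  # new component contributing ~100 observed clones: passes 100 > 3*10
  cand <- parent_mixture(c(0.885, 0.115), c(5, 1), D_total = 1375)
  ok <- passes_noise_threshold(cand, inc)
  expect_true(ok)
  expect_equal(attr(ok, "E_new"), 1375 * 0.115 * (1 - exp(-1)),
               tolerance = 1e-9)
  # ~4 expected clones: fails 4 < 3*2
  cand2 <- parent_mixture(c(1 - 0.0063, 0.0063), c(5, 1), D_total = 1000)
  expect_false(passes_noise_threshold(cand2, inc))
  # multiplier 0 disables the guard
  expect_true(passes_noise_threshold(cand2, inc,
                                     algo_config(noise_sd_multiplier = 0)))
})

test_that("mostly-unseen components must move the spectrum above noise", {
  # incumbent: 1000 clones at m = 3; candidate adds a m = 0.02 component
  # positing ~800 extra (mostly missing) clones while barely changing the
  # expected spectrum: E_new is large but the spectrum shift is sub-noise
  inc <- parent_mixture(1, 3, D_total = 1000)
  cand <- parent_mixture(c(0.556, 0.444), c(3, 0.02), D_total = 1800)
  ok <- passes_noise_threshold(cand, inc)
  expect_false(ok)
  expect_gt(attr(ok, "E_new"), 9)         # old count check alone would pass
  expect_lt(attr(ok, "z_spectrum"), 3)    # spectrum shift is within noise
})

test_that("reconstruct handles a single directly counted clone", {
  d <- clone_size_distribution(1e5, 1)
  fit <- reconstruct(d, scale = repertoire_scale(1e5, 1e9), seed = 1)
  expect_equal(fit$k, 0)
  expect_equal(fit$diversity_overall[["0"]], 1)
  expect_equal(fit$missing, 0)
})

test_that("reconstruct is a fixed point on noise-free expected spectra", {
  w <- c(0.6, 0.4); m <- c(1.5, 9); D <- 5e4
  sizes <- 1:30
  counts <- round(D * (w[1] * dpois(sizes, m[1]) + w[2] * dpois(sizes, m[2])))
  obs <- clone_size_distribution(sizes, counts)
  fit <- reconstruct(obs, scale = repertoire_scale(sum(sizes * counts), 1e9),
                     seed = 1)
  expect_equal(fit$mixture$D_total, D, tolerance = 0.01)
  expect_equal(fit$diversity_overall[["0"]], D, tolerance = 0.01)
})

test_that("large-clone shortcut equals the full fit when no clone is large", {
  set.seed(9)
  D <- 5e3
  draws <- rpois(D, 3)  # max draw stays far below 300
  tab <- table(draws[draws > 0])
  obs <- clone_size_distribution(as.numeric(names(tab)), as.numeric(tab))
  sc <- repertoire_scale(sum(obs$size * obs$count), 1e8)
  f30 <- reconstruct(obs, scale = sc, seed = 1,
                     config = algo_config(large_clone_threshold = 30))
  finf <- reconstruct(obs, scale = sc, seed = 1,
                      config = algo_config(large_clone_threshold = Inf))
  expect_equal(f30$mixture$D_total, finf$mixture$D_total, tolerance = 1e-9)
  expect_equal(f30$k, finf$k)
  expect_equal(f30$diversity_overall, finf$diversity_overall,
               tolerance = 1e-9)
})

test_that("estimates are capped by the overall cell count", {
  # all-singleton spectrum pushes m to its floor; N caps D_total
  d <- clone_size_distribution(1, 500)
  expect_warning(
    fit <- reconstruct(d, scale = repertoire_scale(500, 5000), seed = 1),
    "singleton|capped")
  expect_lte(fit$diversity_overall[["0"]], 5000)
  expect_true(fit$low_confidence)
})

test_that("pure one-component data does not grow spurious components", {
  for (s in 1:4) {
    D <- 3e3
    parent <- uniform_csd(D, size = 1e5)
    samp <- suppressWarnings(poisson_sample(parent, 3 * D, seed = 20 + s))
    fit <- reconstruct(samp, scale = repertoire_scale(3 * D, 3e8),
                       seed = 1)
    expect_lte(fit$k, 2)
    expect_equal(fit$diversity_overall[["0"]], D, tolerance = 0.05)
  }
})

test_that("minimum detected clone size scales the smallest component", {
  mix <- parent_mixture(c(0.5, 0.5), c(1, 4))
  expect_equal(min_detected_clone_size(mix, repertoire_scale(1e6, 1e9)), 1000)
  mix2 <- parent_mixture(c(0.5, 0.5), c(0.5, 4))
  expect_equal(min_detected_clone_size(mix2, repertoire_scale(1e6, 1e9)), 500)
  # sample = whole repertoire
  expect_equal(min_detected_clone_size(mix, repertoire_scale(1e6, 1e6)), 1)
  expect_warning(
    got <- min_detected_clone_size(mix, repertoire_scale(1e6)),
    "omitted")
  expect_true(is.na(got))
})

test_that("upper bound U follows R_max * w_m * m_min * N/S", {
  mix <- parent_mixture(c(0.4, 0.6), c(0.5, 5))
  sc <- repertoire_scale(1e6, 1e9)  # N/S = 1000
  U <- upper_bound_U(mix, R_max = 1000, scale = sc)
  expect_equal(as.numeric(U), 1000 * 0.4 * 0.5 * 1000)
  expect_equal(attr(U, "with_detected"), as.numeric(U) + 1000)
  expect_error(upper_bound_U(mix, R_max = NA, scale = sc), "R_max")
})

test_that("species-richness error declines with coverage on seeded ensembles", {
  set.seed(31)
  ss <- c(0.03, 0.06, 0.12, 0.2)
  med_err <- sapply(c(0.3, 3, 10), function(cov) {
    errs <- sapply(seq_along(ss), function(i) {
      D <- 4e3
      p <- make_parent(parent_spec("exponential", s = ss[i], D = D))
      S <- round(cov * D)
      samp <- poisson_sample(p, S, seed = 40 + i)
      fit <- reconstruct(samp, scale = repertoire_scale(S, attr(p, "cells")),
                         seed = 1)
      abs(fit$diversity_overall[["0"]] - D) / D
    })
    median(errs)
  })
  expect_true(all(diff(med_err) <= 0.02))  # non-increasing up to noise
  expect_lt(med_err[2], 0.10)              # 3x coverage within 10%
})
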