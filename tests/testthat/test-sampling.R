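test_that("Poisson sampling reproduces the analytic zero class", {
  D <- 2000
  parent <- uniform_csd(D, size = 1e6)  # uniform frequencies
  # lambda = 1 per clone: expected missing fraction exp(-1)
  miss <- vapply(1:5, function(s) {
    attr(suppressWarnings(poisson_sample(parent, D, seed = s)), "missing")
  }, numeric(1))
  p0 <- exp(-1)
  se <- sqrt(D * p0 * (1 - p0) * 5)
  expect_lt(abs(sum(miss) - 5 * D * p0), 4 * se)

  # lambda = 10: missing essentially zero
  D2 <- 1000
  parent2 <- uniform_csd(D2, size = 1e6)
  miss2 <- vapply(1:10, function(s) {
    attr(suppressWarnings(poisson_sample(parent2, 10 * D2, seed = s)),
         "missing")
  }, numeric(1))
  expect_true(all(miss2 <= 2))  # expectation is 1000 * exp(-10) = 0.045
})

test_that("sampling zero cells leaves every clone missing", {
  parent <- uniform_csd(50, size = 100)
  s <- suppressWarnings(poisson_sample(parent, 0))
  expect_equal(n_clones(s), 0)
  expect_equal(attr(s, "missing"), 50)
  expect_error(poisson_sample(parent, -1), ">= 0")
  expect_error(poisson_sample(clone_size_distribution(numeric(0), numeric(0)),
                              10), "empty parent")
})

test_that("sampling-model conditions trigger warnings, not errors", {
  small_parent <- uniform_csd(10, size = 10)  # only 100 cells
  expect_warning(poisson_sample(small_parent, 50, seed = 1), "fewer than 10x")
  dominant <- clone_size_distribution(c(1, 50), c(50, 1))  # one clone = 50%
  expect_warning(poisson_sample(dominant, 5, seed = 1), "30%")
})

test_that("fixed-size samples hold exactly the requested cell count", {
  parent <- clone_size_distribution(c(1e4, 5e4), c(400, 100))
  for (s in 1:5) {
    samp <- multinomial_sample(parent, 200, seed = s)
    expect_equal(total_cells(samp), 200)
    expect_lte(n_clones(samp), 200)
    expect_equal(n_clones(samp) + attr(samp, "missing"), 500)
  }
  empty <- multinomial_sample(parent, 0)
  expect_equal(n_clones(empty), 0)
  expect_equal(attr(empty, "missing"), 500)
})

test_that("expected sample spectrum matches hand-evaluated Poisson masses", {
  mix <- parent_mixture(1, 1, D_total = 1000)
  es <- expected_sample_spectrum(mix, 5)
  expect_equal(es$expected_count[1:3], 1000 * dpois(0:2, 1),
               tolerance = 1e-12)
  # two components, zero class by hand: 50 e^-1 + 50 e^-4
  mix2 <- parent_mixture(c(0.5, 0.5), c(1, 4), D_total = 100)
  expect_equal(expected_sample_spectrum(mix2, 0)$expected_count,
               50 * exp(-1) + 50 * exp(-4), tolerance = 1e-12)
})

test_that("expected spectrum conserves clones and cells", {
  mix <- parent_mixture(c(0.3, 0.7), c(0.5, 6), D_total = 5000)
  es <- expected_sample_spectrum(mix, 60)
  expect_equal(sum(es$expected_count), 5000, tolerance = 1e-6)
  expect_equal(sum(es$size * es$expected_count),
               5000 * sum(mix$w * mix$m), tolerance = 1e-6)
})

test_that("degenerate m -> 0 pushes all mass to the missing class", {
  mix <- parent_mixture(1, 1e-10, D_total = 100)
  es <- expected_sample_spectrum(mix, 3)
  expect_equal(es$expected_count[1], 100, tolerance = 1e-6)
  expect_lt(sum(es$expected_count[-1]), 1e-6)
})

test_that("resampling from a fit is seed-deterministic", {
  mix <- parent_mixture(c(0.5, 0.5), c(1, 5), D_total = 2000,
                        scale = repertoire_scale(6000))
  a <- resample_from_fit(mix, seed = 99)
  b <- resample_from_fit(mix, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "missing"), attr(b, "missing"))
})

test_that("resampled zero class tracks the mixture's expectation", {
  mix <- parent_mixture(1, 2, D_total = 500)
  miss <- vapply(1:20, function(s)
    attr(resample_from_fit(mix, seed = s), "missing"), numeric(1))
  exp_miss <- 500 * exp(-2)  # 67.7
  expect_lt(abs(mean(miss) - exp_miss), 3 * sqrt(exp_miss / 20))
})

test_that("resampling a fit equal to a known parent matches direct sampling", {
  # parent: 1000 clones of equal size; fit encodes the same population
  D <- 1000; S <- 2000
  parent <- uniform_csd(D, size = 1e5)
  mix <- parent_mixture(1, S / D, D_total = D,
                        scale = repertoire_scale(S))
  pool_direct <- integer(0); pool_fit <- integer(0)
  for (s in 1:30) {
    ds <- suppressWarnings(poisson_sample(parent, S, seed = s))
    fs <- resample_from_fit(mix, seed = 1000 + s)
    pool_direct <- c(pool_direct, rep(ds$size, ds$count),
                     rep(0, attr(ds, "missing")))
    pool_fit <- c(pool_fit, rep(fs$size, fs$count),
                  rep(0, attr(fs, "missing")))
  }
  tab <- table(factor(pool_direct, levels = 0:10),
               factor(pool_fit, levels = 0:10))
  ct <- suppressWarnings(chisq.test(cbind(table(factor(pool_direct, 0:8)),
                                          table(factor(pool_fit, 0:8)))))
  expect_gt(ct$p.value, 0.01)
})
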