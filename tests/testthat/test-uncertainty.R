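# hand-built ensembles with known error structure
flat_band_ensemble <- function(band = 0.10, n_per = 6) {
  # estimates exactly band away from truth at alternating signs
  rows <- expand.grid(true = c(1e3, 1e4, 1e5),
                      coverage = c(0.1, 0.5, 1, 5, 10),
                      rep = seq_len(n_per))
  sign <- rep_len(c(1, -1, 0.3), nrow(rows))
  data.frame(true = rows$true,
             estimate = rows$true * (1 + sign * band),
             coverage = rows$coverage,
             sample_cells = rows$coverage * rows$true)
}

test_that("profile bands store the worst absolute proportional error", {
  ens <- data.frame(true = rep(1000, 6),
                    estimate = 1000 * (1 + c(0.05, -0.12, 0.03,
                                             0.02, -0.01, 0.005)),
                    coverage = rep(c(0.5, 5), each = 3))
  ens$sample_cells <- ens$coverage * ens$true
  # explicit columns via true/estimate names
  prof <- build_error_profile(
    data.frame(true = ens$true, estimate = ens$estimate,
               coverage = ens$coverage), measure = "raw")
  expect_equal(prof$band[1], 0.12, tolerance = 1e-12)
  expect_equal(prof$band[2], 0.02, tolerance = 1e-12)
})

test_that("bands are regularized to be non-increasing in coverage", {
  ens <- data.frame(true = 1000,
                    estimate = 1000 * (1 + c(0.02, 0.10, 0.01)),
                    coverage = c(0.1, 1, 10))
  prof <- build_error_profile(ens, measure = "raw")
  expect_true(all(diff(prof$band) <= 0))
  expect_equal(prof$band[prof$coverage == min(prof$coverage)], 0.10)
})

test_that("gross outliers are excluded and counted", {
  ens <- data.frame(true = rep(100, 6),
                    estimate = c(105, 95, 2000, 101, 99, 98),
                    coverage = rep(c(1, 10), each = 3))
  prof <- build_error_profile(ens, measure = "raw")
  expect_equal(attr(prof, "n_outliers"), 1)
  expect_lt(max(prof$band), 0.2)
})

test_that("zero-error profiles collapse error bars onto the estimate", {
  prof <- build_error_profile(flat_band_ensemble(band = 0), measure = "raw")
  eb <- error_bars(1000, sample_cells = 1000, prof)
  expect_equal(unname(eb), c(1000, 1000), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("constant 10% band inverts to the textbook bounds", {
  prof <- build_error_profile(flat_band_ensemble(band = 0.10),
                              measure = "raw")
  eb <- error_bars(1000, sample_cells = 1000, prof)
  expect_equal(eb[["lower"]], 1000 / 1.1, tolerance = 1e-3)
  expect_equal(eb[["upper"]], 1000 / 0.9, tolerance = 1e-3)
})

test_that("error bars widen as coverage falls", {
  # band shrinking with coverage: 30% at 0.01x down to 1% at 10x
  covs <- 10^seq(-2, 1, by = 0.5)
  ens <- do.call(rbind, lapply(covs, function(cv) {
    band <- 0.01 * (10 / cv)^0.5
    data.frame(true = 1e4, estimate = 1e4 * (1 + c(band, -band)),
               coverage = cv, sample_cells = cv * 1e4)
  }))
  prof <- build_error_profile(ens, measure = "raw")
  widths <- sapply(c(1e5, 1e4, 1e3), function(S) {
    eb <- error_bars(1e4, sample_cells = S, prof)
    eb[["upper"]] - eb[["lower"]]
  })
  expect_true(all(diff(widths) > 0))
})

test_that("calibration finds no adjustment when bars already bracket", {
  set.seed(5)
  ens <- flat_band_ensemble(band = 0.10)
  # true errors are at most the band, so raw bracketing is already ~100%
  prof <- calibrate_profile(ens, measure = "raw", n_splits = 25, seed = 2)
  expect_equal(attr(prof, "upper_adjustment"), 0)
  expect_gte(attr(prof, "calibrated_rate"), 0.95)
})

test_that("calibration raises the upper bar to reach the target rate", {
  set.seed(6)
  n <- 150
  true <- 10^runif(n, 3, 5)
  cov <- 10^runif(n, -1, 1)
  # noisy, downward-biased estimates: raw bars will miss high truths
  est <- true * (1 - 0.1 * runif(n)) * exp(rnorm(n, 0, 0.05))
  ens <- data.frame(true = true, estimate = est, coverage = cov,
                    sample_cells = cov * true)
  prof <- calibrate_profile(ens, measure = "raw", n_splits = 40,
                            target = 0.95, seed = 3)
  expect_gte(attr(prof, "calibrated_rate"), 0.95)
  expect_gte(attr(prof, "calibrated_rate"),
             attr(prof, "raw_rate"))
})

test_that("power tables hit the runnability floor under a zero-error profile", {
  prof <- build_error_profile(flat_band_ensemble(band = 0), measure = "raw")
  tab <- power_table(c(1e3, 1e4), c(1.1, 1.5, 2), prof)
  for (ci in 1:2) {
    D <- c(1e3, 1e4)[ci]
    floor_S <- recondiv:::runnability_floor(D)
    expect_true(all(tab[, ci] == floor_S))
  }
})

test_that("power tables are monotone in fold-difference and diversity", {
  prof <- build_error_profile(flat_band_ensemble(band = 0.08),
                              measure = "raw")
  tab <- power_table(c(1e3, 1e4, 1e5), c(1.2, 1.5, 2, 5), prof)
  for (ci in seq_len(ncol(tab)))
    expect_true(all(diff(tab[, ci]) <= 0))   # larger fold, fewer cells
  for (ri in seq_len(nrow(tab)))
    expect_true(all(diff(tab[ri, ]) >= 0))   # more clones, more cells
})
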