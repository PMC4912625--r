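#' Build an error profile from a calibration ensemble
#'
#' At each coverage bin the profile stores the absolute value of the
#' proportional error of the worst fit, `max |estimate - true| / true`.
#' The band is symmetric: the same proportional band applies above and
#' below a candidate true diversity. After binning, the band is
#' regularized to be non-increasing in coverage (more cells per clone can
#' only tighten the worst case). Ensemble rows with `|proportional error|`
#' greater than `outlier_cut` are excluded and counted in attribute
#' `n_outliers`.
#'
#' @param ensemble data frame with columns `true_q0` (or `true`),
#'   `coverage`, and an estimate column; typically the output of
#'   [run_validation_sweep()].
#' @param measure which diversity measure the profile describes: `"q0"`,
#'   `"q1"`, `"q2"` or `"qinf"` (column `est_<measure>` / `true_<measure>`),
#'   or the names of explicit columns via `true_col` / `est_col`.
#' @param bins_per_decade number of coverage bins per decade (default 2).
#' @param outlier_cut exclude rows with proportional error above this
#'   (default 10).
#' @param upper_adjustment fractional inflation applied to the upper error
#'   bar at lookup time (default 0; set by [calibrate_profile()]).
#' @return an object of class `error_profile`: data frame of `coverage`
#'   (bin geometric mean) and `band` (worst-case proportional error), with
#'   attributes `measure`, `upper_adjustment`, `n_outliers`, `n_used`.
#' @export
build_error_profile <- function(ensemble, measure = "q0",
                                bins_per_decade = 2, outlier_cut = 10,
                                upper_adjustment = 0) {
  true_col <- if (measure %in% c("q0", "q1", "q2", "qinf"))
    paste0("true_", measure) else "true"
  est_col <- if (measure %in% c("q0", "q1", "q2", "qinf"))
    paste0("est_", measure) else "estimate"
  stopifnot(all(c(true_col, est_col, "coverage") %in% names(ensemble)))
  df <- ensemble[is.finite(ensemble[[true_col]]) &
                   is.finite(ensemble[[est_col]]) &
                   is.finite(ensemble$coverage), , drop = FALSE]
  if (nrow(df) == 0) stop("empty ensemble")
  err <- abs(df[[est_col]] - df[[true_col]]) / df[[true_col]]
  out <- err > outlier_cut
  df <- df[!out, , drop = FALSE]
  err <- err[!out]
  if (nrow(df) == 0) stop("all ensemble rows are outliers")
  bin <- round(log10(df$coverage) * bins_per_decade)
  cov_bin <- as.numeric(tapply(log10(df$coverage), bin, mean))
  band <- as.numeric(tapply(err, bin, max))
  o <- order(cov_bin)
  cov_bin <- 10^cov_bin[o]
  band <- band[o]
  # monotone regularization: worst-case error never grows with coverage
  band <- rev(cummax(rev(band)))
  if (length(cov_bin) < 2) stop("need results at >= 2 coverage levels")
  prof <- data.frame(coverage = cov_bin, band = band)
  structure(prof,
            class = c("error_profile", "data.frame"),
            measure = measure,
            upper_adjustment = upper_adjustment,
            n_outliers = sum(out),
            n_used = nrow(df))
}

#' Look up the proportional error band at a coverage
#'
#' Interpolates the profile linearly in (log coverage, log band), with flat
#' extrapolation beyond the tabulated coverage range (attribute
#' `extrapolated` flags this).
#'
#' @param profile an [build_error_profile()] result.
#' @param coverage coverage value(s) at which to evaluate the band.
#' @return proportional band value(s) with attribute `extrapolated`.
#' @export
profile_band <- function(profile, coverage) {
  stopifnot(inherits(profile, "error_profile"), all(coverage > 0))
  lc <- log(profile$coverage)
  b <- profile$band
  extrap <- coverage < min(profile$coverage) | coverage > max(profile$coverage)
  out <- if (any(b <= 0)) {
    stats::approx(lc, b, xout = log(coverage), rule = 2)$y
  } else {
    exp(stats::approx(lc, log(b), xout = log(coverage), rule = 2)$y)
  }
  attr(out, "extrapolated") <- extrap
  out
}

#' Error bars for a diversity estimate
#'
#' Inverts the error profile: the upper bar is the largest true diversity
#' `d` whose lower band edge `d (1 - band)` reaches down to the estimate,
#' and the lower bar the smallest `d` whose upper edge `d (1 + band)`
#' reaches up to it. Because the band is indexed by coverage
#' `sample_cells / d`, which itself depends on the candidate `d`, each
#' bound is solved self-consistently (by root finding in `d`). The upper
#' bar is finally inflated by the profile's calibrated `upper_adjustment`.
#'
#' @param estimate the diversity estimate (effective clones).
#' @param sample_cells number of cells in the sample the estimate came
#'   from.
#' @param profile an [build_error_profile()] result.
#' @return `c(lower, upper)` with attribute `extrapolated` if the solved
#'   coverages fall outside the profile's support.
#' @export
error_bars <- function(estimate, sample_cells, profile) {
  stopifnot(estimate > 0, sample_cells > 0,
            inherits(profile, "error_profile"))
  band_at <- function(d) pmin(profile_band(profile, sample_cells / d), 0.999)
  # upper bar: d (1 - band(S/d)) = estimate, d >= estimate
  f_up <- function(d) d * (1 - band_at(d)) - estimate
  d_up <- tryCatch(
    stats::uniroot(f_up, lower = estimate, upper = estimate * 1e6,
                   extendInt = "upX", tol = estimate * 1e-8)$root,
    error = function(e) estimate / (1 - band_at(estimate)))
  # lower bar: d (1 + band(S/d)) = estimate, d <= estimate
  f_lo <- function(d) d * (1 + band_at(d)) - estimate
  d_lo <- tryCatch(
    stats::uniroot(f_lo, lower = estimate * 1e-6, upper = estimate,
                   tol = estimate * 1e-8)$root,
    error = function(e) estimate / (1 + band_at(estimate)))
  adj <- attr(profile, "upper_adjustment")
  out <- c(lower = d_lo, upper = d_up * (1 + adj))
  ext_lo <- attr(profile_band(profile, sample_cells / d_lo), "extrapolated")
  ext_up <- attr(profile_band(profile, sample_cells / d_up), "extrapolated")
  attr(out, "extrapolated") <- isTRUE(ext_lo) || isTRUE(ext_up)
  out
}

#' Calibrate an error profile to a target bracketing rate
#'
#' Monte-Carlo cross-validation: the ensemble is randomly partitioned into
#' reference and validation sets `n_splits` times; each time, a profile is
#' built from the reference set and its error bars are checked against the
#' validation rows' true diversities. The smallest upper-bar inflation (in
#' 0.1% steps) whose mean bracketing rate reaches `target` is stored in the
#' returned profile.
#'
#' @param ensemble as in [build_error_profile()] (needs >= 20 usable rows).
#' @param measure diversity measure, as in [build_error_profile()].
#' @param n_splits number of random partitions (default 100).
#' @param train_fraction fraction assigned to the reference set (default
#'   0.7).
#' @param target desired bracketing rate (default 0.95).
#' @param max_adjustment largest inflation searched (default 0.5).
#' @param seed integer seed for the random partitions.
#' @return the profile built from the full ensemble with the calibrated
#'   `upper_adjustment`; attributes `raw_rate`, `raw_rate_sd`,
#'   `calibrated_rate`, `calibrated_rate_sd` report the cross-validated
#'   bracketing rates before and after adjustment.
#' @export
calibrate_profile <- function(ensemble, measure = "q0", n_splits = 100,
                              train_fraction = 0.7, target = 0.95,
                              max_adjustment = 0.5, seed = 1L) {
  true_col <- if (measure %in% c("q0", "q1", "q2", "qinf"))
    paste0("true_", measure) else "true"
  est_col <- if (measure %in% c("q0", "q1", "q2", "qinf"))
    paste0("est_", measure) else "estimate"
  df <- ensemble[is.finite(ensemble[[true_col]]) &
                   is.finite(ensemble[[est_col]]), , drop = FALSE]
  if (nrow(df) < 20) stop("ensemble too small to calibrate (need >= 20 rows)")
  set.seed(as.integer(seed))
  n <- nrow(df)
  n_train <- max(2, round(train_fraction * n))
  lo <- up <- tr <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    idx <- sample.int(n, n_train)
    train <- df[idx, , drop = FALSE]
    valid <- df[-idx, , drop = FALSE]
    prof <- tryCatch(build_error_profile(train, measure = measure),
                     error = function(e) NULL)
    if (is.null(prof) || nrow(valid) == 0) next
    bars <- t(vapply(seq_len(nrow(valid)), function(i) {
      error_bars(valid[[est_col]][i],
                 valid$sample_cells[i], prof)
    }, numeric(2)))
    lo[[s]] <- bars[, 1]
    up[[s]] <- bars[, 2]
    tr[[s]] <- valid[[true_col]]
  }
  keep <- !vapply(lo, is.null, logical(1))
  if (!any(keep)) stop("calibration failed on every split")
  lo <- lo[keep]; up <- up[keep]; tr <- tr[keep]
  rate_at <- function(adj) {
    vapply(seq_along(lo), function(s)
      mean(tr[[s]] >= lo[[s]] & tr[[s]] <= up[[s]] * (1 + adj)), numeric(1))
  }
  raw <- rate_at(0)
  adj_grid <- seq(0, max_adjustment, by = 0.001)
  rates <- vapply(adj_grid, function(a) mean(rate_at(a)), numeric(1))
  hit <- which(rates >= target)
  if (length(hit) == 0) {
    warning("target bracketing rate ", target,
            " unreachable; best achievable ", signif(max(rates), 3))
    adj <- adj_grid[which.max(rates)]
  } else adj <- adj_grid[hit[1]]
  final_rate <- rate_at(adj)
  prof <- build_error_profile(df, measure = measure, upper_adjustment = adj)
  attr(prof, "raw_rate") <- mean(raw)
  attr(prof, "raw_rate_sd") <- stats::sd(raw)
  attr(prof, "calibrated_rate") <- mean(final_rate)
  attr(prof, "calibrated_rate_sd") <- stats::sd(final_rate)
  attr(prof, "n_splits") <- length(lo)
  prof
}

# Smallest sample size at which the fit is expected to be runnable: under a
# uniform parent of D clones sampled at S cells, the expected number of
# doubleton clones D * dpois(2, S/D) must reach `min_doublets`.
runnability_floor <- function(D, min_doublets = 10) {
  f <- function(S) D * stats::dpois(2, S / D) - min_doublets
  if (f(2 * D) < 0) return(NA_real_)  # never runnable at this D
  ceiling(stats::uniroot(f, lower = 1e-6, upper = 2 * D,
                         tol = 0.5)$root)
}

#' Power table: minimum cells to detect a fold-difference in diversity
#'
#' For each overall species richness `D` (columns) and fold-difference
#' threshold `f` (rows), finds by binary search the smallest sample size
#' `S` such that the calibrated error bars around estimates of `D` and
#' `f * D` (at coverages `S/D` and `S/(f D)`) do not overlap - the
#' condition for rejecting, at the profile's confidence level, the null
#' hypothesis that the two samples came from the same overall repertoire.
#' A runnability floor is also enforced: below it the sample is expected to
#' contain too few non-singleton clones for the reconstruction to run. The
#' cell counts refer to cells in small clones only (cells in clones above
#' the large-clone threshold are excluded from the requirement).
#'
#' @param diversities vector of overall species-richness levels (> 0).
#' @param fold_thresholds vector of detectable fold-differences (> 1).
#' @param profile a calibrated error profile ([calibrate_profile()]).
#' @param alpha nominal significance level documented for the table
#'   (default 0.05, matching a 95% profile).
#' @param min_doublets runnability floor: required expected doubletons
#'   (default 10).
#' @param max_cells search ceiling (default 1e9).
#' @return matrix of minimum cell counts, rows = fold thresholds, columns =
#'   diversities; `NA` marks unattainable cells; class `power_table`.
#' @export
power_table <- function(diversities, fold_thresholds, profile,
                        alpha = 0.05, min_doublets = 10,
                        max_cells = 1e9) {
  stopifnot(all(diversities > 0), all(fold_thresholds > 1),
            inherits(profile, "error_profile"))
  distinguishable <- function(D, f, S) {
    b1 <- error_bars(D, S, profile)
    b2 <- error_bars(f * D, S, profile)
    b1[["upper"]] < b2[["lower"]]
  }
  tab <- matrix(NA_real_, nrow = length(fold_thresholds),
                ncol = length(diversities),
                dimnames = list(format(fold_thresholds, trim = TRUE),
                                format(diversities, trim = TRUE,
                                       scientific = FALSE, big.mark = ",")))
  for (ci in seq_along(diversities)) {
    D <- diversities[ci]
    floor_S <- runnability_floor(D, min_doublets)
    if (is.na(floor_S)) next
    for (ri in seq_along(fold_thresholds)) {
      f <- fold_thresholds[ri]
      if (!distinguishable(D, f, max_cells)) next  # unattainable
      lo <- floor_S
      if (distinguishable(D, f, lo)) { tab[ri, ci] <- lo; next }
      hi <- max_cells
      while (hi - lo > max(1, lo * 1e-4)) {
        mid <- floor((lo + hi) / 2)
        if (distinguishable(D, f, mid)) hi <- mid else lo <- mid
      }
      tab[ri, ci] <- hi
    }
  }
  structure(tab, class = c("power_table", "matrix"),
            alpha = alpha, min_doublets = min_doublets)
}

#' @export
print.power_table <- function(x, ...) {
  cat("Minimum cells (in small clones) per sample to detect a",
      "fold-difference\nin overall species richness;",
      sprintf("alpha = %.3g\n", attr(x, "alpha")))
  print(unclass(x))
  invisible(x)
}
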