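#' Algorithm configuration for repertoire reconstruction
#'
#' @param large_clone_threshold clones contributing more than this many
#'   cells to the sample are counted directly instead of being fitted by
#'   EM (default 30). For such clones the sampling error is already small,
#'   so exempting them from the fit changes results negligibly while
#'   speeding the fit up greatly. May be `Inf` to fit every clone.
#' @param noise_sd_multiplier a new mixture component is rejected unless
#'   the expected number of observed clones it contributes exceeds this
#'   many Poisson standard deviations (default 3).
#' @param n_scan_starts number of deterministic EM starting points scanned
#'   per component count (default 56).
#' @param em_tolerance relative log-likelihood change below which the inner
#'   EM stops (default 1e-8).
#' @param max_em_iterations cap on inner EM iterations (default 500).
#' @param max_alternations cap on EM / missing-species alternations
#'   (default 50).
#' @param max_components largest mixture size attempted (default 12).
#' @return a list of class `algo_config`.
#' @export
algo_config <- function(large_clone_threshold = 30,
                        noise_sd_multiplier = 3,
                        n_scan_starts = 56,
                        em_tolerance = 1e-8,
                        max_em_iterations = 500,
                        max_alternations = 50,
                        max_components = 12) {
  stopifnot(large_clone_threshold >= 1,
            noise_sd_multiplier >= 0,
            n_scan_starts >= 1,
            em_tolerance > 0,
            max_em_iterations >= 1,
            max_components >= 1, max_components <= 60)
  structure(list(large_clone_threshold = large_clone_threshold,
                 noise_sd_multiplier = noise_sd_multiplier,
                 n_scan_starts = n_scan_starts,
                 em_tolerance = em_tolerance,
                 max_em_iterations = max_em_iterations,
                 max_alternations = max_alternations,
                 max_components = max_components),
            class = "algo_config")
}

#' Fitted parent mixture
#'
#' The reconstructed overall repertoire: `D_total` clones distributed over
#' components `(w_j, m_j)`, where `w_j` is the fraction of parent clones in
#' component `j` and `m_j` the mean number of cells such a clone contributes
#' to the sample, plus (optionally) directly counted large clones.
#'
#' @param w component weights (fractions of parent clones); must sum to 1.
#' @param m component means (cells contributed to the sample); all > 0.
#' @param D_total estimated total number of parent clones behind the fitted
#'   (small-clone) spectrum, observed plus missing.
#' @param missing estimated number of unobserved clones.
#' @param large_clones data frame `size`, `count` of directly counted
#'   clones, or `NULL`.
#' @param scale optional [repertoire_scale()].
#' @param loglik conditional log-likelihood of the fit, if known.
#' @return an object of class `parent_mixture`.
#' @export
parent_mixture <- function(w, m, D_total = NA_real_, missing = NA_real_,
                           large_clones = NULL, scale = NULL,
                           loglik = NA_real_) {
  mix <- structure(list(w = as.numeric(w), m = as.numeric(m),
                        D_total = as.numeric(D_total),
                        missing = as.numeric(missing),
                        large_clones = large_clones, scale = scale,
                        loglik = loglik),
                   class = "parent_mixture")
  validate_mixture(mix, allow_empty = TRUE)
  mix
}

validate_mixture <- function(mix, allow_empty = FALSE) {
  k <- length(mix$w)
  if (k != length(mix$m)) stop("w and m must have equal length")
  if (k == 0) {
    if (!allow_empty) stop("mixture has no components")
    return(invisible(mix))
  }
  if (any(mix$w <= 0)) stop("all component weights must be > 0")
  if (any(mix$m <= 0)) stop("all component means must be > 0")
  if (abs(sum(mix$w) - 1) > 1e-9) stop("component weights must sum to 1")
  invisible(mix)
}

#' @export
print.parent_mixture <- function(x, ...) {
  cat(sprintf("Parent mixture: %d component(s), D_total = %.4g (missing %.4g)\n",
              length(x$w), x$D_total, x$missing))
  if (length(x$w) > 0) {
    df <- data.frame(weight = signif(x$w, 4), mean_cells = signif(x$m, 4))
    print(df, row.names = FALSE)
  }
  nl <- if (is.null(x$large_clones)) 0 else sum(x$large_clones$count)
  if (nl > 0) cat(sprintf("+ %d directly counted large clone(s)\n", nl))
  invisible(x)
}

mixture_p <- function(mix, sizes) {
  vapply(sizes, function(i) sum(mix$w * stats::dpois(i, mix$m)), numeric(1))
}

#' Conditional log-likelihood of an observed spectrum
#'
#' The multinomial log-likelihood of the observed small-clone spectrum given
#' that each clone was detected at all:
#' \deqn{\ell = \sum_{i \ge 1} n_i \,\ln\frac{P(i)}{1 - P(0)},}
#' with `P(i) = sum_j w_j dpois(i, m_j)`. The unobserved zero class enters
#' the fit separately, through the Horvitz-Thompson alternation.
#'
#' @param mixture a [parent_mixture()].
#' @param observed a [clone_size_distribution()] with sizes >= 1.
#' @return the log-likelihood; `-Inf` if any observed size has zero
#'   probability under the mixture.
#' @export
conditional_loglik <- function(mixture, observed) {
  validate_mixture(mixture)
  obs <- observed[observed$size > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observed clones")
  P0 <- sum(mixture$w * exp(-mixture$m))
  if (P0 >= 1 - 1e-12) stop("no detection probability: P(0) = 1")
  Pi <- mixture_p(mixture, obs$size)
  if (any(Pi <= 0)) return(-Inf)
  sum(obs$count * (log(Pi) - log1p(-P0)))
}

#' Horvitz-Thompson estimate of total and missing clones
#'
#' Inverts the pooled detection probability: with `P(0)` the mixture's
#' probability that a clone contributes no cells to the sample,
#' `D_total = n_observed / (1 - P(0))` and
#' `missing = D_total - n_observed`.
#'
#' @param mixture a [parent_mixture()].
#' @param n_observed number of observed (small) clones.
#' @return list with `D_total` and `missing`.
#' @export
horvitz_thompson_missing <- function(mixture, n_observed) {
  validate_mixture(mixture)
  stopifnot(n_observed >= 0)
  P0 <- sum(mixture$w * exp(-mixture$m))
  if (P0 >= 1 - 1e-12) stop("no detection probability: P(0) = 1")
  D <- n_observed / (1 - P0)
  list(D_total = D, missing = D - n_observed)
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1)/(n - k - 1)`. When comparing mixture
#' fits, the observation count is the number of size classes entering the
#' fit, absences included: sizes 0 through the large-clone threshold, i.e.
#' 31 classes at the default threshold of 30 (the zero class enters via the
#' missing-species step).
#'
#' @param loglik maximized log-likelihood.
#' @param k_params number of free parameters (for a `k`-component mixture,
#'   `2k - 1`: `k` means plus `k` weights minus one constraint).
#' @param n_obs number of observations.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k_params, n_obs) {
  stopifnot(is.finite(k_params), k_params >= 0)
  if (n_obs <= k_params + 1)
    stop("insufficient observations for AICc (need n_obs > k_params + 1)")
  -2 * loglik + 2 * k_params + 2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

# Deterministic EM starting points for a k-component mixture. The budget
# of n_scan_starts (56 by default) is spent on two kinds of start:
# grid starts - log-spaced center means in [0.05, 30] crossed with 4
# weight/spread patterns - and, when an incumbent (k-1)-component fit is
# available, split starts that keep the incumbent's components and seed
# one new component at each of 14 log-spaced candidate means (weight
# 0.15). Split starts let a new component survive in regions the merged
# EM dynamics would otherwise never revisit. For k = 1 the patterns
# collapse and duplicates are dropped. The start built from the observed
# mean (the uniform-parent first iterate) is always appended.
scan_starts <- function(k, config, mean_obs, incumbent = NULL) {
  n <- config$n_scan_starts
  starts <- list()
  split_ok <- !is.null(incumbent) && length(incumbent$w) == k - 1
  n_split <- if (split_ok) min(14, max(0, n - 4)) else 0
  if (split_ok && n_split > 0) {
    pos <- exp(seq(log(0.05), log(30), length.out = n_split))
    for (lam in pos) {
      starts[[length(starts) + 1]] <-
        list(w = c(incumbent$w * 0.85, 0.15), m = c(incumbent$m, lam))
    }
  }
  n_grid <- max(2, n - n_split)
  centers <- exp(seq(log(0.05), log(30),
                     length.out = max(2, ceiling(n_grid / 4))))
  patterns <- list(
    list(spread = 3, wr = 1),     # uniform weights, narrow spread
    list(spread = 8, wr = 1),     # uniform weights, wide spread
    list(spread = 5, wr = 0.25),  # small-mean-heavy weights
    list(spread = 5, wr = 4)      # large-mean-heavy weights
  )
  added <- 0
  for (ce in centers) {
    for (pat in patterns) {
      e <- if (k == 1) 0 else (seq_len(k) - (k + 1) / 2) / ((k - 1) / 2)
      m <- pmin(pmax(ce * pat$spread^e, 1e-4), 1e3)
      w <- pat$wr^(seq_len(k) - 1)
      w <- w / sum(w)
      starts[[length(starts) + 1]] <- list(w = w, m = m)
      added <- added + 1
      if (added >= n_grid) break
    }
    if (added >= n_grid) break
  }
  # always include the observed-mean start (uniform parent, first iterate)
  e <- if (k == 1) 0 else (seq_len(k) - (k + 1) / 2) / ((k - 1) / 2)
  starts[[length(starts) + 1]] <-
    list(w = rep(1 / k, k), m = pmin(pmax(mean_obs * 2^e, 1e-4), 1e3))
  key <- vapply(starts, function(s) paste(signif(c(s$w, s$m), 10),
                                          collapse = ","), character(1))
  starts[!duplicated(key)]
}

# Ranking likelihood for scan results: the conditional log-likelihood plus
# the log multinomial coefficient over the predicted spectrum including the
# size-0 (missing) class, ln[D! / (n_0! prod_i n_i!)]. Makes fits with
# different missing-clone counts comparable by the number of ways the
# spectrum's clones can be chosen.
adjusted_loglik <- function(fitres, observed) {
  obs <- observed[observed$size > 0, , drop = FALSE]
  fitres$loglik +
    lgamma(fitres$D_total + 1) - lgamma(fitres$missing + 1) -
    sum(lgamma(obs$count + 1)) +
    fitres$missing * log(sum(fitres$w * exp(-fitres$m))) +
    sum(obs$count) * log1p(-sum(fitres$w * exp(-fitres$m)))
}

m_floor_for <- function(scale) {
  # discreteness bound: a parent clone has at least 1 cell, so its mean
  # sample contribution is at least S/N when the overall size is known
  if (!is.null(scale) && !is.na(scale$total_cells) && scale$total_cells > 0)
    max(scale$sample_cells / scale$total_cells, 1e-12)
  else
    1e-4
}

#' Fit a Poisson mixture with a fixed number of components
#'
#' Alternates (a) EM maximization of the mixture parameters with the
#' missing-clone count held fixed and (b) a Horvitz-Thompson refresh of the
#' missing-clone count, until the number of missing clones is
#' self-consistent. Components converging to the same mean (within 1e-6)
#' are merged before the fit is returned.
#'
#' @param observed small-clone sample spectrum (sizes >= 1), a
#'   [clone_size_distribution()].
#' @param k number of mixture components.
#' @param start optional starting [parent_mixture()] (or list with `w`,
#'   `m`) with `k` components; default: uniform weights, means spread
#'   around the observed mean clone size.
#' @param config an [algo_config()].
#' @param scale optional [repertoire_scale()]; when the overall cell count
#'   is known it imposes the discreteness floor `m >= S/N` on component
#'   means.
#' @return a [parent_mixture()] with attributes `converged`,
#'   `alternations`; its `loglik` field holds the conditional
#'   log-likelihood.
#' @export
fit_fixed_k <- function(observed, k, start = NULL, config = algo_config(),
                        scale = NULL) {
  stopifnot(k >= 1)
  obs <- observed[observed$size > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observed clones")
  mfl <- m_floor_for(scale)
  if (is.null(start)) {
    mean_obs <- sum(obs$size * obs$count) / sum(obs$count)
    e <- if (k == 1) 0 else (seq_len(k) - (k + 1) / 2) / ((k - 1) / 2)
    start <- list(w = rep(1 / k, k), m = pmax(mean_obs * 2^e, mfl))
  }
  stopifnot(length(start$w) == k, length(start$m) == k)
  res <- em_truncated_mixture(obs$size, obs$count,
                              start$w / sum(start$w),
                              pmax(start$m, mfl),
                              config$em_tolerance,
                              config$max_em_iterations,
                              config$max_alternations,
                              mfl)
  if (!isTRUE(res$ok)) stop("fit failed: ", res$reason)
  w <- res$w; m <- res$m
  # merge components that converged to the same mean
  o <- order(m)
  w <- w[o]; m <- m[o]
  if (k > 1) {
    grp <- cumsum(c(1, diff(m) > 1e-6 * pmax(1, m[-1])))
    if (max(grp) < k) {
      w2 <- as.numeric(tapply(w, grp, sum))
      m2 <- as.numeric(tapply(w * m, grp, sum)) / w2
      w <- w2; m <- m2
    }
  }
  w <- w / sum(w)
  mix <- parent_mixture(w, m, D_total = NA_real_, missing = NA_real_,
                        scale = scale)
  ht <- horvitz_thompson_missing(mix, sum(obs$count))
  mix$D_total <- ht$D_total
  mix$missing <- ht$missing
  mix$loglik <- conditional_loglik(mix, obs)
  if (!isTRUE(res$converged))
    warning("mixture fit did not reach self-consistency within ",
            config$max_alternations, " alternations (k = ", k, ")")
  attr(mix, "converged") <- isTRUE(res$converged)
  attr(mix, "alternations") <- res$alternations
  mix
}

#' Multi-start ("scanning") mixture fit
#'
#' Runs [fit_fixed_k()] from a deterministic grid of starting points (56 by
#' default), plus one additional start at the component-wise average of the
#' two best-ranked fits, and returns the best fit. Ranking uses the
#' conditional log-likelihood adjusted by the number of ways to choose the
#' clones in each predicted spectrum (a multinomial coefficient including
#' the predicted missing-clone class). Ties within 1e-9 are broken in
#' favour of the smaller expected sample mass `sum(w * m)`.
#'
#' @inheritParams fit_fixed_k
#' @param incumbent optional best fit with `k - 1` components; part of the
#'   start budget is then spent splitting a new component off it.
#' @return the best [parent_mixture()]; attribute `scan` holds the ranked
#'   adjusted log-likelihoods of all starts.
#' @export
scan_fit <- function(observed, k, config = algo_config(), scale = NULL,
                     incumbent = NULL) {
  obs <- observed[observed$size > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observed clones")
  mean_obs <- sum(obs$size * obs$count) / sum(obs$count)
  starts <- scan_starts(k, config, mean_obs, incumbent)
  fits <- list()
  lls <- numeric(0)
  for (s in starts) {
    f <- tryCatch(
      suppressWarnings(fit_fixed_k(observed, k, start = s, config = config,
                                   scale = scale)),
      error = function(e) NULL)
    if (is.null(f)) next
    fits[[length(fits) + 1]] <- f
    lls[length(lls) + 1] <- adjusted_loglik(f, obs)
  }
  if (length(fits) == 0)
    stop("all ", length(starts), " scanning starts failed for k = ", k)
  # one extra fit from the average of the two top-ranked results,
  # components matched by rank of m
  if (length(fits) >= 2) {
    top <- order(lls, decreasing = TRUE)[1:2]
    a <- fits[[top[1]]]; b <- fits[[top[2]]]
    if (length(a$w) == length(b$w)) {
      oa <- order(a$m); ob <- order(b$m)
      w_avg <- (a$w[oa] + b$w[ob]) / 2
      m_avg <- (a$m[oa] + b$m[ob]) / 2
      kk <- length(w_avg)
      if (kk < k) {  # merged fits: pad back to k by splitting the largest
        pad <- k - kk
        w_avg <- c(w_avg, rep(w_avg[kk] / 2, pad))
        w_avg[kk] <- w_avg[kk] / 2
        m_avg <- c(m_avg, m_avg[kk] * 1.5^seq_len(pad))
      }
      f <- tryCatch(
        suppressWarnings(fit_fixed_k(observed, k,
                                     start = list(w = w_avg / sum(w_avg),
                                                  m = m_avg),
                                     config = config, scale = scale)),
        error = function(e) NULL)
      if (!is.null(f)) {
        fits[[length(fits) + 1]] <- f
        lls[length(lls) + 1] <- adjusted_loglik(f, obs)
      }
    }
  }
  best <- which(lls >= max(lls) - 1e-9)
  if (length(best) > 1) {
    kk <- vapply(fits[best], function(f) length(f$w), numeric(1))
    mass <- vapply(fits[best], function(f) sum(f$w * f$m), numeric(1))
    best <- best[order(kk, mass)][1]
  } else best <- best[1]
  out <- fits[[best]]
  attr(out, "scan") <- sort(lls, decreasing = TRUE)
  attr(out, "adjusted_loglik") <- lls[best]
  out
}

#' Sampling-noise guard for a candidate extra component
#'
#' A candidate fit with one more component than the incumbent is accepted
#' only if its new component stands above sampling noise. Two checks are
#' applied. First, the expected number of observed clones attributable to
#' the new component, `E = D_total * w_new * (1 - exp(-m_new))`, must
#' exceed `noise_sd_multiplier * sqrt(E)` (the Poisson standard deviation
#' of that expectation). Second, when the new component posits clones that
#' are mostly unobservable (`m_new < 1` cell in the sample) - the regime in
#' which likelihood methods can inflate diversity without bound by adding
#' ever more small clones - the candidate must also move the expected
#' sample spectrum by more than `noise_sd_multiplier` Poisson standard
#' deviations in at least one size class:
#' `max_i |E_i(cand) - E_i(inc)| / sqrt(E_i(inc))` over the small-clone
#' window. A small component whose only observable effect is a
#' within-noise reshuffle of singleton and doubleton counts is rejected,
#' however much it raises the likelihood. The new component is identified
#' as the candidate component farthest (in log mean) from every incumbent
#' component.
#'
#' @param candidate the larger [parent_mixture()].
#' @param incumbent the current [parent_mixture()] (may be `NULL`).
#' @param config an [algo_config()].
#' @return `TRUE` or `FALSE`, with attributes `E_new` and `z_spectrum`.
#' @export
passes_noise_threshold <- function(candidate, incumbent,
                                   config = algo_config()) {
  validate_mixture(candidate)
  mult <- config$noise_sd_multiplier
  if (is.null(incumbent) || length(incumbent$w) == 0) {
    j <- which.min(candidate$w)
  } else {
    d <- vapply(candidate$m, function(mm)
      min(abs(log(mm) - log(incumbent$m))), numeric(1))
    j <- which.max(d)
  }
  E_new <- candidate$D_total * candidate$w[j] * (1 - exp(-candidate$m[j]))
  z <- NA_real_
  ok <- if (mult == 0) TRUE else E_new > mult * sqrt(E_new)
  if (ok && mult > 0 && candidate$m[j] < 1 &&
      !is.null(incumbent) && length(incumbent$w) > 0 &&
      is.finite(incumbent$D_total)) {
    sizes <- seq_len(min(config$large_clone_threshold, 30))
    Ei <- incumbent$D_total * mixture_p(incumbent, sizes)
    Ec <- candidate$D_total * mixture_p(candidate, sizes)
    z <- max(abs(Ec - Ei) / sqrt(pmax(Ei, 1)))
    ok <- z > mult
  }
  attr(ok, "E_new") <- E_new
  attr(ok, "z_spectrum") <- z
  ok
}

#' Reconstruct the overall repertoire from a sample spectrum
#'
#' The full estimation pipeline. The observed spectrum is split at the
#' large-clone threshold: clones contributing more cells than the threshold
#' have small sampling error and are counted directly, while the small-clone
#' spectrum is fitted by a scanned, zero-truncated Poisson-mixture EM with
#' Horvitz-Thompson missing-species estimation. Components are added one at
#' a time; a larger mixture is kept only if it lowers the AICc and its new
#' component passes the sampling-noise guard. The reconstructed parent then
#' yields overall Hill diversities, the number of missing clones, the
#' minimum detected clone size, and (when an error profile is supplied)
#' error bars and the species-richness upper bound U.
#'
#' @param observed the sample spectrum, a [clone_size_distribution()]
#'   (sizes >= 1).
#' @param scale a [repertoire_scale()]; when `NULL`, the realized sample
#'   cell count of `observed` is used for S and the overall cell count N is
#'   treated as unknown (the minimum detected clone size and U are then
#'   omitted).
#' @param config an [algo_config()].
#' @param seed integer seed controlling the attached resampled spectrum.
#' @param profile optional calibrated [build_error_profile()] output used
#'   to attach error bars and the upper bound U.
#' @param orders Hill orders to report (default `c(0, 1, 2, Inf)`).
#' @return an object of class `recon_fit`; see [write_report()] for the
#'   serialized field list.
#' @export
reconstruct <- function(observed, scale = NULL, config = algo_config(),
                        seed = 1L, profile = NULL,
                        orders = c(0, 1, 2, Inf)) {
  stopifnot(inherits(observed, "clone_size_distribution"))
  obs <- observed[observed$size > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observed clones")
  if (is.null(scale))
    scale <- repertoire_scale(sample_cells = total_cells(observed))
  thr <- config$large_clone_threshold
  small <- obs[obs$size <= thr, , drop = FALSE]
  large <- obs[obs$size > thr, , drop = FALSE]
  n_large <- sum(large$count)
  n_small_clones <- sum(small$count)
  small_cells <- sum(small$size * small$count)
  low_confidence <- FALSE
  trajectory <- list()

  if (n_small_clones == 0) {
    # nothing to fit: every clone is directly counted
    mix <- parent_mixture(numeric(0), numeric(0), D_total = 0, missing = 0,
                          large_clones = large, scale = scale)
    k_best <- 0L
    ll <- NA_real_
    aicc_best <- NA_real_
  } else {
    if (small_cells < 5)
      stop("too few cells in small clones (", small_cells,
           ") for reconstruction; analyse more cells")
    if (all(small$size == 1)) {
      low_confidence <- TRUE
      warning("small-clone spectrum is all singletons; ",
              "missing-species estimate is unreliable")
    }
    small_csd <- clone_size_distribution(small$size, small$count)
    n_aicc <- min(thr, 30) + 1  # size classes 0..threshold, absences included
    inc <- scan_fit(small_csd, 1, config = config, scale = scale)
    inc_aicc <- aicc(inc$loglik, 1, n_aicc)
    trajectory[[1]] <- list(k = 1, loglik = inc$loglik, aicc = inc_aicc,
                            accepted = TRUE, noise_pass = NA)
    k <- 1
    while (k < config$max_components) {
      cand <- tryCatch(
        suppressWarnings(scan_fit(small_csd, k + 1, config = config,
                                  scale = scale, incumbent = inc)),
        error = function(e) NULL)
      if (is.null(cand)) break
      k_eff <- length(cand$w)
      cand_aicc <- aicc(cand$loglik, 2 * k_eff - 1, n_aicc)
      np <- passes_noise_threshold(cand, inc, config)
      accept <- k_eff > length(inc$w) && cand_aicc < inc_aicc && isTRUE(np)
      trajectory[[length(trajectory) + 1]] <-
        list(k = k + 1, loglik = cand$loglik, aicc = cand_aicc,
             accepted = accept, noise_pass = isTRUE(np))
      if (!accept) break
      inc <- cand
      inc_aicc <- cand_aicc
      k <- k + 1
    }
    mix <- inc
    mix$large_clones <- large
    mix$scale <- scale
    k_best <- length(mix$w)
    ll <- mix$loglik
    aicc_best <- inc_aicc
  }

  # boundedness: clones cannot outnumber cells in the overall repertoire
  capped <- FALSE
  if (!is.na(scale$total_cells) && length(mix$w) > 0 &&
      mix$D_total + n_large > scale$total_cells) {
    mix$D_total <- scale$total_cells - n_large
    mix$missing <- mix$D_total - n_small_clones
    capped <- TRUE
    low_confidence <- TRUE
    warning("estimate capped at the overall cell count N")
  }

  div_sample <- diversity_profile(observed, orders)
  div_overall <- overall_diversity(mix, orders)
  mdcs <- NA_real_
  if (length(mix$m) > 0) {
    if (!is.na(scale$total_cells)) {
      mdcs <- min_detected_clone_size(mix, scale)
    } else {
      warning("overall cell count N unknown; minimum detected clone size ",
              "and upper bound U omitted")
    }
  }

  fit <- structure(list(
    mixture = mix,
    k = k_best,
    n_observed_clones = sum(obs$count),
    n_large_clones = n_large,
    diversity_sample = div_sample,
    diversity_overall = div_overall,
    missing = if (length(mix$w) > 0) mix$missing else 0,
    missing_bounds = c(NA_real_, NA_real_),
    diversity_bounds = NULL,
    min_detected_clone_size = mdcs,
    upper_bound_U = NA_real_,
    upper_bound_U_with_detected = NA_real_,
    log_likelihood = ll,
    aicc = aicc_best,
    trajectory = trajectory,
    low_confidence = low_confidence,
    capped = capped,
    seed = as.integer(seed),
    config = config,
    scale = scale
  ), class = "recon_fit")

  if (!is.null(profile)) {
    eb <- error_bars(div_overall[["0"]], scale$sample_cells, profile)
    fit$diversity_bounds <- list(q0 = c(lower = eb[1], upper = eb[2]))
    fit$missing_bounds <- pmax(eb - sum(obs$count), 0)
    if (!is.na(mdcs)) {
      U <- upper_bound_U(fit, R_max = eb[2], scale = scale)
      fit$upper_bound_U <- U
      fit$upper_bound_U_with_detected <- attr(U, "with_detected")
    }
  }
  fit$resampled_spectrum <- resample_from_fit(mix, seed = seed)
  fit
}

#' @export
print.recon_fit <- function(x, ...) {
  cat("Repertoire reconstruction\n")
  cat(sprintf("  observed clones: %s (of which %s counted directly)\n",
              format(x$n_observed_clones, big.mark = ","),
              format(x$n_large_clones, big.mark = ",")))
  cat(sprintf("  mixture components: %d; missing clones: %.4g\n",
              x$k, x$missing))
  cat("  overall diversity (effective clones):\n")
  for (nm in names(x$diversity_overall))
    cat(sprintf("    q=%s: %.6g (sample: %.6g)\n", nm,
                x$diversity_overall[[nm]], x$diversity_sample[[nm]]))
  if (!is.na(x$min_detected_clone_size))
    cat(sprintf("  minimum detected clone size: %.4g cells\n",
                x$min_detected_clone_size))
  if (!is.na(x$upper_bound_U))
    cat(sprintf("  upper bound U: %.4g clones\n", x$upper_bound_U))
  if (x$low_confidence) cat("  [low-confidence fit]\n")
  invisible(x)
}

# Hill diversities of the reconstructed overall repertoire: D_total * w_j
# clones with relative mass m_j each, plus large clones at their observed
# sample sizes (the same sample-cell unit).
overall_diversity <- function(mix, orders = c(0, 1, 2, Inf)) {
  sizes <- mix$m
  counts <- if (length(mix$w) > 0) mix$D_total * mix$w else numeric(0)
  if (!is.null(mix$large_clones) && nrow(mix$large_clones) > 0) {
    sizes <- c(sizes, mix$large_clones$size)
    counts <- c(counts, mix$large_clones$count)
  }
  if (length(sizes) == 0) stop("empty mixture: nothing to measure")
  tot <- sum(sizes * counts)
  p <- sizes / tot
  out <- vapply(orders, function(q) {
    if (q == 0) sum(counts) else hill_from_groups(p, counts, q)
  }, numeric(1))
  names(out) <- ifelse(is.infinite(orders), "inf", format(orders, trim = TRUE))
  out
}

#' Minimum detected clone size
#'
#' The smallest fitted component mean `m_min` is the mean number of cells
#' that the smallest detectable parent clone contributes to the sample;
#' scaled to the overall repertoire it corresponds to `m_min * N / S`
#' cells. Clones smaller than this contribute essentially no cells to the
#' sample and are invisible to the fit.
#'
#' @param mixture a fitted [parent_mixture()].
#' @param scale a [repertoire_scale()] with known `total_cells`.
#' @return clone size in cells of the overall repertoire.
#' @export
min_detected_clone_size <- function(mixture, scale) {
  stopifnot(inherits(mixture, "parent_mixture"),
            inherits(scale, "repertoire_scale"))
  if (length(mixture$m) == 0) stop("mixture has no fitted components")
  if (is.na(scale$total_cells) || scale$sample_cells <= 0) {
    warning("N or S unknown; minimum detected clone size omitted")
    return(NA_real_)
  }
  min(mixture$m) * scale$total_cells / scale$sample_cells
}

#' Upper bound U on overall species richness
#'
#' Accounts for clones that may be "hiding" below the minimum detected
#' clone size by assuming all cells in clones that could be smaller are
#' singlets: `U = R_max * w_m * m_min * N / S`, where `R_max` is the upper
#' error bar of the species-richness estimate and `(w_m, m_min)` the weight
#' and mean of the smallest fitted component. The variant that adds back
#' the detected richness, `U + R_max`, is attached as attribute
#' `with_detected`.
#'
#' @param fit a `recon_fit` (or [parent_mixture()]).
#' @param R_max upper error bar of the overall species-richness estimate.
#' @param scale a [repertoire_scale()] with known `total_cells`.
#' @return the clone-count bound, with attribute `with_detected`.
#' @export
upper_bound_U <- function(fit, R_max, scale) {
  if (is.na(R_max)) stop("R_max (upper error bar) is required for U")
  mix <- if (inherits(fit, "recon_fit")) fit$mixture else fit
  stopifnot(inherits(mix, "parent_mixture"))
  if (length(mix$m) == 0) stop("mixture has no fitted components")
  if (is.na(scale$total_cells)) stop("overall cell count N required for U")
  j <- which.min(mix$m)
  U <- R_max * mix$w[j] * mix$m[j] * scale$total_cells / scale$sample_cells
  attr(U, "with_detected") <- U + R_max
  U
}
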