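#' Specification of a synthetic gold-standard parent repertoire
#'
#' Describes one of three families of biologically plausible overall
#' clone-size distributions used for validation and calibration:
#' exponential, `f(x) proportional to exp(-s x)` over integer clone sizes
#' `x` (steep `s = 0.2` to nearly flat `s = 0.02`); reciprocal-exponential,
#' `f(x) proportional to exp(-s x) / x`; and bimodal, two clone-size groups
#' whose mean sizes differ by `size_ratio` (typically 20-30x). Clone sizes
#' are rescaled so the repertoire holds about `N` cells in total.
#'
#' @param family one of `"exponential"`, `"reciprocal_exponential"`,
#'   `"bimodal"`.
#' @param s steepness of the exponential families (> 0).
#' @param size_ratio mean large/small size multiple for the bimodal family
#'   (> 1).
#' @param D number of clones in the parent (>= 1).
#' @param N total cells in the parent (default 1e9); must be >= `D`.
#' @return a list of class `parent_spec`.
#' @export
parent_spec <- function(family = c("exponential", "reciprocal_exponential",
                                   "bimodal"),
                        s = 0.05, size_ratio = 25, D = 1e4, N = 1e9) {
  family <- match.arg(family)
  if (family != "bimodal" && s <= 0) stop("s must be > 0")
  if (family == "bimodal" && size_ratio <= 1) stop("size_ratio must be > 1")
  stopifnot(D >= 1, N >= D)
  structure(list(family = family, s = s, size_ratio = size_ratio,
                 D = D, N = N), class = "parent_spec")
}

# Largest-remainder rounding of D * f so clone counts are integers summing
# exactly to D (the generator's species richness is exact by construction).
round_to_total <- function(frac, D) {
  raw <- frac * D
  fl <- floor(raw)
  rem <- D - sum(fl)
  if (rem > 0) {
    o <- order(raw - fl, decreasing = TRUE)
    fl[o[seq_len(rem)]] <- fl[o[seq_len(rem)]] + 1
  }
  fl
}

#' Generate a gold-standard parent repertoire
#'
#' @param spec a [parent_spec()].
#' @return a [clone_size_distribution()] with exactly `spec$D` clones and
#'   close to `spec$N` cells; attributes `spec` and `cells` record the
#'   generating specification and realized cell count.
#' @export
make_parent <- function(spec) {
  stopifnot(inherits(spec, "parent_spec"))
  D <- spec$D
  if (spec$family %in% c("exponential", "reciprocal_exponential")) {
    s <- spec$s
    xmax <- max(2, ceiling(-log(1e-12) / s))
    x <- seq_len(xmax)
    f <- exp(-s * x)
    if (spec$family == "reciprocal_exponential") f <- f / x
    f <- f / sum(f)
    counts <- round_to_total(f, D)
    keep <- counts > 0
    x <- x[keep]; counts <- counts[keep]
  } else {
    # two size groups, equal clone counts, mean sizes in ratio size_ratio
    x <- c(1, round(spec$size_ratio))
    counts <- round_to_total(c(0.5, 0.5), D)
    if (any(counts == 0)) { x <- x[counts > 0]; counts <- counts[counts > 0] }
  }
  mean_size <- sum(x * counts) / D
  u <- max(1, round(spec$N / (D * mean_size)))
  parent <- clone_size_distribution(x * u, counts)
  if (total_cells(parent) < D)
    stop("infeasible (D, N): cannot place ", D, " clones in ", spec$N,
         " cells")
  attr(parent, "spec") <- spec
  attr(parent, "cells") <- total_cells(parent)
  parent
}

#' Specification of simulated experimental noise
#'
#' Three modes of spectrum-level noise emulating experimental error:
#' `"per_count"` perturbs each clone count `n` by a zero-mean Gaussian with
#' standard deviation `sd_scale * sqrt(n)` (super-Poissonian count noise;
#' default scale 1.22); `"baseline"` adds a small zero-mean perturbation of
#' absolute scale `baseline_level` clones to every size class; `"sporadic"`
#' inflates randomly chosen size classes by a 2-10x factor, reminiscent of
#' PCR jackpot effects; `"none"` is the identity. Perturbed counts are
#' rounded and floored at zero.
#'
#' @param mode one of `"per_count"`, `"baseline"`, `"sporadic"`, `"none"`.
#' @param sd_scale per-count noise scale (default 1.22).
#' @param baseline_level baseline noise SD in clones (default 1).
#' @param sporadic_rate per-size-class probability of a jackpot (default
#'   0.05).
#' @param seed optional integer seed.
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(mode = c("per_count", "baseline", "sporadic", "none"),
                       sd_scale = 1.22, baseline_level = 1,
                       sporadic_rate = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(sd_scale >= 0, baseline_level >= 0,
            sporadic_rate >= 0, sporadic_rate <= 1)
  structure(list(mode = mode, sd_scale = sd_scale,
                 baseline_level = baseline_level,
                 sporadic_rate = sporadic_rate, seed = seed),
            class = "noise_spec")
}

#' Apply simulated experimental noise to a spectrum
#'
#' @param spectrum a [clone_size_distribution()].
#' @param noise a [noise_spec()].
#' @return the perturbed [clone_size_distribution()].
#' @export
apply_noise <- function(spectrum, noise) {
  stopifnot(inherits(spectrum, "clone_size_distribution"),
            inherits(noise, "noise_spec"))
  if (noise$mode == "none") return(spectrum)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  n <- spectrum$count
  n2 <- switch(noise$mode,
    per_count = n + stats::rnorm(length(n), 0, noise$sd_scale * sqrt(n)),
    baseline = n + stats::rnorm(length(n), 0, noise$baseline_level),
    sporadic = {
      hit <- stats::runif(length(n)) < noise$sporadic_rate
      n * ifelse(hit, stats::runif(length(n), 2, 10), 1)
    })
  out <- clone_size_distribution(spectrum$size, pmax(0, round(n2)))
  attr(out, "missing") <- attr(spectrum, "missing")
  out
}

#' Chao1 estimate of species richness
#'
#' The classical lower-bound estimator from singleton (`F1`) and doubleton
#' (`F2`) counts: `S_obs + F1^2 / (2 F2)` when `F2 > 0`, otherwise the
#' bias-corrected `S_obs + F1 (F1 - 1) / 2`. Serves as the fast baseline
#' against which the mixture reconstruction is benchmarked.
#'
#' @param spectrum a sample [clone_size_distribution()].
#' @return the species-richness estimate.
#' @export
chao_estimator <- function(spectrum) {
  stopifnot(inherits(spectrum, "clone_size_distribution"))
  obs <- spectrum[spectrum$size > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop("empty spectrum")
  S_obs <- sum(obs$count)
  F1 <- sum(obs$count[obs$size == 1])
  F2 <- sum(obs$count[obs$size == 2])
  if (F2 > 0) S_obs + F1^2 / (2 * F2) else S_obs + F1 * (F1 - 1) / 2
}

#' Run a gold-standard validation sweep
#'
#' For every combination of parent specification, coverage and seed:
#' builds the parent, Poisson-samples `coverage * D` cells, optionally
#' perturbs the sample with noise, runs [reconstruct()] and
#' [chao_estimator()], and records true and estimated diversities. Rows
#' whose reconstruction fails (for example, samples too small to fit) are
#' kept with `ok = FALSE` and `NA` estimates rather than aborting the
#' sweep. The output feeds [build_error_profile()] and
#' [calibrate_profile()].
#'
#' @param specs list of [parent_spec()]s.
#' @param coverages numeric vector of coverages (sample cells per parent
#'   clone).
#' @param noise a [noise_spec()] (default: no noise).
#' @param seeds integer vector of seeds; one run per (spec, coverage, seed).
#' @param config an [algo_config()].
#' @return a data frame with one row per run: parent descriptors, `coverage`,
#'   `seed`, `sample_cells`, observed clone and cell counts, true and
#'   estimated Hill diversities (`true_q0`, `est_q0`, ...), `chao`,
#'   `missing_true`, `missing_est`, `runtime` and `ok`.
#' @export
run_validation_sweep <- function(specs, coverages, noise = noise_spec("none"),
                                 seeds = 1L, config = algo_config()) {
  if (inherits(specs, "parent_spec")) specs <- list(specs)
  stopifnot(length(specs) > 0, length(coverages) > 0, length(seeds) > 0)
  rows <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    parent <- make_parent(spec)
    truth <- diversity_profile(parent)
    for (cov in coverages) {
      S <- max(1, round(cov * spec$D))
      for (sd in seeds) {
        run_seed <- as.integer((si * 1000003 + round(cov * 1e4) * 101 + sd) %%
                                 .Machine$integer.max)
        samp <- suppressWarnings(poisson_sample(parent, S, seed = run_seed))
        if (noise$mode != "none" && n_clones(samp) > 0) {
          nz <- noise
          nz$seed <- run_seed + 1L
          samp <- apply_noise(samp, nz)
        }
        row <- data.frame(
          family = spec$family,
          shape = if (spec$family == "bimodal") spec$size_ratio else spec$s,
          D = spec$D, coverage = cov, seed = sd, sample_cells = S,
          obs_cells = total_cells(samp), obs_clones = n_clones(samp),
          true_q0 = truth[["0"]], true_q1 = truth[["1"]],
          true_q2 = truth[["2"]], true_qinf = truth[["inf"]],
          est_q0 = NA_real_, est_q1 = NA_real_, est_q2 = NA_real_,
          est_qinf = NA_real_, chao = NA_real_,
          missing_true = spec$D - n_clones(samp),
          missing_est = NA_real_, runtime = NA_real_, ok = FALSE)
        stopifnot(n_clones(samp) <= max(1, total_cells(samp)))  # cells bound
        if (n_clones(samp) > 0) {
          row$chao <- chao_estimator(samp)
          t0 <- proc.time()[["elapsed"]]
          fit <- tryCatch(
            suppressWarnings(reconstruct(
              samp,
              scale = repertoire_scale(S, attr(parent, "cells")),
              config = config, seed = run_seed)),
            error = function(e) NULL)
          row$runtime <- proc.time()[["elapsed"]] - t0
          if (!is.null(fit)) {
            row$est_q0 <- fit$diversity_overall[["0"]]
            row$est_q1 <- fit$diversity_overall[["1"]]
            row$est_q2 <- fit$diversity_overall[["2"]]
            row$est_qinf <- fit$diversity_overall[["inf"]]
            row$missing_est <- fit$missing
            row$ok <- TRUE
          }
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
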