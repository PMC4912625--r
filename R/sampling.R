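#' Repertoire scale: sample size, overall size, coverage
#'
#' Bundles the number of cells in the sample (`S`), optionally the number of
#' cells in the overall repertoire (`N`), and, once the number of overall
#' clones is known, the coverage `S / clones`. Coverage of 1x means one
#' sampled cell per clone in the overall repertoire.
#'
#' @param sample_cells number of cells in the sample (S), >= 0.
#' @param total_cells number of cells in the overall repertoire (N), or `NA`
#'   when unknown. Must satisfy `N >= S`.
#' @return an object of class `repertoire_scale` (a list with elements
#'   `sample_cells`, `total_cells`).
#' @export
repertoire_scale <- function(sample_cells, total_cells = NA_real_) {
  stopifnot(length(sample_cells) == 1, is.finite(sample_cells),
            sample_cells >= 0)
  if (!is.na(total_cells)) {
    stopifnot(is.finite(total_cells), total_cells >= sample_cells)
  }
  structure(list(sample_cells = as.numeric(sample_cells),
                 total_cells = as.numeric(total_cells)),
            class = "repertoire_scale")
}

#' Poisson-sample a parent repertoire
#'
#' Each clone of parent frequency `f` contributes `Poisson(f * sample_cells)`
#' cells to the sample, independently of all other clones. This is the
#' sampling model under which the reconstruction operates; it is accurate
#' when the parent is well mixed, much larger than the sample, and not
#' dominated by any single clone (warnings are emitted when the latter two
#' conditions look violated). The realized number of sampled cells is random
#' with mean `sample_cells`.
#'
#' @param parent a [clone_size_distribution()] of the overall repertoire.
#' @param sample_cells target number of cells to sample (S), >= 0.
#' @param seed optional integer seed for reproducibility.
#' @return the sample spectrum as a [clone_size_distribution()] (sizes >= 1),
#'   with attributes `missing` (number of parent clones that contributed 0
#'   cells) and `realized_cells`.
#' @export
poisson_sample <- function(parent, sample_cells, seed = NULL) {
  stopifnot(inherits(parent, "clone_size_distribution"))
  if (sample_cells < 0) stop("sample_cells must be >= 0")
  if (n_clones(parent) == 0) stop("empty parent distribution")
  obs <- parent[parent$size > 0, , drop = FALSE]
  tot <- sum(obs$size * obs$count)
  if (tot < 10 * sample_cells)
    warning("parent has fewer than 10x the sampled cells; ",
            "Poisson sampling model may be inaccurate")
  if (max(obs$size) / tot > 0.30)
    warning("a single clone exceeds 30% of the parent; ",
            "dominant clones should be counted directly")
  if (!is.null(seed)) set.seed(as.integer(seed))
  D <- sum(obs$count)
  if (sample_cells == 0) {
    out <- clone_size_distribution(numeric(0), numeric(0))
    attr(out, "missing") <- D
    attr(out, "realized_cells") <- 0
    return(out)
  }
  lam <- obs$size / tot * sample_cells
  draws <- unlist(lapply(seq_len(nrow(obs)), function(i) {
    stats::rpois(obs$count[i], lam[i])
  }))
  tab <- table(draws[draws > 0])
  out <- clone_size_distribution(as.numeric(names(tab)), as.numeric(tab))
  attr(out, "missing") <- sum(draws == 0)
  attr(out, "realized_cells") <- sum(draws)
  out
}

#' Sample a parent repertoire at an exactly known size
#'
#' Draws a sample of exactly `sample_cells` cells by a multinomial draw over
#' clones with probabilities proportional to clone size (equivalent to
#' sampling cells without replacement when the parent is much larger than
#' the sample). Unlike [poisson_sample()], whose realized size fluctuates
#' around its target, the fixed-size sample obeys the cells bound against
#' the nominal size exactly: a sample of `S` cells can never contain more
#' than `S` clones. Used when a claim concerns samples of known size;
#' reconstruction itself assumes the Poisson model.
#'
#' @inheritParams poisson_sample
#' @return the sample spectrum, with attributes `missing` and
#'   `realized_cells` (always `sample_cells`).
#' @export
multinomial_sample <- function(parent, sample_cells, seed = NULL) {
  stopifnot(inherits(parent, "clone_size_distribution"))
  if (sample_cells < 0) stop("sample_cells must be >= 0")
  if (n_clones(parent) == 0) stop("empty parent distribution")
  obs <- parent[parent$size > 0, , drop = FALSE]
  if (!is.null(seed)) set.seed(as.integer(seed))
  D <- sum(obs$count)
  if (sample_cells == 0) {
    out <- clone_size_distribution(numeric(0), numeric(0))
    attr(out, "missing") <- D
    attr(out, "realized_cells") <- 0
    return(out)
  }
  prob <- rep(obs$size, obs$count)
  draws <- as.vector(stats::rmultinom(1, size = sample_cells, prob = prob))
  tab <- table(draws[draws > 0])
  out <- clone_size_distribution(as.numeric(names(tab)), as.numeric(tab))
  attr(out, "missing") <- sum(draws == 0)
  attr(out, "realized_cells") <- sample_cells
  out
}

#' Expected sample spectrum under a fitted Poisson mixture
#'
#' For a parent mixture with components `(w_j, m_j)` over `D_total` clones,
#' the expected number of clones contributing exactly `i` cells to the
#' sample is `D_total * sum_j w_j * dpois(i, m_j)`. Size 0 is the expected
#' missing-clone count. Summed over all sizes the expectation equals
#' `D_total`.
#'
#' @param mixture a [parent_mixture()].
#' @param max_size largest clone size (cells in the sample) to tabulate.
#' @return a data frame with columns `size` (0..`max_size`) and
#'   `expected_count`.
#' @export
expected_sample_spectrum <- function(mixture, max_size) {
  stopifnot(inherits(mixture, "parent_mixture"))
  validate_mixture(mixture)
  if (length(mixture$w) == 0) stop("mixture has no components")
  sizes <- 0:max_size
  ec <- vapply(sizes, function(i) {
    sum(mixture$w * stats::dpois(i, mixture$m))
  }, numeric(1)) * mixture$D_total
  data.frame(size = sizes, expected_count = ec)
}

#' Resample a sample spectrum from a fitted model
#'
#' Draws one synthetic realization of the sample that the fitted overall
#' repertoire would produce: each of the `D_total * w_j` clones of component
#' `j` contributes `Poisson(m_j)` cells and each directly counted large
#' clone contributes Poisson cells at its observed size. Used for
#' predicted-versus-observed overlays, including the predicted number of
#' missing clones.
#'
#' @param fit a [parent_mixture()] or a full `recon_fit` report.
#' @param sample_cells optional new sample size; when it differs from the
#'   sample size the model was fitted at, component means are rescaled
#'   proportionally. Default: the fitted sample size.
#' @param seed optional integer seed.
#' @return a [clone_size_distribution()] with attribute `missing`.
#' @export
resample_from_fit <- function(fit, sample_cells = NULL, seed = NULL) {
  mix <- if (inherits(fit, "recon_fit")) fit$mixture else fit
  stopifnot(inherits(mix, "parent_mixture"))
  validate_mixture(mix, allow_empty = TRUE)
  s_fit <- if (!is.null(mix$scale)) mix$scale$sample_cells else NULL
  ratio <- 1
  if (!is.null(sample_cells)) {
    if (sample_cells <= 0) stop("sample_cells must be > 0")
    if (!is.null(s_fit) && s_fit > 0) ratio <- sample_cells / s_fit
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  lam <- numeric(0)
  if (length(mix$w) > 0) {
    n_j <- round(mix$D_total * mix$w)
    lam <- rep(mix$m * ratio, n_j)
  }
  if (!is.null(mix$large_clones) && nrow(mix$large_clones) > 0) {
    lam <- c(lam, rep(mix$large_clones$size * ratio, mix$large_clones$count))
  }
  if (length(lam) == 0) stop("fit has no clones to resample")
  draws <- stats::rpois(length(lam), lam)
  tab <- table(draws[draws > 0])
  out <- clone_size_distribution(as.numeric(names(tab)), as.numeric(tab))
  attr(out, "missing") <- sum(draws == 0)
  attr(out, "realized_cells") <- sum(draws)
  out
}
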