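#' Clone-size distributions
#'
#' A clone-size distribution (or "spectrum") records, for each clone size
#' `x` (cells per clone), the number of clones of exactly that size. It is
#' the canonical representation of both a sample and an overall ("parent")
#' repertoire. A size-0 class is permitted only as the predicted
#' missing-clone class of a model; observed spectra have sizes >= 1.
#'
#' @param sizes integer vector of clone sizes (cells), all >= 0.
#' @param counts vector of clone counts per size, all >= 0. Non-integer
#'   counts are allowed (expected spectra, noise-perturbed spectra).
#' @return An object of class `clone_size_distribution`: a data frame with
#'   columns `size` and `count`, sorted by size, zero-count rows dropped.
#' @examples
#' d <- clone_size_distribution(c(1, 2, 5), c(10, 4, 1))
#' total_cells(d)
#' n_clones(d)
#' @export
clone_size_distribution <- function(sizes, counts) {
  if (length(sizes) != length(counts))
    stop("`sizes` and `counts` must have equal length")
  sizes <- as.numeric(sizes)
  counts <- as.numeric(counts)
  if (any(!is.finite(sizes)) || any(!is.finite(counts)))
    stop("sizes and counts must be finite")
  if (any(sizes < 0)) stop("clone sizes must be >= 0")
  if (any(counts < 0)) stop("clone counts must be >= 0")
  if (any(abs(sizes - round(sizes)) > 1e-8))
    stop("clone sizes must be integers (cells per clone)")
  sizes <- round(sizes)
  keep <- counts > 0
  sizes <- sizes[keep]
  counts <- counts[keep]
  if (anyDuplicated(sizes)) {
    counts <- as.numeric(tapply(counts, sizes, sum))
    sizes <- sort(unique(sizes))
  }
  o <- order(sizes)
  out <- data.frame(size = sizes[o], count = counts[o])
  class(out) <- c("clone_size_distribution", "data.frame")
  out
}

#' @export
print.clone_size_distribution <- function(x, ...) {
  cat(sprintf("Clone-size distribution: %s clones, %s cells, %d size classes\n",
              format(n_clones(x), big.mark = ","),
              format(total_cells(x), big.mark = ","),
              nrow(x)))
  if (nrow(x) > 0 && min(x$size) == 0)
    cat(sprintf("  (includes a size-0 class of %.4g missing clones)\n",
                x$count[x$size == 0]))
  invisible(x)
}

#' @rdname clone_size_distribution
#' @param x a `clone_size_distribution`.
#' @export
total_cells <- function(x) {
  stopifnot(inherits(x, "clone_size_distribution"))
  sum(x$size * x$count)
}

#' @rdname clone_size_distribution
#' @export
n_clones <- function(x) {
  stopifnot(inherits(x, "clone_size_distribution"))
  sum(x$count[x$size > 0])
}

#' Per-clone frequencies of a spectrum
#'
#' Each clone of size `x` has frequency `x / total_cells`; a size class of
#' count `c` contributes `c` identical frequencies. Frequencies are returned
#' grouped by size class together with their multiplicities, which keeps
#' large repertoires (millions of clones, few size classes) cheap. The
#' size-0 class is excluded: missing clones carry no frequency mass.
#'
#' @param dist a [clone_size_distribution()].
#' @return data frame with columns `p` (frequency) and `n` (multiplicity);
#'   `sum(p * n) == 1`.
#' @export
clone_frequencies <- function(dist) {
  stopifnot(inherits(dist, "clone_size_distribution"))
  obs <- dist[dist$size > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observed clones")
  tot <- sum(obs$size * obs$count)
  data.frame(p = obs$size / tot, n = obs$count)
}

# Hill number for grouped frequencies (p, multiplicity n); q may be Inf.
# Used both for observed spectra and for fitted parent mixtures, whose
# "sizes" (mean sample contributions) are positive reals.
hill_from_groups <- function(p, n, q) {
  if (any(p <= 0)) stop("frequencies must be positive")
  if (!isTRUE(q >= 0)) stop("diversity order q must be >= 0")
  if (is.infinite(q)) return(1 / max(p))
  if (abs(q - 1) < 1e-9) return(exp(-sum(n * p * log(p))))
  sum(n * p^q)^(1 / (1 - q))
}

#' Hill-number diversity of a clone-size distribution
#'
#' Computes the effective number of clones of order `q`,
#' \deqn{{}^qD = \left(\sum_i p_i^q\right)^{1/(1-q)},}
#' where the sum runs over clones (not size classes) and the per-clone
#' frequencies satisfy \eqn{\sum_i p_i = 1}. Special orders are computed by
#' their closed forms: `q = 0` is species richness (a plain clone count),
#' `q -> 1` is the exponential of Shannon entropy (natural log),
#' `q = 2` the inverse Simpson index, and `q = Inf` the reciprocal of the
#' largest clone frequency (inverse Berger-Parker). A band `|q - 1| < 1e-9`
#' is routed to the entropy form because the general formula is singular
#' at `q = 1`.
#'
#' @param dist a [clone_size_distribution()] with at least one clone of
#'   size > 0. A size-0 (missing) class is ignored.
#' @param q diversity order, a single number >= 0 or `Inf`.
#' @return the effective number of clones (>= 1).
#' @examples
#' d <- clone_size_distribution(c(2, 1), c(1, 2)) # p = 1/2, 1/4, 1/4
#' hill_diversity(d, 2)      # 1 / (1/4 + 1/16 + 1/16) = 2.667
#' hill_diversity(d, Inf)    # 1 / (1/2) = 2
#' @export
hill_diversity <- function(dist, q) {
  if (length(q) != 1 || is.na(q)) stop("q must be a single number")
  if (q < 0) stop("diversity order q must be >= 0")
  fr <- clone_frequencies(dist)
  if (q == 0) return(sum(fr$n))
  hill_from_groups(fr$p, fr$n, q)
}

#' Diversity profile over several Hill orders
#'
#' @inheritParams hill_diversity
#' @param orders numeric vector of orders; default `c(0, 1, 2, Inf)`.
#' @return named numeric vector, one effective number per order; `Inf` is
#'   named `"inf"`.
#' @export
diversity_profile <- function(dist, orders = c(0, 1, 2, Inf)) {
  out <- vapply(orders, function(q) hill_diversity(dist, q), numeric(1))
  names(out) <- ifelse(is.infinite(orders), "inf", format(orders, trim = TRUE))
  out
}

#' Convert between entropy in bits and effective clone numbers
#'
#' Shannon entropy measured in bits corresponds to an effective number of
#' `2^bits` equally sized clones; these helpers convert in both directions.
#'
#' @param bits entropy in bits.
#' @param effective effective number of clones (> 0).
#' @return `entropy_bits_to_effective()` returns `2^bits`;
#'   `effective_to_entropy_bits()` returns `log2(effective)`.
#' @export
entropy_bits_to_effective <- function(bits) {
  stopifnot(is.numeric(bits), all(is.finite(bits)))
  2^bits
}

#' @rdname entropy_bits_to_effective
#' @export
effective_to_entropy_bits <- function(effective) {
  stopifnot(is.numeric(effective), all(effective > 0))
  log2(effective)
}

#' Read a clone-size spectrum from a text file
#'
#' Two formats are auto-detected. The canonical interchange format is
#' two-column whitespace/tab-separated text, `clone_size  clone_count`,
#' optional header, sizes ascending. A one-column file is interpreted as a
#' per-clone abundance list (one clone size per entry) and tallied into a
#' spectrum.
#'
#' @param path path to the file.
#' @return a [clone_size_distribution()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no observed clones (empty file): ", path)
  toks <- strsplit(trimws(lines), "[\t ,]+")
  first <- suppressWarnings(as.numeric(toks[[1]]))
  start <- if (any(is.na(first))) 2L else 1L  # skip header line
  if (start > length(toks)) stop("no observed clones in ", path)
  toks <- toks[start:length(toks)]
  ncol <- unique(lengths(toks))
  if (length(ncol) != 1)
    stop("inconsistent number of columns in ", path)
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad) > 0)
    stop(sprintf("non-numeric entry at line %d of %s",
                 bad[1] + start - 1L, path))
  m <- do.call(rbind, vals)
  if (ncol == 1) {
    ab <- m[, 1]
    if (any(ab < 0)) stop("negative clone size in ", path)
    tab <- table(ab[ab > 0])
    return(clone_size_distribution(as.numeric(names(tab)), as.numeric(tab)))
  }
  if (ncol != 2)
    stop("expected 1 or 2 columns in ", path, ", found ", ncol)
  if (any(m[, 1] < 0) || any(m[, 2] < 0)) {
    bad <- which(m[, 1] < 0 | m[, 2] < 0)[1]
    stop(sprintf("negative entry at line %d of %s", bad + start - 1L, path))
  }
  if (anyDuplicated(m[, 1])) {
    dup <- which(duplicated(m[, 1]))[1]
    stop(sprintf("duplicate clone size at line %d of %s",
                 dup + start - 1L, path))
  }
  d <- clone_size_distribution(m[, 1], m[, 2])
  if (n_clones(d) == 0 && !any(d$size == 0)) stop("no observed clones in ", path)
  d
}

#' Write a clone-size spectrum as tab-separated text
#'
#' Writes `clone_size<TAB>clone_count` with a header, sizes ascending. A
#' size-0 row, if present, records the predicted number of missing clones.
#'
#' @param dist a [clone_size_distribution()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(dist, path) {
  stopifnot(inherits(dist, "clone_size_distribution"))
  df <- as.data.frame(dist)
  names(df) <- c("clone_size", "clone_count")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
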