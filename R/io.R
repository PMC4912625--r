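div_to_list <- function(x) as.list(stats::setNames(as.numeric(x), names(x)))

#' Serialize a reconstruction report to JSON
#'
#' Writes every field of a `recon_fit` - mixture, sample and overall
#' diversity maps (keys `"0"`, `"1"`, `"2"`, `"inf"`), missing-species
#' estimate with bounds, minimum detected clone size, upper bound U, the
#' per-k likelihood/AICc trajectory, the resampled spectrum, seed and
#' configuration - so that [read_report()] round-trips it losslessly. When
#' the overall cell count was unknown, the scale-dependent fields are
#' `null` and a warning string records why.
#'
#' @param report a `recon_fit` from [reconstruct()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "recon_fit"))
  mix <- report$mixture
  payload <- list(
    version = as.character(utils::packageVersion("recondiv")),
    seed = report$seed,
    config = unclass(report$config),
    sample_cells = report$scale$sample_cells,
    total_cells = report$scale$total_cells,
    mixture = list(w = mix$w, m = mix$m, D_total = mix$D_total,
                   missing = mix$missing),
    large_clones = if (!is.null(mix$large_clones) && nrow(mix$large_clones))
      list(size = mix$large_clones$size, count = mix$large_clones$count)
    else NULL,
    n_observed_clones = report$n_observed_clones,
    k = report$k,
    diversity_sample = div_to_list(report$diversity_sample),
    diversity_overall = div_to_list(report$diversity_overall),
    diversity_bounds = report$diversity_bounds,
    missing = report$missing,
    missing_bounds = as.numeric(report$missing_bounds),
    min_detected_clone_size = report$min_detected_clone_size,
    upper_bound_U = as.numeric(report$upper_bound_U),
    upper_bound_U_with_detected =
      as.numeric(report$upper_bound_U_with_detected),
    log_likelihood = report$log_likelihood,
    aicc = report$aicc,
    trajectory = report$trajectory,
    low_confidence = report$low_confidence,
    capped = report$capped,
    warning = if (is.na(report$scale$total_cells))
      "overall cell count N unknown: min_detected_clone_size and U omitted"
    else NULL,
    resampled_spectrum = list(
      size = report$resampled_spectrum$size,
      count = report$resampled_spectrum$count,
      missing = as.numeric(attr(report$resampled_spectrum, "missing")))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a reconstruction report back from JSON
#'
#' @param path a file written by [write_report()].
#' @return a `recon_fit` equivalent to the one serialized.
#' @export
read_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  scale <- repertoire_scale(p$sample_cells,
                            if (is.null(p$total_cells)) NA_real_
                            else p$total_cells)
  large <- if (!is.null(p$large_clones))
    data.frame(size = p$large_clones$size, count = p$large_clones$count)
  else NULL
  mix <- parent_mixture(p$mixture$w, p$mixture$m,
                        D_total = p$mixture$D_total,
                        missing = p$mixture$missing,
                        large_clones = large, scale = scale,
                        loglik = null_na(p$log_likelihood))
  res <- clone_size_distribution(p$resampled_spectrum$size,
                                 p$resampled_spectrum$count)
  attr(res, "missing") <- p$resampled_spectrum$missing
  cfg <- do.call(algo_config, p$config)
  structure(list(
    mixture = mix, k = p$k,
    n_observed_clones = p$n_observed_clones,
    n_large_clones = if (is.null(large)) 0 else sum(large$count),
    diversity_sample = unlist(p$diversity_sample),
    diversity_overall = unlist(p$diversity_overall),
    missing = p$missing,
    missing_bounds = null_na(p$missing_bounds, 2),
    diversity_bounds = p$diversity_bounds,
    min_detected_clone_size = null_na(p$min_detected_clone_size),
    upper_bound_U = null_na(p$upper_bound_U),
    upper_bound_U_with_detected = null_na(p$upper_bound_U_with_detected),
    log_likelihood = null_na(p$log_likelihood),
    aicc = null_na(p$aicc),
    trajectory = p$trajectory,
    low_confidence = isTRUE(p$low_confidence),
    capped = isTRUE(p$capped),
    seed = p$seed, config = cfg, scale = scale,
    resampled_spectrum = res
  ), class = "recon_fit")
}

null_na <- function(x, n = 1) {
  if (is.null(x) || length(x) == 0) rep(NA_real_, n) else as.numeric(x)
}

cli_usage <- function() {
  paste(
    "usage: recon <subcommand> [--flag value ...]",
    "",
    "subcommands:",
    "  fit            --input spectrum.tsv --sample-cells S",
    "                 [--total-cells N] [--threshold 30] [--starts 56]",
    "                 [--seed INT] --output report.json",
    "  resample       --fit report.json [--sample-cells S] [--seed INT]",
    "                 --out spectrum.tsv",
    "  simulate       --family exponential --s 0.05 --clones 1e4",
    "                 [--cells 1e9] --coverage 0.3 [--ratio 25]",
    "                 [--noise none|per_count|baseline|sporadic]",
    "                 [--seed INT] --out sample.tsv [--truth truth.json]",
    "  sweep          --out results.tsv [--coverages 0.1,1,10]",
    "                 [--clones 1e3,1e4] [--steepness 0.02,0.1]",
    "                 [--noise MODE] [--seeds 1,2,3]",
    "  error-profile  --ensemble results.tsv [--measure q0] [--calibrate]",
    "                 [--seed INT] --out profile.json",
    "  power          --profile profile.json --diversities 1e4,1e5",
    "                 --folds 1.1,1.5,2 --out power.tsv",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i + 1 > length(args) || startsWith(args[i + 1], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1
    } else {
      flags[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  flags
}

num_list <- function(x) as.numeric(strsplit(as.character(x), ",")[[1]])

#' Command-line dispatcher
#'
#' Thin shell interface over the package's functions; the `recon` script
#' installed under `exec/` calls this with `commandArgs(trailingOnly =
#' TRUE)`. Every run that involves randomness takes `--seed` and records
#' it in its outputs.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code: 0 on success, 1 on runtime failure, 2 on
#'   usage errors.
#' @export
cli_dispatch <- function(argv) {
  if (length(argv) == 0) { message(cli_usage()); return(2L) }
  sub <- argv[1]
  known <- c("fit", "resample", "simulate", "sweep", "error-profile", "power")
  if (!sub %in% known) { message(cli_usage()); return(2L) }
  flags <- tryCatch(parse_flags(argv[-1]),
                    error = function(e) { message(e$message); NULL })
  if (is.null(flags)) { message(cli_usage()); return(2L) }
  need <- function(...) {
    miss <- setdiff(c(...), names(flags))
    if (length(miss) > 0) {
      message("missing required flag(s): ",
              paste0("--", miss, collapse = ", "), "\n", cli_usage())
      TRUE
    } else FALSE
  }
  seed <- as.integer(if (!is.null(flags$seed)) flags$seed else 1L)
  out <- tryCatch({
    switch(sub,
      fit = {
        if (need("input", "sample-cells", "output")) return(2L)
        spec <- read_spectrum(flags$input)
        scale <- repertoire_scale(
          as.numeric(flags[["sample-cells"]]),
          if (!is.null(flags[["total-cells"]]))
            as.numeric(flags[["total-cells"]]) else NA_real_)
        cfg <- algo_config(
          large_clone_threshold =
            if (!is.null(flags$threshold)) as.numeric(flags$threshold) else 30,
          n_scan_starts =
            if (!is.null(flags$starts)) as.integer(flags$starts) else 56)
        fit <- reconstruct(spec, scale = scale, config = cfg, seed = seed)
        write_report(fit, flags$output)
        message("wrote ", flags$output)
      },
      resample = {
        if (need("fit", "out")) return(2L)
        fit <- read_report(flags$fit)
        sc <- if (!is.null(flags[["sample-cells"]]))
          as.numeric(flags[["sample-cells"]]) else NULL
        res <- resample_from_fit(fit, sample_cells = sc, seed = seed)
        miss <- attr(res, "missing")
        full <- clone_size_distribution(c(0, res$size), c(miss, res$count))
        write_spectrum(full, flags$out)
        message("wrote ", flags$out)
      },
      simulate = {
        if (need("family", "clones", "coverage", "out")) return(2L)
        spec <- parent_spec(
          family = flags$family,
          s = if (!is.null(flags$s)) as.numeric(flags$s) else 0.05,
          size_ratio = if (!is.null(flags$ratio))
            as.numeric(flags$ratio) else 25,
          D = as.numeric(flags$clones),
          N = if (!is.null(flags$cells)) as.numeric(flags$cells) else 1e9)
        parent <- make_parent(spec)
        S <- round(as.numeric(flags$coverage) * spec$D)
        samp <- poisson_sample(parent, S, seed = seed)
        if (!is.null(flags$noise) && flags$noise != "none")
          samp <- apply_noise(samp, noise_spec(flags$noise, seed = seed + 1L))
        write_spectrum(samp, flags$out)
        if (!is.null(flags$truth)) {
          jsonlite::write_json(
            list(seed = seed, spec = unclass(spec),
                 diversity = div_to_list(diversity_profile(parent)),
                 sample_cells = S,
                 missing = as.numeric(attr(samp, "missing"))),
            flags$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        }
        message("wrote ", flags$out)
      },
      sweep = {
        if (need("out")) return(2L)
        covs <- if (!is.null(flags$coverages))
          num_list(flags$coverages) else c(0.1, 1, 10)
        Ds <- if (!is.null(flags$clones)) num_list(flags$clones) else 1e4
        ss <- if (!is.null(flags$steepness))
          num_list(flags$steepness) else c(0.02, 0.05, 0.1, 0.2)
        seeds <- if (!is.null(flags$seeds))
          as.integer(num_list(flags$seeds)) else seed
        nz <- if (!is.null(flags$noise) && flags$noise != "none")
          noise_spec(flags$noise) else noise_spec("none")
        specs <- list()
        for (D in Ds) for (s in ss)
          specs[[length(specs) + 1]] <- parent_spec("exponential", s = s,
                                                    D = D)
        res <- run_validation_sweep(specs, covs, noise = nz, seeds = seeds)
        utils::write.table(res, flags$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        message("wrote ", flags$out)
      },
      `error-profile` = {
        if (need("ensemble", "out")) return(2L)
        ens <- utils::read.delim(flags$ensemble)
        measure <- if (!is.null(flags$measure)) flags$measure else "q0"
        prof <- if (isTRUE(flags$calibrate) || identical(flags$calibrate, "true"))
          calibrate_profile(ens, measure = measure, seed = seed)
        else build_error_profile(ens, measure = measure)
        jsonlite::write_json(
          list(measure = attr(prof, "measure"),
               upper_adjustment = attr(prof, "upper_adjustment"),
               raw_rate = attr(prof, "raw_rate"),
               calibrated_rate = attr(prof, "calibrated_rate"),
               seed = seed,
               coverage = prof$coverage, band = prof$band),
          flags$out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        message("wrote ", flags$out)
      },
      power = {
        if (need("profile", "diversities", "folds", "out")) return(2L)
        pj <- jsonlite::read_json(flags$profile, simplifyVector = TRUE)
        prof <- structure(
          data.frame(coverage = pj$coverage, band = pj$band),
          class = c("error_profile", "data.frame"),
          measure = pj$measure,
          upper_adjustment = pj$upper_adjustment)
        tab <- power_table(num_list(flags$diversities),
                           num_list(flags$folds), prof)
        utils::write.table(cbind(fold = rownames(tab), as.data.frame(tab)),
                           flags$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        message("wrote ", flags$out)
      })
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  if (!is.integer(out)) out <- 0L
  out
}
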