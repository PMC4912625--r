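# shared fixtures, built once per test run

# spectrum with per-clone frequencies (1/2, 1/4, 1/4)
csd_half_quarter <- function() clone_size_distribution(c(1, 2), c(2, 1))

uniform_csd <- function(n_clones, size = 1) {
  clone_size_distribution(size, n_clones)
}

# random spectrum generator for property-style loops
random_csd <- function(n_classes = 8, max_size = 40, max_count = 50) {
  sizes <- sort(sample.int(max_size, n_classes))
  clone_size_distribution(sizes, sample.int(max_count, n_classes,
                                            replace = TRUE))
}

# expand a spectrum into a per-clone abundance vector (vegan-style input)
csd_to_abundances <- function(d) rep(d$size[d$size > 0], d$count[d$size > 0])

# small gold-standard sweep shared by the uncertainty tests; cached so the
# expensive reconstructions run once per session
.shared <- new.env()
small_sweep <- function() {
  if (is.null(.shared$sweep)) {
    specs <- list(
      parent_spec("exponential", s = 0.03, D = 3e3),
      parent_spec("exponential", s = 0.08, D = 1e4),
      parent_spec("exponential", s = 0.2, D = 1e4),
      parent_spec("bimodal", size_ratio = 25, D = 3e3))
    .shared$sweep <- run_validation_sweep(
      specs, coverages = c(0.1, 0.3, 1, 3, 10), seeds = 1:2)
  }
  .shared$sweep
}
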