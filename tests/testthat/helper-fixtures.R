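# Fixture builders shared across test files. Everything is generated in code
# under fixed seeds; no data files.

# A small hand-assembled class: `n` compounds, fingerprints of length
# `n_bits` with deterministic pseudo-random bits, potencies spread over the
# full window.
tiny_class <- function(n = 12, n_bits = 64, class_id = "TINY", seed = 101) {
  withr::with_seed(seed, {
    pic50 <- seq(5, 11, length.out = n)
    tibble::tibble(
      compound_id = sprintf("%s-%03d", class_id, seq_len(n)),
      class_id = class_id,
      smiles = NA_character_,
      pic50 = pic50,
      subrange = assign_subrange(pic50),
      series_id = rep_len(1:3, n),
      fingerprint = lapply(seq_len(n), function(i) {
        as.integer(stats::runif(n_bits) < 0.25)
      })
    )
  })
}

random_fp <- function(n_bits = 128, density = 0.2) {
  as.integer(stats::runif(n_bits) < density)
}

# Brute-force Tanimoto: explicit set arithmetic over bit indices.
tanimoto_oracle <- function(a, b) {
  sa <- which(a == 1)
  sb <- which(b == 1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# Exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# assignments (zeros discarded first), independent of stats::psignrank.
signed_rank_enum_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(1)
  }
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% r
  p_ge <- mean(W_all >= W_obs)
  p_le <- mean(W_all <= W_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Cached scaled-down study objects so several test files can share one
# expensive computation within a test run.
.study_cache <- new.env(parent = emptyenv())

study_suite <- function() {
  if (is.null(.study_cache$suite)) {
    .study_cache$suite <- generate_benchmark_suite(
      3, synth_config(min_per_subrange = 135L, n_compounds = 660L), seed = 20240101
    )
  }
  .study_cache$suite
}

study_ladder <- function() {
  if (is.null(.study_cache$ladder)) {
    .study_cache$ladder <- run_ladder(
      study_suite(), methods = c("SVR", "RFR", "1NN", "3NN", "MR"),
      n_trials = 10L, seed = 20240102, grid = reduced_grid()
    )
  }
  .study_cache$ladder
}
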