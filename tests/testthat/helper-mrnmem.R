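# Shared fixtures for the suite. All presets are generated in code; no
# stored data.

mrn_base <- function() standard_params("MRN-baseline")
na_base <- function() standard_params("MRN-NA")
na_cal <- function() standard_params("MRN-NA-calibrated")

# the low-cooperativity, strong-binding corner used throughout the
# first-passage analyses
na_n3K15 <- function() with_params(na_base(), n = 3, K = 15)
mrn_n3K15 <- function() with_params(mrn_base(), n = 3, K = 15)

# random non-negative states for consistency sweeps
random_states <- function(n, max = 150, seed = 1) {
  with_preserved_seed <- getFromNamespace("with_preserved_seed", "mrnmem")
  with_preserved_seed(seed, {
    matrix(stats::runif(3 * n, 0, max), ncol = 3)
  })
}
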