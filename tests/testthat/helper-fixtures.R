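# Shared fixtures and independent oracles for the test suite.

# Small, fast phantom config for structural tests.
small_config <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(20L, 20L, 18L),
                                 hu_noise_sd = 0), list(...))
  do.call(phantom_config, args)
}

# Memoized default noiseless phantom series (the study-condition phantom).
.fixture_env <- new.env(parent = emptyenv())
default_noiseless_phantom <- function() {
  if (is.null(.fixture_env$phantom))
    .fixture_env$phantom <- generate_phantom(phantom_config(hu_noise_sd = 0))
  .fixture_env$phantom
}

# Independent logistic-model oracle: recomputes every in-mask voxel's
# noiseless gas fraction from first principles (own logistic, own depth
# normalization) without calling the generator's model function.
oracle_gas_fractions <- function(config, mask_array, peep) {
  dims <- dim(mask_array)
  zin <- which(apply(mask_array, 3, any))
  z0 <- min(zin); z1 <- max(zin)
  hz <- (seq_len(dims[3]) - z0) / (z1 - z0)
  h <- array(rep(hz, each = dims[1] * dims[2]), dim = dims)[mask_array]
  g_min <- config$gas_frac_range[1]
  g_max <- rep(config$gas_frac_range[2], length(h))
  slope <- rep(config$opening_depth_slope, length(h))
  if (config$injury) {
    g_max[h > 0.5] <- pmax(g_min + 0.01, config$gas_frac_range[2] - 0.15)
    slope[h > 0.5] <- 1.5 * config$opening_depth_slope
  }
  p_open <- config$opening_intercept + slope * h +
    config$iap_transmission * config$iap
  x <- (peep - p_open) / config$sigmoid_width
  g_min + (g_max - g_min) / (1 + exp(-x))
}

# Independent compartment-fraction oracle from HU values (printed bins).
oracle_fractions <- function(hu) {
  n <- sum(hu >= -1000 & hu <= 200)
  c(overdistended = sum(hu >= -1000 & hu < -900),
    normally_aerated = sum(hu >= -900 & hu < -500),
    poorly_aerated = sum(hu >= -500 & hu < -100),
    atelectatic = sum(hu >= -100 & hu <= 200)) / n * 100
}

# Geometric oracle for the lower inflection point: numerical tangent at the
# true inflection (complex-step derivative, immune to subtractive
# cancellation), intersected with the lower asymptote V = a by root finding.
oracle_lower_inflection <- function(a, b, c, d) {
  f <- function(p) a + b / (1 + exp(-(p - c) / d))
  h <- 1e-30 * d
  slope <- Im(f(complex(real = c, imaginary = h))) / h
  tangent_minus_a <- function(p) (f(c) + slope * (p - c)) - a
  uniroot(tangent_minus_a, interval = c(c - 1e3 * d, c),
          tol = 1e-12)$root
}

expect_rms_definition <- function(fit) {
  expect_equal(fit$rms, sqrt(mean((fit$volumes - fit$fitted)^2)),
               tolerance = 1e-12)
}

whole_fractions <- function(el) {
  quantify_aeration(el$ct, el$mask)$compartments$fraction_pct
}
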