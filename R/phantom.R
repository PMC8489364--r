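#' Configuration for a synthetic lung CT phantom
#'
#' Defines a supine-lung CT phantom whose voxel aeration follows a
#' gravitational (dorso-ventral) recruitment model. Each in-mask voxel has an
#' opening pressure that increases linearly with normalized depth `h` along
#' the dependent axis and with the transmitted fraction of intra-abdominal
#' pressure (IAP); its gas fraction follows a logistic function of airway
#' pressure around that opening pressure:
#'
#' \deqn{g(h, P) = g_{min} + (g_{max} - g_{min}) \,
#'       \sigma\!\left(\frac{P - P_{open}(h)}{w}\right), \qquad
#'       P_{open}(h) = \theta_0 + \theta_1 h + k_{iap} \cdot IAP}
#'
#' with \eqn{\sigma} the standard logistic function. Hounsfield units are
#' derived from the gas fraction by the linear gas/tissue mixture
#' (HU = -1000 g) plus optional Gaussian noise. Dependent voxels (large `h`)
#' therefore collapse at low PEEP and re-aerate as PEEP rises, reproducing the
#' dorsal-dominant atelectasis and ventral-dominant overdistension pattern of
#' supine lungs under intra-abdominal hypertension.
#'
#' The phantom's functional form is a stand-in for real regional mechanics;
#' its parameters are not calibrated to any particular species' anatomy.
#'
#' @param grid_shape Integer vector of 3 voxel counts per axis. Axis 1 is
#'   left-right, axis 3 is the dependent (ventro-dorsal) axis with index 1 the
#'   most ventral voxel (supine convention).
#' @param voxel_size Numeric vector of 3 voxel edge lengths (mm).
#' @param peep_levels Airway pressures (cmH2O) at which volumes are generated;
#'   strictly increasing, all >= 0.
#' @param iap Intra-abdominal pressure (cmH2O).
#' @param injury If `TRUE`, the dependent half (`h > 0.5`) gets a reduced
#'   achievable gas fraction and a steeper opening-pressure slope, emulating
#'   oleic-acid-type injury concentrated in dorsal segments.
#' @param gas_frac_range Length-2 numeric `(g_min, g_max)` achievable voxel
#'   gas fractions, `0 <= g_min < g_max <= 1`.
#' @param opening_intercept Opening-pressure intercept \eqn{\theta_0} (cmH2O).
#' @param opening_depth_slope Opening-pressure depth slope \eqn{\theta_1}
#'   (cmH2O per unit normalized depth); must be >= 0.
#' @param iap_transmission Fraction \eqn{k_{iap}} of IAP transmitted to the
#'   voxel opening pressure (default 0.5, a typical abdomino-thoracic
#'   transmission).
#' @param sigmoid_width Logistic width `w` (cmH2O), > 0.
#' @param hu_noise_sd Standard deviation of additive Gaussian HU noise (>= 0).
#' @param lung_radius_frac Ellipsoid semi-axes as a fraction of the grid
#'   dimensions (default 0.4, so the lung occupies 80% of each axis).
#' @param seed RNG seed; all phantom randomness flows from it.
#'
#' @return An object of class `phantom_config` (a validated list).
#' @seealso [generate_phantom()]
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 56L),
                           voxel_size = c(3, 3, 3),
                           peep_levels = c(5, 12, 17, 22, 27),
                           iap = 27,
                           injury = FALSE,
                           gas_frac_range = c(0.03, 0.905),
                           opening_intercept = -12,
                           opening_depth_slope = 50,
                           iap_transmission = 0.5,
                           sigmoid_width = 3,
                           hu_noise_sd = 30,
                           lung_radius_frac = 0.4,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths (mm)")
  if (length(peep_levels) < 1L || any(peep_levels < 0) ||
      any(diff(peep_levels) <= 0))
    stop("peep_levels must be strictly increasing and all >= 0")
  if (length(gas_frac_range) != 2L ||
      gas_frac_range[1] < 0 || gas_frac_range[2] > 1 ||
      gas_frac_range[1] >= gas_frac_range[2])
    stop("gas_frac_range must satisfy 0 <= g_min < g_max <= 1")
  if (sigmoid_width <= 0) stop("sigmoid_width must be > 0")
  if (hu_noise_sd < 0) stop("hu_noise_sd must be >= 0")
  if (opening_depth_slope < 0) stop("opening_depth_slope must be >= 0")
  if (iap < 0) stop("iap must be >= 0")
  if (lung_radius_frac <= 0 || lung_radius_frac > 0.5)
    stop("lung_radius_frac must be in (0, 0.5]")
  structure(list(
    grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
    peep_levels = as.numeric(peep_levels), iap = iap, injury = isTRUE(injury),
    gas_frac_range = as.numeric(gas_frac_range),
    opening_intercept = opening_intercept,
    opening_depth_slope = opening_depth_slope,
    iap_transmission = iap_transmission,
    sigmoid_width = sigmoid_width, hu_noise_sd = hu_noise_sd,
    lung_radius_frac = lung_radius_frac, seed = as.integer(seed)
  ), class = "phantom_config")
}

# Evaluate the noiseless voxel gas fraction g(h, P) for a config.
# Exposed so tests can use the model itself as a brute-force oracle.
#' Noiseless phantom gas fraction
#'
#' Evaluates the phantom's voxel gas-fraction model \eqn{g(h, P)} directly
#' (no grid, no noise). Useful as a closed-form oracle for aeration results
#' computed on generated phantoms.
#'
#' @param config A [phantom_config()].
#' @param h Normalized depth(s) in `[0, 1]` (0 = ventral, 1 = dorsal).
#' @param peep Airway pressure(s) (cmH2O).
#' @return Numeric gas fractions in `[0, 1]`, recycled over `h` and `peep`.
#' @export
phantom_gas_fraction <- function(config, h, peep) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$gas_frac_range
  g_max <- rep_len(g[2], length(h))
  slope <- rep_len(config$opening_depth_slope, length(h))
  if (config$injury) {
    dep <- h > 0.5
    g_max[dep] <- pmax(g[1] + 0.01, g[2] - 0.15)
    slope[dep] <- 1.5 * config$opening_depth_slope
  }
  p_open <- config$opening_intercept + slope * h +
    config$iap_transmission * config$iap
  g[1] + (g_max - g[1]) * stats::plogis((peep - p_open) / config$sigmoid_width)
}

#' Generate a synthetic CT phantom series across PEEP levels
#'
#' Builds one ellipsoidal lung mask (identical geometry at every PEEP level)
#' and, for each PEEP level, a CT volume whose in-mask HU follow the
#' gravitational recruitment model of [phantom_config()]. Out-of-mask voxels
#' are set to 0 HU (water-equivalent body).
#'
#' @param config A [phantom_config()].
#' @return A list with one element per PEEP level, each a list with
#'   components `peep` (cmH2O), `ct` (a [ct_volume()]) and `mask`
#'   (a [lung_mask()]).
#' @examples
#' cfg <- phantom_config(grid_shape = c(16, 16, 14), hu_noise_sd = 0,
#'                       peep_levels = c(5, 27))
#' ph <- generate_phantom(cfg)
#' length(ph)
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape
  semi <- config$lung_radius_frac * dims
  if (any(semi < 2))
    stop("grid too small to contain the lung ellipsoid: each semi-axis must ",
         "span at least 2 voxels, got (",
         paste(signif(semi, 3), collapse = ", "), ") for grid (",
         paste(dims, collapse = ", "), ")")
  ctr <- (dims + 1) / 2
  ax <- lapply(1:3, function(k) ((seq_len(dims[k]) - ctr[k]) / semi[k])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  inside <- d2 <= 1
  if (!any(inside)) stop("grid too small: lung mask is empty")

  # normalized depth over the mask's extent along the dependent axis (axis 3)
  zin <- which(apply(inside, 3, any))
  z0 <- min(zin); z1 <- max(zin)
  hz <- if (z1 > z0) (seq_len(dims[3]) - z0) / (z1 - z0) else
    rep(0.5, dims[3])
  h <- array(rep(hz, each = dims[1] * dims[2]), dim = dims)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  mask <- lung_mask(inside)
  idx <- which(inside)
  g_clean <- vapply(config$peep_levels, function(p)
    phantom_gas_fraction(config, h[idx], p), numeric(length(idx)))
  lapply(seq_along(config$peep_levels), function(i) {
    hu <- array(0, dim = dims)
    hu[idx] <- -1000 * g_clean[, i]
    if (config$hu_noise_sd > 0)
      hu[idx] <- hu[idx] + stats::rnorm(length(idx), 0, config$hu_noise_sd)
    list(peep = config$peep_levels[i],
         ct = ct_volume(hu, spacing = config$voxel_size),
         mask = mask)
  })
}
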