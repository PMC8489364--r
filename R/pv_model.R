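#' Venegas sigmoid pressure-volume model
#'
#' Evaluates the four-parameter sigmoid
#' \deqn{V(P) = a + \frac{b}{1 + e^{-(P-c)/d}}}
#' used to describe respiratory pressure-volume relationships: `a` is the
#' lower asymptote (L), `b` the signed volume span (L), `c` the pressure of
#' the true inflection point (cmH2O) and `d` the width parameter (cmH2O,
#' > 0). The lower and upper inflection (corner) points, where the tangent at
#' `P = c` meets the asymptotes, lie at `c - 2d` and `c + 2d`.
#'
#' @param pressure Pressure(s), cmH2O.
#' @param a,b,c,d Model parameters.
#' @return Volumes at `pressure`.
#' @export
venegas_volume <- function(pressure, a, b, c, d) {
  a + b / (1 + exp(-(pressure - c) / d))
}

# Accept either a PV data frame (pressure_cmH2O, volume) or two vectors.
as_pv_xy <- function(data, volumes = NULL) {
  if (is.data.frame(data)) {
    need <- c("pressure_cmH2O", "volume")
    if (!all(need %in% names(data)))
      stop("PV data frame must have columns ", paste(need, collapse = ", "))
    xy <- list(p = as.numeric(data$pressure_cmH2O),
               v = as.numeric(data$volume))
  } else {
    xy <- list(p = as.numeric(data), v = as.numeric(volumes))
  }
  if (length(xy$p) != length(xy$v))
    stop("pressures and volumes differ in length")
  if (anyNA(xy$p) || anyNA(xy$v) || !all(is.finite(c(xy$p, xy$v))))
    stop("pressures and volumes must be finite")
  if (length(unique(xy$p)) < 2L)
    stop("need at least 2 distinct pressures")
  xy
}

model_rms <- function(observed, fitted) sqrt(mean((observed - fitted)^2))

new_pv_fit <- function(family, par, xy, fitted, converged,
                       degenerate = FALSE, message = NA_character_) {
  structure(list(
    family = family, parameters = par,
    rms = if (is.null(fitted)) NA_real_ else model_rms(xy$v, fitted),
    pressures = xy$p, volumes = xy$v, fitted = fitted,
    converged = converged, degenerate = degenerate, message = message
  ), class = c(paste0(family, "_fit"), "pv_fit"))
}

#' @export
print.pv_fit <- function(x, ...) {
  cat("<pv_fit> family:", x$family,
      if (!x$converged) "(NOT converged)" else if (x$degenerate)
        "(degenerate)" else "", "\n")
  if (!is.null(x$parameters))
    cat("  parameters:", paste(names(x$parameters),
                               signif(x$parameters, 5),
                               sep = " = ", collapse = ", "), "\n")
  cat("  rms:", signif(x$rms, 5), "on", length(x$pressures), "points\n")
  invisible(x)
}

# Shared bounded Levenberg-Marquardt driver over a deterministic start grid.
lm_multistart <- function(formula, xy, starts, lower, upper) {
  best <- NULL
  env <- list2env(list(P = xy$p, V = xy$v))
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, start = st, lower = lower, upper = upper,
                        data = env,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rms <- model_rms(xy$v, stats::fitted(fit))
    if (is.null(best) || rms < best$rms) best <- list(fit = fit, rms = rms)
  }
  best
}

at_bound <- function(value, lower, upper, tol = 1e-3) {
  span <- upper - lower
  (is.finite(lower) && value - lower < tol * min(span, abs(lower) + 1)) ||
    (is.finite(upper) && upper - value < tol * min(span, abs(upper) + 1))
}

#' Fit the Venegas sigmoid to pressure-volume data
#'
#' Bounded nonlinear least squares with a deterministic multi-start grid:
#' `c` is started at 5 equally spaced pressures over the observed range and
#' `d` at 1, 3 and 6 cmH2O, with `a`/`b` initialized from the volume
#' extremes. `d` is constrained to (0.1, 50) cmH2O and `b` is free-signed,
#' so decreasing compartments (e.g. atelectasis) fit with `b < 0`. The best
#' converged start (smallest RMS) is kept.
#'
#' A fit is flagged `degenerate` when the optimum pins a parameter to its
#' bound or places `c` far outside the observed pressure range — the
#' signatures of an unidentifiable sigmoid (e.g. near-constant or
#' near-linear data). Degenerate fits are excluded from model selection.
#'
#' @param data A data frame with columns `pressure_cmH2O` and `volume`, or a
#'   numeric pressure vector.
#' @param volumes Volumes when `data` is a vector.
#' @param init Optional named list/vector `(a, b, c, d)` used as an
#'   additional start.
#' @param d_bounds Length-2 bounds for `d` (default `c(0.1, 50)` cmH2O).
#' @return A `pv_fit` object (family `"venegas"`) with elements
#'   `parameters` (a, b, c, d), `rms`, `fitted`, `converged`, `degenerate`.
#' @export
fit_venegas <- function(data, volumes = NULL, init = NULL,
                        d_bounds = c(0.1, 50)) {
  xy <- as_pv_xy(data, volumes)
  if (length(unique(xy$p)) < 4L)
    stop("Venegas fit needs at least 4 distinct pressures")
  ord <- order(xy$p)
  v_lo <- xy$v[ord][1]; v_hi <- xy$v[ord][length(ord)]
  b0 <- v_hi - v_lo
  if (abs(b0) < 1e-12) b0 <- 1e-3 * max(1, abs(v_lo))
  p_rng <- range(xy$p); p_span <- diff(p_rng)
  c_lo <- p_rng[1] - 2 * p_span
  c_hi <- p_rng[2] + 2 * p_span
  starts <- list()
  for (c0 in seq(p_rng[1], p_rng[2], length.out = 5))
    for (d0 in c(1, 3, 6))
      starts[[length(starts) + 1L]] <- list(a = v_lo, b = b0, c = c0,
                                            d = min(max(d0, d_bounds[1]),
                                                    d_bounds[2]))
  if (!is.null(init)) starts <- c(starts, list(as.list(init)[c("a", "b",
                                                               "c", "d")]))
  lower <- c(a = -Inf, b = -Inf, c = c_lo, d = d_bounds[1])
  upper <- c(a = Inf, b = Inf, c = c_hi, d = d_bounds[2])
  best <- lm_multistart(V ~ a + b / (1 + exp(-(P - c) / d)), xy,
                        starts, lower, upper)
  if (is.null(best))
    return(new_pv_fit("venegas", NULL, xy, NULL, FALSE,
                      message = "no start converged"))
  par <- stats::coef(best$fit)
  v_scale <- max(abs(xy$v), 1e-12)
  degen <- abs(par["b"]) < 1e-8 * v_scale ||
    at_bound(par["d"], d_bounds[1], d_bounds[2]) ||
    par["c"] < p_rng[1] - p_span || par["c"] > p_rng[2] + p_span
  new_pv_fit("venegas", par, xy, stats::fitted(best$fit), TRUE,
             degenerate = unname(degen),
             message = if (degen) "parameters at bounds or unidentifiable"
             else NA_character_)
}

#' Fit a saturating exponential pressure-volume model
#'
#' Fits \eqn{V(P) = a + b (1 - e^{-P/\tau})} with \eqn{\tau > 0} (the
#' standard saturating respiratory PV form) by bounded nonlinear least
#' squares over a deterministic grid of \eqn{\tau} starts.
#'
#' @inheritParams fit_venegas
#' @param tau_bounds Length-2 bounds for `tau` (default `c(0.1, 500)`).
#' @return A `pv_fit` object (family `"exponential"`) with parameters
#'   `(a, b, tau)`.
#' @export
fit_exponential <- function(data, volumes = NULL, tau_bounds = c(0.1, 500)) {
  xy <- as_pv_xy(data, volumes)
  if (length(unique(xy$p)) < 3L)
    stop("exponential fit needs at least 3 distinct pressures")
  ord <- order(xy$p)
  v_lo <- xy$v[ord][1]; v_hi <- xy$v[ord][length(ord)]
  p_hi <- max(xy$p)
  starts <- lapply(c(2, 5, 10, 20, 50), function(t0) {
    sat <- 1 - exp(-p_hi / t0)
    list(a = v_lo, b = if (abs(sat) > 1e-9) (v_hi - v_lo) / sat else
      v_hi - v_lo, tau = t0)
  })
  best <- lm_multistart(V ~ a + b * (1 - exp(-P / tau)), xy, starts,
                        lower = c(a = -Inf, b = -Inf, tau = tau_bounds[1]),
                        upper = c(a = Inf, b = Inf, tau = tau_bounds[2]))
  if (is.null(best))
    return(new_pv_fit("exponential", NULL, xy, NULL, FALSE,
                      message = "no start converged"))
  par <- stats::coef(best$fit)
  v_scale <- max(abs(xy$v), 1e-12)
  degen <- abs(par["b"]) < 1e-8 * v_scale ||
    at_bound(par["tau"], tau_bounds[1], tau_bounds[2])
  new_pv_fit("exponential", par, xy, stats::fitted(best$fit), TRUE,
             degenerate = unname(degen),
             message = if (degen) "tau at bounds or unidentifiable"
             else NA_character_)
}

#' Fit a linear pressure-volume model
#'
#' Ordinary least squares for \eqn{V(P) = a + bP}.
#'
#' @inheritParams fit_venegas
#' @return A `pv_fit` object (family `"linear"`) with parameters `(a, b)`.
#' @export
fit_linear <- function(data, volumes = NULL) {
  xy <- as_pv_xy(data, volumes)
  fit <- stats::lm(v ~ p, data = data.frame(p = xy$p, v = xy$v))
  par <- c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
  new_pv_fit("linear", par, xy, unname(stats::fitted(fit)), TRUE)
}

#' Select the best pressure-volume model by smallest RMS
#'
#' Fits the Venegas sigmoid, saturating exponential and linear models and
#' returns the converged, non-degenerate fit with the smallest root mean
#' square between observed and fitted volumes. Exact RMS ties are broken in
#' favour of the more expressive family (venegas > exponential > linear).
#' No degrees-of-freedom penalty is applied (raw RMS), which is a known bias
#' toward the richer families.
#'
#' @inheritParams fit_venegas
#' @return The winning `pv_fit`; the full list of attempted fits is attached
#'   as attribute `"attempts"`.
#' @export
select_best_model <- function(data, volumes = NULL) {
  xy <- as_pv_xy(data, volumes)
  attempts <- list(
    venegas = tryCatch(fit_venegas(xy$p, xy$v), error = function(e)
      new_pv_fit("venegas", NULL, xy, NULL, FALSE, message = conditionMessage(e))),
    exponential = tryCatch(fit_exponential(xy$p, xy$v), error = function(e)
      new_pv_fit("exponential", NULL, xy, NULL, FALSE, message = conditionMessage(e))),
    linear = tryCatch(fit_linear(xy$p, xy$v), error = function(e)
      new_pv_fit("linear", NULL, xy, NULL, FALSE, message = conditionMessage(e)))
  )
  ok <- vapply(attempts, function(f) f$converged && !f$degenerate, logical(1))
  if (!any(ok)) {
    msgs <- vapply(attempts, function(f)
      paste0(f$family, ": ", if (!f$converged) f$message else "degenerate"),
      character(1))
    stop("no pressure-volume model could be fitted -- ",
         paste(msgs, collapse = "; "))
  }
  cand <- attempts[ok]
  rms <- vapply(cand, `[[`, numeric(1), "rms")
  best_rms <- min(rms)
  tol <- 1e-9 * max(1, best_rms)
  tied <- which(rms <= best_rms + tol)
  rank <- match(vapply(cand[tied], `[[`, character(1), "family"),
                c("venegas", "exponential", "linear"))
  winner <- cand[[tied[which.min(rank)]]]
  attr(winner, "attempts") <- attempts
  winner
}

#' Inflection points of a fitted Venegas sigmoid
#'
#' The lower and upper inflection (corner) points are the pressures where
#' the tangent at the true inflection `P = c` (slope `b/(4d)`) intersects
#' the lower and upper asymptotes: `c - 2d` and `c + 2d`.
#'
#' @param fit A converged `pv_fit` of family `"venegas"`.
#' @return A list of class `inflection_points` with `lower`,
#'   `true_inflection` and `upper` (cmH2O).
#' @export
inflection_points <- function(fit) {
  if (!inherits(fit, "pv_fit") || !identical(fit$family, "venegas"))
    stop("inflection points are defined only for a Venegas sigmoid fit ",
         "(the linear model has none; the exponential has no inflection)")
  if (!fit$converged) stop("Venegas fit did not converge")
  cc <- unname(fit$parameters["c"]); dd <- unname(fit$parameters["d"])
  structure(list(lower = cc - 2 * dd, true_inflection = cc,
                 upper = cc + 2 * dd),
            class = "inflection_points")
}

#' Optimal CT inflation PEEP range
#'
#' The interval between the lower inflection points of the atelectatic and
#' overdistended compartment pressure-volume curves: PEEP above the lower
#' bound has recruited most recruitable (atelectatic) lung, while PEEP below
#' the upper bound has not yet entered the steep part of the overdistension
#' curve.
#'
#' @param atelectatic_fit Converged Venegas `pv_fit` for the atelectatic
#'   compartment.
#' @param overdistended_fit Converged Venegas `pv_fit` for the overdistended
#'   compartment.
#' @return A list of class `optimal_peep_range` with `low` (atelectatic
#'   lower inflection), `high` (overdistended lower inflection) and
#'   `well_formed` (`low <= high`). The bounds are never swapped; an
#'   ill-formed range is reported as such.
#' @export
optimal_peep_range <- function(atelectatic_fit, overdistended_fit) {
  low <- inflection_points(atelectatic_fit)$lower
  high <- inflection_points(overdistended_fit)$lower
  structure(list(low = low, high = high, well_formed = low <= high),
            class = "optimal_peep_range")
}

#' @export
print.optimal_peep_range <- function(x, ...) {
  cat(sprintf("Optimal CT inflation PEEP range: %.1f to %.1f cmH2O%s\n",
              x$low, x$high,
              if (!x$well_formed) "  [ill-formed: low > high]" else ""))
  invisible(x)
}

#' Rescale compartment volumes to fractional change over the PEEP range
#'
#' Re-expresses volumes as the fractional change between the lowest and
#' highest pressure: `(V - V_low) / (V_high - V_low)`, where `V_low` and
#' `V_high` are the (mean) volumes observed at the minimum and maximum
#' pressure. Raw volumes are the default elsewhere; this helper supports
#' fitting on normalized trajectories.
#'
#' @param data PV data frame with columns `pressure_cmH2O`, `volume`.
#' @return The data frame with `volume` replaced by the fractional volume.
#' @export
as_fractional_volumes <- function(data) {
  xy <- as_pv_xy(data)
  v_lo <- mean(xy$v[xy$p == min(xy$p)])
  v_hi <- mean(xy$v[xy$p == max(xy$p)])
  if (abs(v_hi - v_lo) < 1e-12)
    stop("volumes at the lowest and highest pressure are equal; ",
         "fractional rescaling is undefined")
  data$volume <- (data$volume - v_lo) / (v_hi - v_lo)
  data
}
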