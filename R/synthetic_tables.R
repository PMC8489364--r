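#' Ground-truth parameters for a sigmoid PEEP-volume trajectory
#'
#' @param a Baseline volume (L), the lower asymptote.
#' @param b Signed volume span (L); negative for compartments that shrink
#'   with pressure (e.g. atelectasis).
#' @param c Pressure of the true inflection (cmH2O).
#' @param d Width parameter (cmH2O), > 0.
#' @param noise_sd Additive Gaussian volume noise (L), >= 0.
#' @return An object of class `sigmoid_truth`.
#' @seealso [generate_pv_dataset()], [venegas_volume()]
#' @export
sigmoid_truth <- function(a, b, c, d, noise_sd = 0) {
  if (d <= 0) stop("d must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(a = a, b = b, c = c, d = d, noise_sd = noise_sd),
            class = "sigmoid_truth")
}

#' Generate a PEEP-volume dataset from a known sigmoid
#'
#' Simulates compartment volumes observed at a set of PEEP levels,
#' \eqn{V_i = a + b/(1+e^{-(P_i-c)/d}) + \epsilon_i} with
#' \eqn{\epsilon_i \sim N(0, noise\_sd^2)}, seeded and reproducible.
#'
#' @param truth A [sigmoid_truth()].
#' @param peep_levels At least 2 pressures (cmH2O).
#' @param seed RNG seed.
#' @param compartment,condition,phase Tags carried into the output table.
#' @return A data frame with columns `pressure_cmH2O`, `volume`,
#'   `compartment`, `condition`, `phase`.
#' @export
generate_pv_dataset <- function(truth, peep_levels, seed = 1L,
                                compartment = "atelectatic",
                                condition = "healthy",
                                phase = "descending") {
  stopifnot(inherits(truth, "sigmoid_truth"))
  if (length(peep_levels) < 2L) stop("need at least 2 PEEP levels")
  v <- venegas_volume(peep_levels, truth$a, truth$b, truth$c, truth$d)
  if (truth$noise_sd > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, truth$noise_sd)
  }
  data.frame(pressure_cmH2O = as.numeric(peep_levels), volume = v,
             compartment = compartment, condition = condition, phase = phase)
}

#' Generate per-subject physiology titration tables
#'
#' Simulates the long-format titration table the mechanics module consumes:
#' one row per (subject, phase, PEEP, endpoint). Each subject's descending
#' value is the supplied median times multiplicative lognormal noise with
#' log-sd `noise_cv`; the ascending value is the descending value minus
#' `hysteresis_delta` (so descending minus ascending recovers
#' `+hysteresis_delta`). Cells listed in `missing_spec` are blanked to `NA`.
#'
#' @param medians Data frame with columns `endpoint`, `peep_cmH2O`, `value`
#'   giving the median of each endpoint at each PEEP level (an optional
#'   `condition` column is carried through).
#' @param n_subjects Number of subjects to simulate.
#' @param noise_cv Lognormal log-sd of the multiplicative noise (0 = exact
#'   medians).
#' @param missing_spec Optional data frame with columns `subject`, `phase`,
#'   `peep_cmH2O`, `endpoint` naming cells to blank; rows that reference
#'   cells not present in the table are rejected.
#' @param hysteresis_delta Additive descending-minus-ascending offset
#'   applied per endpoint (a single number, recycled).
#' @param seed RNG seed.
#' @return A data frame with columns `subject`, `phase`
#'   (ascending/descending), `peep_cmH2O`, `endpoint`, `value` (and
#'   `condition` if supplied).
#' @export
generate_physiology_table <- function(medians, n_subjects, noise_cv = 0.1,
                                      missing_spec = NULL,
                                      hysteresis_delta = 0, seed = 1L) {
  need <- c("endpoint", "peep_cmH2O", "value")
  if (!is.data.frame(medians) || !all(need %in% names(medians)))
    stop("medians must have columns ", paste(need, collapse = ", "))
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  per_subject <- lapply(seq_len(n_subjects), function(s) {
    noise <- if (noise_cv > 0) stats::rlnorm(nrow(medians), 0, noise_cv) else
      rep(1, nrow(medians))
    desc <- medians
    desc$subject <- s
    desc$phase <- "descending"
    desc$value <- medians$value * noise
    asc <- desc
    asc$phase <- "ascending"
    asc$value <- desc$value - hysteresis_delta
    rbind(asc, desc)
  })
  out <- do.call(rbind, per_subject)
  rownames(out) <- NULL
  front <- c("subject", "phase", "peep_cmH2O", "endpoint")
  out <- out[, c(front, setdiff(names(out), c(front, "value")), "value")]

  if (!is.null(missing_spec)) {
    mneed <- c("subject", "phase", "peep_cmH2O", "endpoint")
    if (!all(mneed %in% names(missing_spec)))
      stop("missing_spec must have columns ", paste(mneed, collapse = ", "))
    key <- function(df) paste(df$subject, df$phase, df$peep_cmH2O,
                              df$endpoint, sep = "\r")
    hit <- match(key(missing_spec), key(out))
    if (anyNA(hit)) {
      bad <- missing_spec[is.na(hit), , drop = FALSE]
      stop("missing_spec references unknown cells: ",
           paste(utils::capture.output(print(bad, row.names = FALSE)),
                 collapse = " "))
    }
    out$value[hit] <- NA_real_
  }
  out
}
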