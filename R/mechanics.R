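#' Derive static respiratory mechanics and oxygenation endpoints
#'
#' Computes, per record, the static two-point elastances and transpulmonary
#' pressures from end-inspiratory/end-expiratory airway and esophageal
#' pressures and tidal volume:
#' \deqn{E_{rs} = (P_{aw,insp} - P_{aw,exp})/V_T, \quad
#'       E_W = (P_{es,insp} - P_{es,exp})/V_T, \quad E_L = E_{rs} - E_W}
#' \deqn{P_{L} = P_{aw} - P_{es} \textrm{ (matched phase)}, \quad
#'       P/F = PaO_2 / FiO_2}
#' `P_aw_exp` is the total end-expiratory airway pressure (set PEEP plus
#' intrinsic PEEP when measured; otherwise set PEEP). The partitioning
#' identity `E_rs = E_W + E_L` holds exactly by construction.
#'
#' @param records Data frame with columns `P_aw_insp`, `P_aw_exp`,
#'   `P_es_insp`, `P_es_exp` (cmH2O), `V_T` (L), and optionally `PaO2`
#'   (mmHg) and `FiO2` (fraction in (0, 1]).
#' @return The input with derived columns `E_rs`, `E_W`, `E_L` (cmH2O/L),
#'   `P_L_insp`, `P_L_exp` (cmH2O) and `pf_ratio` (mmHg; `NA` when blood-gas
#'   inputs are absent).
#' @examples
#' derive_mechanics(data.frame(P_aw_insp = 30, P_aw_exp = 10,
#'                             P_es_insp = 20, P_es_exp = 10, V_T = 0.5,
#'                             PaO2 = 90, FiO2 = 0.6))
#' @export
derive_mechanics <- function(records) {
  need <- c("P_aw_insp", "P_aw_exp", "P_es_insp", "P_es_exp", "V_T")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (any(records$V_T <= 0)) stop("V_T must be > 0 (L)")
  has_gas <- all(c("PaO2", "FiO2") %in% names(records))
  if (has_gas && any(records$FiO2 <= 0 | records$FiO2 > 1))
    stop("FiO2 must lie in (0, 1]")
  records$E_rs <- (records$P_aw_insp - records$P_aw_exp) / records$V_T
  records$E_W <- (records$P_es_insp - records$P_es_exp) / records$V_T
  records$E_L <- records$E_rs - records$E_W
  records$P_L_insp <- records$P_aw_insp - records$P_es_insp
  records$P_L_exp <- records$P_aw_exp - records$P_es_exp
  records$pf_ratio <- if (has_gas) records$PaO2 / records$FiO2 else NA_real_
  records
}

#' Classify lung injury from the P/F ratio
#'
#' Injury is present when the ratio of arterial oxygen tension to inspired
#' oxygen fraction is strictly below 300 mmHg.
#'
#' @param pf_ratio P/F ratio(s), mmHg, >= 0.
#' @return Logical, `TRUE` when injured.
#' @export
classify_injury <- function(pf_ratio) {
  if (any(pf_ratio < 0)) stop("pf_ratio must be >= 0")
  pf_ratio < 300
}

#' Select the best PEEP for a titration target
#'
#' Applies the titration rule to descending-phase values: the PEEP level at
#' which the endpoint is highest (e.g. P/F ratio, gas volume) or lowest
#' (e.g. elastances, atelectatic fraction). Physiology and CT endpoints are
#' measured on the descending limb, so only descending rows enter the
#' selection. When several subjects are present the endpoint is summarized
#' by its median per PEEP level first. Exact ties are broken toward the
#' lowest PEEP (the clinically conservative choice) and flagged.
#'
#' @param table Long titration table with columns `phase`, `peep_cmH2O`,
#'   `endpoint`, `value` (and optionally `subject`, `condition`).
#' @param target Endpoint name to optimize (must be present at every PEEP
#'   level).
#' @param direction `"highest"` or `"lowest"`.
#' @return A list of class `best_peep` with `target`, `direction`,
#'   `peep_cmH2O`, `value` and `tie`.
#' @export
best_peep <- function(table, target, direction = c("highest", "lowest")) {
  direction <- match.arg(direction)
  need <- c("phase", "peep_cmH2O", "endpoint", "value")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  avail <- unique(table$endpoint)
  if (!target %in% avail)
    stop("unknown target '", target, "'; available targets: ",
         paste(sort(avail), collapse = ", "))
  rows <- table[table$phase == "descending" & table$endpoint == target, ,
                drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no descending-phase rows for target '", target, "'")
  peeps <- sort(unique(table$peep_cmH2O))
  med <- vapply(peeps, function(p) {
    v <- rows$value[rows$peep_cmH2O == p]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  if (anyNA(med))
    stop("target '", target, "' is missing at PEEP ",
         paste(peeps[is.na(med)], collapse = ", "),
         " cmH2O after imputation")
  score <- if (direction == "highest") med else -med
  winners <- peeps[score == max(score)]
  structure(list(target = target, direction = direction,
                 peep_cmH2O = min(winners),
                 value = med[match(min(winners), peeps)],
                 tie = length(winners) > 1L),
            class = "best_peep")
}

#' @export
print.best_peep <- function(x, ...) {
  cat(sprintf("Best PEEP for %s (%s): %g cmH2O (value %g)%s\n",
              x$target, x$direction, x$peep_cmH2O, x$value,
              if (x$tie) "  [tie resolved to lowest PEEP]" else ""))
  invisible(x)
}

#' Ascending-descending hysteresis
#'
#' Computes, per (subject, PEEP, endpoint) cell, the descending-minus-
#' ascending difference, and summarizes deltas per (endpoint, PEEP) by
#' median and IQR. Cells lacking one of the two phases are skipped and
#' reported.
#'
#' @param table Long titration table with columns `subject`, `phase`,
#'   `peep_cmH2O`, `endpoint`, `value` (optional `condition` is carried
#'   through and kept separate).
#' @return A list of class `hysteresis` with `deltas` (per-cell data frame
#'   with column `delta`), `summary` (median/IQR per endpoint x PEEP) and
#'   `skipped` (cells missing a phase).
#' @export
hysteresis <- function(table) {
  need <- c("subject", "phase", "peep_cmH2O", "endpoint", "value")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  keys <- c("subject", "peep_cmH2O", "endpoint",
            intersect("condition", names(table)))
  asc <- table[table$phase == "ascending", c(keys, "value")]
  des <- table[table$phase == "descending", c(keys, "value")]
  names(asc)[names(asc) == "value"] <- "ascending"
  names(des)[names(des) == "value"] <- "descending"
  merged <- merge(des, asc, by = keys, all = TRUE)
  ok <- !is.na(merged$ascending) & !is.na(merged$descending)
  skipped <- merged[!ok, keys, drop = FALSE]
  deltas <- merged[ok, , drop = FALSE]
  deltas$delta <- deltas$descending - deltas$ascending
  agg_keys <- deltas[, c("endpoint", "peep_cmH2O"), drop = FALSE]
  summ <- do.call(rbind, lapply(
    split(seq_len(nrow(deltas)), agg_keys, drop = TRUE), function(i) {
      q <- stats::quantile(deltas$delta[i], c(0.25, 0.5, 0.75),
                           names = FALSE, type = 7)
      data.frame(endpoint = deltas$endpoint[i][1],
                 peep_cmH2O = deltas$peep_cmH2O[i][1],
                 n = length(i), q25 = q[1], median = q[2], q75 = q[3])
    }))
  rownames(summ) <- NULL
  structure(list(deltas = deltas, summary = summ, skipped = skipped),
            class = "hysteresis")
}

#' Impute missing titration values from average relative differences
#'
#' For a subject `s` missing endpoint `e` at cell `j` (a PEEP level within a
#' phase and, when present, condition), the imputed value is the mean of the
#' other subjects' observed values at `j` multiplied by the subject's
#' average relative difference
#' \deqn{r_s = \mathrm{mean}_{j'~obs}\left[
#'   e_s(j') / \mathrm{mean}_{others}(e~at~j') \right]}
#' taken over the cells `j'` of the same endpoint (and condition) where `s`
#' was observed. The rule is applied per endpoint. It is a no-op on fully
#' observed tables and scale-equivariant per endpoint.
#'
#' @param table Long titration table with columns `subject`, `phase`,
#'   `peep_cmH2O`, `endpoint`, `value` (optional `condition`), with `NA`
#'   marking missing values; needs >= 2 subjects.
#' @return A list of class `imputation` with `table` (values filled where
#'   possible) and `unimputable` (cells whose preconditions failed, left
#'   `NA`).
#' @export
impute_missing <- function(table) {
  need <- c("subject", "phase", "peep_cmH2O", "endpoint", "value")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (length(unique(table$subject)) < 2L)
    stop("imputation needs at least 2 subjects")
  has_cond <- "condition" %in% names(table)
  grp <- if (has_cond) interaction(table$endpoint, table$condition,
                                   drop = TRUE) else
    factor(table$endpoint)
  cell <- paste(table$phase, table$peep_cmH2O, sep = "\r")
  out <- table
  failed <- integer(0)
  for (g in levels(grp)) {
    gi <- which(grp == g)
    sub <- table[gi, ]
    gcell <- cell[gi]
    others_mean <- function(cl, excl) {
      v <- sub$value[gcell == cl & sub$subject != excl]
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else mean(v)
    }
    miss <- which(is.na(sub$value))
    for (m in miss) {
      s <- sub$subject[m]
      target_mean <- others_mean(gcell[m], s)
      obs <- which(sub$subject == s & !is.na(sub$value))
      ratios <- vapply(obs, function(o) {
        om <- others_mean(gcell[o], s)
        if (is.na(om) || om == 0) NA_real_ else sub$value[o] / om
      }, numeric(1))
      ratios <- ratios[!is.na(ratios)]
      if (is.na(target_mean) || length(ratios) == 0L) {
        failed <- c(failed, gi[m])
      } else {
        out$value[gi[m]] <- target_mean * mean(ratios)
      }
    }
  }
  unimputable <- out[failed, setdiff(names(out), "value"), drop = FALSE]
  rownames(unimputable) <- NULL
  structure(list(table = out, unimputable = unimputable),
            class = "imputation")
}
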