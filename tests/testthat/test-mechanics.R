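mech_record <- function(...) {
  defaults <- list(P_aw_insp = 30, P_aw_exp = 10, P_es_insp = 20,
                   P_es_exp = 10, V_T = 0.5, PaO2 = 90, FiO2 = 0.6)
  args <- utils::modifyList(defaults, list(...))
  do.call(data.frame, args)
}

test_that("elastances follow the static two-point formulas and partition exactly", {
  r <- derive_mechanics(mech_record())
  expect_equal(r$E_rs, 40)
  expect_equal(r$E_W, 20)
  expect_equal(r$E_L, 20)
  expect_equal(r$pf_ratio, 150)
  expect_equal(r$P_L_insp, 10)
  expect_equal(r$P_L_exp, 0)
  # degenerate chest wall: no esophageal swing
  r <- derive_mechanics(mech_record(P_es_insp = 12, P_es_exp = 12))
  expect_equal(r$E_W, 0)
  expect_equal(r$E_L, r$E_rs)
  # identity holds exactly on arbitrary records
  set.seed(2)
  recs <- data.frame(P_aw_insp = runif(50, 20, 60),
                     P_aw_exp = runif(50, 5, 30),
                     P_es_insp = runif(50, 10, 40),
                     P_es_exp = runif(50, 5, 30),
                     V_T = runif(50, 0.2, 0.6))
  out <- derive_mechanics(recs)
  expect_equal(out$E_rs, out$E_W + out$E_L, tolerance = 1e-14)
})

test_that("invalid tidal volume or FiO2 are rejected", {
  expect_error(derive_mechanics(mech_record(V_T = 0)), "V_T")
  expect_error(derive_mechanics(mech_record(FiO2 = 1.2)), "FiO2")
  expect_error(derive_mechanics(mech_record(FiO2 = 0)), "FiO2")
})

test_that("injury classification is a strict threshold at P/F 300", {
  expect_true(classify_injury(299.9))
  expect_false(classify_injury(300))
  expect_true(classify_injury(153))
  expect_error(classify_injury(-1), ">= 0")
})

test_that("best PEEP is the descending-phase argmax/argmin with lowest-PEEP tie-break", {
  tab <- data.frame(subject = 1, phase = "descending",
                    peep_cmH2O = rep(c(5, 12, 17, 22, 27), 2),
                    endpoint = rep(c("E_rs", "pf_ratio"), each = 5),
                    value = c(103, 94, 85, 81, 92, 175, 235, 244, 285, 243))
  r <- best_peep(tab, "E_rs", "lowest")
  expect_equal(r$peep_cmH2O, 22)
  expect_equal(r$value, 81)
  expect_false(r$tie)
  expect_equal(best_peep(tab, "pf_ratio", "highest")$peep_cmH2O, 22)
  # all equal -> lowest PEEP with tie flag
  tie <- tab[tab$endpoint == "E_rs", ]
  tie$value <- 7
  rt <- best_peep(tie, "E_rs", "lowest")
  expect_equal(rt$peep_cmH2O, 5)
  expect_true(rt$tie)
  # invariant under strictly monotone endpoint transformations
  tr <- tab[tab$endpoint == "E_rs", ]
  tr$value <- exp(tr$value / 50)
  expect_equal(best_peep(tr, "E_rs", "lowest")$peep_cmH2O, 22)
  # ascending rows must not influence the choice
  asc <- tab[tab$endpoint == "E_rs", ]
  asc$phase <- "ascending"
  asc$value <- rev(asc$value)
  expect_equal(best_peep(rbind(tab, asc), "E_rs", "lowest")$peep_cmH2O, 22)
})

test_that("best PEEP errors name unknown targets and missing cells", {
  tab <- data.frame(subject = 1, phase = "descending",
                    peep_cmH2O = c(5, 12, 17), endpoint = "E_rs",
                    value = c(100, NA, 90))
  expect_error(best_peep(tab, "nope", "lowest"), "available targets")
  expect_error(best_peep(tab, "E_rs", "lowest"), "missing at PEEP 12")
})

test_that("hysteresis deltas use the descending-minus-ascending convention", {
  tab <- data.frame(subject = rep(1:2, each = 4),
                    phase = rep(c("ascending", "descending"), 4),
                    peep_cmH2O = rep(c(5, 5, 12, 12), 2),
                    endpoint = "pf_ratio",
                    value = c(100, 100, 100, 100, 100, 90, 80, 85))
  h <- hysteresis(tab)
  expect_equal(sort(h$deltas$delta), c(-10, 0, 0, 5))
  expect_equal(h$summary$median[h$summary$peep_cmH2O == 5], -5)
  # identical phases -> all zero
  same <- tab
  same$value <- 42
  expect_true(all(hysteresis(same)$deltas$delta == 0))
  # a missing phase is skipped and reported
  drop1 <- tab[-1, ]
  h2 <- hysteresis(drop1)
  expect_equal(nrow(h2$skipped), 1)
  expect_equal(h2$skipped$subject, 1)
  expect_equal(h2$skipped$peep_cmH2O, 5)
})

test_that("a generated phase offset is recovered as the median hysteresis delta", {
  med <- data.frame(endpoint = "E_rs", peep_cmH2O = c(5, 12, 17, 22, 27),
                    value = c(103, 94, 85, 81, 92))
  tab <- generate_physiology_table(med, n_subjects = 6, noise_cv = 0.08,
                                   hysteresis_delta = 3.5, seed = 21)
  h <- hysteresis(tab)
  expect_equal(h$summary$median, rep(3.5, 5))
})

test_that("imputation is a no-op on fully observed tables and scale-equivariant", {
  med <- data.frame(endpoint = "E_rs", peep_cmH2O = c(5, 12, 17),
                    value = c(100, 90, 85))
  tab <- generate_physiology_table(med, 4, noise_cv = 0.1, seed = 3)
  out <- impute_missing(tab)
  expect_equal(out$table$value, tab$value)
  expect_equal(nrow(out$unimputable), 0)
  # blank one cell; multiplying the endpoint by k scales the imputation by k
  tab$value[7] <- NA
  v1 <- impute_missing(tab)$table$value[7]
  tab_k <- tab
  tab_k$value <- tab_k$value * 3
  expect_equal(impute_missing(tab_k)$table$value[7], 3 * v1)
})

test_that("a subject identical to the others is imputed at the others' mean", {
  tab <- expand.grid(subject = 1:3, phase = "descending",
                     peep_cmH2O = c(5, 12, 17), endpoint = "E_rs",
                     stringsAsFactors = FALSE)
  tab$value <- rep(c(100, 90, 85), each = 3)
  tab$value[tab$subject == 2 & tab$peep_cmH2O == 12] <- NA
  out <- impute_missing(tab)
  expect_equal(out$table$value[is.na(tab$value)], 90)
})

test_that("cells without an observable ratio or donors are reported, not guessed", {
  tab <- expand.grid(subject = 1:2, phase = "descending",
                     peep_cmH2O = c(5, 12), endpoint = "E_rs",
                     stringsAsFactors = FALSE)
  tab$value <- c(100, 110, 90, 95)
  tab$value[tab$subject == 2] <- NA  # subject 2 observed nowhere
  out <- impute_missing(tab)
  expect_equal(nrow(out$unimputable), 2)
  expect_true(all(is.na(out$table$value[tab$subject == 2])))
  expect_error(impute_missing(tab[tab$subject == 1, ]), "2 subjects")
})
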