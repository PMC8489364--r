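test_that("the sigmoid evaluates to a + b/2 at c and approaches its asymptotes", {
  for (par in list(c(0.1, 0.9, 12, 3), c(0.9, -0.8, 10, 2))) {
    a <- par[1]; b <- par[2]; cc <- par[3]; dd <- par[4]
    expect_equal(venegas_volume(cc, a, b, cc, dd), a + b / 2)
    expect_equal(venegas_volume(cc - 50 * dd, a, b, cc, dd), a,
                 tolerance = 1e-9)
    expect_equal(venegas_volume(cc + 50 * dd, a, b, cc, dd), a + b,
                 tolerance = 1e-9)
  }
})

test_that("Venegas parameters are recovered exactly from noiseless data, both signs of b", {
  P <- c(0, 5, 10, 15, 20, 25, 30)
  for (truth in list(c(a = 0.1, b = 0.9, c = 12, d = 3),
                     c(a = 0.9, b = -0.8, c = 10, d = 2))) {
    d <- generate_pv_dataset(sigmoid_truth(truth["a"], truth["b"],
                                           truth["c"], truth["d"]), P)
    fit <- fit_venegas(d)
    expect_true(fit$converged)
    expect_false(fit$degenerate)
    expect_equal(unname(fit$parameters), unname(truth), tolerance = 1e-3)
    expect_gt(fit$parameters["d"], 0)
    expect_rms_definition(fit)
  }
})

test_that("constant-volume data yield a flagged degenerate Venegas fit", {
  d <- data.frame(pressure_cmH2O = c(5, 12, 17, 22, 27), volume = rep(1, 5))
  fit <- fit_venegas(d)
  expect_true(fit$degenerate || !fit$converged)
})

test_that("under-determined inputs are rejected", {
  expect_error(fit_venegas(c(5, 12, 17), c(1, 2, 3)), "4 distinct")
  expect_error(fit_exponential(c(5, 12), c(1, 2)), "3 distinct")
  expect_error(fit_linear(5, 1), "2 distinct")
})

test_that("linear data are fitted exactly and the exponential recovers tau", {
  P <- c(5, 12, 17, 22, 27)
  lf <- fit_linear(P, 2 + 0.5 * P)
  expect_equal(unname(lf$parameters), c(2, 0.5), tolerance = 1e-12)
  expect_lt(lf$rms, 1e-12)
  expect_rms_definition(lf)
  V <- 0.3 + 1.2 * (1 - exp(-P / 8))
  ef <- fit_exponential(P, V)
  expect_equal(unname(ef$parameters["tau"]), 8, tolerance = 1e-3)
  expect_equal(unname(ef$parameters[c("a", "b")]), c(0.3, 1.2),
               tolerance = 1e-3)
  expect_rms_definition(ef)
})

test_that("model selection picks the smallest-RMS converged family", {
  # sigmoid data with mild noise -> venegas
  d <- generate_pv_dataset(sigmoid_truth(0.1, 0.9, 12, 3, noise_sd = 0.018),
                           c(5, 12, 17, 22, 27), seed = 42)
  expect_equal(select_best_model(d)$family, "venegas")
  # pure-line data: sigmoid and exponential degenerate to bound-pinned
  # parameters and are excluded -> linear
  P <- c(5, 12, 17, 22, 27)
  sel <- select_best_model(P, 2 + 0.5 * P)
  expect_equal(sel$family, "linear")
  att <- attr(sel, "attempts")
  expect_true(att$venegas$degenerate || !att$venegas$converged)
  # exponential-generated data -> exponential beats linear and the
  # degenerate-screened venegas cannot shadow an honest smaller RMS
  V <- 0.3 + 1.2 * (1 - exp(-P / 8))
  sel <- select_best_model(P, V)
  expect_true(sel$family %in% c("exponential", "venegas"))
  expect_lt(sel$rms, fit_linear(P, V)$rms)
})

test_that("fits are invariant to pair reordering and equivariant to affine volume rescaling", {
  P <- c(5, 12, 17, 22, 27)
  V <- venegas_volume(P, 0.1, 0.9, 12, 3) + c(0.01, -0.02, 0.015, 0, -0.01)
  f1 <- fit_venegas(P, V)
  shuffle <- c(3, 1, 5, 2, 4)
  f2 <- fit_venegas(P[shuffle], V[shuffle])
  expect_equal(f1$parameters, f2$parameters, tolerance = 1e-6)
  # affine rescale V' = 2V + 1: a' = 2a + 1, b' = 2b, c and d unchanged
  f3 <- fit_venegas(P, 2 * V + 1)
  expect_equal(unname(f3$parameters["a"]),
               unname(2 * f1$parameters["a"] + 1), tolerance = 1e-4)
  expect_equal(unname(f3$parameters["b"]),
               unname(2 * f1$parameters["b"]), tolerance = 1e-4)
  expect_equal(unname(f3$parameters[c("c", "d")]),
               unname(f1$parameters[c("c", "d")]), tolerance = 1e-4)
})

test_that("inflection points are c - 2d and c + 2d, defined only for the sigmoid", {
  d <- generate_pv_dataset(sigmoid_truth(0.1, 0.9, 12, 3),
                           c(0, 5, 10, 15, 20, 25, 30))
  fit <- fit_venegas(d)
  ip <- inflection_points(fit)
  expect_equal(ip$lower, 6, tolerance = 1e-3)
  expect_equal(ip$true_inflection, 12, tolerance = 1e-3)
  expect_equal(ip$upper, 18, tolerance = 1e-3)
  expect_equal(ip$upper - ip$lower, 4 * unname(fit$parameters["d"]),
               tolerance = 1e-9)
  lf <- fit_linear(c(5, 12, 17, 22, 27), 1:5)
  expect_error(inflection_points(lf), "only for a Venegas")
})

test_that("the inflection interval collapses to c as d approaches zero", {
  lower <- function(dd) {
    f <- structure(list(family = "venegas", converged = TRUE,
                        parameters = c(a = 0, b = 1, c = 12, d = dd)),
                   class = c("venegas_fit", "pv_fit"))
    inflection_points(f)
  }
  for (dd in c(1, 1e-3, 1e-9)) {
    ip <- lower(dd)
    expect_equal(ip$upper - ip$lower, 4 * dd)
  }
  expect_equal(lower(1e-12)$lower, 12, tolerance = 1e-9)
})

test_that("the optimal PEEP range takes lower inflections in order and flags ill-formed ranges", {
  mkfit <- function(cc, dd) structure(
    list(family = "venegas", converged = TRUE,
         parameters = c(a = 0, b = 1, c = cc, d = dd)),
    class = c("venegas_fit", "pv_fit"))
  r <- optimal_peep_range(mkfit(13.5, 3), mkfit(20.9, 3))
  expect_equal(r$low, 7.5)
  expect_equal(r$high, 14.9)
  expect_true(r$well_formed)
  # identical fits give a zero-width, well-formed range
  r0 <- optimal_peep_range(mkfit(12, 3), mkfit(12, 3))
  expect_equal(r0$low, r0$high)
  expect_true(r0$well_formed)
  # never silently swapped
  rb <- optimal_peep_range(mkfit(25, 3), mkfit(10, 3))
  expect_false(rb$well_formed)
  expect_gt(rb$low, rb$high)
  lf <- fit_linear(c(5, 12, 17, 22, 27), 1:5)
  expect_error(optimal_peep_range(lf, mkfit(12, 3)), "only for a Venegas")
})

test_that("fractional-volume rescaling maps the PEEP-range endpoints to 0 and 1", {
  d <- generate_pv_dataset(sigmoid_truth(0.1, 0.9, 12, 3),
                           c(5, 12, 17, 22, 27))
  fr <- as_fractional_volumes(d)
  expect_equal(fr$volume[1], 0)
  expect_equal(fr$volume[5], 1)
  # c and d are unchanged by the (affine) rescaling
  expect_equal(unname(fit_venegas(fr)$parameters[c("c", "d")]),
               unname(fit_venegas(d)$parameters[c("c", "d")]),
               tolerance = 1e-4)
  expect_error(as_fractional_volumes(
    data.frame(pressure_cmH2O = c(5, 27), volume = c(1, 1))), "undefined")
})
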