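release_times <- c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24)

test_that("eval_model implements both model forms and their bounds", {
  ## Peppas-Sahlin reduces to a pure line for k2 = 0, m = 1
  expect_equal(eval_model("PS", c(k1 = 2, k2 = 0, m = 1), c(0, 1, 3)),
               c(0, 2, 6))
  ## t^n = 1 at t = 1 for the power-law model
  expect_equal(eval_model("KP_F0", c(F0 = 0, K_KP = 26.2569, n = 0.1183), 1),
               26.2569)
  ## scalar-arithmetic oracle at t = 4 h
  expect_equal(eval_model("PS", c(k1 = 5.1761, k2 = -0.2349, m = 0.83), 4),
               5.1761 * 4^0.83 - 0.2349 * 4^1.66, tolerance = 1e-12)
  ## out-of-bound parameters are rejected
  expect_error(eval_model("PS", c(k1 = 1, k2 = 1, m = 1.2), 1),
               "invalid parameters")
  expect_error(eval_model("KP_F0", c(F0 = -1, K_KP = 1, n = 0.5), 1),
               "invalid parameters")
  expect_error(eval_model("KP_F0", c(F0 = 0, K_KP = 1, n = 2.5), 1),
               "invalid parameters")
})

test_that("goodness_of_fit matches the hand-arithmetic oracle and flags edge cases", {
  g <- goodness_of_fit(c(1, 2, 3), c(1.1, 2.0, 2.9), p = 3)
  expect_equal(g$wss, 0.02, tolerance = 1e-12)
  expect_equal(g$r_squared, 0.99, tolerance = 1e-12)
  expect_equal(g$aic, 3 * log(0.02) + 6, tolerance = 1e-12)
  expect_equal(g$msc, log(100) - 2, tolerance = 1e-12)

  perf <- goodness_of_fit(c(1, 2, 3, 4), c(1, 2, 3, 4), p = 3)
  expect_equal(perf$r_squared, 1)
  expect_identical(perf$aic, -Inf)
  expect_identical(perf$msc, Inf)

  expect_error(goodness_of_fit(rep(2, 5), rep(2.1, 5), p = 3),
               "degenerate observations")
  ## independent recomputation of r2 = 1 - WSS/SST
  withr::with_seed(11, {
    for (i in 1:10) {
      obs <- runif(8, 0, 100); pred <- obs + rnorm(8, 0, 2)
      g <- goodness_of_fit(obs, pred, p = 3)
      expect_equal(g$r_squared,
                   1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
                   tolerance = 1e-12)
    }
  })
})

test_that("AIC, MSC and WSS rankings coincide for equal N and p", {
  withr::with_seed(21, {
    for (i in 1:20) {
      obs <- runif(9, 0, 100)
      g1 <- goodness_of_fit(obs, obs + rnorm(9, 0, 3), p = 3)
      g2 <- goodness_of_fit(obs, obs + rnorm(9, 0, 3), p = 3)
      expect_identical(g1$wss < g2$wss, g1$aic < g2$aic)
      expect_identical(g1$wss < g2$wss, g1$msc > g2$msc)
    }
  })
})

test_that("noiseless round trips recover every published Peppas-Sahlin row", {
  kin <- reference_kinetics()
  ps <- kin[kin$model_id == "PS", ]
  for (i in seq_len(nrow(ps))) {
    truth <- c(k1 = ps$k1[i], k2 = ps$k2[i], m = ps$m[i])
    prof <- simulate_dissolution("PS", truth, release_times,
                                 formulation_id = ps$formulation_id[i])
    fit <- fit_model(prof, "PS")
    expect_lt(fit$wss, 1e-8)
    expect_equal(unname(fit$parameters), unname(truth), tolerance = 1e-3)
  }
  ## and one power-law row
  kp <- kin[kin$model_id == "KP_F0" & kin$formulation_id == "IP30E", ]
  truth <- c(F0 = kp$F0, K_KP = kp$K_KP, n = kp$n)
  fit <- fit_model(simulate_dissolution("KP_F0", truth, release_times), "KP_F0")
  expect_lt(fit$wss, 1e-8)
  expect_equal(unname(fit$parameters), unname(truth), tolerance = 1e-3)
})

test_that("fit_model matches a brute-force exponent-grid oracle on a toy profile", {
  tt <- c(0.5, 1, 2, 4)
  y <- 2.0 * tt^0.6 + 0.5 * tt^1.2 + c(0.3, -0.2, 0.1, -0.1)
  prof <- dissolution_profile(tt, y)
  fit <- fit_model(prof, "PS")
  ## oracle: exhaustive 1e-3 grid over the nonlinear exponent, exact linear
  ## least squares (lm) for k1, k2 at each grid point
  oracle_wss <- min(vapply(seq(0.001, 1, by = 0.001), function(m) {
    sum(resid(lm(y ~ 0 + I(tt^m) + I(tt^(2 * m))))^2)
  }, numeric(1)))
  expect_lt(fit$wss, oracle_wss + 1e-6)
})

test_that("k1 recovery is unbiased under 1% noise (200 seeded replicates)", {
  truth <- c(k1 = 5.1761, k2 = -0.2349, m = 0.83)
  k1s <- vapply(1:200, function(i) {
    prof <- simulate_dissolution("PS", truth, release_times,
                                 noise_sd = 1, seed = 3000 + i)
    fit_model(prof, "PS")$parameters[["k1"]]
  }, numeric(1))
  se <- sd(k1s) / sqrt(length(k1s))
  expect_lt(abs(mean(k1s) - truth[["k1"]]), 3 * se)
})

test_that("fit_model input contracts", {
  expect_error(fit_model(dissolution_profile(c(0, 1, 2, 4), c(0, 10, 20, 30)),
                         "PS"),
               "underdetermined")  # t = 0 excluded leaves 3 points
})

test_that("select_model follows the three criteria and flags ties", {
  prof <- simulate_dissolution("PS", c(k1 = 5.1761, k2 = -0.2349, m = 0.83),
                               release_times)
  ps <- fit_model(prof, "PS")
  kp <- fit_model(prof, "KP_F0")
  best <- select_model(list(kp, ps))
  expect_identical(best$model_id, "PS")
  expect_false(attr(best, "criteria_disagree"))
  ## the generating model wins on power-law data too
  prof2 <- simulate_dissolution("KP_F0", c(F0 = 5, K_KP = 10, n = 0.4),
                                release_times)
  best2 <- select_model(list(fit_model(prof2, "KP_F0"),
                             fit_model(prof2, "PS")))
  expect_identical(best2$model_id, "KP_F0")
  ## published selection pattern: higher r2 / lower AIC / higher MSC wins
  f1 <- structure(list(model_id = "KP_F0", r_squared = 0.9956,
                       aic = 20.4575, msc = 3.8429), class = "model_fit")
  f2 <- structure(list(model_id = "PS", r_squared = 0.9973,
                       aic = 16.1655, msc = 4.2330), class = "model_fit")
  expect_identical(select_model(list(f1, f2))$model_id, "PS")
  ## identical fits tie, first returned
  tied <- select_model(list(f2, f2))
  expect_true(attr(tied, "tie"))
  expect_identical(tied$model_id, "PS")
  expect_error(select_model(list(f1)), "at least 2 fits")
})

test_that("mechanism classification follows the sign and size of k1, k2", {
  mk_ps <- function(k1, k2) structure(
    list(model_id = "PS", parameters = c(k1 = k1, k2 = k2, m = 0.5),
         formulation_id = "x"), class = "model_fit")
  m1 <- classify_mechanism(mk_ps(31.4441, -5.3375))
  expect_identical(m1$label, "diffusion_dominant")
  expect_equal(m1$dissolution_rate_k, 31.4441)
  m2 <- classify_mechanism(mk_ps(-0.2924, 0.3694))
  expect_identical(m2$label, "erosion_relaxation_dominant")
  expect_equal(m2$dissolution_rate_k, 0.3694)
  m3 <- classify_mechanism(mk_ps(1, 1))
  expect_identical(m3$label, "mixed")
  expect_equal(m3$dissolution_rate_k, 1)
  expect_warning(m4 <- classify_mechanism(mk_ps(-1, -2)), "no positive k")
  expect_equal(m4$dissolution_rate_k, 0)
  kp <- structure(list(model_id = "KP_F0",
                       parameters = c(F0 = 0.2, K_KP = 1, n = 0.5)),
                  class = "model_fit")
  expect_error(classify_mechanism(kp), "not a Peppas-Sahlin fit")
  ## burst flag comes from the companion power-law fit's F0
  m5 <- classify_mechanism(mk_ps(2, 1), kp_fit = kp)
  expect_true(m5$burst)
})

test_that("dissolution profile validation", {
  expect_error(dissolution_profile(c(1, 1, 2, 3), c(0, 1, 2, 3)),
               "bad time axis")
  expect_error(dissolution_profile(1:4, c(0, 10, 120, 30)), "released")
  expect_error(simulate_dissolution("PS", c(k1 = 1, k2 = 0, m = 0.5),
                                    c(2, 1), 0), "bad time axis")
})
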