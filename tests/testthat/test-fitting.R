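test_that("noiseless synthetic TACs are recovered exactly", {
  truth <- frame_average(lncap_rc(), default_cp(), full_sched())
  fit <- fit_tac(truth, default_cp())
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  rel <- abs(coef(fit) - rc_vector(lncap_rc())) / rc_vector(lncap_rc())
  expect_true(all(rel < 5e-3))
  expect_lt(fit$wrss, 1e-12)
})

test_that("recovery holds across a grid of generating constants", {
  # spans the PSMA+ / PSMA- parameter ranges
  grid <- expand.grid(K1 = c(0.05, 0.12, 0.25),
                      k2 = c(0.10, 0.18, 0.30),
                      k3 = c(0.008, 0.08, 0.20),
                      k4 = c(0.004, 0.02, 0.061))
  for (i in seq_len(nrow(grid))) {
    rc <- rate_constants(grid$K1[i], grid$k2[i], grid$k3[i], grid$k4[i])
    truth <- frame_average(rc, default_cp(), full_sched())
    fit <- fit_tac(truth, default_cp())
    rel <- abs(coef(fit) - rc_vector(rc)) / rc_vector(rc)
    expect_true(all(rel < 5e-3),
                info = sprintf("grid row %d: max rel err %.2g", i, max(rel)))
  }
})

test_that("a nested one-compartment truth yields a vanishing k3", {
  rc1 <- rate_constants(0.2, 0.3, 0, 0)
  truth <- frame_average(rc1, default_cp(), full_sched())
  fit2 <- fit_tac(truth, default_cp())
  expect_lte(coef(fit2)["k3"], 1e-3)
  expect_equal(coef(fit2)[["K1"]], 0.2, tolerance = 5e-3)

  # and the one-compartment fit recovers it exactly
  fit1 <- fit_tac(truth, default_cp(), model = "1tc")
  expect_equal(unname(coef(fit1)), c(0.2, 0.3), tolerance = 5e-3)
  # nested models: richer fit can never do worse (epsilon absorbs
  # floating-point noise when both objectives sit at machine zero)
  expect_lte(fit2$wrss, fit1$wrss * (1 + 1e-8) + 1e-20)
})

test_that("an all-zero TAC is flagged degenerate at the K1 bound", {
  zeros <- tac(full_sched(), rep(0, 53))
  fit <- fit_tac(zeros, default_cp())
  expect_true(fit$degenerate)
  expect_lte(coef(fit)[["K1"]], 2e-6)
  expect_error(fit_tac(tac(full_sched(), c(NA, rep(1, 52))), default_cp()),
               "non-finite")
})

test_that("fit is deterministic and start-order invariant", {
  noisy <- add_noise(frame_average(lncap_rc(), default_cp(), full_sched()),
                     0.05, seed = 5)
  f1 <- fit_tac(noisy, default_cp())
  f2 <- fit_tac(noisy, default_cp())
  expect_identical(coef(f1), coef(f2))
  # permuting the rows of the start design must not change the solution
  starts <- tacfit:::.start_grid(4L, 20L)
  perm <- starts[c(11:20, 1:10), ]
  f3 <- fit_tac(noisy, default_cp(), starts = perm)
  expect_equal(coef(f1), coef(f3), tolerance = 1e-8)
})

test_that("optimizer objective decreases along the accepted trace", {
  noisy <- add_noise(frame_average(lncap_rc(), default_cp(), full_sched()),
                     0.05, seed = 17)
  fit <- fit_tac(noisy, default_cp())
  expect_true(all(diff(fit$trace) <= 1e-10 * fit$trace[1]))
})

test_that("standard errors scale sensibly and cover the truth", {
  noisy <- add_noise(frame_average(lncap_rc(), default_cp(), full_sched()),
                     0.03, seed = 23)
  fit <- fit_tac(noisy, default_cp())
  expect_true(all(is.finite(fit$se)))
  expect_true(all(fit$se > 0))
  v <- vcov(fit)
  expect_equal(sqrt(diag(v)), fit$se, tolerance = 1e-8)
})

test_that("model selection uses AICc and prefers truth-generating models", {
  truth2 <- frame_average(lncap_rc(), default_cp(), full_sched())
  noisy2 <- add_noise(truth2, 0.05, seed = 3)
  f2 <- fit_tac(noisy2, default_cp(), model = "2tc")
  f1 <- fit_tac(noisy2, default_cp(), model = "1tc")
  sel <- select_model(f1, f2)
  expect_identical(sel$model, "2tc")
  # AICc definition check against direct arithmetic
  n <- 53; p <- 4
  expect_equal(f2$aicc, n * log(f2$wrss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1))
  # F-test variant returns a valid comparison
  self <- select_model(f1, f2, method = "ftest")
  expect_true(self$p_value >= 0 && self$p_value <= 1)
})

test_that("model selection refuses degenerate sample sizes and breaks ties", {
  cp <- default_cp()
  truth <- frame_average(lncap_rc(), cp, full_sched())
  f2 <- fit_tac(truth, cp, model = "2tc", n_starts = 4)
  f1 <- fit_tac(truth, cp, model = "1tc", n_starts = 4)

  # refusal contract: n must exceed p + 1 for the richer model
  fa <- f2; fb <- f2
  fa$n_frames <- fb$n_frames <- 5L
  expect_error(select_model(fa, fb), "too few frames")

  # exact AICc tie: the simpler model wins deterministically
  f2_tied <- f2
  f2_tied$aicc <- f1$aicc
  sel <- select_model(f1, f2_tied)
  expect_identical(sel$model, "1tc")
})

test_that("fit methods expose predictions, residuals and simulations", {
  truth <- frame_average(lncap_rc(), default_cp(), full_sched())
  fit <- fit_tac(truth, default_cp(), n_starts = 6)
  expect_equal(fitted(fit), truth$value, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  pred <- predict(fit, short_sched())
  expect_s3_class(pred, "tac")
  expect_equal(nrow(pred), 17L)
  inst <- predict(fit, c(1, 10, 30))
  expect_equal(inst, tissue_curve(fit$estimates, default_cp(), c(1, 10, 30)))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3L)
  expect_identical(simulate(fit, nsim = 3, seed = 1)[[2]]$value,
                   sims[[2]]$value)
})

test_that("noiseless recovery study reports zero bias", {
  rep0 <- recovery_study(lncap_rc(), default_cp(), full_sched(),
                         noise_scales = 0, n_reps = 3, seed = 2,
                         n_starts = 6)
  expect_true(all(abs(rep0$summary$rel_bias) < 5e-3))
  expect_true(all(rep0$summary$n_fail == 0))
})
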