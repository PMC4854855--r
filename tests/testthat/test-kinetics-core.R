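test_that("rate-constant validation rejects invalid parameters", {
  expect_error(rate_constants(-0.1, 0.2, 0.1, 0.01), "nonnegative")
  expect_error(rate_constants(0.1, 0.2, 0.1, 0.01, vb = 1), "vb")
  expect_error(rate_constants(NA, 0.2, 0.1, 0.01), "finite")
  expect_silent(rate_constants(0, 0, 0, 0))
})

test_that("macro-parameters match the closed-form quadratic roots", {
  # one-compartment limit: k3 = k4 = 0 collapses onto (0, k2) with all
  # amplitude on the fast term
  mp <- macro_parameters(rate_constants(1, 0.5, 0, 0))
  expect_equal(mp$alpha1, 0)
  expect_equal(mp$alpha2, 0.5)
  expect_equal(mp$theta1, 0)
  expect_equal(mp$theta2, 1)

  # quadratic-root evaluation at the LNCaP-like constants; expected values
  # frozen from an independent polynomial-root oracle,
  # polyroot(c(k2*k4, -(k2+k3+k4), 1)) -> 0.002756045, 0.261243955
  mp <- macro_parameters(lncap_rc())
  expect_equal(mp$alpha1, 0.002756045, tolerance = 1e-6)
  expect_equal(mp$alpha2, 0.261243955, tolerance = 1e-6)
  expect_equal(mp$theta1 + mp$theta2, 0.12, tolerance = 1e-12)

  # irreversible trapping: product of roots is k2*k4 = 0
  mp <- macro_parameters(rate_constants(0.2, 0.3, 0.1, 0))
  expect_identical(mp$alpha1, 0)
})

test_that("root identities hold across random draws", {
  set.seed(11)
  for (i in 1:50) {
    rc <- rate_constants(runif(1, 0.01, 1), runif(1, 0.01, 1),
                         runif(1, 0.001, 0.5), runif(1, 0.001, 0.3))
    mp <- macro_parameters(rc)
    expect_true(mp$alpha1 <= mp$alpha2)
    expect_equal(mp$alpha1 * mp$alpha2, rc$k2 * rc$k4, tolerance = 1e-10)
    expect_equal(mp$alpha1 + mp$alpha2, rc$k2 + rc$k3 + rc$k4,
                 tolerance = 1e-10)
    expect_equal(mp$theta1 + mp$theta2, rc$K1, tolerance = 1e-10)
  }
})

test_that("repeated-root degeneracy is handled analytically", {
  # (k2 + k3 + k4)^2 = 4 k2 k4 forces a double root: pick k3 = 0, k2 = k4
  rc <- rate_constants(0.1, 0.2, 0, 0.2)
  mp <- macro_parameters(rc)
  expect_true(mp$repeated)
  expect_equal(mp$alpha1, mp$alpha2)
  # impulse response stays finite and continuous around the degeneracy
  h_deg <- tissue_impulse_response(rc, c(0, 1, 5, 20))
  rc_near <- rate_constants(0.1, 0.2, 1e-4, 0.2)
  h_near <- tissue_impulse_response(rc_near, c(0, 1, 5, 20))
  expect_equal(h_deg, h_near, tolerance = 1e-2)
})

test_that("impulse response has the biexponential structure", {
  set.seed(21)
  for (i in 1:10) {
    rc <- rate_constants(runif(1, 0.01, 1), runif(1, 0.01, 1),
                         runif(1, 0, 0.5), runif(1, 0, 0.3))
    expect_equal(tissue_impulse_response(rc, 0), rc$K1)
  }
  # irreversible plateau: with k4 = 0 the trapped-flux term persists
  rc <- rate_constants(0.3, 0.25, 0.1, 0)
  mp <- macro_parameters(rc)
  expect_equal(tissue_impulse_response(rc, 1e4), mp$theta1, tolerance = 1e-10)

  # direct scalar evaluation at t = 10 min for the LNCaP-like constants
  mp <- macro_parameters(lncap_rc())
  expected <- mp$theta1 * exp(-mp$alpha1 * 10) + mp$theta2 * exp(-mp$alpha2 * 10)
  expect_equal(tissue_impulse_response(lncap_rc(), 10), expected)
  expect_error(tissue_impulse_response(lncap_rc(), -1), "nonnegative")
})

test_that("derived metrics reproduce the published worked ratios", {
  lncap <- derived_metrics(rate_constants(0.12, 0.18, 0.082, 0.004))
  expect_equal(lncap$retention_ratio, 20.5)
  pc3 <- derived_metrics(rate_constants(0.10, 0.10 / 0.49, 0.008, 0.061))
  expect_equal(round(pc3$retention_ratio, 2), 0.13)

  # no binding: both ratios vanish
  none <- derived_metrics(rate_constants(0.1, 0.2, 0, 0.01))
  expect_equal(none$binding_fraction, 0)
  expect_equal(none$retention_ratio, 0)

  # flagged infinities rather than errors
  irr <- derived_metrics(rate_constants(0.1, 0.2, 0.05, 0))
  expect_true(irr$infinite_retention)
  expect_identical(irr$retention_ratio, Inf)
})

test_that("distribution volume dominates the delivery ratio", {
  set.seed(31)
  for (i in 1:25) {
    rc <- rate_constants(runif(1, 0.01, 1), runif(1, 0.01, 1),
                         runif(1, 0, 0.5), runif(1, 1e-4, 0.3))
    dm <- derived_metrics(rc)
    expect_gte(dm$vt, dm$delivery_ratio)
    expect_true(dm$binding_fraction >= 0 && dm$binding_fraction <= 1)
  }
})
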