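test_that("SUV follows its normalization definition", {
  # concentration equal to dose per gram gives SUV 1
  expect_equal(as.numeric(suv(250, injected_mbq = 5, body_weight_g = 20)), 1)
  expect_equal(as.numeric(suv(0, 5, 20)), 0)
  expect_equal(as.numeric(suv(100, 5, 20)), 0.4)
  expect_error(suv(100, 0, 20), "positive")
  expect_error(suv(-1, 5, 20), "nonnegative")
})

test_that("uptake ratios reproduce the worked tumor contrast", {
  expect_equal(tumor_to_reference(1.1, 0.1), 11)
  expect_equal(tumor_to_reference(0.7, 0.7), 1)
  expect_equal(tumor_to_reference(0, 2), 0)
  expect_error(tumor_to_reference(1, 0), "positive")
})

test_that("blocking reduction reproduces the worked percentage", {
  expect_equal(blocking_reduction(1.1, 0.22), 80)
  expect_equal(blocking_reduction(0.8, 0.8), 0)
  expect_equal(blocking_reduction(0.8, 0), 100)
  expect_error(blocking_reduction(0, 0.1), "positive")
})

test_that("ratio metrics are scale invariant", {
  set.seed(51)
  for (i in 1:20) {
    a <- runif(1, 0.1, 3); b <- runif(1, 0.01, a); c <- runif(1, 0.5, 10)
    expect_equal(tumor_to_reference(c * a, c * b), tumor_to_reference(a, b))
    expect_equal(blocking_reduction(c * a, c * b), blocking_reduction(a, b))
  }
})

test_that("internalized fraction matches the published cell data", {
  # PSMA+ cells: 45.47 membrane-bound vs 35.05 internalized
  f <- internalized_fraction(45.47, 35.05)
  expect_equal(f, 43.53, tolerance = 1e-4)
  expect_equal(round(f), 44)
  # PSMA- cells: 4.30 vs 0.76
  expect_equal(internalized_fraction(4.30, 0.76), 15.0, tolerance = 1e-2)
  expect_equal(internalized_fraction(0, 5), 100)
  expect_error(internalized_fraction(0, 0), "positive")
})

test_that("membrane and internalized fractions partition exactly", {
  set.seed(61)
  for (i in 1:20) {
    m <- runif(1, 0, 50); int <- runif(1, 0.1, 50)
    expect_equal(internalized_fraction(m, int) + internalized_fraction(int, m),
                 100)
  }
})

test_that("per-mg normalization follows its definition", {
  expect_equal(percent_of_total_per_mg(100, 100, 1), 100)
  expect_equal(percent_of_total_per_mg(50, 100, 2), 25)
  expect_equal(percent_of_total_per_mg(0, 100, 1), 0)
  expect_error(percent_of_total_per_mg(10, 0, 1), "positive")
  expect_error(percent_of_total_per_mg(10, 100, 0), "positive")
})

test_that("summary t test matches the hand-computed pooled oracle", {
  # published blocking summaries: 1.1 +/- 0.1 (n=5) vs 0.2 +/- 0.05 (n=4)
  res <- unpaired_t_from_summary(1.1, 0.1, 5, 0.2, 0.05, 4)
  expect_equal(res$t, 7.40, tolerance = 1e-2)
  expect_equal(res$df, 7)
  expect_lt(res$p, 0.05)
  # symmetry under group swap
  swap <- unpaired_t_from_summary(0.2, 0.05, 4, 1.1, 0.1, 5)
  expect_equal(swap$p, res$p)
  expect_equal(swap$t, -res$t)
  # identical groups
  same <- unpaired_t_from_summary(1, 0.1, 5, 1, 0.1, 5)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(unpaired_t_from_summary(1, 0.1, 1, 1, 0.1, 5), "n >= 2")
})

test_that("summary t test agrees with t.test on reconstructed samples", {
  # build raw samples whose mean/SEM equal the summaries exactly, then let
  # stats::t.test be the oracle for both variants
  make_sample <- function(n, m, sem) {
    z <- as.numeric(scale(stats::rnorm(n)))
    m + sem * sqrt(n) * z
  }
  set.seed(71)
  for (i in 1:10) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    m1 <- runif(1, 0, 2); m2 <- runif(1, 0, 2)
    s1 <- runif(1, 0.02, 0.3); s2 <- runif(1, 0.02, 0.3)
    x <- make_sample(n1, m1, s1); y <- make_sample(n2, m2, s2)
    pooled <- unpaired_t_from_summary(m1, s1, n1, m2, s2, n2)
    ref_p <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$t, unname(ref_p$statistic), tolerance = 1e-8)
    expect_equal(pooled$p, ref_p$p.value, tolerance = 1e-8)
    welch <- unpaired_t_from_summary(m1, s1, n1, m2, s2, n2, variant = "welch")
    ref_w <- stats::t.test(x, y)
    expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-8)
    expect_equal(welch$p, ref_w$p.value, tolerance = 1e-8)
  }
})

test_that("assay tables summarize per condition", {
  wells <- data.frame(
    well = paste0("A", 1:6),
    condition = rep(c("LNCaP", "PC3"), each = 3),
    membrane_counts = c(4540, 4550, 4551, 430, 425, 435),
    internalized_counts = c(3500, 3510, 3505, 76, 75, 77),
    protein_mg = rep(1, 6),
    total_counts = rep(1e4, 6))
  out <- internalization_summary(wells)
  expect_equal(nrow(out), 2L)
  ln <- out[out$condition == "LNCaP", ]
  expect_equal(ln$membrane_mean, 45.47, tolerance = 1e-3)
  expect_equal(ln$internalized_fraction,
               internalized_fraction(ln$membrane_mean, ln$internalized_mean))
  expect_equal(ln$internalized_fraction_report, 44)
  pc <- out[out$condition == "PC3", ]
  expect_equal(pc$internalized_fraction, 15.03, tolerance = 1e-2)
})
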