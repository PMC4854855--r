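# shared fixtures: the LNCaP-like generating constants, the default bolus,
# and the 60-min 53-frame acquisition schedule

lncap_rc <- function() rate_constants(0.12, 0.18, 0.08, 0.004)
pc3_rc <- function() make_scenario("PC3")$rc

default_cp <- function() feng_input()

full_sched <- function() parse_frame_spec("10x2,8x5,6x10,6x20,8x60,10x120,5x300")
short_sched <- function() parse_frame_spec("6x10,6x60,5x300")

# relative error with the denominator floored at a fraction of the curve
# peak, so frames where the true value is (numerically) zero compare on an
# absolute scale instead of dividing roundoff by roundoff
rel_err_floored <- function(x, ref, floor_frac = 1e-3) {
  max(abs(x - ref) / pmax(abs(ref), floor_frac * max(abs(ref))))
}

# independent oracle: integrate the two-tissue ODE system
#   C1' = K1 Cp - (k2 + k3) C1 + k4 C2
#   C2' = k3 C1 - k4 C2
# with a stiff solver and return total tissue concentration at `times`
ode_tissue <- function(rc, cp, times, rtol = 1e-10, atol = 1e-12) {
  deriv <- function(t, y, parms) {
    cpv <- eval_input(cp, t)
    list(c(rc$K1 * cpv - (rc$k2 + rc$k3) * y[1] + rc$k4 * y[2],
           rc$k3 * y[1] - rc$k4 * y[2]))
  }
  out <- deSolve::lsoda(c(0, 0), times = sort(unique(c(0, times))),
                        func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  tot <- out[, 2] + out[, 3]
  (1 - rc$vb) * tot[match(times, out[, 1])] + rc$vb * eval_input(cp, times)
}
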