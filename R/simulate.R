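# Observation model: C_T(t) = (1 - vb) * (h (*) Cp)(t) + vb * Cp(t).
# Whole blood serves directly as the model input (the tracers this package
# targets show negligible plasma protein binding and no circulating
# radiometabolites); `plasma_fraction` is a hook for users who do have a
# plasma correction, applied as a constant multiplier on the input.

# closed-form tissue curve terms for a parametric input (shares the input's
# delay, returned as attribute "t0")
tissue_terms <- function(rc, cp) {
  stopifnot(inherits(cp, "input_parametric"))
  conv <- es_convolve(impulse_terms(rc), cp$terms)
  if (rc$vb > 0) {
    blood <- cp$terms
    blood$coef <- blood$coef * rc$vb / (1 - rc$vb)  # rescaled below
    conv <- es_simplify(es_append(conv, blood))
  }
  conv$coef <- conv$coef * (1 - rc$vb)
  attr(conv, "t0") <- cp$t0
  conv
}

#' Instantaneous tissue concentration under the two-tissue model
#'
#' Evaluates the model tissue curve
#' \deqn{C_T(t) = (1 - v_b)\,(h \otimes C_p)(t) + v_b\,C_p(t)}
#' at arbitrary times. For a parametric ([feng_input]) input the convolution
#' with the biexponential impulse response is evaluated in closed form; for
#' a sampled input it falls back to trapezoidal quadrature on a fine uniform
#' grid.
#'
#' @param rc a [rate_constants] object (its `vb` enters the observation
#'   model).
#' @param cp an `input_fn`.
#' @param t times in minutes, `>= 0`.
#' @param plasma_fraction constant plasma-to-whole-blood scaling applied to
#'   the input before convolution; defaults to 1 (whole blood as input).
#' @param dt quadrature step (min) for the sampled-input path.
#' @return Tissue concentrations at `t` (input concentration units).
#' @examples
#' rc <- rate_constants(0.12, 0.18, 0.08, 0.004)
#' tissue_curve(rc, feng_input(), c(1, 10, 30, 57))
#' @export
tissue_curve <- function(rc, cp, t, plasma_fraction = 1, dt = 1 / 120) {
  stopifnot(inherits(rc, "rate_constants"), inherits(cp, "input_fn"))
  if (any(t < 0)) stop("times must be nonnegative", call. = FALSE)
  if (inherits(cp, "input_parametric")) {
    terms <- tissue_terms(rc, cp)
    return(plasma_fraction * es_eval(terms, t - attr(terms, "t0")))
  }
  g <- conv_grid(rc, cp, t_max = max(t, dt), dt = dt)
  plasma_fraction * stats::approx(g$t, g$ct, xout = t, rule = 2)$y
}

# brute-force convolution of the impulse response with an arbitrary input on
# a uniform grid (trapezoidal rule); also the numerical oracle against which
# the closed-form path is validated
conv_grid <- function(rc, cp, t_max, dt = 1 / 120) {
  tg <- seq(0, t_max + dt, by = dt)
  n <- length(tg)
  cpv <- eval_input(cp, tg)
  hv <- es_eval(impulse_terms(rc), tg)
  conv <- stats::convolve(cpv, rev(hv), type = "open")[seq_len(n)] * dt
  # Riemann -> trapezoid endpoint correction
  conv <- conv - dt / 2 * (cpv[1L] * hv + cpv * hv[1L])
  conv[1L] <- 0
  ct <- (1 - rc$vb) * conv + rc$vb * cpv
  list(t = tg, ct = pmax(ct, 0))
}

#' Frame-averaged time-activity curve predicted by the model
#'
#' Computes the model TAC on an acquisition schedule: each frame value is
#' the time-average \eqn{\frac{1}{\Delta t_i}\int_{t_i}^{t_i+\Delta t_i}
#' C_T(t)\,dt} of the instantaneous tissue curve over the frame, matching
#' how framed PET data are formed. Frame integrals are exact
#' (antiderivatives of the exponential-polynomial closed form) for
#' parametric inputs and trapezoidal on a fine grid otherwise.
#'
#' @inheritParams tissue_curve
#' @param schedule a [frame_schedule].
#' @param method `"auto"` (closed form when available), `"closed"`, or
#'   `"grid"` (force quadrature; used for cross-validation).
#' @return A [tac] with one frame-averaged value per frame.
#' @examples
#' rc <- rate_constants(0.12, 0.18, 0.08, 0.004)
#' sched <- parse_frame_spec("10x2,8x5,6x10,6x20,8x60,10x120,5x300")
#' frame_average(rc, feng_input(), sched)
#' @export
frame_average <- function(rc, cp, schedule, method = c("auto", "closed", "grid"),
                          plasma_fraction = 1, dt = 1 / 120) {
  stopifnot(inherits(rc, "rate_constants"), inherits(cp, "input_fn"),
            inherits(schedule, "frame_schedule"))
  method <- match.arg(method)
  closed_ok <- inherits(cp, "input_parametric")
  if (method == "closed" && !closed_ok)
    stop("closed-form frame averaging requires a parametric input", call. = FALSE)
  use_closed <- closed_ok && method != "grid"
  lo_min <- schedule$start_s / 60
  hi_min <- schedule$end_s / 60
  if (use_closed) {
    terms <- tissue_terms(rc, cp)
    t0 <- attr(terms, "t0")
    ints <- es_integrate(terms, lo_min - t0, hi_min - t0)
  } else {
    g <- conv_grid(rc, cp, t_max = max(hi_min), dt = dt)
    cum <- c(0, cumsum((g$ct[-1L] + g$ct[-length(g$ct)]) / 2) * dt)
    cum_at <- function(x) stats::approx(g$t, cum, xout = x)$y
    ints <- cum_at(hi_min) - cum_at(lo_min)
  }
  tac(schedule, plasma_fraction * ints / (hi_min - lo_min))
}

#' Frame-averaged blood curve
#'
#' Averages an input function over acquisition frames, producing the blood
#' TAC a scanner-side blood region of interest would report.
#'
#' @param cp an `input_fn`.
#' @param schedule a [frame_schedule].
#' @param n_sub sub-samples per frame used for the average.
#' @return A [tac].
#' @export
blood_tac <- function(cp, schedule, n_sub = 50L) {
  stopifnot(inherits(cp, "input_fn"), inherits(schedule, "frame_schedule"))
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    tt <- seq(schedule$start_s[i], schedule$end_s[i], length.out = n_sub) / 60
    v <- eval_input(cp, tt)
    sum((v[-1L] + v[-n_sub]) / 2) / (n_sub - 1L)  # trapezoid average
  }, 0)
  tac(schedule, vals)
}
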