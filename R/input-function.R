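#' Parametric bolus input function
#'
#' A Feng-type tracer bolus model for the blood input curve:
#' \deqn{C_p(t) = (A_1 (t-t_0) - A_2 - A_3) e^{-\lambda_1 (t-t_0)} +
#'   A_2 e^{-\lambda_2 (t-t_0)} + A_3 e^{-\lambda_3 (t-t_0)}}
#' for `t >= t0` and 0 before the bolus arrives. The form is continuous at
#' `t0` (it evaluates to 0 there) and describes a sharp first-pass spike
#' followed by a multi-exponential washout.
#'
#' The default parameter set is a documented mouse-plausible bolus in
#' SUV-like concentration units: a fast spike peaking within the first half
#' minute and a slow terminal washout leaving a low blood level at an hour.
#' It is configuration, not data: simulations that depend on it state it
#' explicitly.
#'
#' @param A1 spike amplitude (concentration x min^-1).
#' @param A2,A3 washout amplitudes (concentration).
#' @param lambda1,lambda2,lambda3 decay rates (min^-1), `lambda1 > lambda2 >
#'   lambda3 >= 0`.
#' @param t0 bolus arrival delay (min).
#' @return An object of classes `input_parametric` and `input_fn`.
#' @examples
#' cp <- feng_input()
#' eval_input(cp, c(0, 0.5, 1, 10, 60))
#' @export
feng_input <- function(A1 = 30, A2 = 0.7, A3 = 0.25,
                       lambda1 = 4, lambda2 = 0.5, lambda3 = 0.01,
                       t0 = 0.25) {
  if (!(lambda1 > lambda2 && lambda2 > lambda3 && lambda3 >= 0))
    stop("decay rates must satisfy lambda1 > lambda2 > lambda3 >= 0",
         call. = FALSE)
  if (A1 < 0 || A2 < 0 || A3 < 0 || t0 < 0)
    stop("amplitudes and delay must be nonnegative", call. = FALSE)
  terms <- es_simplify(es_terms(coef = c(A1, -A2 - A3, A2, A3),
                                power = c(1L, 0L, 0L, 0L),
                                rate = c(lambda1, lambda1, lambda2, lambda3)))
  structure(list(A = c(A1, A2, A3), lambda = c(lambda1, lambda2, lambda3),
                 t0 = t0, terms = terms),
            class = c("input_parametric", "input_fn"))
}

#' Sampled input function from discrete blood measurements
#'
#' Builds an input function from sampled blood concentrations: piecewise
#' linear interpolation between samples, zero before the first sample, and a
#' mono-exponential tail beyond the last sample fitted to the final three
#' points (floored at zero, never increasing).
#'
#' @param time_min sample times in minutes, strictly increasing, `>= 0`.
#' @param conc concentrations at the sample times, nonnegative.
#' @return An object of classes `input_sampled` and `input_fn`.
#' @examples
#' cp <- feng_input()
#' tt <- seq(0, 57, by = 1 / 60)
#' cps <- input_from_samples(tt, eval_input(cp, tt))
#' @export
input_from_samples <- function(time_min, conc) {
  if (length(time_min) < 3L)
    stop("at least 3 samples are required", call. = FALSE)
  if (length(time_min) != length(conc))
    stop("time and concentration vectors must have equal length", call. = FALSE)
  if (any(diff(time_min) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  if (any(conc < 0) || any(!is.finite(conc)) || any(time_min < 0))
    stop("samples must be finite and nonnegative", call. = FALSE)
  n <- length(time_min)
  tail_idx <- (n - 2L):n
  tv <- conc[tail_idx]
  if (all(tv > 0)) {
    # log-linear fit through the last three points; decay floored at 0
    fit <- stats::lm.fit(cbind(1, time_min[tail_idx] - time_min[n]), log(tv))
    tail_rate <- max(0, -fit$coefficients[2L])
  } else {
    tail_rate <- Inf  # tail already at zero
  }
  structure(list(time = as.numeric(time_min), conc = as.numeric(conc),
                 tail_rate = tail_rate),
            class = c("input_sampled", "input_fn"))
}

#' Evaluate an input function
#'
#' @param fn an `input_fn` object ([feng_input] or [input_from_samples]).
#' @param t times in minutes.
#' @return Concentrations at `t`.
#' @export
eval_input <- function(fn, t) UseMethod("eval_input")

#' @export
eval_input.input_parametric <- function(fn, t) {
  es_eval(fn$terms, t - fn$t0)
}

#' @export
eval_input.input_sampled <- function(fn, t) {
  n <- length(fn$time)
  out <- numeric(length(t))
  inside <- t >= fn$time[1L] & t <= fn$time[n]
  if (any(inside))
    out[inside] <- stats::approx(fn$time, fn$conc, xout = t[inside])$y
  beyond <- t > fn$time[n]
  if (any(beyond)) {
    last <- fn$conc[n]
    out[beyond] <- if (is.finite(fn$tail_rate))
      last * exp(-fn$tail_rate * (t[beyond] - fn$time[n])) else 0
  }
  pmax(out, 0)
}

#' @export
print.input_parametric <- function(x, ...) {
  cat("Parametric bolus input function:\n")
  cat(sprintf("  amplitudes A = (%.4g, %.4g, %.4g), rates lambda = (%.4g, %.4g, %.4g) min^-1, t0 = %.4g min\n",
              x$A[1], x$A[2], x$A[3], x$lambda[1], x$lambda[2], x$lambda[3], x$t0))
  invisible(x)
}

#' @export
print.input_sampled <- function(x, ...) {
  cat(sprintf("Sampled input function: %d samples on [%.3g, %.3g] min, tail rate %.4g min^-1\n",
              length(x$time), x$time[1], x$time[length(x$time)], x$tail_rate))
  invisible(x)
}
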