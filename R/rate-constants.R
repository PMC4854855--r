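#' Micro-parameters of the reversible two-tissue compartment model
#'
#' Constructs and validates the set of first-order rate constants describing
#' tracer exchange between blood, a free/nonspecific tissue compartment and a
#' specifically bound compartment: `K1` (blood-to-tissue delivery), `k2`
#' (tissue-to-blood efflux), `k3` (binding/trapping) and `k4` (dissociation),
#' all in min^-1, plus an optional fractional blood volume `vb`.
#'
#' @param K1 delivery rate constant (min^-1), `>= 0`.
#' @param k2 efflux rate constant (min^-1), `>= 0`.
#' @param k3 binding rate constant (min^-1), `>= 0`. `k3 = 0` reduces the
#'   model to a single tissue compartment.
#' @param k4 dissociation rate constant (min^-1), `>= 0`. `k4 = 0` gives
#'   irreversible trapping.
#' @param vb fractional blood volume in the region of interest, `0 <= vb < 1`.
#'   Defaults to 0 (no blood-volume term in the observation model).
#'
#' @return An object of class `rate_constants`.
#' @examples
#' rc <- rate_constants(K1 = 0.12, k2 = 0.18, k3 = 0.08, k4 = 0.004)
#' derived_metrics(rc)
#' @export
rate_constants <- function(K1, k2, k3, k4, vb = 0) {
  vals <- c(K1 = unname(K1), k2 = unname(k2), k3 = unname(k3),
            k4 = unname(k4), vb = unname(vb))
  if (any(!is.finite(vals)))
    stop("rate constants must be finite numbers", call. = FALSE)
  if (any(vals[c("K1", "k2", "k3", "k4")] < 0))
    stop("rate constants K1, k2, k3, k4 must be nonnegative", call. = FALSE)
  if (vb < 0 || vb >= 1)
    stop("fractional blood volume vb must satisfy 0 <= vb < 1", call. = FALSE)
  structure(as.list(vals), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, digits = 4, ...) {
  cat("Two-tissue-compartment rate constants (min^-1):\n")
  cat(sprintf("  K1 = %.*g  k2 = %.*g  k3 = %.*g  k4 = %.*g",
              digits, x$K1, digits, x$k2, digits, x$k3, digits, x$k4))
  if (x$vb > 0) cat(sprintf("  (vb = %.*g)", digits, x$vb))
  cat("\n")
  invisible(x)
}

#' Extract the four rate constants as a named vector
#'
#' @param rc a [rate_constants] object.
#' @return `c(K1, k2, k3, k4)` (vb is not included; it is an observation-
#'   model setting, not a kinetic parameter).
#' @export
rc_vector <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  c(K1 = rc$K1, k2 = rc$k2, k3 = rc$k3, k4 = rc$k4)
}

#' Macro-parameters (biexponential form) of the two-tissue model
#'
#' Converts the micro rate constants into the hybrid decay rates and
#' amplitudes of the closed-form tissue impulse response
#' \deqn{h(t) = \theta_1 e^{-\alpha_1 t} + \theta_2 e^{-\alpha_2 t},}
#' where \eqn{\alpha_{1,2} = \frac{1}{2}\left[(k_2+k_3+k_4) \mp
#' \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4}\right]}. The amplitudes satisfy
#' `theta1 + theta2 = K1` and `alpha1 * alpha2 = k2 * k4`.
#'
#' When the discriminant vanishes the two rates coincide and the impulse
#' response degenerates to \eqn{(\theta + c\,t)e^{-\alpha t}}; this limit is
#' returned analytically (flagged by `repeated = TRUE`) rather than by
#' perturbing the inputs.
#'
#' @param rc a [rate_constants] object.
#' @return A list with `alpha1 <= alpha2`, `theta1`, `theta2`, and `repeated`.
#' @examples
#' macro_parameters(rate_constants(0.12, 0.18, 0.08, 0.004))
#' @export
macro_parameters <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  s <- rc$k2 + rc$k3 + rc$k4
  disc <- s^2 - 4 * rc$k2 * rc$k4
  disc <- max(disc, 0)  # roundoff guard; true discriminant is >= 0
  r <- sqrt(disc)
  alpha1 <- (s - r) / 2
  alpha2 <- (s + r) / 2
  if (r < .es_rate_tol) {
    # repeated root: h(t) = [K1 + K1*(k3 + k4 - alpha) t] e^{-alpha t}
    return(list(alpha1 = alpha1, alpha2 = alpha2,
                theta1 = rc$K1, theta2 = 0,
                slope = rc$K1 * (rc$k3 + rc$k4 - alpha1), repeated = TRUE))
  }
  list(alpha1 = alpha1, alpha2 = alpha2,
       theta1 = rc$K1 * (rc$k3 + rc$k4 - alpha1) / (alpha2 - alpha1),
       theta2 = rc$K1 * (alpha2 - rc$k3 - rc$k4) / (alpha2 - alpha1),
       slope = 0, repeated = FALSE)
}

# impulse response as an exponential-polynomial sum (internal)
impulse_terms <- function(rc) {
  mp <- macro_parameters(rc)
  if (mp$repeated) {
    es_terms(c(mp$theta1, mp$slope), c(0L, 1L), c(mp$alpha1, mp$alpha1))
  } else {
    es_simplify(es_terms(c(mp$theta1, mp$theta2), c(0L, 0L),
                         c(mp$alpha1, mp$alpha2)))
  }
}

#' Tissue impulse response of the two-tissue model
#'
#' Evaluates \eqn{h(t) = \theta_1 e^{-\alpha_1 t} + \theta_2 e^{-\alpha_2 t}}
#' (total tissue response to a unit bolus in blood) at times `t`. `h(0) = K1`
#' and, for irreversible trapping (`k4 = 0`), `h` plateaus at the trapped
#' flux `theta1` as `t` grows.
#'
#' @param rc a [rate_constants] object.
#' @param t times in minutes, `>= 0`.
#' @return Response values in min^-1.
#' @export
tissue_impulse_response <- function(rc, t) {
  if (any(t < 0)) stop("times must be nonnegative", call. = FALSE)
  es_eval(impulse_terms(rc), t)
}

#' Derived trapping metrics of the two-tissue model
#'
#' Computes the standard interpretation layer on top of the micro-parameters:
#' the net delivery ratio `K1/k2`, the binding fraction `k3/(k2+k3)` (the
#' probability that an extracted tracer molecule binds rather than washes
#' back out), the retention ratio `k3/k4` (equilibrium bound-to-free
#' partition; large values indicate molecular trapping) and the total
#' distribution volume `VT = (K1/k2) * (1 + k3/k4)`.
#'
#' Divisions by a zero rate are reported as `Inf` and flagged, not raised:
#' `k4 = 0` (irreversible trapping) legitimately yields an infinite retention
#' ratio.
#'
#' @param rc a [rate_constants] object.
#' @return An object of class `derived_metrics`: a list with
#'   `delivery_ratio`, `binding_fraction`, `retention_ratio`, `vt`, and
#'   logical flags `infinite_retention`, `infinite_delivery`.
#' @examples
#' derived_metrics(rate_constants(0.12, 0.18, 0.082, 0.004))
#' @export
derived_metrics <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  delivery <- if (rc$k2 > 0) rc$K1 / rc$k2 else Inf
  binding <- if (rc$k2 + rc$k3 > 0) rc$k3 / (rc$k2 + rc$k3) else 0
  retention <- if (rc$k4 > 0) rc$k3 / rc$k4 else if (rc$k3 > 0) Inf else 0
  vt <- delivery * (1 + retention)
  structure(list(delivery_ratio = delivery, binding_fraction = binding,
                 retention_ratio = retention, vt = vt,
                 infinite_retention = is.infinite(retention),
                 infinite_delivery = is.infinite(delivery)),
            class = "derived_metrics")
}

#' @export
print.derived_metrics <- function(x, digits = 4, ...) {
  cat("Derived kinetic metrics:\n")
  cat(sprintf("  delivery ratio  K1/k2      = %.*g\n", digits, x$delivery_ratio))
  cat(sprintf("  binding fraction k3/(k2+k3) = %.*g\n", digits, x$binding_fraction))
  cat(sprintf("  retention ratio k3/k4      = %.*g%s\n", digits, x$retention_ratio,
              if (x$infinite_retention) " (irreversible)" else ""))
  cat(sprintf("  distribution volume VT     = %.*g\n", digits, x$vt))
  invisible(x)
}
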