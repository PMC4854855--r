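# Internal algebra on exponential-polynomial sums:
#   f(t) = sum_i coef_i * t^power_i * exp(-rate_i * t),  t >= 0
# represented as a list of parallel numeric vectors (coef, power, rate) --
# deliberately not a data.frame: these objects are rebuilt inside every
# objective evaluation of the fitter. Everything the closed-form simulation
# path needs (convolution with the tissue impulse response, exact integrals
# over acquisition frames) stays inside this family, so no quadrature is
# involved for parametric bolus inputs.

# rates closer than this are treated as coincident (repeated-root limit);
# the analytic limit avoids catastrophic cancellation in 1/d^k factors
.es_rate_tol <- 1e-6

es_terms <- function(coef, power, rate) {
  list(coef = as.numeric(coef), power = as.numeric(power),
       rate = as.numeric(rate))
}

es_append <- function(a, b) {
  list(coef = c(a$coef, b$coef), power = c(a$power, b$power),
       rate = c(a$rate, b$rate))
}

# merge duplicate (power, rate) terms and drop zero coefficients
es_simplify <- function(terms) {
  if (length(terms$coef) == 0L) return(terms)
  key <- paste(terms$power, signif(terms$rate, 12L))
  coef <- rowsum(terms$coef, key)
  first <- !duplicated(key)
  out <- list(coef = coef[match(key[first], rownames(coef)), 1L],
              power = terms$power[first], rate = terms$rate[first])
  keep <- abs(out$coef) > 0
  list(coef = unname(out$coef[keep]), power = out$power[keep],
       rate = out$rate[keep])
}

es_eval <- function(terms, t) {
  t <- as.numeric(t)
  out <- numeric(length(t))
  pos <- t >= 0
  if (!any(pos) || length(terms$coef) == 0L) return(out)
  tp <- t[pos]
  acc <- numeric(length(tp))
  for (i in seq_along(terms$coef)) {
    acc <- acc + terms$coef[i] * tp^terms$power[i] * exp(-terms$rate[i] * tp)
  }
  out[pos] <- acc
  out
}

# convolution of the pair t^p e^{-a t} (*) t^q e^{-b t} on [0, t]:
#   integral_0^t (t-s)^p e^{-a(t-s)} s^q e^{-b s} ds
# Expanding the binomial and integrating s^k e^{(a-b)s} termwise keeps the
# result inside the exponential-polynomial family.
es_conv_pair <- function(p, a, q, b) {
  d <- a - b
  if (abs(d) < .es_rate_tol) {
    # repeated-rate limit: each binomial term integrates to t^{p+q+1}/(m+q+1)
    m <- 0:p
    coef <- sum(choose(p, m) * (-1)^m / (m + q + 1))
    return(es_terms(coef, p + q + 1, a))
  }
  cf <- pw <- rt <- numeric(0)
  for (m in 0:p) {
    k <- m + q
    j <- 0:k
    cm <- choose(p, m) * (-1)^m
    # e^{-a t} t^{p-m} * I_k(t) with I_k = int_0^t s^k e^{d s} ds
    cf <- c(cf, cm * (-1)^j * factorial(k) / factorial(k - j) / d^(j + 1),
            -cm * (-1)^k * factorial(k) / d^(k + 1))
    pw <- c(pw, (p - m) + (k - j), p - m)
    rt <- c(rt, rep(b, k + 1L), a)
  }
  es_terms(cf, pw, rt)
}

# full convolution of two exponential-polynomial sums
es_convolve <- function(A, B) {
  out <- es_terms(numeric(0), numeric(0), numeric(0))
  for (i in seq_along(A$coef)) {
    for (j in seq_along(B$coef)) {
      tm <- es_conv_pair(A$power[i], A$rate[i], B$power[j], B$rate[j])
      tm$coef <- tm$coef * A$coef[i] * B$coef[j]
      out <- es_append(out, tm)
    }
  }
  es_simplify(out)
}

# antiderivative F(t) of t^p e^{-mu t}, vectorized over t (constant of
# integration immaterial); integral over [lo, hi] is F(hi) - F(lo)
.es_antideriv <- function(p, mu, t) {
  if (mu < .es_rate_tol) return(t^(p + 1) / (p + 1))
  acc <- numeric(length(t))
  for (j in 0:p)
    acc <- acc + factorial(p) / factorial(p - j) * t^(p - j) / mu^(j + 1)
  -exp(-mu * t) * acc
}

es_integrate <- function(terms, lo, hi) {
  stopifnot(length(lo) == length(hi))
  lo <- pmax(lo, 0)
  hi <- pmax(hi, 0)
  out <- numeric(length(lo))
  for (i in seq_along(terms$coef)) {
    p <- terms$power[i]; mu <- terms$rate[i]; cf <- terms$coef[i]
    out <- out + cf * (.es_antideriv(p, mu, hi) - .es_antideriv(p, mu, lo))
  }
  out
}
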