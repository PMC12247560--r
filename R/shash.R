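# Parameter validation ----------------------------------------------------

check_shape <- function(epsilon, delta) {
  if (any(!is.finite(epsilon))) stop("'epsilon' must be finite", call. = FALSE)
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop("'delta' must be finite and > 0", call. = FALSE)
  invisible(NULL)
}

check_scale <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be finite and > 0", call. = FALSE)
  invisible(NULL)
}

# Sinh-arcsinh transform --------------------------------------------------

#' Sinh-arcsinh transform and its inverse
#'
#' The transform `xi(x) = sinh(delta * asinh(x) - epsilon)` maps a
#' SHASH-distributed variable back to the standard Gaussian domain;
#' its inverse `sinh((asinh(z) + epsilon) / delta)` turns standard
#' Gaussian draws into SHASH draws.  `epsilon` controls skew and
#' `delta > 0` controls tail weight; `epsilon = 0, delta = 1` is the
#' identity.
#'
#' @param x numeric vector.
#' @param epsilon skew parameter (any real).
#' @param delta tail-weight parameter, strictly positive.
#' @return numeric vector of the same length as `x`.
#' @examples
#' sinh_arcsinh(0.7, 0, 1)              # identity
#' inv_sinh_arcsinh(sinh_arcsinh(2, 1, 0.5), 1, 0.5)
#' @export
sinh_arcsinh <- function(x, epsilon, delta) {
  check_shape(epsilon, delta)
  sinh(delta * asinh(x) - epsilon)
}

#' @rdname sinh_arcsinh
#' @export
inv_sinh_arcsinh <- function(x, epsilon, delta) {
  check_shape(epsilon, delta)
  sinh((asinh(x) + epsilon) / delta)
}

# numerically safe helpers ------------------------------------------------

log_cosh <- function(t) {
  a <- abs(t)
  a + log1p(exp(-2 * a)) - log(2)
}

# 0.5 * sinh(t)^2, clamped so the log-density stays finite even where
# sinh(t)^2 overflows double precision (|t| > ~355)
half_sq_sinh <- function(t) {
  v <- 0.5 * sinh(t)^2
  bad <- !is.finite(v)
  if (any(bad)) v[bad] <- 0.25 * exp(700)
  v
}

# SHASH density -----------------------------------------------------------

#' Density of the basic (two-parameter) SHASH distribution
#'
#' Density of `X = inv_sinh_arcsinh(Z)` for standard Gaussian `Z`,
#' obtained by change of variables:
#' `log f(x) = log(delta) + log(cosh(delta*asinh(x) - epsilon))
#'  - log(1 + x^2)/2 - log(2*pi)/2 - sinh(delta*asinh(x) - epsilon)^2/2`.
#' Computed entirely in log space; the `cosh` term would overflow in
#' linear space already at moderate `|x|`.
#'
#' @inheritParams sinh_arcsinh
#' @param log logical; return the log-density?
#' @return numeric vector of (log-)density values.
#' @export
dshash <- function(x, epsilon, delta, log = FALSE) {
  check_shape(epsilon, delta)
  t <- delta * asinh(x) - epsilon
  lp <- log(delta) + log_cosh(t) - 0.5 * log1p(x^2) -
    0.5 * log(2 * pi) - half_sq_sinh(t)
  if (log) lp else exp(lp)
}

#' Random draws from the basic SHASH distribution
#' @param n number of draws.
#' @inheritParams sinh_arcsinh
#' @export
rshash <- function(n, epsilon, delta) {
  inv_sinh_arcsinh(stats::rnorm(n), epsilon, delta)
}

# Bessel machinery --------------------------------------------------------

# log K_nu(1/4), modified Bessel function of the second kind, evaluated
# stably for large order via upward recurrence with renormalisation
# (K_{v+1} = K_{v-1} + (2v/z) K_v is forward-stable for K).
log_besselK_quarter <- function(nu) {
  nu <- abs(nu)
  z <- 0.25
  out <- numeric(length(nu))
  for (i in seq_along(nu)) {
    v <- nu[i]
    k <- besselK(z, v)
    if (is.finite(k) && k > 0) {
      out[i] <- log(k)
      next
    }
    f <- v - floor(v)
    m <- round(v - f)           # number of unit steps up from order f
    k0 <- besselK(z, f)
    k1 <- besselK(z, f + 1)
    lscale <- 0
    if (m >= 2) {
      for (j in seq_len(m - 1)) {
        ord <- f + j
        k2 <- k0 + (2 * ord / z) * k1
        k0 <- k1
        k1 <- k2
        if (k1 > 1e280) {
          k0 <- k0 / 1e280
          k1 <- k1 / 1e280
          lscale <- lscale + log(1e280)
        }
      }
    }
    out[i] <- log(k1) + lscale
  }
  out
}

#' Bessel term P(q) of the SHASH moment formula
#'
#' `P(q) = exp(1/4)/sqrt(8*pi) * (K_{(q+1)/2}(1/4) + K_{(q-1)/2}(1/4))`
#' with `K` the modified Bessel function of the second kind.  Symmetric
#' in `q` (the order symmetry of `K`), positive, and `P(0) = 1`,
#' `P(2) = 3` by the half-integer closed forms.  Evaluated via
#' exponentially scaled Bessel values so that large orders (small
#' `delta`) do not overflow.
#'
#' @param q numeric vector of (possibly negative) orders.
#' @export
shash_P <- function(q) {
  if (any(!is.finite(q))) stop("'q' must be finite", call. = FALSE)
  exp(log_shash_P(q))
}

log_shash_P <- function(q) {
  l1 <- log_besselK_quarter((q + 1) / 2)
  l2 <- log_besselK_quarter((q - 1) / 2)
  m <- pmax(l1, l2)
  0.25 - 0.5 * log(8 * pi) + m + log(exp(l1 - m) + exp(l2 - m))
}

# Analytic moments --------------------------------------------------------

#' Non-central moments of the basic SHASH distribution
#'
#' Analytic r-th non-central moment
#' `m(r) = 2^-r * sum_i choose(r, i) * (-1)^i *
#'         exp((r - 2i) * epsilon / delta) * P((r - 2i) / delta)`.
#' Terms are combined on the log scale with explicit signs so that the
#' Bessel factors can be astronomically large without overflow.
#'
#' @param r positive integer moment order.
#' @inheritParams sinh_arcsinh
#' @return scalar moment value.
#' @examples
#' shash_moment(2, 0, 1)   # 1: standard Gaussian second moment
#' @export
shash_moment <- function(r, epsilon, delta) {
  if (length(r) != 1L || r < 1 || r != round(r))
    stop("'r' must be a single positive integer", call. = FALSE)
  check_shape(epsilon, delta)
  if (length(epsilon) != 1L || length(delta) != 1L)
    stop("'epsilon' and 'delta' must be scalars here", call. = FALSE)
  i <- 0:r
  logmag <- lchoose(r, i) + (r - 2 * i) * epsilon / delta +
    log_shash_P((r - 2 * i) / delta) - r * log(2)
  sgn <- (-1)^i
  m <- max(logmag)
  sum(sgn * exp(logmag - m)) * exp(m)
}

#' Central variance of the basic SHASH distribution
#'
#' `eta^2 = m(2) - m(1)^2`, strictly positive for any finite
#' `(epsilon, delta)`.
#'
#' @inheritParams sinh_arcsinh
#' @export
shash_eta2 <- function(epsilon, delta) {
  s <- shashb_stats(epsilon, delta)
  s$eta2
}

# Vectorised mean / central variance of the basic SHASH law, using the
# closed forms m(1) = sinh(e/d) P(1/d), m(2) = (cosh(2e/d) P(2/d) - 1)/2
# (the r = 1, 2 cases of the general moment formula).
shashb_stats <- function(epsilon, delta) {
  check_shape(epsilon, delta)
  n <- max(length(epsilon), length(delta))
  epsilon <- rep_len(epsilon, n)
  delta <- rep_len(delta, n)
  p1 <- exp(log_shash_P(1 / delta))
  p2 <- exp(log_shash_P(2 / delta))
  m1 <- sinh(epsilon / delta) * p1
  m2 <- 0.5 * (cosh(2 * epsilon / delta) * p2 - 1)
  eta2 <- m2 - m1^2
  list(m1 = m1, m2 = m2, eta2 = eta2, eta = sqrt(eta2), p1 = p1, p2 = p2)
}

# Located-scaled families -------------------------------------------------

#' Density of the SHASH_o distribution
#'
#' The canonical four-parameter family: a basic SHASH variable scaled by
#' `sigma` and shifted by `mu`.  Its mean and variance entangle with
#' `epsilon` and `delta` (`E = mu + sigma*m(1)`, `Var = sigma^2*eta^2`).
#'
#' @param x numeric vector of evaluation points.
#' @param mu location parameter.
#' @param sigma scale parameter, strictly positive.
#' @inheritParams dshash
#' @export
dshasho <- function(x, mu, sigma, epsilon, delta, log = FALSE) {
  check_scale(sigma)
  lp <- dshash((x - mu) / sigma, epsilon, delta, log = TRUE) - log(sigma)
  if (log) lp else exp(lp)
}

#' Density, sampling and Gaussian-domain maps for the SHASH_b distribution
#'
#' SHASH_b first standardises the basic SHASH law by its analytic mean
#' `m(1)` and standard deviation `eta`, then applies `mu` and `sigma`.
#' As a result `mu` and `sigma` are *exactly* the distribution mean and
#' standard deviation for every `(epsilon, delta)`, which removes the
#' strong posterior correlations that make the SHASH_o parameterisation
#' hard to sample.  The generating map from a standard Gaussian draw `z`
#' is
#' `lambda(z) = (inv_sinh_arcsinh(z) - m(1)) / eta * sigma + mu`
#' (`shashb_from_gaussian`), and its inverse
#' `lambda^{-1}(y) = sinh_arcsinh((y - mu)/sigma * eta + m(1))`
#' (`shashb_to_gaussian`) is the deviation (z-)score map.
#'
#' All functions are vectorised over parameters, so covariate-dependent
#' `epsilon`/`delta` (one value per observation) are supported.
#'
#' @inheritParams dshasho
#' @param log logical; return the log-density?
#' @return `dshashb`: (log-)density values; `rshashb`: `n` draws;
#'   `qshashb`/`pshashb`: quantiles / probabilities;
#'   `shashb_from_gaussian`/`shashb_to_gaussian`: transformed vectors.
#' @examples
#' dshashb(0, 0, 1, 0, 1, log = TRUE)   # log dnorm(0)
#' qshashb(0.5, 2, 3, 1, 0.8)           # median of a skewed member
#' @export
dshashb <- function(x, mu, sigma, epsilon, delta, log = FALSE) {
  check_scale(sigma)
  s <- shashb_stats(epsilon, delta)
  z <- (x - mu) / sigma * s$eta + s$m1
  lp <- dshash(z, epsilon, delta, log = TRUE) + log(s$eta) - log(sigma)
  if (log) lp else exp(lp)
}

#' @rdname dshashb
#' @param n number of draws.
#' @export
rshashb <- function(n, mu, sigma, epsilon, delta) {
  shashb_from_gaussian(stats::rnorm(n), mu, sigma, epsilon, delta)
}

#' @rdname dshashb
#' @param z standard-Gaussian-domain values (e.g. centile levels).
#' @export
shashb_from_gaussian <- function(z, mu, sigma, epsilon, delta) {
  check_scale(sigma)
  s <- shashb_stats(epsilon, delta)
  (inv_sinh_arcsinh(z, epsilon, delta) - s$m1) / s$eta * sigma + mu
}

#' @rdname dshashb
#' @param y observation-domain values.
#' @export
shashb_to_gaussian <- function(y, mu, sigma, epsilon, delta) {
  check_scale(sigma)
  s <- shashb_stats(epsilon, delta)
  sinh_arcsinh((y - mu) / sigma * s$eta + s$m1, epsilon, delta)
}

#' @rdname dshashb
#' @param p probabilities.
#' @export
qshashb <- function(p, mu, sigma, epsilon, delta) {
  shashb_from_gaussian(stats::qnorm(p), mu, sigma, epsilon, delta)
}

#' @rdname dshashb
#' @param q quantiles.
#' @export
pshashb <- function(q, mu, sigma, epsilon, delta) {
  stats::pnorm(shashb_to_gaussian(q, mu, sigma, epsilon, delta))
}

# Link functions ----------------------------------------------------------

#' Positivity and tail-parameter link functions
#'
#' `softplus(x) = log(1 + exp(x))` maps the real line to the positive
#' half-line and is used as the link for scale parameters.
#' `delta_link(x) = softplus(10*x)/10 + 0.3` is the link for the
#' tail-weight parameter `delta`: the factor 10 makes the map nearly the
#' identity above zero, and the 0.3 offset keeps the sampler away from
#' the numerically unstable region `delta < 0.3` (where the Bessel terms
#' of the moment formula explode).  The floor is a sampling device only:
#' the density functions themselves accept any `delta > 0`.
#' Both links are monotone and overflow-safe for `|x|` up to at least
#' `1e3`; `inv_softplus` and `inv_delta_link` are their inverses.
#'
#' @param x numeric vector.
#' @return numeric vector; `softplus(x) > 0`, `delta_link(x) >= 0.3`.
#' @examples
#' softplus(0)          # log(2)
#' delta_link(0)        # log(2)/10 + 0.3
#' @export
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' @rdname softplus
#' @param y positive values to map back through `softplus`.
#' @export
inv_softplus <- function(y) {
  if (any(y <= 0)) stop("'y' must be > 0", call. = FALSE)
  ifelse(y > 30, y, log(expm1(y)))
}

#' @rdname softplus
#' @export
delta_link <- function(x) {
  softplus(10 * x) / 10 + 0.3
}

#' @rdname softplus
#' @param d delta values (> 0.3) to map back through `delta_link`.
#' @export
inv_delta_link <- function(d) {
  if (any(d <= 0.3)) stop("'d' must be > 0.3", call. = FALSE)
  inv_softplus(10 * (d - 0.3)) / 10
}
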