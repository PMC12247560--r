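# Hierarchical generative model: log joint density and gradient ----------

# Per-subject derivative bundle of the basic SHASH log-density
# logS(x; e, d) evaluated at x, with partials in x, e and d.
# xi*C terms are clamped so extreme leapfrog excursions yield huge
# finite gradients (and get rejected) instead of NaN.
.shash_pieces <- function(x, e, d) {
  a <- asinh(x)
  s1 <- 1 / sqrt(1 + x^2)
  t <- d * a - e
  sh <- sinh(t)
  ch <- cosh(t)
  Th <- sh / ch
  xiC <- sh * ch
  bad <- !is.finite(xiC)
  if (any(bad)) xiC[bad] <- sign(t[bad]) * 0.25 * exp(700)
  hs <- 0.5 * sh^2
  bad <- !is.finite(hs)
  if (any(bad)) hs[bad] <- 0.25 * exp(700)
  lc <- ifelse(is.finite(ch), log(ch), abs(t) - log(2))
  list(
    dx = Th * d * s1 - x * s1^2 - xiC * d * s1,
    de = -Th + xiC,
    dd = 1 / d + Th * a - xiC * a,
    ll = log(d) + lc - 0.5 * log1p(x^2) - 0.5 * log(2 * pi) - hs
  )
}

# SHASH_b moment terms and their partials with respect to epsilon and
# delta.  The epsilon partials are analytic; the delta partials involve
# the derivative of the Bessel function in its order, for which no
# closed form exists, so they are obtained by central differences on the
# (scalar-per-observation, data-independent) moment functions.
.shashb_sens <- function(e, d) {
  s0 <- shashb_stats(e, d)
  dm1_de <- cosh(e / d) * s0$p1 / d
  dm2_de <- sinh(2 * e / d) * s0$p2 / d
  deta2_de <- dm2_de - 2 * s0$m1 * dm1_de
  h <- 1e-6 * (1 + abs(d))
  sp <- shashb_stats(e, d + h)
  sm <- shashb_stats(e, d - h)
  list(m1 = s0$m1, eta = s0$eta,
       dm1_de = dm1_de,
       deta_de = deta2_de / (2 * s0$eta),
       dm1_dd = (sp$m1 - sm$m1) / (2 * h),
       deta_dd = (sp$eta - sm$eta) / (2 * h))
}

# Likelihood log-density and its per-subject partials in (mu, sigma,
# epsilon, delta).  eps/delta may be scalars or per-subject vectors.
.loglik_terms <- function(family, y, mu, sigma, eps, delta) {
  if (family == "normal") {
    r <- (y - mu) / sigma
    return(list(ll = sum(stats::dnorm(y, mu, sigma, log = TRUE)),
                dmu = r / sigma,
                dsigma = (r^2 - 1) / sigma,
                deps = NULL, ddelta = NULL))
  }
  if (family == "shasho") {
    x <- (y - mu) / sigma
    p <- .shash_pieces(x, eps, delta)
    return(list(ll = sum(p$ll) - sum(rep_len(log(sigma), length(y))),
                dmu = -p$dx / sigma,
                dsigma = -p$dx * x / sigma - 1 / sigma,
                deps = p$de, ddelta = p$dd))
  }
  # shashb
  sn <- .shashb_sens(eps, delta)
  u <- (y - mu) / sigma
  x <- u * sn$eta + sn$m1
  p <- .shash_pieces(x, eps, delta)
  list(ll = sum(p$ll) + sum(rep_len(log(sn$eta) - log(sigma), length(y))),
       dmu = -p$dx * sn$eta / sigma,
       dsigma = -p$dx * u * sn$eta / sigma - 1 / sigma,
       deps = p$dx * (u * sn$deta_de + sn$dm1_de) + p$de + sn$deta_de / sn$eta,
       ddelta = p$dx * (u * sn$deta_dd + sn$dm1_dd) + p$dd + sn$deta_dd / sn$eta)
}

# Parameter block layout for a given spec / design dimension / site count
.par_layout <- function(spec, D, S) {
  idx <- list()
  k <- 0
  add <- function(name, len) {
    idx[[name]] <<- k + seq_len(len)
    k <<- k + len
  }
  add("w_mu", D)
  add("mu_tau", 1)
  if (spec$mu_model == "random_intercept") {
    add("log_sigma_tau", 1)
    add("nu", S)
  }
  add("w_sigma", D)
  add("tau_sigma", 1)
  if (spec$shape_model == "constant") {
    add("epsilon", 1)
    add("delta_raw", 1)
  } else if (spec$shape_model == "linear") {
    add("w_epsilon", D)
    add("tau_epsilon", 1)
    add("w_delta", D)
    add("tau_delta", 1)
  }
  nm <- character(k)
  for (b in names(idx)) {
    ii <- idx[[b]]
    nm[ii] <- if (length(ii) == 1L) b else paste0(b, "[", seq_along(ii), "]")
  }
  list(idx = idx, npar = k, names = nm)
}

#' Construct the hierarchical generative model
#'
#' Binds a model specification to data, returning an object exposing the
#' log joint density (sum of all prior log-densities plus the likelihood
#' log-density) and its gradient at any free-parameter setting, on the
#' unconstrained scale used by the sampler.  The mean sub-model adds a
#' per-site intercept sampled non-centred as
#' `offset_s = mu_tau + sigma_tau * nu_s` with `nu_s ~ N(0, 1)` and a
#' half-normal prior on `sigma_tau` (sampled as `log(sigma_tau)` with
#' the Jacobian term included).  The scale is
#' `sigma_n = softplus(X_n w_sigma + tau_sigma)` and, for SHASH
#' variants, `delta_n = delta_link(raw)` so that `delta >= 0.3`.
#'
#' @param spec an [hbr_spec()].
#' @param X design matrix from [build_design_matrix()].
#' @param batch integer site index (1-based, dense) as from the
#'   `batch_index` used at fit time; every site must be present.
#' @param y numeric response vector (normally standardised).
#' @return an object of class `"hbr_model"` with elements `lp(theta)`,
#'   `lp_grad(theta)` (returning `list(lp, grad)`), `init()`,
#'   `par_names`, `dims`.
#' @export
hbr_model <- function(spec, X, batch, y) {
  stopifnot(inherits(spec, "hbr_spec"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n || length(batch) != n)
    stop("'X', 'batch' and 'y' must agree in length", call. = FALSE)
  if (any(!is.finite(y))) stop("'y' must be finite", call. = FALSE)
  if (any(is.na(batch))) stop("unseen batch label at fit time", call. = FALSE)
  S <- max(batch)
  if (!setequal(unique(batch), seq_len(S)))
    stop("batch index must be dense 1..S with every site present", call. = FALSE)
  D <- ncol(X)
  lay <- .par_layout(spec, D, S)
  idx <- lay$idx
  pr <- spec$priors
  ri <- spec$mu_model == "random_intercept"
  tX <- t(X)

  # N(m, s) prior contribution for one block
  prior_lp <- function(th, ms) sum(stats::dnorm(th, ms[1], ms[2], log = TRUE))
  prior_g <- function(th, ms) -(th - ms[1]) / ms[2]^2

  eval_model <- function(theta, want_grad = TRUE) {
    w_mu <- theta[idx$w_mu]
    mu_tau <- theta[idx$mu_tau]
    w_sigma <- theta[idx$w_sigma]
    tau_sigma <- theta[idx$tau_sigma]
    mu <- drop(X %*% w_mu)
    if (ri) {
      u <- theta[idx$log_sigma_tau]
      st <- exp(u)
      nu <- theta[idx$nu]
      offs <- mu_tau + st * nu
      mu <- mu + offs[batch]
    } else {
      mu <- mu + mu_tau
    }
    sraw <- drop(X %*% w_sigma) + tau_sigma
    sigma <- softplus(sraw)

    if (spec$shape_model == "constant") {
      eps <- theta[idx$epsilon]
      draw <- theta[idx$delta_raw]
      delta <- delta_link(draw)
    } else if (spec$shape_model == "linear") {
      eps <- drop(X %*% theta[idx$w_epsilon]) + theta[idx$tau_epsilon]
      draw <- drop(X %*% theta[idx$w_delta]) + theta[idx$tau_delta]
      delta <- delta_link(draw)
    } else {
      eps <- delta <- draw <- NULL
    }

    lt <- .loglik_terms(spec$likelihood, y, mu, sigma, eps, delta)

    lp <- lt$ll +
      prior_lp(w_mu, pr$w_mu) +
      prior_lp(mu_tau, pr$mu_tau) +
      prior_lp(w_sigma, pr$w_sigma) +
      prior_lp(tau_sigma, pr$tau_sigma)
    if (ri) {
      # half-normal on sigma_tau = exp(u), with log-scale Jacobian
      lp <- lp + (0.5 * log(2) - 0.5 * log(pi) - log(pr$sigma_tau) -
                    st^2 / (2 * pr$sigma_tau^2)) + u +
        prior_lp(nu, pr$nu)
    }
    if (spec$shape_model == "constant") {
      lp <- lp + prior_lp(eps, pr$epsilon) + prior_lp(draw, pr$delta_raw)
    } else if (spec$shape_model == "linear") {
      lp <- lp + prior_lp(theta[idx$w_epsilon], pr$w_epsilon) +
        prior_lp(theta[idx$tau_epsilon], pr$tau_epsilon) +
        prior_lp(theta[idx$w_delta], pr$w_delta) +
        prior_lp(theta[idx$tau_delta], pr$tau_delta)
    }
    if (!want_grad) return(list(lp = lp))

    g <- numeric(lay$npar)
    g[idx$w_mu] <- drop(tX %*% lt$dmu) + prior_g(w_mu, pr$w_mu)
    if (ri) {
      gs <- drop(rowsum(lt$dmu, batch))      # per-site sums, ordered 1..S
      g[idx$mu_tau] <- sum(gs) + prior_g(mu_tau, pr$mu_tau)
      g[idx$nu] <- st * gs + prior_g(nu, pr$nu)
      g[idx$log_sigma_tau] <- st * sum(gs * nu) - st^2 / pr$sigma_tau^2 + 1
    } else {
      g[idx$mu_tau] <- sum(lt$dmu) + prior_g(mu_tau, pr$mu_tau)
    }
    dsr <- lt$dsigma * stats::plogis(sraw)   # chain through softplus
    g[idx$w_sigma] <- drop(tX %*% dsr) + prior_g(w_sigma, pr$w_sigma)
    g[idx$tau_sigma] <- sum(dsr) + prior_g(tau_sigma, pr$tau_sigma)
    if (spec$shape_model == "constant") {
      g[idx$epsilon] <- sum(lt$deps) + prior_g(eps, pr$epsilon)
      g[idx$delta_raw] <- sum(lt$ddelta) * stats::plogis(10 * draw) +
        prior_g(draw, pr$delta_raw)
    } else if (spec$shape_model == "linear") {
      g[idx$w_epsilon] <- drop(tX %*% lt$deps) +
        prior_g(theta[idx$w_epsilon], pr$w_epsilon)
      g[idx$tau_epsilon] <- sum(lt$deps) +
        prior_g(theta[idx$tau_epsilon], pr$tau_epsilon)
      ddr <- lt$ddelta * stats::plogis(10 * draw)
      g[idx$w_delta] <- drop(tX %*% ddr) +
        prior_g(theta[idx$w_delta], pr$w_delta)
      g[idx$tau_delta] <- sum(ddr) +
        prior_g(theta[idx$tau_delta], pr$tau_delta)
    }
    list(lp = lp, grad = g)
  }

  init <- function(jitter = 0.1) {
    th <- numeric(lay$npar)
    th[idx$tau_sigma] <- pr$tau_sigma[1]
    if (ri) th[idx$log_sigma_tau] <- log(0.5)
    if (spec$shape_model == "constant") {
      th[idx$epsilon] <- pr$epsilon[1]
      th[idx$delta_raw] <- pr$delta_raw[1]
    } else if (spec$shape_model == "linear") {
      th[idx$tau_epsilon] <- pr$tau_epsilon[1]
      th[idx$tau_delta] <- pr$tau_delta[1]
    }
    th + stats::rnorm(lay$npar, 0, jitter)
  }

  structure(
    list(spec = spec, X = X, y = y, batch = batch,
         dims = list(n = n, D = D, S = S, npar = lay$npar, idx = idx),
         par_names = lay$names,
         lp = function(theta) eval_model(theta, want_grad = FALSE)$lp,
         lp_grad = function(theta) eval_model(theta, want_grad = TRUE),
         init = init),
    class = "hbr_model")
}

#' Per-subject likelihood parameters at a parameter point
#'
#' Maps one free-parameter vector (a MAP point or a single posterior
#' draw) through the design matrix, site offsets and link functions to
#' the per-subject likelihood parameters `(mu, sigma, epsilon, delta)`.
#' Subjects from sites unseen at fit time (`NA` in `batch`) receive the
#' group-level mean offset.
#'
#' @param spec an [hbr_spec()].
#' @param theta named or unnamed free-parameter vector laid out as in
#'   [hbr_model()].
#' @param X design matrix (built with the training knot record).
#' @param batch integer site index; `NA` marks an unseen site.
#' @param n_sites number of sites the model was fitted with.
#' @return data frame with columns `mu`, `sigma`, `epsilon`, `delta`
#'   (shape columns `NA` for the Gaussian family) and attribute
#'   `"family"`.
#' @export
likelihood_params <- function(spec, theta, X, batch, n_sites) {
  X <- as.matrix(X)
  lay <- .par_layout(spec, ncol(X), n_sites)
  idx <- lay$idx
  mu <- drop(X %*% theta[idx$w_mu])
  if (spec$mu_model == "random_intercept") {
    st <- exp(theta[idx$log_sigma_tau])
    offs <- theta[idx$mu_tau] + st * theta[idx$nu]
    off_sub <- ifelse(is.na(batch), theta[idx$mu_tau], offs[batch])
    mu <- mu + off_sub
  } else {
    mu <- mu + theta[idx$mu_tau]
  }
  sigma <- softplus(drop(X %*% theta[idx$w_sigma]) + theta[idx$tau_sigma])
  if (spec$shape_model == "constant") {
    eps <- rep_len(theta[idx$epsilon], nrow(X))
    delta <- rep_len(delta_link(theta[idx$delta_raw]), nrow(X))
  } else if (spec$shape_model == "linear") {
    eps <- drop(X %*% theta[idx$w_epsilon]) + theta[idx$tau_epsilon]
    delta <- delta_link(drop(X %*% theta[idx$w_delta]) + theta[idx$tau_delta])
  } else {
    eps <- delta <- rep_len(NA_real_, nrow(X))
  }
  out <- data.frame(mu = mu, sigma = sigma, epsilon = eps, delta = delta)
  attr(out, "family") <- spec$likelihood
  out
}
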