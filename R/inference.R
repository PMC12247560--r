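# Posterior sampling, convergence diagnostics, MAP estimation ------------

#' Sample the posterior with the No-U-Turn sampler
#'
#' Runs `chains` independent NUTS chains of `iter` iterations each,
#' discarding the first `warmup` as burn-in (during which the step size
#' and a diagonal mass matrix are adapted).  Chains are seeded
#' deterministically from `seed`, so repeated calls reproduce identical
#' draws.  Runs in which more than 5% of post-warmup transitions
#' diverge raise an error rather than returning silently unreliable
#' draws.
#'
#' @param model an [hbr_model()], or any list with elements `lp_grad`
#'   (function returning `list(lp, grad)`), `init()` and `par_names`.
#' @param chains number of chains (>= 2 required for R-hat).
#' @param iter total iterations per chain.
#' @param warmup burn-in iterations discarded from each chain.
#' @param seed integer seed controlling all sampler randomness.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param max_treedepth maximum NUTS tree depth.
#' @return an object of class `"hbr_samples"`: `draws` is a
#'   `(iter - warmup) x chains x npar` array with parameter dimnames;
#'   `divergences`, `step_size`, `seed`, `warmup` record diagnostics
#'   and provenance.
#' @export
sample_posterior <- function(model, chains = 2, iter = 1500, warmup = 500,
                             seed = 1, target_accept = 0.8,
                             max_treedepth = 10L) {
  stopifnot(iter > warmup, chains >= 1)
  npar <- length(model$par_names)
  keep <- iter - warmup
  draws <- array(NA_real_, c(keep, chains, npar),
                 dimnames = list(NULL, NULL, model$par_names))
  lps <- matrix(NA_real_, keep, chains)
  divs <- integer(chains)
  steps <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + (ch - 1L) * 100003L)
    th0 <- model$init()
    res <- .nuts_chain(model$lp_grad, th0, iter, warmup,
                       target_accept = target_accept,
                       max_treedepth = max_treedepth)
    draws[, ch, ] <- res$draws
    lps[, ch] <- res$lp
    divs[ch] <- res$divergences
    steps[ch] <- res$step_size
  }
  total_div <- sum(divs)
  if (total_div > 0.05 * keep * chains)
    stop(sprintf("sampler unreliable: %d of %d post-warmup transitions diverged",
                 total_div, keep * chains), call. = FALSE)
  if (total_div > 0)
    warning(sprintf("%d divergent transition(s) after warmup", total_div),
            call. = FALSE)
  structure(
    list(draws = draws, lp = lps, chains = chains, warmup = warmup,
         iter = iter, seed = seed, divergences = divs, step_size = steps,
         par_names = model$par_names),
    class = "hbr_samples")
}

#' @export
print.hbr_samples <- function(x, ...) {
  cat(sprintf("Posterior samples: %d chains x %d draws, %d parameters\n",
              x$chains, dim(x$draws)[1], dim(x$draws)[3]))
  cat(sprintf("  warmup %d, seed %d, divergences %s\n", x$warmup, x$seed,
              paste(x$divergences, collapse = "/")))
  invisible(x)
}

#' Extract a draws-by-chains matrix for one parameter
#'
#' @param samples an `hbr_samples` object.
#' @param par parameter name (as in `samples$par_names`).
#' @export
extract_par <- function(samples, par) {
  stopifnot(inherits(samples, "hbr_samples"))
  if (!par %in% samples$par_names) stop("unknown parameter: ", par, call. = FALSE)
  samples$draws[, , par, drop = TRUE]
}

#' Posterior draws as a flat matrix
#'
#' Stacks all chains into one `(draws * chains) x npar` matrix.
#' @inheritParams extract_par
#' @export
draws_matrix <- function(samples) {
  stopifnot(inherits(samples, "hbr_samples"))
  d <- samples$draws
  out <- matrix(d, nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3])
  colnames(out) <- samples$par_names
  out
}

# split-chain potential scale reduction on one draws x chains matrix
.rhat_matrix <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  sm <- cbind(m[seq_len(half), , drop = FALSE],
              m[(n - half + 1):n, , drop = FALSE])
  nn <- nrow(sm)
  cm <- colMeans(sm)
  W <- mean(apply(sm, 2, stats::var))
  B <- nn * stats::var(cm)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Gelman-Rubin convergence diagnostic (R-hat)
#'
#' Potential scale reduction: the ratio of pooled to within-chain
#' variance, about 1 at convergence.  The default is the split-chain
#' rank-normalised variant (each chain is split in half and draws are
#' mapped through normal scores before computing the classic
#' statistic); `method = "classic"` gives the original split-chain
#' Gelman-Rubin value.  Values at or below 1.1 are commonly taken as
#' acceptable and at or below 1.05 as good convergence.
#'
#' @param samples an `hbr_samples` object, or a draws-by-chains matrix.
#' @param pars parameter names (default: all).
#' @param method `"rank"` (rank-normalised) or `"classic"`.
#' @return named numeric vector of R-hat values.
#' @export
rhat <- function(samples, pars = NULL, method = c("rank", "classic")) {
  method <- match.arg(method)
  if (is.matrix(samples)) {
    mats <- list(par = samples)
  } else {
    stopifnot(inherits(samples, "hbr_samples"))
    if (is.null(pars)) pars <- samples$par_names
    mats <- lapply(pars, function(p) extract_par(samples, p))
    names(mats) <- pars
  }
  vapply(mats, function(m) {
    m <- as.matrix(m)
    if (ncol(m) < 2) stop("R-hat requires at least 2 chains", call. = FALSE)
    if (nrow(m) < 4) stop("R-hat requires at least 4 draws per chain", call. = FALSE)
    if (method == "rank") {
      r <- rank(m, ties.method = "average")
      z <- stats::qnorm((r - 3 / 8) / (length(m) + 1 / 4))
      m <- matrix(z, nrow(m), ncol(m))
    }
    .rhat_matrix(m)
  }, numeric(1))
}

#' Trajectory of R-hat over growing chain prefixes
#'
#' Recomputes R-hat on the first `k` retained draws for a grid of `k`,
#' mirroring convergence-versus-chain-length analyses.
#'
#' @inheritParams rhat
#' @param par single parameter name.
#' @param lengths prefix lengths (defaults to 10 points up to the full
#'   chain).
#' @return data frame with columns `length` and `rhat`.
#' @export
rhat_trajectory <- function(samples, par, lengths = NULL,
                            method = c("rank", "classic")) {
  method <- match.arg(method)
  m <- extract_par(samples, par)
  n <- nrow(m)
  if (is.null(lengths)) lengths <- unique(round(seq(20, n, length.out = 10)))
  lengths <- lengths[lengths >= 4 & lengths <= n]
  data.frame(
    length = lengths,
    rhat = vapply(lengths, function(k) rhat(m[seq_len(k), , drop = FALSE],
                                            method = method), numeric(1)))
}

#' Maximum a posteriori estimation
#'
#' Maximises the log joint density on the unconstrained scale with
#' BFGS using the analytic gradient, over `restarts` jittered
#' initialisations, keeping the best optimum.
#'
#' @inheritParams sample_posterior
#' @param restarts number of independent initialisations.
#' @return an object of class `"hbr_map"`: `par` (named vector),
#'   `lp` (achieved log joint), `grad_norm`, `convergence` code from
#'   [stats::optim()].
#' @export
map_estimate <- function(model, restarts = 2, seed = 1) {
  best <- NULL
  set.seed(as.integer(seed))
  for (r in seq_len(restarts)) {
    th0 <- model$init()
    lp0 <- model$lp(th0)
    if (!is.finite(lp0)) next
    fit <- stats::optim(
      th0,
      fn = function(th) -model$lp(th),
      gr = function(th) -model$lp_grad(th)$grad,
      method = "BFGS",
      control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || -fit$value > best$lp) {
      best <- list(par = stats::setNames(fit$par, model$par_names),
                   lp = -fit$value, convergence = fit$convergence,
                   init_lp = lp0)
    }
  }
  if (is.null(best) || best$lp < best$init_lp)
    stop("MAP optimisation failed to improve on initialisation", call. = FALSE)
  best$grad_norm <- sqrt(sum(model$lp_grad(best$par)$grad^2))
  class(best) <- "hbr_map"
  best
}

#' @export
print.hbr_map <- function(x, ...) {
  cat(sprintf("MAP estimate: log joint %.4f (|grad| %.2e, convergence %d)\n",
              x$lp, x$grad_norm, x$convergence))
  invisible(x)
}
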