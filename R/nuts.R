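# No-U-Turn sampler with dual-averaging step-size adaptation and
# windowed diagonal mass-matrix estimation.  Kinetic energy is
# 0.5 * sum(invM * r^2) with momenta r ~ N(0, 1/invM) componentwise;
# invM approximates the posterior variances.

.nuts_leapfrog <- function(th, r, g, eps, invM, lp_grad) {
  r1 <- r + 0.5 * eps * g
  th1 <- th + eps * invM * r1
  e1 <- lp_grad(th1)
  if (!is.finite(e1$lp) || any(!is.finite(e1$grad))) {
    return(list(th = th1, r = r1, lp = -Inf, grad = rep(0, length(th))))
  }
  r1 <- r1 + 0.5 * eps * e1$grad
  list(th = th1, r = r1, lp = e1$lp, grad = e1$grad)
}

.nuts_joint <- function(lp, r, invM) lp - 0.5 * sum(invM * r^2)

.find_epsilon <- function(th, e0, invM, lp_grad) {
  eps <- 1
  r <- stats::rnorm(length(th)) / sqrt(invM)
  j0 <- .nuts_joint(e0$lp, r, invM)
  st <- .nuts_leapfrog(th, r, e0$grad, eps, invM, lp_grad)
  j1 <- .nuts_joint(st$lp, st$r, invM)
  a <- if (is.finite(j1) && j1 - j0 > log(0.5)) 1 else -1
  for (k in 1:50) {
    eps <- eps * 2^a
    st <- .nuts_leapfrog(th, r, e0$grad, eps, invM, lp_grad)
    j1 <- .nuts_joint(st$lp, st$r, invM)
    ok <- is.finite(j1) && a * (j1 - j0) > -a * log(2)
    if (!ok) break
  }
  eps
}

.build_tree <- function(th, r, g, logu, v, j, eps, joint0, invM, lp_grad) {
  if (j == 0L) {
    st <- .nuts_leapfrog(th, r, g, v * eps, invM, lp_grad)
    joint <- .nuts_joint(st$lp, st$r, invM)
    n1 <- as.integer(logu <= joint)
    div <- !is.finite(joint) || (logu - 1000) > joint
    return(list(th_m = st$th, r_m = st$r, g_m = st$grad,
                th_p = st$th, r_p = st$r, g_p = st$grad,
                th1 = st$th, lp1 = st$lp, n1 = n1, s1 = !div,
                alpha = min(1, exp(joint - joint0)), nalpha = 1L,
                div = div))
  }
  t1 <- .build_tree(th, r, g, logu, v, j - 1L, eps, joint0, invM, lp_grad)
  if (!t1$s1) return(t1)
  if (v == -1) {
    t2 <- .build_tree(t1$th_m, t1$r_m, t1$g_m, logu, v, j - 1L, eps, joint0,
                      invM, lp_grad)
    t1$th_m <- t2$th_m; t1$r_m <- t2$r_m; t1$g_m <- t2$g_m
  } else {
    t2 <- .build_tree(t1$th_p, t1$r_p, t1$g_p, logu, v, j - 1L, eps, joint0,
                      invM, lp_grad)
    t1$th_p <- t2$th_p; t1$r_p <- t2$r_p; t1$g_p <- t2$g_p
  }
  ntot <- t1$n1 + t2$n1
  if (t2$n1 > 0L && stats::runif(1) < t2$n1 / max(ntot, 1L)) {
    t1$th1 <- t2$th1
    t1$lp1 <- t2$lp1
  }
  dth <- t1$th_p - t1$th_m
  t1$s1 <- t1$s1 && t2$s1 &&
    sum(dth * (invM * t1$r_m)) >= 0 && sum(dth * (invM * t1$r_p)) >= 0
  t1$n1 <- ntot
  t1$alpha <- t1$alpha + t2$alpha
  t1$nalpha <- t1$nalpha + t2$nalpha
  t1$div <- t1$div || t2$div
  t1
}

# One chain.  Returns post-warmup draws plus diagnostics.
.nuts_chain <- function(lp_grad, theta0, iter, warmup, target_accept = 0.8,
                        max_treedepth = 10L) {
  npar <- length(theta0)
  th <- theta0
  e <- lp_grad(th)
  if (!is.finite(e$lp)) stop("log joint density not finite at initialisation",
                             call. = FALSE)
  invM <- rep(1, npar)
  eps <- .find_epsilon(th, e, invM, lp_grad)
  mu_da <- log(10 * eps)
  log_eps_bar <- 0
  Hbar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  m_da <- 0L

  # mass adaptation windows (Stan-style: init buffer, doubling windows,
  # terminal buffer), only when warmup is long enough
  win_end <- integer(0)
  if (warmup >= 150) {
    b1 <- 75; b3 <- 50
    pos <- b1; w <- 25
    while (pos + w < warmup - b3) {
      if (pos + 2 * w + b3 > warmup) w <- warmup - b3 - pos
      win_end <- c(win_end, pos + w)
      pos <- pos + w
      w <- 2 * w
    }
  }
  acc <- matrix(0, nrow = 0, ncol = npar)

  keep <- iter - warmup
  draws <- matrix(NA_real_, keep, npar)
  lps <- numeric(keep)
  div_count <- 0L
  depths <- integer(iter)

  for (m in seq_len(iter)) {
    r0 <- stats::rnorm(npar) / sqrt(invM)
    joint0 <- .nuts_joint(e$lp, r0, invM)
    logu <- joint0 - stats::rexp(1)
    th_m <- th; th_p <- th; r_m <- r0; r_p <- r0; g_m <- e$grad; g_p <- e$grad
    th1 <- th; lp1 <- e$lp
    j <- 0L; n <- 1L; s <- TRUE
    alpha <- 0; nalpha <- 1L; div <- FALSE
    while (s && j < max_treedepth) {
      v <- if (stats::runif(1) < 0.5) -1 else 1
      if (v == -1) {
        t <- .build_tree(th_m, r_m, g_m, logu, v, j, eps, joint0, invM, lp_grad)
        th_m <- t$th_m; r_m <- t$r_m; g_m <- t$g_m
      } else {
        t <- .build_tree(th_p, r_p, g_p, logu, v, j, eps, joint0, invM, lp_grad)
        th_p <- t$th_p; r_p <- t$r_p; g_p <- t$g_p
      }
      if (t$s1 && t$n1 > 0L && stats::runif(1) < min(1, t$n1 / n)) {
        th1 <- t$th1
        lp1 <- t$lp1
      }
      n <- n + t$n1
      alpha <- t$alpha; nalpha <- t$nalpha; div <- div || t$div
      dth <- th_p - th_m
      s <- t$s1 && sum(dth * (invM * r_m)) >= 0 && sum(dth * (invM * r_p)) >= 0
      j <- j + 1L
    }
    depths[m] <- j
    if (!identical(th1, th)) {
      th <- th1
      e <- lp_grad(th)
    }

    if (m <= warmup) {
      # dual averaging (counter restarts with each mass window)
      m_da <- m_da + 1L
      frac <- 1 / (m_da + t0)
      Hbar <- (1 - frac) * Hbar + frac * (target_accept - alpha / nalpha)
      log_eps <- mu_da - sqrt(m_da) / gamma * Hbar
      pow <- m_da^(-kappa)
      log_eps_bar <- pow * log_eps + (1 - pow) * log_eps_bar
      eps <- exp(log_eps)
      # mass windows
      acc <- rbind(acc, th)
      if (m %in% win_end) {
        nw <- nrow(acc)
        v_est <- apply(acc, 2, stats::var)
        invM <- (nw / (nw + 5)) * v_est + (5 / (nw + 5)) * 1e-3
        invM[invM <= 0 | !is.finite(invM)] <- 1
        acc <- matrix(0, nrow = 0, ncol = npar)
        eps <- .find_epsilon(th, e, invM, lp_grad)
        mu_da <- log(10 * eps)
        log_eps_bar <- 0; Hbar <- 0; m_da <- 0L
      }
      if (m == warmup) eps <- exp(log_eps_bar)
    } else {
      draws[m - warmup, ] <- th
      lps[m - warmup] <- e$lp
      if (div) div_count <- div_count + 1L
    }
  }
  list(draws = draws, lp = lps, divergences = div_count,
       step_size = eps, treedepth = depths)
}
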