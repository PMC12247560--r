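# NUTS sampling, R-hat diagnostics, MAP estimation.

# conjugate toy: y_i ~ N(theta, 1), theta ~ N(0, 1)
# posterior: N(sum(y)/(n+1), 1/(n+1))
conjugate_model <- function(y) {
  n <- length(y)
  list(
    par_names = "theta",
    lp = function(th) sum(dnorm(y, th, 1, log = TRUE)) + dnorm(th, 0, 1, log = TRUE),
    lp_grad = function(th) list(
      lp = sum(dnorm(y, th, 1, log = TRUE)) + dnorm(th, 0, 1, log = TRUE),
      grad = sum(y - th) - th),
    init = function() rnorm(1, 0, 0.5),
    dims = list(npar = 1L))
}

test_that("NUTS recovers a conjugate posterior", {
  set.seed(51)
  y <- rnorm(20, 1.5, 1)
  m <- conjugate_model(y)
  post_mean <- sum(y) / (length(y) + 1)
  post_sd <- sqrt(1 / (length(y) + 1))
  s <- sample_posterior(m, chains = 2, iter = 1200, warmup = 300, seed = 7)
  th <- as.vector(extract_par(s, "theta"))
  expect_equal(mean(th), post_mean, tolerance = 4 * post_sd / sqrt(200))
  expect_equal(sd(th), post_sd, tolerance = 0.1 * post_sd)
  expect_lte(unname(rhat(s, "theta")), 1.05)
})

test_that("sampling is exactly reproducible under a fixed seed", {
  set.seed(52)
  y <- rnorm(15)
  m <- conjugate_model(y)
  s1 <- sample_posterior(m, chains = 2, iter = 300, warmup = 120, seed = 3)
  s2 <- sample_posterior(m, chains = 2, iter = 300, warmup = 120, seed = 3)
  expect_identical(s1$draws, s2$draws)
  s3 <- sample_posterior(m, chains = 2, iter = 300, warmup = 120, seed = 4)
  expect_false(identical(s1$draws, s3$draws))
})

test_that("R-hat separates converged, identical and disjoint chains", {
  # identical chains: zero between-chain variance
  set.seed(53)
  v <- rnorm(500)
  expect_lte(rhat(cbind(v, v), method = "classic"), 1)
  expect_lte(rhat(cbind(v, v)), 1 + 1e-8)
  # chains from one distribution stay within [0.99, 1.05]
  r <- replicate(100, rhat(matrix(rnorm(2000), 1000, 2)))
  expect_true(all(r >= 0.99 & r <= 1.05))
  rc <- replicate(100, rhat(matrix(rnorm(2000), 1000, 2), method = "classic"))
  expect_true(all(rc >= 0.99 & rc <= 1.05))
  # grossly separated chains
  bad <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(rhat(bad), 1.1)
  expect_gt(rhat(bad, method = "classic"), 1.1)
  # single chain is an error
  expect_error(rhat(matrix(rnorm(100), 100, 1)), "2 chains")
})

test_that("R-hat trajectory over chain prefixes is monotone toward 1 in the long run", {
  set.seed(54)
  m <- conjugate_model(rnorm(20))
  s <- sample_posterior(m, chains = 2, iter = 700, warmup = 200, seed = 9)
  tr <- rhat_trajectory(s, "theta")
  expect_true(all(is.finite(tr$rhat)))
  expect_lte(tr$rhat[nrow(tr)], 1.05)
})

test_that("MAP matches the conjugate closed-form mode and is a fixed point", {
  set.seed(55)
  y <- rnorm(30, -0.8, 1)
  m <- conjugate_model(y)
  est <- map_estimate(m, restarts = 3, seed = 2)
  expect_equal(unname(est$par), sum(y) / (length(y) + 1), tolerance = 1e-6)
  # restarting from the MAP does not improve the log joint
  m2 <- m
  m2$init <- function() est$par
  est2 <- map_estimate(m2, restarts = 1, seed = 2)
  expect_lt(abs(est2$lp - est$lp), 1e-8)
})

test_that("MAP on a Gaussian cohort recovers the generating mean curve", {
  d <- simulate_cohort(sim_config(n_sites = 5, n_per_site = 1000,
                                  family = "normal", seed = 56))
  m <- cohort_model(hbr_spec("N"), d)
  est <- map_estimate(m, restarts = 1, seed = 5)
  X <- build_design_matrix(d$age, d$sex)
  p <- likelihood_params(hbr_spec("N"), est$par, X, batch_index_of(d$site),
                         n_sites = 5)
  truth <- attr(d, "truth")
  expect_lt(mean(abs(p$mu - truth$mu)), 0.05)
  expect_lt(mean(abs(p$sigma - truth$sigma)), 0.05)
})

test_that("more data contracts the posterior on identified mean weights", {
  # the sex weight is identified (the spline-age directions are partly
  # prior-constrained), so its posterior sd must shrink with n
  sd_wsex <- function(n_per_site, seed) {
    d <- simulate_cohort(sim_config(n_sites = 2, n_per_site = n_per_site,
                                    family = "normal", seed = seed))
    m <- cohort_model(hbr_spec("N"), d)
    s <- sample_posterior(m, chains = 2, iter = 400, warmup = 200, seed = seed)
    sd(draws_matrix(s)[, "w_mu[7]"])
  }
  expect_gt(sd_wsex(50, 58) / sd_wsex(450, 59), 1.5)
})

test_that("NUTS handles the hierarchical SHASH_b model on a small cohort", {
  d <- simulate_cohort(sim_config(n_sites = 2, n_per_site = 100, seed = 57))
  m <- cohort_model(hbr_spec("Sb1"), d)
  s <- sample_posterior(m, chains = 2, iter = 400, warmup = 200, seed = 6)
  expect_equal(dim(s$draws), c(200L, 2L, m$dims$npar))
  expect_true(all(is.finite(s$draws)))
  # delta stays above the link floor in every draw
  dr <- delta_link(as.vector(extract_par(s, "delta_raw")))
  expect_true(all(dr >= 0.3))
})
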