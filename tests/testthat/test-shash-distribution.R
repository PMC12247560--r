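# The sinh-arcsinh transform, SHASH densities, moments and links.

test_that("sinh-arcsinh transform matches closed forms and inverts", {
  expect_equal(sinh_arcsinh(0.7, 0, 1), 0.7, tolerance = 1e-14)
  expect_equal(sinh_arcsinh(0, 1, 1), sinh(-1), tolerance = 1e-12)
  # double-angle closed form: 2*sinh(asinh 1)*cosh(asinh 1) = 2*sqrt(2)
  expect_equal(sinh_arcsinh(1, 0, 2), 2 * sqrt(2), tolerance = 1e-12)
  x <- seq(-10, 10, length.out = 41)
  for (e in c(-1, 0, 1.5)) {
    for (d in c(0.4, 1, 3)) {
      expect_equal(inv_sinh_arcsinh(sinh_arcsinh(x, e, d), e, d), x,
                   tolerance = 1e-9)
      # strictly increasing
      expect_true(all(diff(sinh_arcsinh(x, e, d)) > 0))
    }
  }
  expect_error(sinh_arcsinh(1, 0, 0), "delta")
  expect_error(sinh_arcsinh(1, 0, -1), "delta")
})

test_that("SHASH density reduces to the standard Gaussian and normalises", {
  expect_equal(dshash(0, 0, 1, log = TRUE), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_equal(dshash(c(-1, 0, 2), 0, 1), dnorm(c(-1, 0, 2)),
               tolerance = 1e-12)
  for (e in c(-1, 0, 1)) {
    for (d in c(0.3, 0.5, 1, 2, 5)) {
      expect_equal(quad(function(x) dshash(x, e, d)), 1, tolerance = 1e-6)
    }
  }
})

test_that("SHASH log-density stays finite at extreme arguments", {
  v <- dshash(c(-1e6, 1e6), 1, 2, log = TRUE)
  expect_true(all(is.finite(v)))
  expect_true(all(v < -100))
})

test_that("SHASH density is skew-symmetric in (x, epsilon)", {
  x <- c(-3, -0.5, 0, 1.2, 7)
  for (d in c(0.5, 1, 2)) {
    expect_equal(dshash(x, 1.3, d, log = TRUE),
                 dshash(-x, -1.3, d, log = TRUE), tolerance = 1e-12)
  }
})

test_that("draws from the generative transform follow the density", {
  set.seed(401)
  e <- 0.7; d <- 1.4
  x <- rshash(1e5, e, d)
  ks <- suppressWarnings(
    ks.test(x, function(q) pnorm(sinh_arcsinh(q, e, d))))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("Bessel term P has its half-integer values and symmetry", {
  expect_equal(shash_P(0), 1, tolerance = 1e-12)
  expect_equal(shash_P(2), 3, tolerance = 1e-12)
  for (q in c(0.3, 1.7, 5)) expect_equal(shash_P(q), shash_P(-q),
                                         tolerance = 1e-12)
  # scaled evaluation keeps large orders finite where representable
  expect_true(is.finite(shash_P(150)))
  expect_equal(shash_P(150), shash_P(-150))
})

test_that("analytic moments match the Gaussian member and a sampling oracle", {
  expect_equal(shash_moment(1, 0, 1), 0, tolerance = 1e-12)
  expect_equal(shash_moment(2, 0, 1), 1, tolerance = 1e-12)
  expect_equal(shash_eta2(0, 1), 1, tolerance = 1e-12)
  # odd moments vanish at epsilon = 0
  expect_equal(shash_moment(3, 0, 0.8), 0, tolerance = 1e-10)
  set.seed(402)
  x <- rshash(1e6, 0.5, 1.5)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - shash_moment(1, 0.5, 1.5)), 3 * se)
})

test_that("moment formula agrees with quadrature for r = 1..4 over a shape grid", {
  for (e in c(-1, 0, 0.5)) {
    for (d in c(0.5, 1, 2)) {
      for (r in 1:4) {
        m_q <- quad_shash_moment(r, e, d)
        m_a <- shash_moment(r, e, d)
        expect_equal(m_a, m_q, tolerance = 1e-6,
                     label = sprintf("m(%d) at (%g, %g)", r, e, d))
      }
    }
  }
})

test_that("SHASH_o is the affine family: identity, normalisation, mean shift", {
  x <- c(-2, 0.3, 4)
  expect_equal(dshasho(x, 0, 1, 0.5, 0.8, log = TRUE),
               dshash(x, 0.5, 0.8, log = TRUE), tolerance = 1e-12)
  expect_equal(quad(function(x) dshasho(x, 2, 3, 0.5, 0.8)), 1,
               tolerance = 1e-6)
  # E[Omega] = mu + sigma * m(1), which differs from mu when epsilon != 0
  mean_q <- quad(function(x) x * dshasho(x, 2, 3, 0.5, 0.8))
  expect_equal(mean_q, 2 + 3 * shash_moment(1, 0.5, 0.8), tolerance = 1e-6)
  expect_gt(abs(mean_q - 2), 0.1)
  expect_error(dshasho(0, 0, -1, 0, 1), "sigma")
})

test_that("SHASH_b matches the standard normal in the Gaussian case", {
  x <- c(-1, 0, 2)
  expect_equal(dshashb(x, 0, 1, 0, 1, log = TRUE), dnorm(x, log = TRUE),
               tolerance = 1e-12)
  expect_error(dshashb(0, 0, 1, 0, -1), "delta")
})

test_that("SHASH_b mean and variance are exactly mu and sigma^2", {
  cases <- list(c(0, 1, 0, 1), c(2, 3, 1.5, 0.8), c(-1, 0.5, -0.7, 0.35),
                c(0, 1, 0.3, 1.2), c(5, 2, 2, 3))
  for (p in cases) {
    f <- function(x) dshashb(x, p[1], p[2], p[3], p[4])
    expect_equal(quad(function(x) x * f(x)), p[1], tolerance = 1e-6,
                 label = sprintf("mean at (%s)", paste(p, collapse = ",")))
    expect_equal(quad(function(x) (x - p[1])^2 * f(x)), p[2]^2,
                 tolerance = 1e-6,
                 label = sprintf("variance at (%s)", paste(p, collapse = ",")))
  }
  set.seed(403)
  b <- rshashb(1e6, 2, 3, 1.5, 0.8)
  expect_equal(mean(b), 2, tolerance = 0.02)
  expect_equal(var(b), 9, tolerance = 0.05)
})

test_that("SHASH_b is the SHASH_o family under an affine re-mapping", {
  set.seed(404)
  for (k in 1:5) {
    e <- runif(1, -1.5, 1.5)
    d <- runif(1, 0.4, 2.5)
    mu <- rnorm(1)
    sigma <- runif(1, 0.5, 3)
    m1 <- shash_moment(1, e, d)
    eta <- sqrt(shash_eta2(e, d))
    x <- rnorm(5, mu, 2 * sigma)
    expect_equal(dshashb(x, mu, sigma, e, d, log = TRUE),
                 dshasho(x, mu - sigma * m1 / eta, sigma / eta, e, d,
                         log = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("the generating transform and the z-score map are inverses", {
  z <- seq(-10, 10, length.out = 81)
  for (p in list(c(0, 1, 0, 1), c(2, 3, 1.5, 0.8), c(-1, 0.5, -0.7, 0.35))) {
    y <- shashb_from_gaussian(z, p[1], p[2], p[3], p[4])
    expect_equal(shashb_to_gaussian(y, p[1], p[2], p[3], p[4]), z,
                 tolerance = 1e-9)
  }
})

test_that("SHASH_b sampling is seeded and epsilon controls the skew sign", {
  set.seed(11); a <- rshashb(1000, 0, 1, 1, 1)
  set.seed(11); b <- rshashb(1000, 0, 1, 1, 1)
  expect_identical(a, b)
  set.seed(405)
  g <- rshashb(1e6, 0, 1, 0, 1)
  expect_equal(mean((g - mean(g))^3) / sd(g)^3, 0, tolerance = 0.02)
  expect_equal(mean((g - mean(g))^4) / var(g)^2 - 3, 0, tolerance = 0.05)
  s <- rshashb(1e5, 0, 1, 1, 1)
  expect_gt(mean((s - mean(s))^3), 0)
})

test_that("link functions match closed forms, are monotone and overflow-safe", {
  expect_equal(softplus(0), log(2), tolerance = 1e-12)
  expect_equal(delta_link(0), log(2) / 10 + 0.3, tolerance = 1e-12)
  expect_equal(delta_link(1), softplus(10) / 10 + 0.3, tolerance = 1e-12)
  expect_equal(delta_link(1), 1.3, tolerance = 1e-4)
  x <- seq(-1000, 1000, length.out = 2001)
  sp <- softplus(x)
  dl <- delta_link(x)
  expect_true(all(is.finite(sp)) && all(diff(sp) >= 0))
  expect_true(all(is.finite(dl)) && all(dl >= 0.3) && all(diff(dl) >= 0))
  # strictly positive and increasing wherever the result is representable
  xr <- seq(-700, 700, length.out = 1401)
  expect_true(all(softplus(xr) > 0) && all(diff(softplus(xr)) > 0))
  y <- c(0.01, 0.5, 3, 40)
  expect_equal(softplus(inv_softplus(y)), y, tolerance = 1e-9)
  d <- c(0.31, 0.9, 1.3, 4)
  expect_equal(delta_link(inv_delta_link(d)), d, tolerance = 1e-9)
})
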