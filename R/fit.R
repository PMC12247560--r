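# High-level fitting interface --------------------------------------------

#' Fit a hierarchical normative model to a cohort
#'
#' Builds the design matrix (storing its knot record), densely recodes
#' the site labels, constructs the generative model and runs either
#' NUTS sampling or MAP optimisation.  The response is expected on a
#' standardised scale (see [standardise()]); any standardisation record
#' attached to `data` is carried into the fit for later inversion of
#' predictions.
#'
#' @param data data frame with columns `age`, `sex`, `site` and the
#'   response.
#' @param spec an [hbr_spec()].
#' @param response name of the response column.
#' @param method `"mcmc"` or `"map"`.
#' @param chains,iter,warmup,seed passed to [sample_posterior()]
#'   (`seed` also seeds MAP restarts).
#' @param restarts MAP restarts when `method = "map"`.
#' @param ... further arguments to [sample_posterior()].
#' @return an object of class `"hbr_fit"` holding the spec, knot
#'   record, site levels, standardisation record (if any), the fitted
#'   posterior (`$samples`) and/or MAP (`$map`), and the training data.
#' @export
hbr_fit <- function(data, spec, response = "y",
                    method = c("mcmc", "map"),
                    chains = 2, iter = 1500, warmup = 500, seed = 1,
                    restarts = 2, ...) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "hbr_spec"))
  for (col in c("age", "sex", "site", response)) {
    if (!col %in% names(data)) stop("missing column: ", col, call. = FALSE)
  }
  X <- build_design_matrix(data$age, data$sex)
  bi <- batch_index(data$site)
  y <- data[[response]]
  model <- hbr_model(spec, X, as.integer(bi), y)
  fit <- list(
    spec = spec,
    knots = attr(X, "knots"),
    site_levels = attr(bi, "levels"),
    standardisation = attr(data, "standardisation"),
    response = response,
    method = method,
    seed = seed,
    data = data)
  if (method == "mcmc") {
    fit$samples <- sample_posterior(model, chains = chains, iter = iter,
                                    warmup = warmup, seed = seed, ...)
  } else {
    fit$map <- map_estimate(model, restarts = restarts, seed = seed)
  }
  class(fit) <- "hbr_fit"
  fit
}

#' @export
print.hbr_fit <- function(x, ...) {
  cat("Hierarchical normative model fit (", x$spec$variant, ", ",
      x$method, ")\n", sep = "")
  cat("  sites:", length(x$site_levels), " subjects:", nrow(x$data), "\n")
  if (!is.null(x$samples)) print(x$samples)
  if (!is.null(x$map)) print(x$map)
  invisible(x)
}

# rebuild the generative model bound to the training data
refit_model <- function(fit) {
  X <- build_design_matrix(fit$data$age, fit$data$sex, knots = fit$knots)
  bi <- batch_index(fit$data$site, levels = fit$site_levels)
  hbr_model(fit$spec, X, as.integer(bi), fit$data[[fit$response]])
}

#' Add a MAP estimate to an existing fit
#'
#' Rebuilds the generative model bound to the training data and runs
#' [map_estimate()], so that point (MAP) deviation scores are available
#' alongside posterior draws.
#'
#' @param fit an [hbr_fit()].
#' @param restarts,seed passed to [map_estimate()].
#' @return the fit with a `$map` element.
#' @export
add_map <- function(fit, restarts = 2, seed = fit$seed) {
  stopifnot(inherits(fit, "hbr_fit"))
  fit$map <- map_estimate(refit_model(fit), restarts = restarts, seed = seed)
  fit
}

# one parameter vector from a fit: MAP point, posterior mean, or a draw
point_theta <- function(fit, estimate = c("auto", "map", "mean", "draw"),
                        draw = NULL) {
  estimate <- match.arg(estimate)
  if (estimate == "auto") {
    estimate <- if (!is.null(fit$map)) "map" else "mean"
  }
  if (estimate == "map") {
    if (is.null(fit$map)) stop("fit has no MAP estimate", call. = FALSE)
    return(fit$map$par)
  }
  if (is.null(fit$samples)) stop("fit has no posterior samples", call. = FALSE)
  dm <- draws_matrix(fit$samples)
  if (estimate == "mean") return(colMeans(dm))
  if (is.null(draw)) stop("'draw' index required", call. = FALSE)
  dm[draw, ]
}

#' Per-subject likelihood parameters from a fitted model
#'
#' Evaluates the fitted model at new covariates, using the stored knot
#' record and site coding; unseen sites fall back to the group-level
#' mean offset.
#'
#' @param fit an [hbr_fit()].
#' @param newdata data frame with `age`, `sex`, `site` (defaults to the
#'   training data).
#' @param estimate `"auto"` (MAP when present, else posterior mean),
#'   `"map"`, `"mean"`, or `"draw"`.
#' @param draw draw index when `estimate = "draw"` (row of the stacked
#'   draws matrix).
#' @return parameter data frame as in [likelihood_params()].
#' @export
predict_params <- function(fit, newdata = NULL,
                           estimate = c("auto", "map", "mean", "draw"),
                           draw = NULL) {
  stopifnot(inherits(fit, "hbr_fit"))
  if (is.null(newdata)) newdata <- fit$data
  X <- build_design_matrix(newdata$age, newdata$sex, knots = fit$knots)
  bi <- batch_index(newdata$site, levels = fit$site_levels)
  theta <- point_theta(fit, estimate, draw)
  likelihood_params(fit$spec, theta, X, as.integer(bi),
                    n_sites = length(fit$site_levels))
}

#' Deviation scores from a fitted model
#'
#' `estimator = "point"` evaluates [zscore()] at a single parameter
#' point (MAP when available, otherwise the posterior mean).
#' `estimator = "mcmc"` computes a z-score per retained posterior draw
#' and averages over draws.
#'
#' @inheritParams predict_params
#' @param estimator `"point"` or `"mcmc"`.
#' @param thin keep every `thin`-th draw for the MCMC estimator.
#' @return numeric vector of deviation scores with attribute
#'   `"estimator"`.
#' @export
zscores <- function(fit, newdata = NULL, estimator = c("point", "mcmc"),
                    thin = 1L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(fit, "hbr_fit"))
  if (is.null(newdata)) newdata <- fit$data
  y <- newdata[[fit$response]]
  if (estimator == "point") {
    z <- zscore(y, predict_params(fit, newdata))
  } else {
    if (is.null(fit$samples)) stop("fit has no posterior samples", call. = FALSE)
    dm <- draws_matrix(fit$samples)
    rows <- seq(1, nrow(dm), by = thin)
    X <- build_design_matrix(newdata$age, newdata$sex, knots = fit$knots)
    bi <- as.integer(batch_index(newdata$site, levels = fit$site_levels))
    acc <- numeric(length(y))
    for (r in rows) {
      p <- likelihood_params(fit$spec, dm[r, ], X, bi,
                             n_sites = length(fit$site_levels))
      acc <- acc + zscore(y, p)
    }
    z <- acc / length(rows)
  }
  attr(z, "estimator") <- if (estimator == "point") "MAP" else "MCMC-mean"
  z
}

#' Centile curves from a fitted model
#'
#' Evaluates the fitted centiles on an age grid at fixed sex and site.
#'
#' @inheritParams predict_params
#' @param age_grid ages at which to evaluate (default: 100 points over
#'   the training knot span).
#' @param sex sex indicator for the curves (0 or 1).
#' @param site site label; `NA` (default) uses the group-level mean
#'   offset.
#' @param levels Gaussian-space levels.
#' @return data frame in long format: `age`, `level`, `percentile`,
#'   `value`.
#' @export
centile_curves <- function(fit, age_grid = NULL, sex = 0, site = NA,
                           levels = -3:3,
                           estimate = c("auto", "map", "mean", "draw"),
                           draw = NULL) {
  stopifnot(inherits(fit, "hbr_fit"))
  if (is.null(age_grid))
    age_grid <- seq(fit$knots$boundary[1], fit$knots$boundary[2], length.out = 100)
  nd <- data.frame(age = age_grid, sex = sex,
                   site = if (is.na(site)) "(new site)" else site)
  p <- predict_params(fit, nd, estimate = estimate, draw = draw)
  cv <- centile_values(p, levels = levels)
  data.frame(
    age = rep(age_grid, times = length(levels)),
    level = rep(levels, each = length(age_grid)),
    percentile = rep(attr(cv, "percentiles"), each = length(age_grid)),
    value = as.vector(cv))
}
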