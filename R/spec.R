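# Model specification -----------------------------------------------------

#' Default prior settings
#'
#' Named list of `(location, scale)` pairs for every free parameter of
#' the hierarchical model.  Scales are standard deviations.  Central
#' values are used throughout except for the raw tail parameter, whose
#' prior is centred at 1 to push the sampler away from the unstable
#' low-`delta` region, and the raw scale intercept, centred at 1 because
#' responses are standardised so the scale is expected near 1.
#'
#' @return named list of numeric length-2 vectors (`sigma_tau` is a
#'   single half-normal scale).
#' @export
default_priors <- function() {
  list(
    w_mu        = c(0, 1),
    mu_tau      = c(0, 1),
    sigma_tau   = 1,          # half-normal scale
    nu          = c(0, 1),
    w_sigma     = c(0, 1),
    tau_sigma   = c(1, 1),
    epsilon     = c(0, 1),
    delta_raw   = c(1, 1),
    w_epsilon   = c(0, 0.2),
    tau_epsilon = c(0, 0.2),
    w_delta     = c(0, 0.2),
    tau_delta   = c(1, 0.3)
  )
}

#' Specify a hierarchical normative model variant
#'
#' The four likelihood variants:
#' * `"N"`   — Gaussian likelihood; mean with site random intercept,
#'   heteroskedastic scale through a softplus link.
#' * `"So1"` — SHASH_o likelihood; constant skew `epsilon` and tail
#'   `delta` (through `delta_link`, so `delta >= 0.3`).
#' * `"Sb1"` — moment-standardised SHASH_b likelihood; constant
#'   `epsilon` and `delta`.
#' * `"Sb2"` — SHASH_b with `epsilon` and raw `delta` as linear
#'   regressions on the design matrix (covariate-dependent skew and
#'   tail weight), with tighter priors on those weights.
#'
#' In every variant the mean is a linear function of the design matrix
#' plus a site-specific intercept sampled (non-centred) as a deviation
#' from a group mean; `mu_random_intercept = FALSE` ablates the site
#' term down to the single group-level intercept, which is useful for
#' demonstrating residual site effects.  The raw scale is a linear fixed
#' effect mapped through `softplus`.
#'
#' @param variant one of `"N"`, `"So1"`, `"Sb1"`, `"Sb2"`.
#' @param mu_random_intercept logical; include the per-site random
#'   intercept in the mean?
#' @param priors prior settings as from [default_priors()]; entries
#'   override the defaults.
#' @return an object of class `"hbr_spec"`.
#' @examples
#' hbr_spec("Sb1")
#' @export
hbr_spec <- function(variant = c("Sb1", "N", "So1", "Sb2"),
                     mu_random_intercept = TRUE,
                     priors = NULL) {
  variant <- match.arg(variant)
  p <- default_priors()
  if (!is.null(priors)) {
    bad <- setdiff(names(priors), names(p))
    if (length(bad)) stop("unknown prior entries: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(priors)] <- priors
  }
  sc <- unlist(lapply(p, function(v) v[length(v)]))
  if (any(sc <= 0)) stop("prior scales must be strictly positive", call. = FALSE)
  likelihood <- switch(variant, N = "normal", So1 = "shasho",
                       Sb1 = "shashb", Sb2 = "shashb")
  shape_model <- switch(variant, N = "none", So1 = "constant",
                        Sb1 = "constant", Sb2 = "linear")
  structure(
    list(variant = variant,
         likelihood = likelihood,
         shape_model = shape_model,
         mu_model = if (mu_random_intercept) "random_intercept" else "fixed_intercept",
         priors = p),
    class = "hbr_spec")
}

#' @export
print.hbr_spec <- function(x, ...) {
  cat("Hierarchical normative model spec\n")
  cat("  variant:    ", x$variant, "\n")
  cat("  likelihood: ", x$likelihood, "\n")
  cat("  mu model:   linear +", if (x$mu_model == "random_intercept")
    "site random intercept" else "single intercept", "\n")
  cat("  shape model:", x$shape_model, "\n")
  invisible(x)
}

#' Read and write model specifications as plain-text config
#'
#' Serialises an [hbr_spec()] to JSON and back, losslessly.
#'
#' @param spec an `hbr_spec` object.
#' @param path file path.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "hbr_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hbr_spec(variant = x$variant,
           mu_random_intercept = identical(x$mu_model, "random_intercept"),
           priors = x$priors)
}
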