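# Cohort I/O, preprocessing, persistence ----------------------------------

#' Read a cohort table from delimited text
#'
#' Validates and normalises a subjects-by-columns table: age and
#' responses must be numeric and complete, sex must code to 0/1, and
#' site labels are recoded to a factor whose level order (the dense
#' integer coding) is stored for round-tripping.
#'
#' @param path file path.
#' @param age,sex,site column names in the file.
#' @param responses character vector of response column names.
#' @param sep field separator.
#' @return data frame with columns `age`, `sex`, `site` (factor) and
#'   the response columns, plus attribute `"site_levels"`.
#' @export
read_cohort <- function(path, age = "age", sex = "sex", site = "site",
                        responses = "y", sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(age, sex, site, responses)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(age = raw[[age]], sex = raw[[sex]],
                    site = as.character(raw[[site]]),
                    check.names = FALSE)
  for (r in responses) out[[r]] <- raw[[r]]
  if (!is.numeric(out$age) || any(!is.finite(out$age)))
    stop("column '", age, "' must be numeric and complete", call. = FALSE)
  sx <- out$sex
  if (is.character(sx)) {
    sx <- c(M = 1, F = 0, m = 1, f = 0, "0" = 0, "1" = 1)[sx]
  }
  if (any(is.na(sx)) || !all(sx %in% c(0, 1)))
    stop("column '", sex, "' must code to 0/1 (or M/F)", call. = FALSE)
  out$sex <- as.numeric(sx)
  for (r in responses) {
    if (!is.numeric(out[[r]]) || any(!is.finite(out[[r]])))
      stop("response column '", r, "' must be numeric and complete",
           call. = FALSE)
  }
  levels <- sort(unique(out$site))
  out$site <- factor(out$site, levels = levels)
  attr(out, "site_levels") <- levels
  out
}

#' Write a cohort (and optional generative truth) to delimited text
#'
#' @param data cohort data frame (e.g. from [simulate_cohort()]).
#' @param path output file path.
#' @param truth_path optional path for a JSON sidecar recording the
#'   `"truth"` attribute, for later recovery checks.
#' @param sep field separator.
#' @export
write_cohort <- function(data, path, truth_path = NULL, sep = ",") {
  utils::write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    tr <- attr(data, "truth")
    if (is.null(tr)) stop("'data' has no truth attribute", call. = FALSE)
    tr$config <- unclass(tr$config)
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' Feature-wise standardisation fitted on a training split
#'
#' Subtracts the mean and divides by the standard deviation of each
#' response column, with both statistics estimated on the fit split
#' only and applied to all rows.  An optional natural-log transform per
#' column (for strictly positive, severely skewed responses) is applied
#' before standardising.  The transform record is attached so that
#' predictions can be mapped back via [unstandardise()].
#'
#' @param data cohort data frame.
#' @param responses response column names.
#' @param fit_idx row indices of the fit (training) split; defaults to
#'   all rows.
#' @param log_transform logical, recycled over `responses`.
#' @return `data` with transformed responses and attribute
#'   `"standardisation"` (per column: `mean`, `sd`, `log`).
#' @export
standardise <- function(data, responses = "y", fit_idx = seq_len(nrow(data)),
                        log_transform = FALSE) {
  if (!length(fit_idx)) stop("fit split is empty", call. = FALSE)
  log_transform <- rep_len(log_transform, length(responses))
  rec <- list()
  for (k in seq_along(responses)) {
    r <- responses[k]
    v <- data[[r]]
    if (log_transform[k]) {
      if (any(v <= 0)) stop("log transform requires strictly positive '",
                            r, "'", call. = FALSE)
      v <- log(v)
    }
    m <- mean(v[fit_idx])
    s <- stats::sd(v[fit_idx])
    if (!is.finite(s) || s <= 0) stop("zero standard deviation in fit split of '",
                                      r, "'", call. = FALSE)
    data[[r]] <- (v - m) / s
    rec[[r]] <- list(mean = m, sd = s, log = log_transform[k])
  }
  attr(data, "standardisation") <- rec
  data
}

#' Invert a standardisation record
#'
#' @param values standardised values.
#' @param record one column's record from the `"standardisation"`
#'   attribute (`list(mean, sd, log)`).
#' @return values on the original scale.
#' @export
unstandardise <- function(values, record) {
  v <- values * record$sd + record$mean
  if (isTRUE(record$log)) v <- exp(v)
  v
}

#' Stratified cross-validation folds with small-cell filtering
#'
#' Site-by-sex cells with fewer than `min_count` subjects are dropped
#' before splitting (so every retained site appears, for both sexes, in
#' every training split); the remaining subjects are dealt round-robin
#' into `k` folds within each cell, in a seeded random order.
#'
#' @param data cohort data frame with `site` and `sex`.
#' @param k number of folds.
#' @param min_count minimum subjects per site-by-sex cell.
#' @param seed integer seed.
#' @return an object of class `"fold_spec"`: `fold` (integer per row,
#'   `NA` for dropped rows), `dropped` (row indices), `k`, `seed`.
#' @export
stratified_folds <- function(data, k = 10, min_count = 10, seed = 1) {
  if (k < 2) stop("'k' must be >= 2", call. = FALSE)
  cell <- interaction(data$site, data$sex, drop = TRUE)
  counts <- table(cell)
  small <- names(counts)[counts < min_count]
  keep <- !(as.character(cell) %in% small)
  if (sum(keep) < k) stop("fewer retained subjects than folds", call. = FALSE)
  fold <- rep(NA_integer_, nrow(data))
  set.seed(as.integer(seed))
  for (cl in setdiff(levels(cell), small)) {
    rows <- which(as.character(cell) == cl & keep)
    rows <- rows[sample.int(length(rows))]
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  if (min_count < k)
    warning("min_count < k: some folds may miss a retained cell", call. = FALSE)
  structure(list(fold = fold, dropped = which(!keep), k = k, seed = seed),
            class = "fold_spec")
}

# Model persistence --------------------------------------------------------

# CSV writer that round-trips doubles exactly (17 significant digits)
.write_full_csv <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Save and load a fitted model as a plain-text bundle
#'
#' Writes a directory containing a JSON manifest (spec, knot record,
#' site coding, standardisation record, seed, package version), the MAP
#' estimate (JSON), posterior draws (CSV, one column per parameter plus
#' chain/draw indices) and the training data (CSV).  `load_model`
#' reconstructs an [hbr_fit()] producing identical predictions;
#' a bundle without a knot record is refused rather than silently
#' re-deriving knots.
#'
#' @param fit an `hbr_fit`.
#' @param dir bundle directory (created if needed).
#' @export
save_model <- function(fit, dir) {
  stopifnot(inherits(fit, "hbr_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("shashnorm")),
    spec = unclass(fit$spec),
    knots = fit$knots,
    site_levels = fit$site_levels,
    standardisation = fit$standardisation,
    response = fit$response,
    method = fit$method,
    seed = fit$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  .write_full_csv(fit$data, file.path(dir, "training_data.csv"))
  if (!is.null(fit$map)) {
    jsonlite::write_json(list(par = as.list(fit$map$par), lp = fit$map$lp,
                              grad_norm = fit$map$grad_norm,
                              convergence = fit$map$convergence),
                         file.path(dir, "map.json"),
                         auto_unbox = TRUE, digits = I(17))
  }
  if (!is.null(fit$samples)) {
    s <- fit$samples
    dm <- draws_matrix(s)
    keep <- dim(s$draws)[1]
    df <- data.frame(chain = rep(seq_len(s$chains), each = keep),
                     draw = rep(seq_len(keep), times = s$chains),
                     dm, check.names = FALSE)
    .write_full_csv(df, file.path(dir, "posterior.csv"))
    jsonlite::write_json(
      list(chains = s$chains, iter = s$iter, warmup = s$warmup,
           seed = s$seed, divergences = s$divergences,
           step_size = s$step_size, par_names = s$par_names),
      file.path(dir, "sampler.json"), auto_unbox = TRUE, digits = I(17))
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (is.null(mf$format_version) || mf$format_version != 1L)
    stop("unsupported model bundle version", call. = FALSE)
  if (is.null(mf$knots) || is.null(mf$knots$interior))
    stop("model bundle is missing the knot record", call. = FALSE)
  data <- utils::read.csv(file.path(dir, "training_data.csv"))
  data$site <- factor(data$site, levels = mf$site_levels)
  fit <- list(
    spec = hbr_spec(mf$spec$variant,
                    mu_random_intercept = identical(mf$spec$mu_model,
                                                    "random_intercept"),
                    priors = mf$spec$priors),
    knots = list(interior = as.numeric(mf$knots$interior),
                 boundary = as.numeric(mf$knots$boundary)),
    site_levels = mf$site_levels,
    standardisation = mf$standardisation,
    response = mf$response,
    method = mf$method,
    seed = mf$seed,
    data = data)
  map_path <- file.path(dir, "map.json")
  if (file.exists(map_path)) {
    m <- jsonlite::read_json(map_path, simplifyVector = TRUE)
    fit$map <- structure(list(par = unlist(m$par), lp = m$lp,
                              grad_norm = m$grad_norm,
                              convergence = m$convergence),
                         class = "hbr_map")
  }
  post_path <- file.path(dir, "posterior.csv")
  if (file.exists(post_path)) {
    sj <- jsonlite::read_json(file.path(dir, "sampler.json"),
                              simplifyVector = TRUE)
    df <- utils::read.csv(post_path, check.names = FALSE)
    keep <- sj$iter - sj$warmup
    npar <- length(sj$par_names)
    draws <- array(NA_real_, c(keep, sj$chains, npar),
                   dimnames = list(NULL, NULL, sj$par_names))
    for (ch in seq_len(sj$chains)) {
      draws[, ch, ] <- as.matrix(df[df$chain == ch, sj$par_names, drop = FALSE])
    }
    fit$samples <- structure(
      list(draws = draws, lp = NULL, chains = sj$chains, warmup = sj$warmup,
           iter = sj$iter, seed = sj$seed, divergences = sj$divergences,
           step_size = sj$step_size, par_names = sj$par_names),
      class = "hbr_samples")
  }
  class(fit) <- "hbr_fit"
  fit
}
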