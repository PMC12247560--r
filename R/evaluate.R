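# Deviation scores, centiles, goodness-of-fit -----------------------------

#' Deviation (z-) scores at fixed likelihood parameters
#'
#' Maps observations through the fitted distribution back to the
#' Gaussian domain.  For the SHASH_b family this is the inverse of the
#' generating transform:
#' `z = sinh_arcsinh((y - mu)/sigma * eta + m(1))`; for SHASH_o,
#' `z = sinh_arcsinh((y - mu)/sigma)`; for the Gaussian family it
#' reduces to `(y - mu)/sigma`.  Under a correctly specified model the
#' scores of healthy data are standard normal.
#'
#' @param y numeric response vector.
#' @param params per-subject parameter data frame from
#'   [likelihood_params()] / [predict_params()] (columns `mu`, `sigma`,
#'   `epsilon`, `delta`, attribute `"family"`).
#' @return numeric vector of deviation scores.
#' @export
zscore <- function(y, params) {
  fam <- attr(params, "family")
  if (is.null(fam)) stop("'params' must carry a \"family\" attribute", call. = FALSE)
  check_scale(params$sigma)
  switch(fam,
         normal = (y - params$mu) / params$sigma,
         shasho = sinh_arcsinh((y - params$mu) / params$sigma,
                               params$epsilon, params$delta),
         shashb = shashb_to_gaussian(y, params$mu, params$sigma,
                                     params$epsilon, params$delta),
         stop("unknown family: ", fam, call. = FALSE))
}

#' Centile curves over a covariate grid
#'
#' Response values at fixed Gaussian-space levels `g`, obtained by
#' pushing `g` through the fitted generating transform at each grid
#' point (for the Gaussian family this is `mu + g * sigma`).  Levels
#' `-3..3` correspond to the 0.1, 2.3, 15.9, 50, 84.1, 97.7 and 99.9
#' percentiles.  Curves are strictly increasing in `g` at every grid
#' point because the transform is monotone.
#'
#' @param params per-subject (grid-point) parameter data frame as in
#'   [zscore()].
#' @param levels Gaussian-space levels.
#' @return matrix of dimension `nrow(params) x length(levels)`; column
#'   names give the level, attribute `"percentiles"` the corresponding
#'   percentile (rounded to one decimal).
#' @export
centile_values <- function(params, levels = -3:3) {
  fam <- attr(params, "family")
  if (is.null(fam)) stop("'params' must carry a \"family\" attribute", call. = FALSE)
  out <- vapply(levels, function(g) {
    switch(fam,
           normal = params$mu + g * params$sigma,
           shasho = params$mu + params$sigma *
             inv_sinh_arcsinh(g, params$epsilon, params$delta),
           shashb = shashb_from_gaussian(g, params$mu, params$sigma,
                                         params$epsilon, params$delta),
           stop("unknown family: ", fam, call. = FALSE))
  }, numeric(nrow(params)))
  out <- matrix(out, nrow = nrow(params))
  colnames(out) <- as.character(levels)
  attr(out, "percentiles") <- round(stats::pnorm(levels) * 100, 1)
  out
}

#' Skew and excess kurtosis of deviation scores
#'
#' Third and fourth standardised central moments of the scores; the
#' fourth is reduced by 3 (excess kurtosis) so that the ideal value of
#' both is 0 for standard-normal deviations.
#'
#' @param z numeric vector of deviation scores (n >= 8).
#' @return list with `skew`, `excess_kurtosis`, `n`.
#' @export
moments_report <- function(z) {
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 8) stop("need at least 8 scores", call. = FALSE)
  m <- mean(z)
  m2 <- mean((z - m)^2)
  if (m2 <= 0) stop("zero variance in scores", call. = FALSE)
  list(skew = mean((z - m)^3) / m2^1.5,
       excess_kurtosis = mean((z - m)^4) / m2^2 - 3,
       n = n)
}

# rank-based (Mann-Whitney) AUC with midrank tie handling
.rank_auc <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  r <- rank(c(x1, x0), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pairwise site-separability of deviation scores
#'
#' For every pair of sites, the rank-based AUC of classifying site
#' membership from the z-scores alone, stored as `|AUC - 0.5|` (0 =
#' sites indistinguishable, i.e. site effects fully removed; 0.5 =
#' perfect separation).  Diagonal 0 by convention; the raw AUC matrix
#' is attached as attribute `"auc"`.
#'
#' @param z deviation scores.
#' @param site site labels (factor or character), >= 2 sites.
#' @return S x S matrix of `|AUC - 0.5|` with site dimnames.
#' @export
auc_matrix <- function(z, site) {
  site <- as.character(site)
  lev <- sort(unique(site))
  if (length(lev) < 2) stop("need at least 2 sites", call. = FALSE)
  S <- length(lev)
  A <- matrix(0, S, S, dimnames = list(lev, lev))
  raw <- matrix(0.5, S, S, dimnames = list(lev, lev))
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      zi <- z[site == lev[i]]
      zj <- z[site == lev[j]]
      if (!length(zi) || !length(zj)) {
        A[i, j] <- A[j, i] <- NA_real_
        raw[i, j] <- raw[j, i] <- NA_real_
        next
      }
      a <- .rank_auc(zi, zj)
      raw[i, j] <- a
      raw[j, i] <- 1 - a
      A[i, j] <- A[j, i] <- abs(a - 0.5)
    }
  }
  attr(A, "auc") <- raw
  A
}

#' Quantile-quantile data for deviation scores
#'
#' Paired theoretical (standard normal) and empirical quantiles, for
#' qq-plotting by the caller.
#'
#' @param z deviation scores.
#' @return data frame with columns `theoretical`, `empirical`.
#' @export
qq_data <- function(z) {
  z <- z[is.finite(z)]
  data.frame(theoretical = stats::qnorm(stats::ppoints(length(z))),
             empirical = sort(z))
}

#' Write goodness-of-fit tables as delimited text
#'
#' `write_moments_table` takes a named list of [moments_report()]
#' results (one per phenotype/model) and writes one row each with
#' columns `label, skew, excess_kurtosis, n`.  `write_auc_table`
#' writes a labelled square `|AUC - 0.5|` matrix.
#'
#' @param reports named list of moment reports.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_moments_table <- function(reports, path, sep = ",") {
  df <- data.frame(
    label = names(reports),
    skew = vapply(reports, function(r) r$skew, numeric(1)),
    excess_kurtosis = vapply(reports, function(r) r$excess_kurtosis, numeric(1)),
    n = vapply(reports, function(r) r$n, numeric(1)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_moments_table
#' @param mat matrix from [auc_matrix()].
#' @export
write_auc_table <- function(mat, path, sep = ",") {
  utils::write.table(as.data.frame(mat), path, sep = sep,
                     row.names = TRUE, col.names = NA, quote = FALSE)
  invisible(path)
}
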