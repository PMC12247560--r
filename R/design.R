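# Covariate design matrix -------------------------------------------------

#' Build the covariate design matrix
#'
#' Columns are a 5-column cubic B-spline basis expansion of age
#' (two interior knots placed equally over the training age range),
#' followed by age rescaled to \[0, 1\] over that range, and the binary
#' sex indicator: 7 columns in total.  The knot record returned with the
#' matrix must be stored with a fitted model and passed back at
#' prediction time so that the basis is reproduced exactly; ages outside
#' the knot span are clamped to the boundary with a warning.
#'
#' @param age numeric vector of ages in years.
#' @param sex binary (0/1) vector.
#' @param knots optional knot record from a previous call (the
#'   `"knots"` attribute of a design matrix); when `NULL`, knots are
#'   derived from the range of `age`.
#' @return numeric matrix with columns `bs1..bs5`, `age`, `sex` and a
#'   `"knots"` attribute `list(interior, boundary)`.
#' @examples
#' X <- build_design_matrix(c(25, 40, 60, 75), c(0, 1, 0, 1))
#' ncol(X)  # 7
#' @export
build_design_matrix <- function(age, sex, knots = NULL) {
  if (any(!is.finite(age))) stop("'age' must be finite", call. = FALSE)
  if (length(sex) != length(age)) stop("'age' and 'sex' lengths differ", call. = FALSE)
  if (!all(sex %in% c(0, 1))) stop("'sex' must be binary 0/1", call. = FALSE)
  if (is.null(knots)) {
    boundary <- range(age)
    if (diff(boundary) <= 0) {
      # degenerate training range: widen symmetrically so bs() is defined
      boundary <- boundary + c(-0.5, 0.5)
    }
    interior <- boundary[1] + diff(boundary) * c(1, 2) / 3
    knots <- list(interior = interior, boundary = boundary)
  } else {
    if (is.null(knots$interior) || is.null(knots$boundary))
      stop("knot record must contain 'interior' and 'boundary'", call. = FALSE)
  }
  clamped <- age < knots$boundary[1] | age > knots$boundary[2]
  if (any(clamped)) {
    warning(sprintf("%d age value(s) outside the knot span were clamped", sum(clamped)),
            call. = FALSE)
    age <- pmin(pmax(age, knots$boundary[1]), knots$boundary[2])
  }
  B <- splines::bs(age, knots = knots$interior, Boundary.knots = knots$boundary,
                   degree = 3, intercept = FALSE)
  age01 <- (age - knots$boundary[1]) / diff(knots$boundary)
  X <- cbind(B[, 1:5, drop = FALSE], age01, sex)
  colnames(X) <- c(paste0("bs", 1:5), "age", "sex")
  attr(X, "knots") <- knots
  X
}

# Batch (site) index ------------------------------------------------------

# Densely recode a site label vector against an optional reference level
# set; unseen labels at prediction time are flagged with NA and handled
# downstream (offset falls back to the group mean).
batch_index <- function(site, levels = NULL) {
  site <- as.character(site)
  if (is.null(levels)) levels <- sort(unique(site))
  idx <- match(site, levels)
  structure(idx, levels = levels)
}
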