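# Model-quality metrics, rater consistency, the linear-regression baseline
# and the 2- vs 4-parameter comparative ranking analysis.

#' Root-mean-square error
#'
#' @param actual,predicted Equal-length numeric vectors of magnitudes.
#' @return `sqrt(mean((actual - predicted)^2))`.
#' @export
rmse <- function(actual, predicted) {
  stopifnot(is.numeric(actual), is.numeric(predicted))
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (!length(actual)) stop("need at least one record")
  sqrt(mean((actual - predicted)^2))
}

#' Mean absolute percentage error
#'
#' Mean of `|actual - predicted| / |actual|`, reported as a fraction (0.18
#' means 18%). Records with `actual == 0` would divide by zero; they are
#' excluded and their count attached as attribute `n_excluded`.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return MAPE as a fraction, with attribute `n_excluded`.
#' @export
mape <- function(actual, predicted) {
  stopifnot(is.numeric(actual), is.numeric(predicted))
  if (length(actual) != length(predicted)) stop("length mismatch")
  keep <- actual != 0
  if (!any(keep)) stop("MAPE undefined: every actual value is zero")
  out <- mean(abs((actual[keep] - predicted[keep]) / actual[keep]))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' The squared sample correlation between actual and predicted magnitudes,
#' always in `[0, 1]`.
#'
#' @param actual,predicted Equal-length numeric vectors, `n >= 2`, each
#'   with nonzero variance.
#' @return Squared correlation.
#' @export
r_squared <- function(actual, predicted) {
  stopifnot(is.numeric(actual), is.numeric(predicted))
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 2) stop("need at least two records")
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0) {
    stop("R squared undefined: zero variance")
  }
  stats::cor(actual, predicted)^2
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient for a cases-by-items rating matrix:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total scores))`, items
#' in columns. For inter-rater consistency of a multi-site survey, put the
#' rated risks in rows and the raters (sites) in columns — alpha then
#' measures how consistently the raters order the risks. A matrix with no
#' variance at all (every item constant) is the 0/0 limit of the formula
#' and returns 1 — perfect agreement; any other zero-total-variance matrix
#' is an error.
#'
#' @param ratings Numeric matrix, cases in rows (>= 2), items in columns
#'   (>= 2).
#' @return Alpha.
#' @export
cronbach_alpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  stopifnot(is.numeric(ratings))
  k <- ncol(ratings)
  if (k < 2) stop("Cronbach's alpha needs at least 2 items")
  if (nrow(ratings) < 2) stop("Cronbach's alpha needs at least 2 raters")
  item_var <- apply(ratings, 2, stats::var)
  total_var <- stats::var(rowSums(ratings))
  if (total_var == 0) {
    if (all(item_var == 0)) return(1)  # perfect agreement
    stop("Cronbach's alpha undefined: zero total-score variance")
  }
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

#' Metrics report
#'
#' Bundles the three fit measures. A metric that is undefined for the data
#' at hand (MAPE with all-zero actuals, R squared with zero variance) is
#' reported as `NA` rather than aborting the report.
#'
#' @param actual,predicted Equal-length magnitude vectors.
#' @return A `metrics_report` list with `rmse`, `mape`, `r2`, `n`.
#' @export
metrics_report <- function(actual, predicted) {
  structure(list(
    rmse = rmse(actual, predicted),
    mape = tryCatch(as.numeric(mape(actual, predicted)),
                    error = function(e) NA_real_),
    r2 = tryCatch(r_squared(actual, predicted),
                  error = function(e) NA_real_),
    n = length(actual)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  RMSE = %.4f  MAPE = %.4f  R2 = %.4f\n",
              x$n, x$rmse, x$mape, x$r2))
  invisible(x)
}

#' Ordinary least-squares baseline
#'
#' Fits magnitude on the four normalized ratings by OLS (intercept
#' included) and reports test-set metrics — the conventional regression
#' benchmark the neuro-fuzzy model is compared against. A rank-deficient
#' design is solved anyway (dropped coefficients set to zero) with a
#' warning.
#'
#' @param train_x,test_x Matrices of normalized inputs (one column per
#'   rating parameter).
#' @param train_y,test_y Magnitude targets.
#' @return A [metrics_report()] on the test set, with the fitted
#'   coefficients attached as attribute `coefficients`.
#' @export
linear_baseline <- function(train_x, train_y, test_x, test_y) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  fit <- stats::lm.fit(cbind(1, train_x), train_y)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    warning("rank-deficient design; dropped coefficients set to zero")
    beta[is.na(beta)] <- 0
  }
  pred <- drop(cbind(1, test_x) %*% beta)
  out <- metrics_report(test_y, pred)
  attr(out, "coefficients") <- beta
  out
}

#' Compare 2-parameter and 4-parameter risk rankings
#'
#' The traditional assessment ranks risks by probability x severity alone;
#' the four-parameter magnitude adds exposure and detectability. This ranks
#' each risk under both schemes (2-parameter score normalized over its raw
#' range `[1, 81]`) and reports the tie-group structure — risks the
#' 2-parameter scheme cannot distinguish often separate under four
#' parameters.
#'
#' @param records Assessment data frame with columns `risk_id` and raw
#'   ratings `probability`, `severity`, `exposure`, `detectability` (any
#'   admissible encoding).
#' @param aggregation Multi-site aggregation rule, see
#'   [aggregate_magnitudes()].
#' @return A list with `ranks` (data frame: `risk_id`, `score2`, `score4`,
#'   `rank2`, `rank4`) and `tie_groups` (per scheme, the sizes of groups
#'   sharing a score).
#' @export
compare_parameterizations <- function(records, aggregation = "mean") {
  stopifnot(is.data.frame(records))
  p <- coerce_rating(records$probability, "probability")$raw
  s <- coerce_rating(records$severity, "severity")$raw
  e <- coerce_rating(records$exposure, "exposure")$raw
  d <- coerce_rating(records$detectability, "detectability")$raw
  score2 <- normalize_minmax(p * s, 1, 81)
  score4 <- risk_magnitude(p, s, e, d)$norm
  agg2 <- tapply(score2, records$risk_id, aggregate_magnitudes,
                 method = aggregation)
  agg4 <- tapply(score4, records$risk_id, aggregate_magnitudes,
                 method = aggregation)
  agg2 <- agg2[unique(as.character(records$risk_id))]
  agg4 <- agg4[names(agg2)]
  ranks <- data.frame(
    risk_id = names(agg2),
    score2 = as.numeric(agg2),
    score4 = as.numeric(agg4),
    rank2 = as.integer(rank(-agg2, ties.method = "min")),
    rank4 = as.integer(rank(-agg4, ties.method = "min")),
    stringsAsFactors = FALSE
  )
  rownames(ranks) <- NULL
  list(
    ranks = ranks,
    tie_groups = list(
      two_parameter = as.integer(table(ranks$score2)),
      four_parameter = as.integer(table(ranks$score4))
    )
  )
}
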