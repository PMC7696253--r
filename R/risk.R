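# Four-parameter risk magnitude, evaluation bands and ranking.
#
# The risk magnitude of one assessment is the product of its four raw
# ratings, RM = p * s * e * d, spanning [1, 6561] on the raw 1-9 ladder and
# min-max normalized onto [0, 1]. Bands (Negligible / Minor / Major /
# Critical) partition the magnitude axis and each mandates an action.

#' Round half away from zero
#'
#' Conventional rounding used when comparing against published 3-decimal
#' tables (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.as_raw_rating <- function(x, parameter) {
  if (is.data.frame(x)) return(x$raw)
  coerce_rating(x, parameter)$raw
}

#' Four-parameter risk magnitude
#'
#' Computes the raw risk magnitude `RM = p * s * e * d` and its
#' normalization onto `[0, 1]` (raw range `[1, 6561]` on the odd 1-9
#' ladder). Inputs may be raw odd integers, verbal anchors, normalized
#' values, or rows returned by [coerce_rating()]; vectors are accepted and
#' recycled rules are not applied (all four must have equal length).
#'
#' @param p,s,e,d Ratings for probability, severity, exposure,
#'   detectability.
#' @return A list with numeric vectors `raw` (in `[1, 6561]`) and `norm`
#'   (in `[0, 1]`, full precision).
#' @examples
#' risk_magnitude(5, 9, 5, 5)  # raw 1125, norm 0.1713...
#' @export
risk_magnitude <- function(p, s, e, d) {
  raw <- .as_raw_rating(p, "probability") *
    .as_raw_rating(s, "severity") *
    .as_raw_rating(e, "exposure") *
    .as_raw_rating(d, "detectability")
  list(raw = raw, norm = normalize_minmax(raw, RM_RAW_MIN, RM_RAW_MAX))
}

#' Normalize raw band cutpoints
#'
#' Applies the magnitude normalization `(x - 1)/6560` to raw band
#' cutpoints. With `digits` set, values are truncated toward zero at that
#' many decimals — the display convention of the published band table
#' (e.g. raw 256 -> 255/6560 = 0.03887, shown as 0.038).
#'
#' @param raw_cutpoints Strictly increasing raw cutpoints spanning
#'   `[1, 6561]`.
#' @param digits Optional decimal places for truncated display values;
#'   `NULL` (default) returns full precision.
#' @return Numeric vector of normalized cutpoints.
#' @export
band_boundaries_from_raw <- function(raw_cutpoints = BAND_RAW_CUTPOINTS,
                                     digits = NULL) {
  stopifnot(is.numeric(raw_cutpoints), length(raw_cutpoints) >= 2)
  if (any(diff(raw_cutpoints) <= 0)) {
    stop("raw cutpoints must be strictly increasing")
  }
  norm <- normalize_minmax(raw_cutpoints, RM_RAW_MIN, RM_RAW_MAX)
  if (!is.null(digits)) norm <- trunc(norm * 10^digits) / 10^digits
  norm
}

#' Evaluation bands
#'
#' The four magnitude bands with their raw and normalized ranges and
#' mandated actions. Bands are half-open `[lower, upper)` with the top band
#' closed at the maximum. By default the normalized cutpoints are the exact
#' normalizations of the raw cutpoints (self-consistent with the raw
#' intervals for every integer magnitude); `style = "printed"` uses the
#' published 3-decimal cutpoints 0.002 / 0.012 / 0.038 instead.
#'
#' @param raw_cutpoints Raw cutpoints, default `c(1, 16, 81, 256, 6561)`.
#' @param style `"exact"` (default) or `"printed"`.
#' @return Data frame with columns `band`, `action`, `raw_lo`, `raw_hi`,
#'   `norm_lo`, `norm_hi`.
#' @export
evaluation_bands <- function(raw_cutpoints = BAND_RAW_CUTPOINTS,
                             style = c("exact", "printed")) {
  style <- match.arg(style)
  stopifnot(length(raw_cutpoints) == 5)
  norm <- switch(style,
    exact = band_boundaries_from_raw(raw_cutpoints),
    printed = band_boundaries_from_raw(raw_cutpoints, digits = 3)
  )
  data.frame(
    band = BAND_NAMES,
    action = unname(BAND_ACTIONS[BAND_NAMES]),
    raw_lo = raw_cutpoints[1:4],
    raw_hi = raw_cutpoints[2:5],
    norm_lo = norm[1:4],
    norm_hi = norm[2:5],
    stringsAsFactors = FALSE
  )
}

#' Classify normalized magnitudes into evaluation bands
#'
#' Assigns each normalized magnitude to its band (half-open intervals,
#' top band closed at 1) and the action the band mandates: Negligible risks
#' are accepted, Minor and Major risks mitigated, Critical risks eliminated
#' (work stops until the magnitude drops).
#'
#' @param norm_rm Numeric vector of normalized magnitudes in `[0, 1]`.
#' @param bands A band table from [evaluation_bands()].
#' @return Data frame with columns `norm_rm`, `band`, `action`.
#' @examples
#' classify_magnitude(0.171)  # Critical -> Eliminate
#' @export
classify_magnitude <- function(norm_rm, bands = evaluation_bands()) {
  stopifnot(is.numeric(norm_rm))
  lo <- bands$norm_lo[1]
  hi <- bands$norm_hi[nrow(bands)]
  if (any(norm_rm < lo | norm_rm > hi)) {
    stop("magnitude outside [", lo, ", ", hi, "]")
  }
  idx <- findInterval(norm_rm, bands$norm_lo)  # top band absorbs norm_rm == hi
  data.frame(
    norm_rm = norm_rm,
    band = bands$band[idx],
    action = bands$action[idx],
    stringsAsFactors = FALSE
  )
}

#' Aggregate per-site magnitudes for one risk
#'
#' The multi-site summary of a risk's normalized magnitudes. The default is
#' the arithmetic mean; median and max are available for more conservative
#' summaries.
#'
#' @param x Numeric vector of normalized magnitudes, length >= 1.
#' @param method `"mean"` (default), `"median"`, or `"max"`.
#' @return A single aggregated magnitude, full precision.
#' @export
aggregate_magnitudes <- function(x, method = c("mean", "median", "max")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x))
  if (!length(x)) stop("cannot aggregate an empty set of magnitudes")
  switch(method,
    mean = mean(x),
    median = stats::median(x),
    max = max(x)
  )
}

#' Rank risks by aggregated magnitude
#'
#' Sorts risks by descending aggregated magnitude (rank 1 = largest; ties
#' share the smaller rank, competition style) and attaches each risk's band
#' and action.
#'
#' @param aggregated Named numeric vector of aggregated normalized
#'   magnitudes, one per risk.
#' @param bands Band table, see [evaluation_bands()].
#' @return A `risk_report` data frame with columns `risk_id`,
#'   `aggregated_rm`, `band`, `action`, `rank`, ordered by rank (ties in
#'   input order).
#' @export
rank_risks <- function(aggregated, bands = evaluation_bands()) {
  stopifnot(is.numeric(aggregated), length(aggregated) >= 1)
  if (is.null(names(aggregated))) {
    names(aggregated) <- paste0("R", seq_along(aggregated))
  }
  if (anyDuplicated(names(aggregated))) {
    stop("duplicate risk identifiers in aggregated magnitudes")
  }
  cls <- classify_magnitude(unname(aggregated), bands)
  rk <- rank(-aggregated, ties.method = "min")
  out <- data.frame(
    risk_id = names(aggregated),
    aggregated_rm = unname(aggregated),
    band = cls$band,
    action = cls$action,
    rank = as.integer(rk),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank), ]  # stable: ties keep input order
  rownames(out) <- NULL
  class(out) <- c("risk_report", "data.frame")
  out
}

#' @export
print.risk_report <- function(x, digits = 3, ...) {
  cat("Risk report:", nrow(x), "risks, ",
      sum(x$band == "Critical"), "critical\n")
  y <- as.data.frame(x)
  y$aggregated_rm <- round_half_up(y$aggregated_rm, digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}
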