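# File I/O and the end-to-end assessment pipeline.

#' Read an assessment file
#'
#' Delimited text with headers `risk_id`, `site_id`, `probability`,
#' `severity`, `exposure`, `detectability` (in any column order — mapping
#' is by header name, never position). Ratings may be verbal anchors, raw
#' odd integers, or normalized values; every rating is validated against
#' the ladder and the first offending record is named. Duplicate
#' (risk, site) pairs are rejected. Raw ratings and the normalized risk
#' magnitude are recomputed on load.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @param encoding Rating encoding passed to [coerce_rating()].
#' @return Data frame with `risk_id`, `site_id`, raw rating columns, and
#'   `magnitude`.
#' @export
read_assessments <- function(path, sep = ",", encoding = "auto") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  missing <- setdiff(.REQUIRED_HEADERS, names(df))
  if (length(missing)) {
    stop("assessment file ", path, " is missing header(s): ",
         paste(missing, collapse = ", "))
  }
  key <- paste(df$risk_id, df$site_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), c("risk_id", "site_id")][1, ]
    stop("duplicate assessment for risk ", d$risk_id, " at site ", d$site_id)
  }
  out <- df[c("risk_id", "site_id")]
  for (p in RISK_PARAMETERS) {
    out[[p]] <- coerce_rating(df[[p]], p, encoding = encoding)$raw
  }
  out$magnitude <- risk_magnitude(out$probability, out$severity,
                                  out$exposure, out$detectability)$norm
  out
}

#' Write assessments to a delimited file
#'
#' Writes the standard assessment layout (raw ratings); a file written
#' here reads back identically through [read_assessments()].
#'
#' @param records Assessment data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(records, path, sep = ",") {
  cols <- intersect(c(.REQUIRED_HEADERS, "magnitude"), names(records))
  utils::write.table(records[cols], path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a risk report
#'
#' @param report A `risk_report` from [rank_risks()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, sep = ",") {
  utils::write.table(as.data.frame(report), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a risk report
#'
#' @param path File written by [write_report()].
#' @param sep Field separator.
#' @return A `risk_report` data frame.
#' @export
read_report <- function(path, sep = ",") {
  out <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  class(out) <- c("risk_report", "data.frame")
  out
}

#' End-to-end predictive assessment pipeline
#'
#' Runs the full chain on a multi-site assessment dataset: site-level
#' train/test split, ANFIS training on the training sites, magnitude
#' prediction for the held-out sites, per-risk aggregation of the
#' predictions, band classification, ranking, and test-set metrics
#' (with the OLS baseline for comparison). With `out_dir` set, the
#' report, predictions, model and a JSON manifest (full configuration,
#' seed, package version) are written to disk; the manifest suffices to
#' reproduce the run.
#'
#' @param records Assessment data frame (from [read_assessments()] or
#'   [generate_ratings()]) with a `magnitude` column.
#' @param config An [anfis_config()].
#' @param train_sites,test_sites,train_fraction,seed Split controls, see
#'   [split_by_site()].
#' @param aggregation Aggregation rule, see [aggregate_magnitudes()].
#' @param bands Band table, see [evaluation_bands()].
#' @param out_dir Optional output directory for artifacts.
#' @return List with `report` (ranked risks), `metrics` (ANFIS test
#'   metrics), `baseline` (OLS test metrics), `model`, `predictions`
#'   (test records with a `predicted` column), and `split`.
#' @export
run_pipeline <- function(records, config = anfis_config(),
                         train_sites = NULL, test_sites = NULL,
                         train_fraction = 0.7, seed = 1,
                         aggregation = "mean", bands = evaluation_bands(),
                         out_dir = NULL) {
  stopifnot(is.data.frame(records), "magnitude" %in% names(records))
  split <- split_by_site(records, train_sites = train_sites,
                         test_sites = test_sites,
                         train_fraction = train_fraction, seed = seed)
  norm_inputs <- function(df) {
    vapply(RISK_PARAMETERS,
           function(p) coerce_rating(df[[p]], p)$normalized,
           numeric(nrow(df)))
  }
  Xtr <- norm_inputs(split$train); ytr <- split$train$magnitude
  Xte <- norm_inputs(split$test); yte <- split$test$magnitude

  model <- anfis_fit(build_anfis(config), Xtr, ytr)
  pred <- anfis_predict(model, Xte)

  predictions <- split$test
  predictions$predicted <- as.numeric(pred)

  agg <- tapply(predictions$predicted, predictions$risk_id,
                aggregate_magnitudes, method = aggregation)
  agg <- agg[unique(as.character(predictions$risk_id))]
  report <- rank_risks(stats::setNames(as.numeric(agg), names(agg)), bands)

  metrics <- metrics_report(yte, as.numeric(pred))
  baseline <- linear_baseline(Xtr, ytr, Xte, yte)

  out <- list(report = report, metrics = metrics, baseline = baseline,
              model = model, predictions = predictions, split = split)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, "report.csv"))
    utils::write.table(
      predictions[c("risk_id", "site_id", "magnitude", "predicted")],
      file.path(out_dir, "predictions.csv"), sep = ",", row.names = FALSE,
      quote = FALSE)
    write_anfis(model, file.path(out_dir, "model.json"))
    manifest <- list(
      package = "anfisrisk",
      version = as.character(utils::packageVersion("anfisrisk")),
      seed = seed,
      train_fraction = train_fraction,
      train_sites = sort(unique(split$train$site_id)),
      test_sites = sort(unique(split$test$site_id)),
      aggregation = aggregation,
      config = model$config[setdiff(names(model$config), "seed")],
      metrics = unclass(metrics),
      baseline = unclass(baseline)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
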