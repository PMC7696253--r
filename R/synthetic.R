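# Synthetic multi-site expert-rating generator and bundled case-study
# fixtures.
#
# The generator emulates the structure of a field-observation campaign:
# each risk has a latent hazard profile (a center level 1-5 per rating
# parameter), one expert per site rates every risk, and rater disagreement
# is discrete ladder jitter (+/- one level), never an off-ladder value.

#' Configuration for the synthetic rating generator
#'
#' @param n_risks,n_sites Counts; the default 29 x 10 mirrors a
#'   multi-site construction survey (290 records).
#' @param profiles Optional integer matrix `n_risks x 4` of center levels
#'   (1-5) per parameter (columns probability, severity, exposure,
#'   detectability). If `NULL`, profiles are sampled once, uniformly over
#'   the ladder. `"case_study"` samples levels with the marginal level
#'   frequencies of the bundled case-study site.
#' @param rater_sd Probability that a rating is shifted one level off its
#'   profile center (split evenly between +1 and -1; clamped to the
#'   ladder).
#' @param seed Seed; fully determines the output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_risks = 29, n_sites = 10, profiles = NULL,
                             rater_sd = 0.1, seed = 1) {
  stopifnot(n_risks >= 1, n_sites >= 1, rater_sd >= 0, rater_sd <= 1)
  if (is.matrix(profiles)) {
    stopifnot(nrow(profiles) == n_risks, ncol(profiles) == 4,
              all(profiles %in% 1:5))
  }
  structure(list(n_risks = as.integer(n_risks),
                 n_sites = as.integer(n_sites),
                 profiles = profiles, rater_sd = rater_sd,
                 seed = seed), class = "synthetic_config")
}

.sample_profiles <- function(config) {
  if (is.matrix(config$profiles)) return(config$profiles)
  probs <- if (identical(config$profiles, "case_study")) {
    ratings <- load_case_study_assessments()
    lapply(RISK_PARAMETERS, function(p) {
      lv <- coerce_rating(ratings[[p]], p)$level
      tabulate(lv, 5) / length(lv)
    })
  } else {
    rep(list(rep(0.2, 5)), 4)
  }
  m <- vapply(probs, function(pr) {
    sample(1:5, config$n_risks, replace = TRUE, prob = pr)
  }, integer(config$n_risks))
  if (config$n_risks == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- RISK_PARAMETERS
  m
}

#' Generate a synthetic expert-rating dataset
#'
#' Produces `n_risks x n_sites` assessment records. Every rating is the
#' risk's profile center for that parameter, shifted one ladder level up or
#' down with probability `rater_sd` (clamped to 1-5), and the record's
#' risk magnitude is computed from the jittered ratings. The noise-free
#' profile magnitudes — the ground truth a well-trained model should
#' rank by — are attached as attribute `profile_magnitude`.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `risk_id`, `site_id`, raw `probability`,
#'   `severity`, `exposure`, `detectability`, and `magnitude` (normalized);
#'   attributes `profiles` and `profile_magnitude`.
#' @examples
#' head(generate_ratings(synthetic_config(n_risks = 3, n_sites = 2)))
#' @export
generate_ratings <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  profiles <- .sample_profiles(config)
  colnames(profiles) <- RISK_PARAMETERS
  n <- config$n_risks * config$n_sites
  risk <- rep(seq_len(config$n_risks), times = config$n_sites)
  out <- data.frame(
    risk_id = sprintf("R%02d", risk),
    site_id = sprintf("S%02d", rep(seq_len(config$n_sites),
                                   each = config$n_risks)),
    stringsAsFactors = FALSE
  )
  for (p in RISK_PARAMETERS) {
    center <- profiles[risk, p]
    shift <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                    prob = c(config$rater_sd / 2, 1 - config$rater_sd,
                             config$rater_sd / 2))
    level <- pmin(pmax(center + shift, 1L), 5L)
    out[[p]] <- .LADDER_RAW[level]
  }
  out$magnitude <- risk_magnitude(out$probability, out$severity,
                                  out$exposure, out$detectability)$norm
  raw_prof <- matrix(.LADDER_RAW[profiles], nrow(profiles))
  attr(out, "profiles") <- profiles
  attr(out, "profile_magnitude") <- stats::setNames(
    normalize_minmax(apply(raw_prof, 1, prod), RM_RAW_MIN, RM_RAW_MAX),
    sprintf("R%02d", seq_len(config$n_risks)))
  out
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "anfisrisk")
  if (path == "") path <- file.path("inst", "extdata", file)  # pre-install
  if (!file.exists(path)) stop("bundled fixture not found: ", file)
  path
}

#' Bundled case-study assessments
#'
#' The 29 published worked-example records from one construction site of a
#' Malaysian multi-site safety survey: raw ratings for probability,
#' severity, detectability and exposure plus the published normalized
#' magnitude. On load, each magnitude is recomputed from the raw ratings
#' and compared with the published value at 3 decimals; any mismatch
#' signals fixture corruption.
#'
#' @return Data frame with columns `risk_id`, `site_id`, `probability`,
#'   `severity`, `detectability`, `exposure`, `reported_magnitude`, and the
#'   recomputed `magnitude` (full precision).
#' @export
load_case_study_assessments <- function() {
  df <- utils::read.csv(.extdata("case_study_assessments.csv"),
                        stringsAsFactors = FALSE)
  df$magnitude <- risk_magnitude(df$probability, df$severity, df$exposure,
                                 df$detectability)$norm
  if (!all(round_half_up(df$magnitude, 3) == df$reported_magnitude)) {
    stop("case-study assessment fixture corrupted: recomputed magnitudes ",
         "disagree with the published column")
  }
  df
}

#' Bundled risk register
#'
#' The 29 occupational safety risks of the case study (codes SR1-SR29 with
#' short descriptions): electrocution, conflagration, entrapment, falls
#' from height, struck-by hazards, ergonomic and overexertion injuries,
#' heat and chemical exposures, and so on.
#'
#' @return Data frame with columns `code`, `description`; codes validated
#'   unique.
#' @export
load_risk_register <- function() {
  df <- utils::read.csv(.extdata("risk_register.csv"),
                        stringsAsFactors = FALSE)
  validate_risk_register(df)
}

#' Validate a risk register
#'
#' @param register Data frame with columns `code`, `description`.
#' @return The register, invisibly usable; errors on duplicate codes.
#' @export
validate_risk_register <- function(register) {
  stopifnot(is.data.frame(register),
            all(c("code", "description") %in% names(register)))
  dup <- register$code[duplicated(register$code)]
  if (length(dup)) {
    stop("duplicate risk code(s) in register: ",
         paste(unique(dup), collapse = ", "))
  }
  register
}

#' Bundled case-study summary report
#'
#' The published per-risk summary of the case study's held-out site:
#' actual and model-predicted magnitudes for one test site, the aggregated
#' magnitude over the whole test set, the published band, action, and
#' rank. Kept verbatim, including its four rows whose published band
#' disagrees with the band table applied to the published aggregated value
#' (see [classification_discrepancies()]).
#'
#' @return Data frame with columns `risk_id`, `actual`, `predicted`,
#'   `error`, `aggregated`, `band`, `action`, `rank`.
#' @export
load_case_study_report <- function() {
  utils::read.csv(.extdata("case_study_report.csv"), stringsAsFactors = FALSE)
}

#' Discrepancies between the published bands and the band table
#'
#' Applies the band table to the published aggregated magnitudes of the
#' case-study report and lists the rows whose published band differs — the
#' published summary is internally inconsistent for a handful of rows, and
#' this enumerates them deterministically instead of replicating the
#' inconsistency.
#'
#' @param report A case-study report, default [load_case_study_report()].
#' @param bands Band table, see [evaluation_bands()].
#' @return Data frame of discrepant rows: `risk_id`, `aggregated`,
#'   `published_band`, `computed_band`.
#' @export
classification_discrepancies <- function(report = load_case_study_report(),
                                         bands = evaluation_bands()) {
  computed <- classify_magnitude(report$aggregated, bands)$band
  bad <- computed != report$band
  data.frame(
    risk_id = report$risk_id[bad],
    aggregated = report$aggregated[bad],
    published_band = report$band[bad],
    computed_band = computed[bad],
    stringsAsFactors = FALSE
  )
}
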