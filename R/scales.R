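# Five-level linguistic rating scales for the four risk parameters.
#
# Each parameter (probability, severity, exposure, detectability) is rated on
# a five-level ladder. Raw expert ratings use the odd integers {1,3,5,7,9};
# min-max normalization maps them onto {0, 0.25, 0.5, 0.75, 1}, and each level
# carries a triangular fuzzy number on the normalized [0,1] axis.

#' Triangular membership function
#'
#' Constructs a triangular fuzzy number with lower bound `a`, mode `b` and
#' upper bound `c` (all on the normalized rating axis). Shoulder shapes with
#' `a == b` or `b == c` are allowed; membership is 1 at the flat end.
#'
#' @param a Lower bound.
#' @param b Mode.
#' @param c Upper bound. Must satisfy `a <= b <= c`.
#' @return An object of class `tri_mf`.
#' @examples
#' mf <- tri_mf(0.25, 0.5, 0.75)
#' triangular_membership(0.375, mf)
#' @export
tri_mf <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1, length(b) == 1, length(c) == 1)
  if (!(a <= b && b <= c)) {
    stop("invalid triangular membership function: need a <= b <= c, got (",
         a, ", ", b, ", ", c, ")")
  }
  structure(list(a = a, b = b, c = c), class = "tri_mf")
}

#' @export
print.tri_mf <- function(x, ...) {
  cat(sprintf("Triangular MF (a = %g, b = %g, c = %g)\n", x$a, x$b, x$c))
  invisible(x)
}

#' Evaluate a triangular membership function
#'
#' Membership is 0 outside `[a, c]`, rises linearly from `a` to 1 at the mode
#' `b`, and falls linearly back to 0 at `c`. Shoulder functions (`a == b` or
#' `b == c`) return 1 on the flat end so that extreme ratings are fully
#' covered.
#'
#' @param x Numeric vector of points on the normalized axis.
#' @param mf A [tri_mf()] object (or numeric length-3 vector `c(a, b, c)`).
#' @return Numeric vector of membership degrees in `[0, 1]`.
#' @export
triangular_membership <- function(x, mf) {
  if (is.numeric(mf) && length(mf) == 3) mf <- tri_mf(mf[1], mf[2], mf[3])
  stopifnot(inherits(mf, "tri_mf"), is.numeric(x))
  a <- mf$a; b <- mf$b; cc <- mf$c
  mu <- numeric(length(x))
  if (b > a) {
    left <- x >= a & x < b
    mu[left] <- (x[left] - a) / (b - a)
  }
  if (cc > b) {
    right <- x > b & x <= cc
    mu[right] <- (cc - x[right]) / (cc - b)
  }
  mu[x == b] <- 1
  mu
}

#' Min-max normalization
#'
#' Linearly rescales `x` from `[xmin, xmax]` onto `[0, 1]`.
#'
#' @param x Numeric vector with `xmin <= x <= xmax`.
#' @param xmin,xmax Scale bounds, `xmax > xmin`.
#' @return `(x - xmin) / (xmax - xmin)`.
#' @examples
#' normalize_minmax(3, 1, 9)     # 0.25
#' normalize_minmax(1125, 1, 6561)
#' @export
normalize_minmax <- function(x, xmin, xmax) {
  stopifnot(is.numeric(x), is.numeric(xmin), is.numeric(xmax))
  if (xmax <= xmin) {
    stop("invalid scale: xmax (", xmax, ") must exceed xmin (", xmin, ")")
  }
  if (any(x < xmin | x > xmax)) {
    bad <- x[x < xmin | x > xmax][1]
    stop("value ", bad, " outside scale [", xmin, ", ", xmax, "]")
  }
  (x - xmin) / (xmax - xmin)
}

#' The built-in rating ladder
#'
#' Returns the five-level scale for each of the four risk parameters as a
#' 20-row data frame: the verbal anchor, the canonical ladder label (in
#' risk-contribution order), raw odd value, normalized value, and triangular
#' fuzzy number bounds. Detectability's verbal anchors run reversed (a risk
#' that is very easy to detect contributes least), but its numeric ladder is
#' identical, so a higher normalized value always means a higher risk
#' contribution.
#'
#' The raw odd ladder \{1,3,5,7,9\} is the unique odd-integer scale whose
#' min-max normalization yields the tabulated \{0, 0.25, 0.5, 0.75, 1\};
#' even raw values are rejected, never interpolated.
#'
#' @return A data frame with columns `parameter`, `anchor`, `label`, `level`,
#'   `raw`, `normalized`, `tfn_a`, `tfn_b`, `tfn_c`.
#' @export
rating_scales <- function() {
  out <- do.call(rbind, lapply(RISK_PARAMETERS, function(p) {
    anchors <- if (p == "detectability") rev(.LADDER_LABELS) else .LADDER_LABELS
    data.frame(
      parameter = p,
      anchor = anchors,
      label = .LADDER_LABELS,
      level = 1:5,
      raw = .LADDER_RAW,
      normalized = .LADDER_NORM,
      tfn_a = .LADDER_TFN[, "a"],
      tfn_b = .LADDER_TFN[, "b"],
      tfn_c = .LADDER_TFN[, "c"],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Export the rating scales to a delimited file
#'
#' @param path File path; written as CSV with a header.
#' @return `path`, invisibly.
#' @export
write_rating_scales <- function(path) {
  utils::write.csv(rating_scales(), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# canonical key for a label string: lowercase letters only, with the
# two-letter shorthands expanded
.canon_label <- function(x) {
  key <- tolower(gsub("[^A-Za-z]", "", x))
  short <- c(vl = "verylow", l = "low", m = "medium", h = "high",
             vh = "veryhigh")
  ifelse(key %in% names(short), unname(short[match(key, names(short))]), key)
}

.check_parameter <- function(parameter) {
  parameter <- tolower(parameter)
  if (!parameter %in% RISK_PARAMETERS) {
    stop("unknown rating parameter '", parameter, "'; expected one of ",
         paste(RISK_PARAMETERS, collapse = ", "))
  }
  parameter
}

#' Normalized value of a linguistic level
#'
#' Looks up the normalized value of a verbal anchor on a parameter's scale.
#' Anchors are matched case- and punctuation-insensitively, and the
#' shorthands VL/L/M/H/VH resolve too. For detectability the anchors are
#' reversed: "Very High" (easily detected) maps to 0.
#'
#' @param label Verbal anchor, e.g. `"Medium"` or `"VH"`.
#' @param parameter One of `"probability"`, `"severity"`, `"exposure"`,
#'   `"detectability"`.
#' @return The normalized value in \{0, 0.25, 0.5, 0.75, 1\}.
#' @export
level_to_normalized <- function(label, parameter) {
  parameter <- .check_parameter(parameter)
  scales <- rating_scales()
  rows <- scales[scales$parameter == parameter, ]
  idx <- match(.canon_label(label), .canon_label(rows$anchor))
  if (anyNA(idx)) {
    stop("unknown level '", label[which(is.na(idx))[1]], "' for parameter '",
         parameter, "'")
  }
  rows$normalized[idx]
}

#' Coerce a rating in any admissible encoding to its ladder level
#'
#' Ratings may arrive as verbal anchors (`"High"`, `"VH"`), raw odd integers
#' (\{1,3,5,7,9\}) or normalized values (\{0, 0.25, 0.5, 0.75, 1\}). This
#' resolves each to the unique ladder level of the named parameter's scale.
#' Numeric values must hit a ladder point exactly (tolerance 1e-9);
#' off-ladder values such as raw 4 or normalized 0.3 are an error, never
#' interpolated.
#'
#' The value 1 is both a valid raw rating (level 1) and a valid normalized
#' rating (level 5). Under `encoding = "auto"` the raw reading wins; pass
#' `encoding = "normalized"` for files on the normalized scale.
#'
#' @param value Vector of ratings (character or numeric).
#' @param parameter Scale name.
#' @param encoding `"auto"` (default), `"raw"`, or `"normalized"`.
#' @return A data frame with one row per input value, the matching rows of
#'   [rating_scales()].
#' @examples
#' coerce_rating(7, "exposure")         # High, normalized 0.75
#' coerce_rating("VH", "severity")      # VeryHigh
#' @export
coerce_rating <- function(value, parameter,
                          encoding = c("auto", "raw", "normalized")) {
  parameter <- .check_parameter(parameter)
  encoding <- match.arg(encoding)
  scales <- rating_scales()
  rows <- scales[scales$parameter == parameter, ]
  tol <- 1e-9

  resolve_one <- function(v, i) {
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) {
        idx <- match(.canon_label(v), .canon_label(rows$anchor))
        if (is.na(idx)) {
          stop("record ", i, ": unknown ", parameter, " rating '", v, "'")
        }
        return(idx)
      }
      v <- num
    }
    if (!is.finite(v)) stop("record ", i, ": missing ", parameter, " rating")
    raw_idx <- which(abs(rows$raw - v) < tol)
    norm_idx <- which(abs(rows$normalized - v) < tol)
    idx <- switch(encoding,
      raw = raw_idx,
      normalized = norm_idx,
      auto = if (length(raw_idx)) raw_idx else norm_idx
    )
    if (!length(idx)) {
      stop("record ", i, ": ", parameter, " rating ", v,
           " is off the ladder (raw {1,3,5,7,9} or normalized ",
           "{0,0.25,0.5,0.75,1})")
    }
    idx
  }

  idx <- vapply(seq_along(value), function(i) resolve_one(value[i], i), 1L)
  out <- rows[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
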