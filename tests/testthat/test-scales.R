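# Linguistic rating scales, triangular memberships, normalization.

test_that("min-max normalization is exact on the ladder and rejects bad input", {
  expect_equal(normalize_minmax(3, 1, 9), 0.25)
  expect_equal(normalize_minmax(1, 1, 9), 0)
  expect_equal(normalize_minmax(c(1, 3, 5, 7, 9), 1, 9),
               c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(round(normalize_minmax(1125, 1, 6561), 3), 0.171)
  expect_error(normalize_minmax(1, 5, 5), "invalid scale")
  expect_error(normalize_minmax(11, 1, 9), "outside")
})

test_that("normalization is affine and order-preserving", {
  x <- sort(runif(50, 1, 9))
  y <- normalize_minmax(x, 1, 9)
  expect_true(all(diff(y) > 0))
  expect_equal(y, (x - 1) / 8)
})

test_that("triangular membership follows the piecewise-linear form", {
  mf <- tri_mf(0.25, 0.5, 0.75)
  expect_equal(triangular_membership(0.5, mf), 1)
  expect_equal(triangular_membership(0.25, mf), 0)
  expect_equal(triangular_membership(0.375, mf), 0.5)
  expect_equal(triangular_membership(c(-1, 0.1, 0.9, 2), mf), rep(0, 4))
  # ramps are linear
  x <- seq(0.25, 0.5, by = 0.05)
  expect_equal(triangular_membership(x, mf), (x - 0.25) / 0.25)
})

test_that("shoulder MFs return 1 at the flat end", {
  lo <- tri_mf(0, 0, 0.25)
  hi <- tri_mf(0.75, 1, 1)
  expect_equal(triangular_membership(0, lo), 1)
  expect_equal(triangular_membership(0.125, lo), 0.5)
  expect_equal(triangular_membership(1, hi), 1)
  expect_equal(triangular_membership(0.875, hi), 0.5)
})

test_that("invalid triangular parameters are rejected", {
  expect_error(tri_mf(0.5, 0.25, 0.75), "a <= b <= c")
})

test_that("the ladder ties raw, normalized and TFN values together", {
  sc <- rating_scales()
  expect_equal(nrow(sc), 20)
  expect_setequal(unique(sc$parameter),
                  c("probability", "severity", "exposure", "detectability"))
  per <- split(sc, sc$parameter)
  for (tab in per) {
    expect_equal(tab$raw, c(1, 3, 5, 7, 9))
    expect_equal(tab$normalized, (tab$raw - 1) / 8)
    expect_true(all(diff(tab$normalized) > 0))
    # membership of each level's normalized value in its own TFN is 1
    for (i in 1:5) {
      expect_equal(
        triangular_membership(tab$normalized[i],
                              tri_mf(tab$tfn_a[i], tab$tfn_b[i], tab$tfn_c[i])),
        1)
    }
  }
})

test_that("detectability anchors are reversed but its ladder is identical", {
  sc <- rating_scales()
  det <- sc[sc$parameter == "detectability", ]
  prob <- sc[sc$parameter == "probability", ]
  expect_equal(det$normalized, prob$normalized)
  expect_equal(det$anchor, rev(prob$anchor))
  # easily detected risk contributes least
  expect_equal(level_to_normalized("Very High", "detectability"), 0)
  expect_equal(level_to_normalized("Very Low", "detectability"), 1)
})

test_that("verbal anchors resolve case-insensitively with shorthands", {
  expect_equal(level_to_normalized("Medium", "probability"), 0.5)
  expect_equal(level_to_normalized("Very low", "probability"), 0)
  expect_equal(level_to_normalized("Very High", "severity"), 1)
  expect_equal(level_to_normalized("VH", "severity"), 1)
  expect_error(level_to_normalized("Enormous", "severity"), "unknown level")
  expect_error(level_to_normalized("High", "luck"), "unknown rating parameter")
})

test_that("coerce_rating accepts all three encodings and round-trips", {
  lvl <- coerce_rating(7, "exposure")
  expect_equal(lvl$label, "High")
  expect_equal(lvl$normalized, 0.75)
  expect_equal(coerce_rating("VH", "severity")$label, "VeryHigh")

  sc <- rating_scales()
  for (i in seq_len(nrow(sc))) {
    p <- sc$parameter[i]
    by_raw <- coerce_rating(sc$raw[i], p)
    by_label <- coerce_rating(sc$anchor[i], p)
    by_norm <- coerce_rating(sc$normalized[i], p, encoding = "normalized")
    expect_equal(by_raw$level, sc$level[i])
    expect_equal(by_label$level, sc$level[i])
    expect_equal(by_norm$level, sc$level[i])
  }
})

test_that("off-ladder numerics are rejected, never interpolated", {
  expect_error(coerce_rating(0.3, "probability"), "off the ladder")
  expect_error(coerce_rating(4, "severity"), "off the ladder")
  expect_error(coerce_rating(2.9999, "severity"), "off the ladder")
  # exact ladder hit within 1e-9 tolerance passes
  expect_equal(coerce_rating(0.25 + 1e-12, "probability",
                             encoding = "normalized")$level, 2)
})

test_that("raw reading wins for the ambiguous value 1 unless told otherwise", {
  expect_equal(coerce_rating(1, "probability")$normalized, 0)
  expect_equal(coerce_rating(1, "probability", encoding = "normalized")$level, 5)
})

test_that("scale export writes the full 20-row table", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_rating_scales(path)
  back <- read.csv(path)
  expect_equal(nrow(back), 20)
  expect_equal(back$normalized, rating_scales()$normalized)
})
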