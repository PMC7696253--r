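# Shared constants: the rating ladder, the magnitude range, band defaults.

RISK_PARAMETERS <- c("probability", "severity", "exposure", "detectability")

# ladder in risk-contribution order (level 1 = lowest risk contribution)
.LADDER_LABELS <- c("VeryLow", "Low", "Medium", "High", "VeryHigh")
.LADDER_RAW <- c(1L, 3L, 5L, 7L, 9L)
.LADDER_NORM <- c(0, 0.25, 0.5, 0.75, 1)
.LADDER_TFN <- matrix(
  c(0, 0, 0.25,
    0, 0.25, 0.5,
    0.25, 0.5, 0.75,
    0.5, 0.75, 1,
    0.75, 1, 1),
  ncol = 3, byrow = TRUE, dimnames = list(NULL, c("a", "b", "c"))
)

RM_RAW_MIN <- 1
RM_RAW_MAX <- 6561  # 9^4

BAND_NAMES <- c("Negligible", "Minor", "Major", "Critical")
BAND_ACTIONS <- c(Negligible = "Accept", Minor = "Mitigate",
                  Major = "Mitigate", Critical = "Eliminate")
BAND_RAW_CUTPOINTS <- c(1, 16, 81, 256, 6561)

.REQUIRED_HEADERS <- c("risk_id", "site_id", RISK_PARAMETERS)
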