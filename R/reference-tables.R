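# Published reference values used as worked-example inputs: the
# EudraVigilance anti-HER2 extraction (dashboard snapshot of 4 March 2021)
# and the 101-case canine mammary-carcinoma cohort summaries.

#' Blood-and-lymphatic reaction counts of the anti-HER2 antibody class
#'
#' Report counts of inflammation-related preferred terms within the "Blood
#' and lymphatic system disorders" SOC for trastuzumab (i.v. and s.c.
#' combined), trastuzumab emtansine and pertuzumab, as extracted from the
#' public EudraVigilance dashboard for the 18–64-year female population
#' (snapshot of 4 March 2021). `soc_total` is each drug's total report count
#' in that SOC — the denominator of the reaction shares.
#'
#' @return Data frame with columns `drug`, `soc_total`, `reaction`, `count`.
#' @seealso [reaction_share()], [build_contingency()]
#' @export
antiher2_blood_counts <- function() {
  tot <- c(trastuzumab = 3435L, `trastuzumab emtansine` = 623L,
           pertuzumab = 1122L)
  df <- rbind(
    data.frame(drug = "trastuzumab",
               reaction = c("platelet count decreased",
                            "neutrophil count decreased",
                            "lymphocyte count decreased",
                            "c reactive protein increased",
                            "eosinophil count increased"),
               count = c(258L, 363L, 32L, 39L, 14L)),
    data.frame(drug = "trastuzumab emtansine",
               reaction = c("platelet count decreased",
                            "neutrophil count decreased",
                            "lymphocyte count decreased",
                            "c reactive protein increased"),
               count = c(286L, 21L, 9L, 6L)),
    data.frame(drug = "pertuzumab",
               reaction = c("platelet count decreased",
                            "neutrophil count decreased",
                            "lymphocyte count decreased",
                            "c reactive protein increased"),
               count = c(69L, 128L, 19L, 10L))
  )
  df$soc_total <- unname(tot[df$drug])
  df[, c("drug", "soc_total", "reaction", "count")]
}

#' Total anti-HER2 report volumes
#'
#' Overall spontaneous-report totals per drug from the same dashboard
#' snapshot: trastuzumab 12711, pertuzumab 3230, trastuzumab emtansine 1345.
#'
#' @return Named integer vector.
#' @export
antiher2_report_totals <- function() {
  c(trastuzumab = 12711L, pertuzumab = 3230L,
    `trastuzumab emtansine` = 1345L)
}

#' Histotype frequencies of the 101-case canine cohort
#'
#' Histological classification (Goldschmidt system) of 101 canine mammary
#' carcinomas; simple carcinomas carry a subtype, other histotypes do not.
#'
#' @return Data frame with columns `histotype`, `subtype`, `n` (sums to 101).
#' @export
canine_histotype_counts <- function() {
  data.frame(
    histotype = c(rep("simple carcinoma", 4), "comedocarcinoma",
                  "micropapillary invasive carcinoma",
                  "anaplastic carcinoma", "intraductal papillary carcinoma",
                  "solid carcinoma"),
    subtype = c("tubulopapillary", "cystic-papillary", "tubular",
                "cribriform", NA, NA, NA, NA, NA),
    n = c(37L, 41L, 5L, 2L, 7L, 2L, 2L, 4L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Malignancy-grade totals of the canine cohort
#'
#' Grade distribution (Pena grading system) of the 101 carcinomas:
#' 45 grade I, 34 grade II, 22 grade III.
#'
#' @return Named integer vector `c(G1 = 45, G2 = 34, G3 = 22)`.
#' @export
canine_grade_counts <- function() c(G1 = 45L, G2 = 34L, G3 = 22L)

#' Per-grade infiltrate and serum summaries of the canine cohort
#'
#' Mean and standard deviation of per-field positive-cell counts (400x
#' fields, 0.1885 mm2 each, 10 fields per case) for CD68 macrophages and
#' CD20 lymphocytes (monoclonal and polyclonal antibody), plus serum
#' platelet, lymphocyte and neutrophil values per microlitre (n = 4 animals
#' per grade), by malignancy grade.
#'
#' @return List with elements `n_cases` (per grade), `markers` (data frame
#'   `grade`, `marker`, `mean`, `sd`) and `serum` (data frame `grade`,
#'   `analyte`, `mean`, `sd`, `n`).
#' @export
canine_grade_summaries <- function() {
  list(
    n_cases = canine_grade_counts(),
    markers = data.frame(
      grade = rep(c("G1", "G2", "G3"), each = 3),
      marker = rep(c("cd68", "cd20m", "cd20p"), times = 3),
      mean = c(6, 39.5, 48.1, 26, 34.13, 42.13, 46.5, 30.13, 36.3),
      sd = c(4.24, 10.2, 11.2, 18.38, 9.1, 9.1, 24.64, 4.1, 8.5),
      stringsAsFactors = FALSE
    ),
    serum = data.frame(
      grade = rep(c("G1", "G2", "G3"), each = 3),
      analyte = rep(c("platelet", "lymphocyte", "neutrophil"), times = 3),
      mean = c(221000, 4001.1, 5432, 295000, 2060, 8692, 381000, 2721.1, 11200),
      sd = c(20000, 800, 1000, 30000, 600, 432, 40000, 1100, 6300),
      n = 4L,
      stringsAsFactors = FALSE
    )
  )
}
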