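#' Microscope field protocol
#'
#' Counting protocol of the immunostaining evaluation: positively stained
#' cells counted in the first `n_fields` high-power fields encountered at
#' the stated magnification, each field covering `field_area` square
#' millimetres.
#'
#' @param magnification Label, default `"400x"`.
#' @param field_area Field area in mm^2 (> 0), default 0.1885.
#' @param n_fields Fields per case (>= 1), default 10.
#' @return An object of class `field_protocol`.
#' @export
field_protocol <- function(magnification = "400x", field_area = 0.1885,
                           n_fields = 10) {
  if (!is.numeric(field_area) || field_area <= 0) {
    stop("'field_area' must be > 0", call. = FALSE)
  }
  if (!is_count(n_fields) || n_fields < 1) {
    stop("'n_fields' must be a positive integer", call. = FALSE)
  }
  structure(list(magnification = magnification, field_area = field_area,
                 n_fields = as.integer(n_fields)),
            class = "field_protocol")
}

# Field-count column names for a marker, inferred from the cohort header.
marker_columns <- function(cohort, marker) {
  cols <- grep(sprintf("^%s_f[0-9]+$", marker), names(cohort), value = TRUE)
  if (!length(cols)) stop("no field-count columns found for marker '",
                          marker, "'", call. = FALSE)
  cols[order(as.integer(sub(".*_f", "", cols)))]
}

#' Histotype-by-grade frequency table
#'
#' Tallies a cohort of cases into a histotype (with subtype breakdown) by
#' grade frequency table with row totals and percentage of the cohort.
#' Cases with a missing grade contribute to the totals only.
#'
#' @param cases Cohort data frame with columns `histotype`, `grade`, and
#'   optionally `subtype`.
#' @param digits Decimal places for the percentage column (default 1).
#' @return Data frame with one row per (histotype, subtype) plus a per-
#'   histotype `<histotype> (all)` row for subtyped histotypes and a final
#'   `total` row; columns `histotype`, `subtype`, `G1`, `G2`, `G3`, `total`,
#'   `pct`.
#' @examples
#' h <- canine_histotype_counts()
#' cohort <- data.frame(histotype = rep(h$histotype, h$n),
#'                      subtype = rep(h$subtype, h$n), grade = NA)
#' aggregate_histotype_grade(cohort)
#' @export
aggregate_histotype_grade <- function(cases, digits = 1) {
  grades <- c("G1", "G2", "G3")
  n_total <- nrow(cases)
  if (n_total == 0) {
    return(data.frame(histotype = "total", subtype = NA, G1 = 0L, G2 = 0L,
                      G3 = 0L, total = 0L, pct = NA_real_))
  }
  subtype <- if ("subtype" %in% names(cases)) as.character(cases$subtype) else rep(NA_character_, n_total)
  grade <- as.character(cases$grade)

  cell <- function(sel) {
    g <- vapply(grades, function(gg) sum(sel & !is.na(grade) & grade == gg,
                                         na.rm = TRUE), integer(1))
    c(as.list(g), list(total = sum(sel), pct = round(100 * sum(sel) / n_total, digits)))
  }
  rows <- list()
  for (h in unique(cases$histotype)) {
    sel_h <- cases$histotype == h
    subs <- unique(subtype[sel_h])
    subs <- subs[!is.na(subs)]
    if (length(subs)) {
      for (s in subs) {
        rows[[length(rows) + 1]] <- c(list(histotype = h, subtype = s),
                                      cell(sel_h & !is.na(subtype) & subtype == s))
      }
      rows[[length(rows) + 1]] <- c(list(histotype = sprintf("%s (all)", h),
                                         subtype = NA_character_), cell(sel_h))
    } else {
      rows[[length(rows) + 1]] <- c(list(histotype = h, subtype = NA_character_),
                                    cell(sel_h))
    }
  }
  rows[[length(rows) + 1]] <- c(list(histotype = "total", subtype = NA_character_),
                                cell(rep(TRUE, n_total)))
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Percentage distribution over tumor grades
#'
#' `100 * count / total` per grade, rounded half-to-even.
#'
#' @param counts Named or ordered numeric vector of per-grade case counts
#'   with positive sum.
#' @param digits Decimal places (default 1).
#' @return Numeric vector of percentages, same names as `counts`.
#' @examples
#' grade_percentages(c(G1 = 45, G2 = 34, G3 = 22))
#' @export
grade_percentages <- function(counts, digits = 1) {
  total <- sum(counts)
  if (!is.numeric(counts) || any(counts < 0) || total <= 0) {
    stop("'counts' must be non-negative with a positive total", call. = FALSE)
  }
  round(100 * counts / total, digits)
}

#' Infiltrate density from per-field counts
#'
#' Converts one case's per-field positive-cell counts into a mean count per
#' field and a density per square millimetre under a [field_protocol()].
#'
#' @param field_counts Numeric vector of length `protocol$n_fields`.
#' @param protocol A [field_protocol()].
#' @return List with `mean_per_field` and `per_mm2`.
#' @examples
#' density_from_fields(rep(19, 10), field_protocol())
#' @export
density_from_fields <- function(field_counts, protocol = field_protocol()) {
  stopifnot(inherits(protocol, "field_protocol"))
  if (length(field_counts) != protocol$n_fields) {
    stop(sprintf("expected %d field counts, got %d", protocol$n_fields,
                 length(field_counts)), call. = FALSE)
  }
  if (any(!is.finite(field_counts)) || any(field_counts < 0)) {
    stop("field counts must be finite and >= 0", call. = FALSE)
  }
  m <- mean(field_counts)
  list(mean_per_field = m, per_mm2 = m / protocol$field_area)
}

#' Per-grade summaries of a marker
#'
#' Summarises a cohort per grade: each case is first reduced to the mean of
#' its field counts (avoiding pseudo-replication of fields within a case),
#' then the across-case mean and sample standard deviation (n - 1
#' denominator) are reported. Grades with a single case report `NA` for the
#' standard deviation.
#'
#' @param cases Cohort data frame (see [simulate_ihc_cohort()]).
#' @param marker One of the marker prefixes in the cohort, e.g. `"cd68"`.
#' @return Data frame with columns `grade`, `marker`, `n`, `mean`, `sd`.
#' @export
summarize_by_grade <- function(cases, marker) {
  cols <- marker_columns(cases, marker)
  per_case <- rowMeans(as.matrix(cases[, cols, drop = FALSE]))
  grades <- sort(unique(as.character(cases$grade)))
  out <- do.call(rbind, lapply(grades, function(g) {
    v <- per_case[cases$grade == g]
    data.frame(grade = g, marker = marker, n = length(v), mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample t-test from summary statistics
#'
#' Computes the unpaired two-sample t-test directly from group sizes, means
#' and standard deviations — the form needed when only published summary
#' tables are available. `variant = "welch"` (default) uses the
#' unequal-variance statistic with Welch–Satterthwaite degrees of freedom;
#' `"pooled"` is the classical equal-variance Student test. The p-value is
#' two-sided.
#'
#' @param n1,mean1,sd1 First group: size (>= 2), mean, standard deviation.
#' @param n2,mean2,sd2 Second group.
#' @param variant `"welch"` or `"pooled"`.
#' @return An object of class `summary_ttest`: list with `statistic`, `df`,
#'   `p.value`, `variant`.
#' @examples
#' # G1 vs G3 macrophage counts of the canine cohort
#' ttest_summary(45, 6, 4.24, 22, 46.5, 24.64)
#' @export
ttest_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                          variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (sd1 == 0 && sd2 == 0) {
    stop("at least one group must have positive standard deviation",
         call. = FALSE)
  }
  if (variant == "welch") {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean1 - mean2) / se
  structure(list(statistic = t, df = df,
                 p.value = 2 * stats::pt(-abs(t), df), variant = variant),
            class = "summary_ttest")
}

#' @export
print.summary_ttest <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s) from summary statistics\n", x$variant))
  cat(sprintf("  t = %.4f, df = %.2f, two-sided p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Pairwise between-grade tests
#'
#' Runs [ttest_summary()] on every grade pair (G1 vs G2, G1 vs G3, G2 vs G3)
#' of a per-grade summary table such as the one returned by
#' [summarize_by_grade()]. No multiplicity adjustment is applied by default;
#' `p_adjust` enables one (any method of [stats::p.adjust()]).
#'
#' @param summaries Data frame with columns `grade`, `n`, `mean`, `sd`
#'   covering all three grades (one row per grade).
#' @param variant Passed to [ttest_summary()].
#' @param p_adjust Multiplicity correction method (default `"none"`).
#' @return Data frame with columns `group1`, `group2`, `statistic`, `df`,
#'   `p.value` (and `p.adjusted` when a correction is requested).
#' @export
pairwise_grade_tests <- function(summaries, variant = c("welch", "pooled"),
                                 p_adjust = "none") {
  variant <- match.arg(variant)
  grades <- c("G1", "G2", "G3")
  if (!all(grades %in% summaries$grade)) {
    stop("summaries must cover grades G1, G2 and G3", call. = FALSE)
  }
  s <- summaries[match(grades, summaries$grade), ]
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- do.call(rbind, lapply(pairs, function(p) {
    i <- p[1]; j <- p[2]
    tt <- ttest_summary(s$n[i], s$mean[i], s$sd[i],
                        s$n[j], s$mean[j], s$sd[j], variant)
    data.frame(group1 = grades[i], group2 = grades[j],
               statistic = tt$statistic, df = tt$df, p.value = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  if (p_adjust != "none") {
    out$p.adjusted <- stats::p.adjust(out$p.value, method = p_adjust)
  }
  rownames(out) <- NULL
  out
}

#' Serum inflammation ratios
#'
#' Neutrophil-to-lymphocyte (NLR) and platelet-to-lymphocyte (PLR) ratios,
#' the serum inflammation biomarkers whose low values track favourable
#' outcome in breast cancer.
#'
#' @param platelet,lymphocyte,neutrophil Counts per microlitre; `lymphocyte`
#'   must be positive. Vectorised.
#' @return List with `nlr` and `plr`.
#' @examples
#' compute_cbc_ratios(platelet = 221000, lymphocyte = 4001.1, neutrophil = 5432)
#' @export
compute_cbc_ratios <- function(platelet, lymphocyte, neutrophil) {
  if (any(!is.finite(lymphocyte)) || any(lymphocyte <= 0)) {
    stop("lymphocyte count must be positive", call. = FALSE)
  }
  list(nlr = neutrophil / lymphocyte, plr = platelet / lymphocyte)
}
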