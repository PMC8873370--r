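#' 2x2 contingency table for disproportionality analysis
#'
#' Cell conventions of the Proportional Reporting Ratio: `a` counts rows of
#' the reaction of interest for the drug of interest, `b` the same reaction
#' for all other drugs in the class, `c` all other reactions for the drug of
#' interest, and `d` all other reactions for the other drugs.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param drug,reaction Optional labels carried along for reporting.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              reaction = NA_character_) {
  for (cell in list(a, b, c, d)) {
    if (!is_count(cell)) stop("cells a, b, c, d must be non-negative integers",
                              call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d,
                 drug = drug, reaction = reaction),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table%s\n",
              if (!is.na(x$drug)) sprintf(" [%s / %s]", x$drug, x$reaction) else ""))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("reaction", "other reactions"),
                              c("drug", "other drugs")))
  print(m)
  invisible(x)
}

#' Build a 2x2 table from an analysis set
#'
#' Counts (report, reaction) rows within an explicit drug class: the
#' comparator is `class_drugs` minus the drug of interest, never inferred
#' from the data. Labels are matched case-insensitively after trimming.
#'
#' @param x An `analysis_set` (see [filter_reports()]) or line-listing
#'   data frame.
#' @param drug Drug of interest; must be one of `class_drugs`.
#' @param reaction Reaction (preferred term) of interest.
#' @param class_drugs Character vector of all drugs in the class (>= 2).
#' @return A [contingency_table()]; `a + b + c + d` equals the number of rows
#'   for `class_drugs` in the analysis set.
#' @export
build_contingency <- function(x, drug, reaction, class_drugs) {
  reports <- if (inherits(x, "analysis_set")) x$reports else x
  if (length(class_drugs) < 2) {
    stop("'class_drugs' must contain at least two drugs", call. = FALSE)
  }
  if (!norm_label(drug) %in% norm_label(class_drugs)) {
    stop("'drug' must be a member of 'class_drugs'", call. = FALSE)
  }
  dcol <- norm_label(reports$drug)
  rcol <- norm_label(reports$reaction_pt)
  in_class <- dcol %in% norm_label(class_drugs)
  is_drug <- in_class & dcol == norm_label(drug)
  is_comp <- in_class & !is_drug
  is_react <- rcol == norm_label(reaction)
  contingency_table(
    a = sum(is_drug & is_react), b = sum(is_comp & is_react),
    c = sum(is_drug & !is_react), d = sum(is_comp & !is_react),
    drug = drug, reaction = reaction
  )
}

#' Proportional Reporting Ratio of a 2x2 table
#'
#' Computes `PRR = (a / (a + c)) / (b / (b + d))`: the share of the reaction
#' of interest among the drug of interest's reports, relative to the same
#' share among the comparator drugs' reports. A PRR of 1 indicates
#' proportional reporting; values of 2 and above are the conventional
#' disproportionality threshold.
#'
#' A comparator arm with no report of the reaction (`b = 0`) leaves the ratio
#' undefined; under `zero_policy = "strict"` (the default) this is an error,
#' while `"haldane"` first adds 0.5 to all four cells. Silent corrections
#' distort the PRR on near-degenerate tables, hence strict is the default.
#'
#' @param table A [contingency_table()].
#' @param zero_policy `"strict"` or `"haldane"`.
#' @return A non-negative number.
#' @examples
#' compute_prr(contingency_table(a = 10, b = 10, c = 90, d = 190))  # 2
#' @export
compute_prr <- function(table, zero_policy = c("strict", "haldane")) {
  stopifnot(inherits(table, "contingency_table"))
  zero_policy <- match.arg(zero_policy)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (a + c == 0) stop("empty drug-of-interest arm (a + c = 0)", call. = FALSE)
  if (b + d == 0) stop("empty comparator arm (b + d = 0)", call. = FALSE)
  if (b == 0) {
    if (zero_policy == "strict") {
      stop("comparator has no report of the reaction (b = 0); ",
           "use zero_policy = \"haldane\" to correct", call. = FALSE)
    }
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a / (a + c)) / (b / (b + d))
}

#' Pearson chi-square statistic of a 2x2 table
#'
#' Evaluates `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; with `yates = TRUE`
#' the Yates continuity correction reduces `|ad - bc|` by `N/2` (floored at
#' zero) before squaring, so the corrected statistic never exceeds the
#' uncorrected one. A table with any zero margin has no defined statistic and
#' returns 0 flagged as degenerate (attribute `"degenerate"`).
#'
#' @param table A [contingency_table()].
#' @param yates Apply the continuity correction?
#' @return Non-negative number; attribute `"degenerate"` is `TRUE` when a
#'   margin is empty.
#' @export
compute_chi2 <- function(table, yates = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    return(structure(0, degenerate = TRUE))
  }
  dev <- abs(a * d - b * c)
  if (yates) dev <- max(0, dev - n / 2)
  chi2 <- n * dev^2 / prod(margins)
  structure(as.numeric(chi2), degenerate = FALSE)
}

#' Signal rule thresholds
#'
#' The classical multi-criterion disproportionality rule: a (drug, reaction)
#' pair is a signal when PRR >= `prr_min`, the reaction-of-interest case
#' count is at least `min_cases`, and the chi-square statistic is at least
#' `chi2_min` — with the additional exclusion that a PRR exactly equal to 1
#' is never a signal.
#'
#' @param prr_min Minimum PRR (default 2).
#' @param min_cases Minimum number of cases of the reaction (default 3).
#' @param chi2_min Minimum chi-square (default 4).
#' @return An object of class `signal_rule`.
#' @export
signal_rule <- function(prr_min = 2, min_cases = 3, chi2_min = 4) {
  if (any(c(prr_min, min_cases, chi2_min) < 0)) {
    stop("signal-rule thresholds must be >= 0", call. = FALSE)
  }
  structure(list(prr_min = prr_min, min_cases = min_cases,
                 chi2_min = chi2_min), class = "signal_rule")
}

#' Evaluate the signal rule
#'
#' Applies a [signal_rule()] to a (PRR, case count, chi-square) triple.
#' Failed criteria are returned as reason codes (`"prr"`, `"min_cases"`,
#' `"chi2"`, `"prr_equals_1"`). The PRR = 1 exclusion is decided exactly on
#' the table's rational value (`a(b+d) == b(a+c)`) when `table` is supplied,
#' avoiding floating-point ties; otherwise on the numeric `prr`.
#'
#' @param prr PRR value.
#' @param n_cases Number of cases of the reaction for the drug of interest
#'   (cell `a`).
#' @param chi2 Chi-square statistic.
#' @param rule A [signal_rule()].
#' @param table Optional [contingency_table()] backing `prr`.
#' @return List with `signal` (logical) and `reasons` (character vector of
#'   failed criteria, empty when `signal` is `TRUE`).
#' @export
evaluate_signal <- function(prr, n_cases, chi2, rule = signal_rule(),
                            table = NULL) {
  stopifnot(inherits(rule, "signal_rule"))
  if (any(!is.finite(c(prr, n_cases, chi2))) || any(c(prr, n_cases, chi2) < 0)) {
    stop("prr, n_cases and chi2 must be finite and non-negative", call. = FALSE)
  }
  reasons <- character()
  if (prr < rule$prr_min) reasons <- c(reasons, "prr")
  if (n_cases < rule$min_cases) reasons <- c(reasons, "min_cases")
  if (chi2 < rule$chi2_min) reasons <- c(reasons, "chi2")
  prr_is_one <- if (!is.null(table)) {
    table$a * (table$b + table$d) == table$b * (table$a + table$c)
  } else {
    prr == 1
  }
  if (prr_is_one) reasons <- c(reasons, "prr_equals_1")
  list(signal = length(reasons) == 0, reasons = reasons)
}

#' Percentage share of a reaction among a report total
#'
#' `100 * count / total`, rounded half-to-even to `digits` decimals — the
#' convention used when quoting, e.g., a platelet-count-decrease share of a
#' drug's blood-and-lymphatic-disorder reports.
#'
#' @param count Number of reports of the reaction (0 <= count <= total).
#' @param total Total reports in the denominator (> 0).
#' @param digits Decimal places (default 1).
#' @return The rounded percentage.
#' @examples
#' reaction_share(286, 623)      # 45.9
#' reaction_share(21, 623, 2)    # 3.37
#' @export
reaction_share <- function(count, total, digits = 1) {
  if (!is_count(total) || total == 0) {
    stop("'total' must be a positive count", call. = FALSE)
  }
  if (!is_count(count) || count > total) {
    stop("'count' must be an integer in [0, total]", call. = FALSE)
  }
  round(100 * count / total, digits)
}

#' Screen every (drug, reaction) pair in a drug class
#'
#' Builds the 2x2 table for every drug in the class against every reaction,
#' computes PRR and chi-square, and applies the signal rule. Degenerate
#' tables (empty comparator-reaction cell under the strict policy, empty
#' margins) yield `NA` statistics with a note rather than an error. Results
#' are sorted by drug, then descending PRR.
#'
#' @param x An `analysis_set` or line-listing data frame.
#' @param class_drugs Drugs forming the class (>= 2).
#' @param reactions Reactions to screen; defaults to every preferred term
#'   present for the class.
#' @param rule A [signal_rule()].
#' @param zero_policy Passed to [compute_prr()].
#' @param yates Passed to [compute_chi2()].
#' @return Data frame with columns `drug`, `reaction`, `a`, `b`, `c`, `d`,
#'   `prr`, `chi2`, `n_cases`, `signal`, `reasons` (semicolon-separated
#'   reason codes / degeneracy notes).
#' @export
prr_screen <- function(x, class_drugs, reactions = NULL,
                       rule = signal_rule(),
                       zero_policy = c("strict", "haldane"),
                       yates = FALSE) {
  zero_policy <- match.arg(zero_policy)
  reports <- if (inherits(x, "analysis_set")) x$reports else x
  if (length(class_drugs) < 2) {
    stop("'class_drugs' must contain at least two drugs", call. = FALSE)
  }
  dcol <- norm_label(reports$drug)
  in_class <- dcol %in% norm_label(class_drugs)
  rows <- reports[in_class, , drop = FALSE]
  if (is.null(reactions)) reactions <- sort(unique(rows$reaction_pt))
  if (!length(reactions)) {
    return(data.frame(drug = character(), reaction = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), prr = numeric(), chi2 = numeric(),
                      n_cases = integer(), signal = logical(),
                      reasons = character(), stringsAsFactors = FALSE))
  }

  # row counts per (drug, reaction), plus per-drug totals
  counts <- table(factor(norm_label(rows$drug), levels = norm_label(class_drugs)),
                  factor(norm_label(rows$reaction_pt),
                         levels = norm_label(reactions)))
  drug_tot <- table(factor(norm_label(rows$drug),
                           levels = norm_label(class_drugs)))
  react_tot <- colSums(counts)
  grand <- sum(drug_tot)

  res <- vector("list", length(class_drugs) * length(reactions))
  k <- 0
  for (i in seq_along(class_drugs)) {
    for (j in seq_along(reactions)) {
      a <- as.integer(counts[i, j])
      ac <- as.integer(drug_tot[i])
      b <- as.integer(react_tot[j]) - a
      bd <- as.integer(grand) - ac
      tab <- contingency_table(a = a, b = b, c = ac - a, d = bd - b,
                               drug = class_drugs[i], reaction = reactions[j])
      prr <- tryCatch(compute_prr(tab, zero_policy),
                      error = function(e) NA_real_)
      chi2 <- compute_chi2(tab, yates = yates)
      notes <- character()
      if (is.na(prr)) notes <- "degenerate_prr"
      if (isTRUE(attr(chi2, "degenerate"))) notes <- c(notes, "degenerate_chi2")
      if (is.na(prr)) {
        sig <- FALSE
        reasons <- notes
      } else {
        ev <- evaluate_signal(prr, a, as.numeric(chi2), rule, table = tab)
        sig <- ev$signal
        reasons <- c(ev$reasons, notes)
      }
      k <- k + 1
      res[[k]] <- data.frame(
        drug = class_drugs[i], reaction = reactions[j],
        a = a, b = b, c = ac - a, d = bd - b,
        prr = prr, chi2 = as.numeric(chi2), n_cases = a,
        signal = sig, reasons = paste(reasons, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$drug, class_drugs), -ifelse(is.na(out$prr), -Inf, out$prr)), ]
  rownames(out) <- NULL
  out
}
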