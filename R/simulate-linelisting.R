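#' Simulate a spontaneous-report line listing
#'
#' Generates a line listing in the one-row-per-(report, reaction) layout of
#' dashboard exports: a report that mentions several preferred terms spans
#' several rows sharing one `report_id`. Exactly `totals[drug]` reports are
#' generated per drug. Reactions are drawn independently per report with the
#' configured (possibly signal-boosted) probabilities; a report whose
#' Bernoulli draws all fail is assigned one reaction drawn proportionally to
#' those probabilities, so within-drug reaction-share ratios — and hence the
#' PRR — are unaffected by the guarantee.
#'
#' Duplicated reports are exact payload copies under a fresh `report_id`,
#' emitted immediately after their original. The returned frame carries an
#' internal `.duplicate_of` column (`NA` for originals) so the true
#' de-duplicated set stays recoverable for validation; [write_line_listing()]
#' drops internal columns.
#'
#' @param config A [pv_config()] object.
#' @param seed Integer seed; defaults to `config$seed`. The same config and
#'   seed always reproduce the identical listing.
#' @return A data frame with columns `report_id`, `drug`, `reaction_pt`,
#'   `soc`, `age_group`, `sex`, `route`, `year`, `serious`, `outcome`,
#'   `concomitant`, plus the internal `.duplicate_of`.
#' @examples
#' cfg <- pv_config(
#'   drugs = c("drugA", "drugB"), totals = 50,
#'   reactions = data.frame(pt = c("nausea", "rash"), soc = "general"),
#'   baseline_probs = c(nausea = 0.3, rash = 0.2), seed = 7
#' )
#' head(simulate_line_listing(cfg))
#' @export
simulate_line_listing <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "pv_config"))
  if (is.null(seed)) stop("a seed is required (in the config or as argument)",
                          call. = FALSE)
  probs <- reaction_prob_matrix(config)
  pts <- config$reactions$pt
  soc_of <- stats::setNames(config$reactions$soc, pts)
  demo <- config$demographics

  with_rng(seed, {
    per_drug <- lapply(config$drugs, function(d) {
      n <- config$totals[[d]]
      p <- probs[d, ]
      hit <- matrix(0L, nrow = n, ncol = length(pts))
      for (j in seq_along(pts)) hit[, j] <- stats::rbinom(n, 1L, p[j])
      none <- which(rowSums(hit) == 0L)
      if (length(none)) {
        forced <- sample.int(length(pts), length(none), replace = TRUE, prob = p)
        hit[cbind(none, forced)] <- 1L
      }
      rep_df <- data.frame(
        drug = d,
        age_group = sample_cat(demo$age_group, n),
        sex = sample_cat(demo$sex, n),
        route = sample_cat(demo$route, n),
        year = as.integer(sample_cat(demo$year, n)),
        serious = stats::runif(n) < demo$serious_prob,
        outcome = sample_cat(demo$outcome, n),
        stringsAsFactors = FALSE
      )
      list(reports = rep_df, hit = hit)
    })

    reports <- do.call(rbind, lapply(per_drug, `[[`, "reports"))
    hit <- do.call(rbind, lapply(per_drug, `[[`, "hit"))
    n_rep <- nrow(reports)

    # duplicate flags drawn once per report; copies sit right after originals
    dup <- if (config$duplicate_rate > 0) {
      stats::runif(n_rep) < config$duplicate_rate
    } else {
      rep(FALSE, n_rep)
    }
    emit <- rep(seq_len(n_rep), times = 1L + dup)
    is_copy <- duplicated(emit)
    ids <- sprintf("R%06d", seq_along(emit))
    orig_id_of <- ids[!is_copy][order(emit[!is_copy])]  # id of each original

    long_idx <- which(hit[emit, , drop = FALSE] == 1L, arr.ind = TRUE)
    long_idx <- long_idx[order(long_idx[, 1L], long_idx[, 2L]), , drop = FALSE]
    row_emit <- long_idx[, 1L]

    out <- reports[emit[row_emit], , drop = FALSE]
    out$report_id <- ids[row_emit]
    out$reaction_pt <- pts[long_idx[, 2L]]
    out$soc <- unname(soc_of[out$reaction_pt])
    out$concomitant <- ""
    out$.duplicate_of <- ifelse(is_copy[row_emit],
                                orig_id_of[emit[row_emit]], NA_character_)
    rownames(out) <- NULL
    out[, c("report_id", "drug", "reaction_pt", "soc", "age_group", "sex",
            "route", "year", "serious", "outcome", "concomitant",
            ".duplicate_of")]
  })
}

#' Closed-form PRR implied by a synthetic configuration
#'
#' Computes the Proportional Reporting Ratio that the configured reporting
#' probabilities and per-drug volumes imply in expectation, serving as the
#' analytic oracle for signal-recovery experiments. Using expected
#' (report, PT) row counts, with `p[j, r]` the (signal-adjusted) probability
#' that a report for drug `j` mentions reaction `r` and `N[j]` the report
#' volume:
#' \deqn{PRR = \frac{N_d p_{dr} / \sum_s N_d p_{ds}}
#'                 {\sum_{j \ne d} N_j p_{jr} / \sum_{j \ne d, s} N_j p_{js}}}
#'
#' With all multipliers equal to 1 every drug shares the same reaction
#' profile and the expected PRR is exactly 1.
#'
#' @param config A [pv_config()] object.
#' @param drug Drug of interest (must appear in `config$drugs`).
#' @param reaction Reaction of interest (must appear in the vocabulary).
#' @return A positive number.
#' @examples
#' cfg <- pv_config(
#'   drugs = c("A", "B"), totals = 1000,
#'   reactions = data.frame(pt = c("R1", "R2"), soc = "s"),
#'   baseline_probs = c(R1 = 0.25, R2 = 0.75),
#'   signals = data.frame(drug = "A", reaction = "R1", lambda = 2),
#'   seed = 1
#' )
#' expected_prr(cfg, "A", "R1")
#' @export
expected_prr <- function(config, drug, reaction) {
  stopifnot(inherits(config, "pv_config"))
  if (!drug %in% config$drugs) stop("unknown drug: ", drug, call. = FALSE)
  if (!reaction %in% config$reactions$pt) {
    stop("unknown reaction: ", reaction, call. = FALSE)
  }
  if (length(config$drugs) < 2) {
    stop("a comparator drug is required to define a PRR", call. = FALSE)
  }
  probs <- reaction_prob_matrix(config)
  n <- config$totals
  others <- setdiff(config$drugs, drug)

  a <- n[[drug]] * probs[drug, reaction]
  ac <- n[[drug]] * sum(probs[drug, ])
  b <- sum(n[others] * probs[others, reaction])
  bd <- sum(n[others] * rowSums(probs[others, , drop = FALSE]))
  if (b <= 0) {
    stop("comparator pool has zero expected count for this reaction",
         call. = FALSE)
  }
  (a / ac) / (b / bd)
}
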