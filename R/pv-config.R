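#' Configuration for a synthetic spontaneous-report line listing
#'
#' Describes the generative model behind [simulate_line_listing()]: a fixed
#' set of suspect drugs, a reaction vocabulary grouped into System Organ
#' Classes (SOCs), per-reaction baseline reporting probabilities, and optional
#' injected signals that multiply a (drug, reaction) probability by a factor
#' `lambda`. The injected `lambda` values are the ground truth that
#' disproportionality screens are later validated against.
#'
#' Each simulated report carries one suspect drug and, independently for each
#' preferred term (PT), a Bernoulli draw with probability
#' `min(1, lambda * baseline)`; at least one reaction per report is
#' guaranteed (a report with no reaction would never appear in a line
#' listing). Demographics are drawn from the configured categorical
#' distributions. With probability `duplicate_rate` a report is emitted a
#' second time under a fresh report identifier, emulating the duplicated
#' submissions that real pharmacovigilance databases accumulate.
#'
#' @param drugs Character vector of unique drug labels.
#' @param totals Number of reports to generate per drug; a single value
#'   recycled over `drugs`, or a vector named by drug.
#' @param reactions Data frame with columns `pt` (preferred term) and `soc`
#'   (System Organ Class), one row per reaction in the vocabulary.
#' @param baseline_probs Numeric vector in (0, 1], named by PT: baseline
#'   probability that a report mentions that reaction.
#' @param signals Optional data frame with columns `drug`, `reaction`,
#'   `lambda` (multiplier, >= 0). Unlisted pairs keep their baseline
#'   probability; the overridden probability is capped at 1.
#' @param demographics Optional list overriding the default categorical
#'   distributions; recognised elements are `age_group`, `sex`, `route`,
#'   `year` (named probability vectors), `serious_prob` (scalar) and
#'   `outcome` (named probability vector).
#' @param duplicate_rate Probability in [0, 1) that a report is duplicated.
#' @param seed Integer seed used by [simulate_line_listing()].
#'
#' @return An object of class `pv_config`.
#' @seealso [simulate_line_listing()], [expected_prr()]
#' @examples
#' cfg <- pv_config(
#'   drugs = c("drugA", "drugB"),
#'   totals = 500,
#'   reactions = data.frame(pt = c("nausea", "rash"), soc = "general"),
#'   baseline_probs = c(nausea = 0.1, rash = 0.05),
#'   signals = data.frame(drug = "drugA", reaction = "rash", lambda = 4),
#'   seed = 1
#' )
#' cfg
#' @export
pv_config <- function(drugs, totals, reactions, baseline_probs,
                      signals = NULL, demographics = list(),
                      duplicate_rate = 0, seed = NULL) {
  drugs <- as.character(drugs)
  if (length(drugs) < 1 || anyDuplicated(drugs) || any(!nzchar(drugs))) {
    stop("'drugs' must be a non-empty vector of unique, non-empty labels",
         call. = FALSE)
  }
  if (length(totals) == 1 && is.null(names(totals))) {
    totals <- stats::setNames(rep(totals, length(drugs)), drugs)
  }
  if (is.null(names(totals))) names(totals) <- drugs
  if (!setequal(names(totals), drugs)) {
    stop("'totals' must be named by drug (or be a single value)", call. = FALSE)
  }
  totals <- totals[drugs]
  if (!all(vapply(totals, is_count, logical(1))) || any(totals < 1)) {
    stop("'totals' must be positive integers", call. = FALSE)
  }

  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!all(c("pt", "soc") %in% names(reactions))) {
    stop("'reactions' needs columns 'pt' and 'soc'", call. = FALSE)
  }
  reactions$pt <- as.character(reactions$pt)
  reactions$soc <- as.character(reactions$soc)
  if (anyDuplicated(reactions$pt)) {
    stop("reaction preferred terms must be unique", call. = FALSE)
  }

  if (!setequal(names(baseline_probs), reactions$pt)) {
    stop("'baseline_probs' must be named by every reaction PT", call. = FALSE)
  }
  baseline_probs <- baseline_probs[reactions$pt]
  if (any(!is.finite(baseline_probs)) || any(baseline_probs <= 0) ||
      any(baseline_probs > 1)) {
    stop("baseline probabilities must lie in (0, 1]", call. = FALSE)
  }

  if (!is.null(signals)) {
    signals <- as.data.frame(signals, stringsAsFactors = FALSE)
    if (!all(c("drug", "reaction", "lambda") %in% names(signals))) {
      stop("'signals' needs columns 'drug', 'reaction', 'lambda'", call. = FALSE)
    }
    if (!all(signals$drug %in% drugs)) {
      stop("signal entry names an unknown drug", call. = FALSE)
    }
    if (!all(signals$reaction %in% reactions$pt)) {
      stop("signal entry names an unknown reaction", call. = FALSE)
    }
    if (anyDuplicated(signals[, c("drug", "reaction")])) {
      stop("(drug, reaction) signal keys must be unique", call. = FALSE)
    }
    if (any(!is.finite(signals$lambda)) || any(signals$lambda < 0)) {
      stop("signal multipliers must be finite and >= 0", call. = FALSE)
    }
  } else {
    signals <- data.frame(drug = character(), reaction = character(),
                          lambda = numeric())
  }

  if (!is.numeric(duplicate_rate) || duplicate_rate < 0 || duplicate_rate >= 1) {
    stop("'duplicate_rate' must lie in [0, 1)", call. = FALSE)
  }

  demo_default <- list(
    age_group = c("0-17" = 0.03, "18-64" = 0.72, "65-85" = 0.22, "85+" = 0.03),
    sex = c(female = 0.92, male = 0.08),
    route = c("i.v." = 0.6, "s.c." = 0.3, "unknown" = 0.1),
    year = stats::setNames(rep(1 / 6, 6), as.character(2015:2020)),
    serious_prob = 0.35,
    outcome = c("recovered" = 0.45, "recovering" = 0.15, "not recovered" = 0.2,
                "drug withdrawn" = 0.12, "unknown" = 0.08)
  )
  demo <- utils::modifyList(demo_default, demographics)
  for (k in c("age_group", "sex", "route", "year", "outcome")) {
    demo[[k]] <- norm_probs(demo[[k]], k)
  }
  if (demo$serious_prob < 0 || demo$serious_prob > 1) {
    stop("'serious_prob' must lie in [0, 1]", call. = FALSE)
  }

  structure(
    list(drugs = drugs, totals = totals, reactions = reactions,
         baseline_probs = baseline_probs, signals = signals,
         demographics = demo, duplicate_rate = duplicate_rate,
         seed = seed),
    class = "pv_config"
  )
}

#' @export
print.pv_config <- function(x, ...) {
  cat("Synthetic line-listing configuration\n")
  cat(sprintf("  drugs: %s\n",
              paste(sprintf("%s (%d)", x$drugs, x$totals), collapse = ", ")))
  cat(sprintf("  reactions: %d PTs in %d SOCs\n",
              nrow(x$reactions), length(unique(x$reactions$soc))))
  cat(sprintf("  injected signals: %d; duplicate rate: %.3f\n",
              nrow(x$signals), x$duplicate_rate))
  invisible(x)
}

# Per-drug reaction probability matrix (drugs x PTs) after applying the
# signal multipliers, capped at 1.
reaction_prob_matrix <- function(config) {
  p <- matrix(rep(config$baseline_probs, each = length(config$drugs)),
              nrow = length(config$drugs),
              dimnames = list(config$drugs, config$reactions$pt))
  if (nrow(config$signals)) {
    for (i in seq_len(nrow(config$signals))) {
      s <- config$signals[i, ]
      p[s$drug, s$reaction] <- min(1, s$lambda * p[s$drug, s$reaction])
    }
  }
  p
}
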