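#' Monte-Carlo operating characteristics of the signal rule
#'
#' Repeatedly simulates line listings from a [pv_config()], screens every
#' (drug, reaction) pair with [prr_screen()], and summarises how the signal
#' rule behaves against the configured ground truth: flag rates (power for
#' injected pairs, false-positive rate for `lambda = 1` pairs) and the mean
#' estimated PRR per pair, each with its Monte-Carlo standard error, next to
#' the analytic [expected_prr()].
#'
#' Replicate seeds are drawn once from the master `seed`, so the whole
#' experiment is deterministic.
#'
#' @param config A [pv_config()] object; its `duplicate_rate` should normally
#'   be 0 so that the screen sees the generative model directly.
#' @param rule A [signal_rule()].
#' @param n_replicates Number of simulated listings (>= 1).
#' @param seed Master seed.
#' @param zero_policy,yates Passed to [prr_screen()].
#' @return Data frame with one row per (drug, reaction) pair: `lambda` (the
#'   configured multiplier), `expected_prr`, `mean_prr`, `se_prr`,
#'   `flag_rate`, `se_flag`, `n_replicates`.
#' @export
operating_characteristics <- function(config, rule = signal_rule(),
                                      n_replicates = 100, seed = 1,
                                      zero_policy = "haldane",
                                      yates = FALSE) {
  stopifnot(inherits(config, "pv_config"), n_replicates >= 1)
  rep_seeds <- with_rng(seed, sample.int(.Machine$integer.max, n_replicates))
  pairs <- expand.grid(drug = config$drugs, reaction = config$reactions$pt,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(pairs$drug, pairs$reaction, sep = "\r")

  prr_mat <- matrix(NA_real_, nrow = n_replicates, ncol = nrow(pairs))
  flag_mat <- matrix(NA, nrow = n_replicates, ncol = nrow(pairs))
  for (r in seq_len(n_replicates)) {
    listing <- simulate_line_listing(config, seed = rep_seeds[r])
    scr <- prr_screen(listing, class_drugs = config$drugs,
                      reactions = config$reactions$pt, rule = rule,
                      zero_policy = zero_policy, yates = yates)
    idx <- match(key, paste(scr$drug, scr$reaction, sep = "\r"))
    prr_mat[r, ] <- scr$prr[idx]
    flag_mat[r, ] <- scr$signal[idx]
  }

  lambda <- rep(1, nrow(pairs))
  if (nrow(config$signals)) {
    m <- match(paste(pairs$drug, pairs$reaction, sep = "\r"),
               paste(config$signals$drug, config$signals$reaction, sep = "\r"))
    lambda[!is.na(m)] <- config$signals$lambda[m[!is.na(m)]]
  }

  flag_rate <- colMeans(flag_mat, na.rm = TRUE)
  mean_prr <- colMeans(prr_mat, na.rm = TRUE)
  n_ok <- colSums(!is.na(prr_mat))
  se_prr <- apply(prr_mat, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
  out <- data.frame(
    drug = pairs$drug, reaction = pairs$reaction, lambda = lambda,
    expected_prr = mapply(function(d, rx) {
      tryCatch(expected_prr(config, d, rx), error = function(e) NA_real_)
    }, pairs$drug, pairs$reaction),
    mean_prr = mean_prr, se_prr = se_prr,
    flag_rate = flag_rate,
    se_flag = sqrt(flag_rate * (1 - flag_rate) / n_replicates),
    n_replicates = n_replicates,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
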