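#' Configuration for a full analysis run
#'
#' Bundles everything [run_pipeline()] needs: the input line listing and/or
#' IHC cohort, the filter, the drug class, the signal rule and the numeric
#' policies. Paths are checked at run time, not construction time.
#'
#' @param linelisting Path to a line-listing CSV, or `NULL` to skip the
#'   disproportionality strand.
#' @param ihc_cohort Path to an IHC cohort CSV, or `NULL` to skip the
#'   grade-association strand.
#' @param filter A [filter_spec()].
#' @param dedup Apply mechanical de-duplication? The deterministic key is a
#'   coarse surrogate for manual duplicate review; on dense listings whose
#'   payload fields have low cardinality it also collapses genuinely distinct
#'   reports, so set `dedup = FALSE` for inputs known to be duplicate-free.
#' @param dedup_key Duplicate key passed to [deduplicate()]; `NULL` uses its
#'   default.
#' @param class_drugs Drug class for the screen (>= 2 when screening).
#' @param rule A [signal_rule()].
#' @param zero_policy,yates Passed to [prr_screen()].
#' @param markers Marker prefixes summarised in the IHC strand.
#' @param test_variant `"welch"` or `"pooled"` for the between-grade tests.
#' @param out_dir Output directory (created if absent).
#' @return An object of class `run_config`.
#' @export
run_config <- function(linelisting = NULL, ihc_cohort = NULL,
                       filter = filter_spec(), dedup = TRUE,
                       dedup_key = NULL, class_drugs = NULL,
                       rule = signal_rule(), zero_policy = "strict",
                       yates = FALSE, markers = c("cd68", "cd20m", "cd20p"),
                       test_variant = "welch", out_dir = ".") {
  stopifnot(inherits(filter, "filter_spec"), inherits(rule, "signal_rule"))
  structure(list(linelisting = linelisting, ihc_cohort = ihc_cohort,
                 filter = filter, dedup = dedup, dedup_key = dedup_key,
                 class_drugs = class_drugs, rule = rule,
                 zero_policy = zero_policy, yates = yates, markers = markers,
                 test_variant = test_variant, out_dir = out_dir),
            class = "run_config")
}

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the two analysis strands end to end
#'
#' Disproportionality strand: read the line listing, de-duplicate, filter,
#' screen every (drug, reaction) pair of the class, and tally reaction
#' shares per drug. Grade-association strand: read the cohort, build the
#' histotype-by-grade table, per-grade marker summaries and pairwise
#' between-grade tests. All artifacts are written atomically as TSV into
#' `out_dir` together with a provenance log; identical inputs and
#' configuration reproduce identical artifacts. A failure in one strand is
#' reported with its stage name and does not block the other strand.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts: `analysis_set`,
#'   `signals`, `shares`, `ihc_tables`, `provenance`, and `errors` (named
#'   list of stage errors, empty on full success).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(errors = list())
  prov <- list(package_version = as.character(utils::packageVersion("advesig")))

  if (!is.null(config$linelisting)) {
    tryCatch({
      raw <- read_line_listing(config$linelisting)
      dedup <- if (config$dedup) {
        if (is.null(config$dedup_key)) deduplicate(raw)
        else deduplicate(raw, key = config$dedup_key)
      } else {
        structure(raw, n_raw = nrow(raw), n_removed = 0L)
      }
      aset <- filter_reports(dedup, config$filter)
      res$analysis_set <- aset
      prov$counts <- aset$provenance
      prov$dedup_removed <- attr(dedup, "n_removed")
      prov$rule <- unclass(config$rule)

      if (!is.null(config$class_drugs)) {
        scr <- prr_screen(aset, config$class_drugs, rule = config$rule,
                          zero_policy = config$zero_policy,
                          yates = config$yates)
        res$signals <- scr
        write_tsv_atomic(scr, file.path(config$out_dir, "signals.tsv"))
      }

      shares <- do.call(rbind, lapply(unique(aset$reports$drug), function(d) {
        cnt <- count_by(aset$reports[aset$reports$drug == d, , drop = FALSE],
                        "reaction_pt")
        data.frame(drug = d, reaction = names(cnt), count = as.integer(cnt),
                   total = sum(cnt),
                   share_pct = vapply(cnt, reaction_share,
                                      numeric(1), total = sum(cnt)),
                   stringsAsFactors = FALSE)
      }))
      res$shares <- shares
      if (!is.null(shares)) {
        write_tsv_atomic(shares, file.path(config$out_dir, "shares.tsv"))
      }
    }, error = function(e) {
      res$errors$linelisting <<- conditionMessage(e)
    })
  }

  if (!is.null(config$ihc_cohort)) {
    tryCatch({
      cohort <- read_ihc_cohort(config$ihc_cohort)
      freq <- aggregate_histotype_grade(cohort)
      write_tsv_atomic(freq, file.path(config$out_dir, "histotype_grade.tsv"))
      summaries <- do.call(rbind, lapply(config$markers, function(m) {
        summarize_by_grade(cohort, m)
      }))
      write_tsv_atomic(summaries, file.path(config$out_dir, "grade_summaries.tsv"))
      tests <- do.call(rbind, lapply(config$markers, function(m) {
        s <- summarize_by_grade(cohort, m)
        if (!all(c("G1", "G2", "G3") %in% s$grade)) return(NULL)
        cbind(marker = m, pairwise_grade_tests(s, config$test_variant))
      }))
      if (!is.null(tests)) {
        write_tsv_atomic(tests, file.path(config$out_dir, "grade_tests.tsv"))
      }
      res$ihc_tables <- list(frequency = freq, summaries = summaries,
                             tests = tests)
      prov$ihc_cases <- nrow(cohort)
    }, error = function(e) {
      res$errors$ihc <<- conditionMessage(e)
    })
  }

  prov_df <- data.frame(key = names(unlist(prov)),
                        value = as.character(unlist(prov)))
  write_tsv_atomic(prov_df, file.path(config$out_dir, "provenance.tsv"))
  res$provenance <- prov
  invisible(res)
}
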