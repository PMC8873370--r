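# Shared fixture builders. Everything is generated in code; no stored data.

grades <- c("G1", "G2", "G3")
markers <- c("cd68", "cd20m", "cd20p")

marker_matrix <- function(values) {
  matrix(values, nrow = 3, ncol = 3,
         dimnames = list(grades, markers))
}

# Table-3-style IHC config: per-field count means/SDs per grade and marker.
cohort_config <- function(n_cases = c(G1 = 45, G2 = 34, G3 = 22),
                          seed = 11, ...) {
  s <- canine_grade_summaries()$markers
  m <- matrix(NA_real_, 3, 3, dimnames = list(grades, markers))
  sd <- m
  for (i in seq_len(nrow(s))) {
    m[s$grade[i], s$marker[i]] <- s$mean[i]
    sd[s$grade[i], s$marker[i]] <- s$sd[i]
  }
  ihc_config(n_cases = n_cases, means = m, sds = sd, seed = seed, ...)
}

# Small three-drug line-listing config with one injected signal.
small_pv_config <- function(n = 2000, lambda = 5, duplicate_rate = 0,
                            seed = 42) {
  pv_config(
    drugs = c("drugA", "drugB", "drugC"), totals = n,
    reactions = data.frame(pt = paste0("R", 1:6),
                           soc = rep(c("blood", "general"), each = 3)),
    baseline_probs = stats::setNames(rep(0.05, 6), paste0("R", 1:6)),
    signals = if (lambda != 1) {
      data.frame(drug = "drugA", reaction = "R1", lambda = lambda)
    } else NULL,
    duplicate_rate = duplicate_rate, seed = seed
  )
}

# Minimal hand-built line-listing frame.
listing_frame <- function(drug, reaction_pt, sex = "female",
                          age_group = "18-64", route = "i.v.", year = 2018,
                          serious = FALSE, soc = "soc1") {
  n <- max(length(drug), length(reaction_pt), length(sex), length(year))
  data.frame(
    report_id = sprintf("H%03d", seq_len(n)),
    drug = rep_len(drug, n), reaction_pt = rep_len(reaction_pt, n),
    soc = rep_len(soc, n), age_group = rep_len(age_group, n),
    sex = rep_len(sex, n), route = rep_len(route, n),
    year = rep_len(year, n), serious = rep_len(serious, n),
    outcome = "recovered", concomitant = "",
    stringsAsFactors = FALSE
  )
}

# Independent brute-force PRR on raw rows, exact rational arithmetic on counts.
brute_force_prr <- function(reports, drug, reaction, class_drugs) {
  rows <- reports[tolower(trimws(reports$drug)) %in% tolower(trimws(class_drugs)), ]
  mine <- tolower(trimws(rows$drug)) == tolower(trimws(drug))
  hit <- tolower(trimws(rows$reaction_pt)) == tolower(trimws(reaction))
  a <- sum(mine & hit); ac <- sum(mine)
  b <- sum(!mine & hit); bd <- sum(!mine)
  (a / ac) / (b / bd)
}

# Cohort replaying the published histotype frequencies (grades unassigned).
histotype_cohort <- function() {
  h <- canine_histotype_counts()
  data.frame(histotype = rep(h$histotype, h$n),
             subtype = rep(h$subtype, h$n),
             grade = NA_character_, stringsAsFactors = FALSE)
}
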