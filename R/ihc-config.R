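#' Configuration for a synthetic canine-IHC cohort
#'
#' Generative specification for a cohort of canine mammary-carcinoma cases
#' with immunohistochemical infiltrate counts. Each case carries a tumor
#' grade (G1–G3) and, for each marker (`cd68` macrophages, `cd20m` and
#' `cd20p` B lymphocytes stained with monoclonal and polyclonal antibody),
#' `n_fields` per-field positive-cell counts. `means` and `sds` parameterise
#' the per-field count distribution per grade and marker; serum complete
#' blood counts (platelet, lymphocyte, neutrophil per microlitre) are drawn
#' per case from grade-specific normals.
#'
#' Per-field counts default to a normal draw truncated at zero and rounded
#' to an integer (`count_model = "truncnorm"`); `"negbin"` draws from a
#' negative binomial with matching mean and variance (falling back to
#' Poisson when the variance does not exceed the mean).
#'
#' @param n_cases Named integer vector `c(G1 = ..., G2 = ..., G3 = ...)`.
#' @param means,sds Numeric matrices (rows `G1`,`G2`,`G3`; columns `cd68`,
#'   `cd20m`, `cd20p`) of per-field count means and standard deviations;
#'   `sds` must be non-negative.
#' @param serum_means,serum_sds Optional matrices (rows `G1`..`G3`; columns
#'   `platelet`, `lymphocyte`, `neutrophil`) for per-case serum values; when
#'   `NULL` no serum columns are generated.
#' @param n_fields Fields counted per case (default 10).
#' @param count_model `"truncnorm"` (default) or `"negbin"`.
#' @param seed Integer seed used by [simulate_ihc_cohort()].
#' @return An object of class `ihc_config`.
#' @export
ihc_config <- function(n_cases, means, sds, serum_means = NULL,
                       serum_sds = NULL, n_fields = 10,
                       count_model = c("truncnorm", "negbin"), seed = NULL) {
  count_model <- match.arg(count_model)
  grades <- c("G1", "G2", "G3")
  markers <- c("cd68", "cd20m", "cd20p")
  if (!setequal(names(n_cases), grades)) {
    stop("'n_cases' must be named G1, G2, G3", call. = FALSE)
  }
  n_cases <- n_cases[grades]
  if (!all(vapply(n_cases, is_count, logical(1)))) {
    stop("case counts must be non-negative integers", call. = FALSE)
  }
  as_mat <- function(m, cols, what) {
    m <- as.matrix(m)
    if (!setequal(rownames(m), grades) || !setequal(colnames(m), cols)) {
      stop(sprintf("'%s' must have rows G1..G3 and columns %s", what,
                   paste(cols, collapse = ", ")), call. = FALSE)
    }
    m[grades, cols, drop = FALSE]
  }
  means <- as_mat(means, markers, "means")
  sds <- as_mat(sds, markers, "sds")
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("standard deviations must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(means)) || any(means < 0)) {
    stop("count means must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(serum_means)) {
    serum_cols <- c("platelet", "lymphocyte", "neutrophil")
    serum_means <- as_mat(serum_means, serum_cols, "serum_means")
    serum_sds <- as_mat(serum_sds, serum_cols, "serum_sds")
    if (any(serum_sds < 0)) stop("serum SDs must be >= 0", call. = FALSE)
  }
  if (!is_count(n_fields) || n_fields < 1) {
    stop("'n_fields' must be a positive integer", call. = FALSE)
  }
  structure(list(n_cases = n_cases, means = means, sds = sds,
                 serum_means = serum_means, serum_sds = serum_sds,
                 n_fields = as.integer(n_fields), count_model = count_model,
                 seed = seed),
            class = "ihc_config")
}

# One draw batch of non-negative integer per-field counts.
draw_counts <- function(n, mean, sd, model) {
  if (sd == 0) return(rep(round(mean), n))
  if (model == "truncnorm") {
    # inverse-CDF sampling from N(mean, sd) truncated below at 0
    lo <- stats::pnorm(0, mean, sd)
    u <- lo + stats::runif(n) * (1 - lo)
    pmax(0L, as.integer(round(stats::qnorm(u, mean, sd))))
  } else {
    if (sd^2 > mean && mean > 0) {
      size <- mean^2 / (sd^2 - mean)
      stats::rnbinom(n, size = size, mu = mean)
    } else {
      stats::rpois(n, mean)
    }
  }
}

#' Simulate a canine-IHC cohort
#'
#' Draws `n_cases[g]` cases per grade; each case gets `n_fields` independent
#' per-field counts per marker from the configured grade/marker distribution,
#' and (when serum parameters are configured) per-case serum platelet,
#' lymphocyte and neutrophil values. Histotype labels are sampled from the
#' empirical histotype frequencies of [canine_histotype_counts()] so cohorts
#' are realistic inputs for [aggregate_histotype_grade()]. Same config and
#' seed reproduce the identical cohort.
#'
#' @param config An [ihc_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Data frame with one row per case: `case_id`, `histotype`,
#'   `subtype`, `grade`, `<marker>_f1` .. `<marker>_f<n_fields>` for each
#'   marker, and `platelet`, `lymphocyte`, `neutrophil` when configured.
#' @export
simulate_ihc_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ihc_config"))
  if (is.null(seed)) stop("a seed is required (in the config or as argument)",
                          call. = FALSE)
  grades <- c("G1", "G2", "G3")
  markers <- colnames(config$means)
  histo <- canine_histotype_counts()
  histo_p <- histo$n / sum(histo$n)

  with_rng(seed, {
    rows <- list()
    for (g in grades) {
      n <- config$n_cases[[g]]
      if (n == 0) next
      hidx <- sample.int(nrow(histo), n, replace = TRUE, prob = histo_p)
      df <- data.frame(
        case_id = sprintf("%s-%03d", g, seq_len(n)),
        histotype = histo$histotype[hidx],
        subtype = histo$subtype[hidx],
        grade = g,
        stringsAsFactors = FALSE
      )
      for (m in markers) {
        cnt <- matrix(draw_counts(n * config$n_fields, config$means[g, m],
                                  config$sds[g, m], config$count_model),
                      nrow = n)
        colnames(cnt) <- sprintf("%s_f%d", m, seq_len(config$n_fields))
        df <- cbind(df, as.data.frame(cnt))
      }
      if (!is.null(config$serum_means)) {
        for (s in colnames(config$serum_means)) {
          df[[s]] <- pmax(0, stats::rnorm(n, config$serum_means[g, s],
                                          config$serum_sds[g, s]))
        }
      }
      rows[[g]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Read / write an IHC cohort CSV
#'
#' One row per case; field-count columns named `<marker>_f<i>`.
#'
#' @param path CSV path.
#' @return For `read_ihc_cohort`, the cohort data frame.
#' @export
read_ihc_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @param cohort Cohort data frame.
#' @rdname read_ihc_cohort
#' @export
write_ihc_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
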