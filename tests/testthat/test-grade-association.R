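test_that("histotype aggregation reproduces the published cohort structure", {
  empty <- aggregate_histotype_grade(data.frame(histotype = character(),
                                                grade = character()))
  expect_equal(empty$total, 0L)

  tab <- aggregate_histotype_grade(histotype_cohort())
  simple <- tab[tab$histotype == "simple carcinoma (all)", ]
  expect_equal(simple$total, 85L)
  expect_equal(round(simple$pct), 84)
  expect_equal(tab$total[tab$histotype == "total"], 101L)
  subtype_rows <- tab[tab$histotype == "simple carcinoma", ]
  expect_setequal(subtype_rows$total, c(37L, 41L, 5L, 2L))
})

test_that("frequency-table marginals equal brute-force tallies on synthetic cohorts", {
  coh <- simulate_ihc_cohort(cohort_config(seed = 17))
  tab <- aggregate_histotype_grade(coh)
  expect_equal(tab$total[tab$histotype == "total"], nrow(coh))
  for (g in grades) {
    expect_equal(tab[[g]][tab$histotype == "total"], sum(coh$grade == g))
  }
  for (h in unique(coh$histotype)) {
    row <- tab[tab$histotype %in% c(h, sprintf("%s (all)", h)), ]
    row <- row[nrow(row), ]  # the per-histotype (all) row when subtyped
    expect_equal(row$total, sum(coh$histotype == h))
  }
})

test_that("grade percentages follow round-half-even arithmetic", {
  expect_equal(unname(grade_percentages(c(G1 = 45, G2 = 34, G3 = 22))),
               c(44.6, 33.7, 21.8))
  expect_equal(unname(grade_percentages(c(10, 0, 0))), c(100, 0, 0))
  expect_equal(unname(grade_percentages(c(1, 1, 1))), rep(33.3, 3))
  expect_error(grade_percentages(c(0, 0, 0)), "positive")
})

test_that("densities convert per-field counts through the field area", {
  expect_equal(density_from_fields(rep(0, 10)),
               list(mean_per_field = 0, per_mm2 = 0))
  d <- density_from_fields(rep(19, 10))
  expect_equal(d$mean_per_field, 19)
  expect_equal(round(d$per_mm2, 1), 100.8)
  # linearity
  x <- c(3, 5, 2, 8, 1, 0, 4, 6, 2, 9)
  expect_equal(density_from_fields(2 * x)$per_mm2,
               2 * density_from_fields(x)$per_mm2)
  expect_error(density_from_fields(rep(1, 7)), "expected 10")
})

test_that("per-grade summaries use per-case means and the n-1 denominator", {
  cfg <- ihc_config(n_cases = c(G1 = 1, G2 = 3, G3 = 2),
                    means = marker_matrix(15), sds = marker_matrix(0), seed = 5)
  coh <- simulate_ihc_cohort(cfg)
  s <- summarize_by_grade(coh, "cd68")
  expect_true(is.na(s$sd[s$grade == "G1"]))  # single case: SD undefined
  expect_equal(s$sd[s$grade == "G2"], 0)
  expect_equal(s$mean, rep(15, 3))
  expect_equal(s$n, c(1L, 3L, 2L))

  big <- ihc_config(n_cases = c(G1 = 300, G2 = 0, G3 = 0),
                    means = marker_matrix(60), sds = marker_matrix(8), seed = 6)
  sb <- summarize_by_grade(simulate_ihc_cohort(big), "cd20p")
  # per-case means average 10 fields, so their SE is sd/sqrt(10)/sqrt(n)
  expect_lt(abs(sb$mean - 60), 3 * 8 / sqrt(10 * 300))
})

test_that("summary t-test agrees with stats::t.test on the raw data", {
  x <- c(12.1, 9.8, 14.2, 11.0, 10.5, 13.3, 12.8, 9.1)
  y <- c(16.4, 18.0, 15.2, 17.7, 19.1, 16.9)
  for (variant in c("welch", "pooled")) {
    ours <- ttest_summary(length(x), mean(x), sd(x),
                          length(y), mean(y), sd(y), variant)
    ref <- stats::t.test(x, y, var.equal = (variant == "pooled"))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p.value, ref$p.value)
  }
})

test_that("summary t-test handles degenerate and boundary inputs", {
  same <- ttest_summary(10, 5, 2, 12, 5, 2)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(ttest_summary(1, 5, 2, 10, 6, 2), "n >= 2")
  expect_error(ttest_summary(5, 5, 0, 5, 6, 0), "positive standard deviation")
  # swapping groups flips the sign but not the p-value
  a <- ttest_summary(45, 6, 4.24, 22, 46.5, 24.64)
  b <- ttest_summary(22, 46.5, 24.64, 45, 6, 4.24)
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$statistic, -b$statistic)
})

test_that("pooled test with equal groups equals the textbook formula", {
  n <- 9; m1 <- 20; m2 <- 23; s <- 4
  ours <- ttest_summary(n, m1, s, n, m2, s, "pooled")
  t_hand <- (m1 - m2) / (s * sqrt(2 / n))
  expect_equal(ours$statistic, t_hand)
  expect_equal(ours$df, 2 * n - 2)
})

test_that("published G1 vs G3 summaries separate at the 0.05 level", {
  s <- canine_grade_summaries()
  n <- s$n_cases
  cd68 <- s$markers[s$markers$marker == "cd68", ]
  p_cd68 <- ttest_summary(n[["G1"]], cd68$mean[cd68$grade == "G1"],
                          cd68$sd[cd68$grade == "G1"],
                          n[["G3"]], cd68$mean[cd68$grade == "G3"],
                          cd68$sd[cd68$grade == "G3"])$p.value
  expect_lt(p_cd68, 0.05)
  cd20 <- s$markers[s$markers$marker == "cd20m", ]
  p_cd20 <- ttest_summary(n[["G1"]], cd20$mean[cd20$grade == "G1"],
                          cd20$sd[cd20$grade == "G1"],
                          n[["G3"]], cd20$mean[cd20$grade == "G3"],
                          cd20$sd[cd20$grade == "G3"])$p.value
  expect_lt(p_cd20, 0.05)
})

test_that("pairwise grade tests cover the three pairs and ignore input order", {
  s <- data.frame(grade = c("G1", "G2", "G3"), n = c(45, 34, 22),
                  mean = c(39.5, 34.13, 30.13), sd = c(10.2, 9.1, 4.1))
  res <- pairwise_grade_tests(s)
  expect_equal(res$group1, c("G1", "G1", "G2"))
  expect_equal(res$group2, c("G2", "G3", "G3"))
  expect_lt(res$p.value[res$group1 == "G1" & res$group2 == "G3"], 0.05)

  shuffled <- pairwise_grade_tests(s[c(3, 1, 2), ])
  expect_equal(shuffled, res)

  same <- data.frame(grade = c("G1", "G2", "G3"), n = 10, mean = 5, sd = 2)
  expect_equal(pairwise_grade_tests(same)$p.value, rep(1, 3))

  adj <- pairwise_grade_tests(s, p_adjust = "holm")
  expect_true(all(adj$p.adjusted >= adj$p.value))
  expect_error(pairwise_grade_tests(s[1:2, ]), "G1, G2 and G3")
})

test_that("serum ratios are computed and scale-invariant", {
  expect_equal(compute_cbc_ratios(300, 100, 100)$nlr, 1)
  r <- compute_cbc_ratios(platelet = 221000, lymphocyte = 4001.1,
                          neutrophil = 5432)
  expect_equal(round(r$nlr, 2), 1.36)
  expect_equal(round(r$plr, 1), 55.2)
  k <- 3.7
  rk <- compute_cbc_ratios(221000 * k, 4001.1 * k, 5432 * k)
  expect_equal(rk$nlr, r$nlr)
  expect_equal(rk$plr, r$plr)
  expect_error(compute_cbc_ratios(1, 0, 1), "positive")
})
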