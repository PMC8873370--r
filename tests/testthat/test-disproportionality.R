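test_that("contingency cells are counted exactly per the a/b/c/d definitions", {
  ll <- listing_frame(drug = c(rep("A", 5), rep("B", 5)),
                      reaction_pt = c("R", "R", "x1", "x2", "x3",
                                      "R", "y1", "y2", "y3", "y4"))
  tab <- build_contingency(ll, "A", "R", c("A", "B"))
  expect_equal(tab$a, 2)
  expect_equal(tab$c, 3)
  expect_equal(tab$b, 1)
  expect_equal(tab$d, 4)
  expect_equal(tab$a + tab$b + tab$c + tab$d, nrow(ll))

  expect_error(build_contingency(ll, "Z", "R", c("A", "B")), "member")
  expect_error(build_contingency(ll, "A", "R", "A"), "at least two")
})

test_that("contingency cells equal a brute-force recount on synthetic listings", {
  cfg <- small_pv_config(n = 300, seed = 61)
  ll <- simulate_line_listing(cfg)
  for (d in cfg$drugs) {
    for (r in c("R1", "R4")) {
      tab <- build_contingency(ll, d, r, cfg$drugs)
      mine <- ll$drug == d
      hit <- ll$reaction_pt == r
      expect_equal(tab$a, sum(mine & hit))
      expect_equal(tab$b, sum(!mine & hit))
      expect_equal(tab$c, sum(mine & !hit))
      expect_equal(tab$d, sum(!mine & !hit))
    }
  }
})

test_that("PRR matches hand arithmetic, including the printed-counts worked example", {
  expect_equal(compute_prr(contingency_table(5, 10, 45, 90)), 1)
  expect_equal(compute_prr(contingency_table(10, 10, 90, 190)), 2)
  # blood-and-lymphatic counts of the anti-HER2 class: platelet count
  # decrease for trastuzumab emtansine vs the two comparator antibodies
  tab <- contingency_table(a = 286, b = 258 + 69, c = 623 - 286,
                           d = (3435 - 258) + (1122 - 69))
  expect_equal(round(compute_prr(tab), 2), 6.40)
})

test_that("zero-cell policies behave as configured", {
  tab <- contingency_table(3, 0, 7, 20)
  expect_error(compute_prr(tab, "strict"), "b = 0")
  expect_equal(compute_prr(tab, "haldane"),
               (3.5 / (3.5 + 7.5)) / (0.5 / (0.5 + 20.5)))
  expect_error(compute_prr(contingency_table(0, 5, 0, 5)), "a \\+ c")
  expect_error(compute_prr(contingency_table(5, 0, 5, 0)), "b \\+ d")
})

test_that("PRR is invariant to within-arm scaling and inverts under arm swap", {
  set.seed(101)
  for (i in 1:50) {
    cells <- sample.int(40, 4)  # all positive
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    k <- sample.int(5, 1) + 1
    scaled_drug <- contingency_table(k * cells[1], cells[2],
                                     k * cells[3], cells[4])
    scaled_comp <- contingency_table(cells[1], k * cells[2],
                                     cells[3], k * cells[4])
    expect_equal(compute_prr(scaled_drug), compute_prr(tab))
    expect_equal(compute_prr(scaled_comp), compute_prr(tab))
    swapped <- contingency_table(cells[2], cells[1], cells[4], cells[3])
    expect_equal(compute_prr(tab) * compute_prr(swapped), 1)
  }
})

test_that("chi-square matches the closed formula and stats::chisq.test", {
  expect_equal(as.numeric(compute_chi2(contingency_table(10, 20, 90, 180))), 0)

  tab <- contingency_table(30, 10, 70, 190)
  hand <- 300 * (30 * 190 - 10 * 70)^2 / (40 * 260 * 100 * 200)
  expect_equal(as.numeric(compute_chi2(tab)), hand)

  m <- matrix(c(30, 70, 10, 190), 2, 2)
  expect_equal(as.numeric(compute_chi2(tab, yates = FALSE)),
               unname(stats::chisq.test(m, correct = FALSE)$statistic))
  expect_equal(as.numeric(compute_chi2(tab, yates = TRUE)),
               unname(stats::chisq.test(m, correct = TRUE)$statistic))

  set.seed(33)
  for (i in 1:25) {
    cells <- sample.int(50, 4)
    tt <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    expect_lte(as.numeric(compute_chi2(tt, yates = TRUE)),
               as.numeric(compute_chi2(tt, yates = FALSE)))
  }

  degen <- compute_chi2(contingency_table(0, 0, 10, 20))
  expect_equal(as.numeric(degen), 0)
  expect_true(attr(degen, "degenerate"))
})

test_that("the signal rule applies all three thresholds and the PRR=1 exclusion", {
  expect_true(evaluate_signal(2.5, 5, 5.0)$signal)
  low_n <- evaluate_signal(3.0, 2, 6.0)
  expect_false(low_n$signal)
  expect_equal(low_n$reasons, "min_cases")
  expect_false(evaluate_signal(1.0, 100, 50.0)$signal)

  # exact rational PRR = 1 is excluded even when the float value drifts
  tab <- contingency_table(3, 6, 7, 14)  # 3/10 vs 6/20: exactly 1
  ev <- evaluate_signal(compute_prr(tab), tab$a, 99, table = tab)
  expect_true("prr_equals_1" %in% ev$reasons)
})

test_that("the signal decision is monotone in prr, n_cases and chi2", {
  rule <- signal_rule()
  set.seed(7)
  for (i in 1:200) {
    prr <- stats::runif(1, 0, 6)
    n <- sample.int(10, 1)
    chi2 <- stats::runif(1, 0, 10)
    if (prr == 1) next
    base <- evaluate_signal(prr, n, chi2, rule)$signal
    bumped <- evaluate_signal(prr + stats::runif(1, 0.01, 2), n + sample.int(5, 1),
                              chi2 + stats::runif(1, 0, 5), rule)$signal
    if (base) expect_true(bumped)
  }
})

test_that("reaction shares reproduce printed percentages under banker's rounding", {
  expect_equal(reaction_share(286, 623), 45.9)
  expect_equal(reaction_share(0, 623), 0.0)
  expect_equal(reaction_share(128, 1122), 11.4)
  expect_equal(reaction_share(21, 623, digits = 2), 3.37)
  expect_error(reaction_share(5, 0), "positive")
  expect_error(reaction_share(7, 5), "0, total")
})

test_that("screening a single-reaction vocabulary yields PRR 1 everywhere", {
  ll <- listing_frame(drug = rep(c("A", "B"), c(8, 12)), reaction_pt = "R")
  scr <- prr_screen(ll, c("A", "B"))
  expect_true(all(scr$prr == 1))
  expect_true(all(!scr$signal))
  expect_true(all(grepl("prr_equals_1", scr$reasons)))
})

test_that("screen rows recompute identically to the unit operations", {
  cfg <- small_pv_config(n = 400, seed = 71)
  ll <- simulate_line_listing(cfg)
  aset <- as_analysis_set(ll)
  scr <- prr_screen(aset, cfg$drugs, zero_policy = "haldane")
  for (i in sample(nrow(scr), 6)) {
    tab <- build_contingency(aset, scr$drug[i], scr$reaction[i], cfg$drugs)
    expect_equal(scr$a[i], tab$a)
    expect_equal(scr$prr[i], compute_prr(tab, "haldane"))
    expect_equal(scr$chi2[i], as.numeric(compute_chi2(tab)))
    expect_equal(scr$signal[i],
                 evaluate_signal(scr$prr[i], tab$a,
                                 as.numeric(compute_chi2(tab)),
                                 table = tab)$signal)
  }
  # sorted by drug, then descending PRR within drug
  expect_equal(scr$drug, rep(cfg$drugs, each = 6))
  for (d in cfg$drugs) {
    expect_false(is.unsorted(rev(scr$prr[scr$drug == d])))
  }
})

test_that("an injected signal is flagged and baseline pairs are not", {
  cfg <- small_pv_config(n = 8000, lambda = 5, seed = 83)
  scr <- prr_screen(simulate_line_listing(cfg), cfg$drugs,
                    zero_policy = "haldane")
  hit <- scr[scr$drug == "drugA" & scr$reaction == "R1", ]
  expect_true(hit$signal)
  expect_lt(mean(scr$signal[!(scr$drug == "drugA" & scr$reaction == "R1")]),
            0.05)
})
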