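test_that("Kruskal-Wallis matches the rank-sum formula and is rank-invariant", {
  des <- suppressWarnings(stage_design(paste0("s", 1:6), rep(1:3, each = 2)))
  v <- c(1, 2, 3, 4, 5, 6)
  kw <- kruskal_wallis(v, des)
  expect_equal(kw$statistic, 192 / 42, tolerance = 1e-12)
  expect_equal(kw$statistic, oracle_kw(v, rep(1:3, each = 2)),
               tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(192 / 42, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # strictly increasing transforms leave (H, p) unchanged
  set.seed(3)
  for (f in list(function(x) exp(x), function(x) x^3 + 5,
                 function(x) 10 * rank(x))) {
    kw2 <- kruskal_wallis(f(v), des)
    expect_equal(kw2$statistic, kw$statistic, tolerance = 1e-12)
    expect_equal(kw2$p, kw$p, tolerance = 1e-12)
  }

  # degenerate input: no rank variation
  expect_equal(kruskal_wallis(rep(2, 6), des), list(statistic = 0, p = 1))
  expect_error(kruskal_wallis(c(1, 2, NA, 4, 5, 6), des), "non-finite")
})

test_that("p-value adjustment matches a hand step-up and validates input", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(2:30, 1))
    expect_equal(adjust_pvalues(p), oracle_bh(p))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_pvalues(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("monotone classification handles ties, constants and reversals", {
  expect_equal(monotonic_direction(c(1, 2, 3, 4)), "MI")
  expect_equal(monotonic_direction(c(4, 3, 2, 1)), "MD")
  expect_equal(monotonic_direction(c(1, 3, 2, 4)), "none")
  expect_equal(monotonic_direction(c(1, 1, 2, 2)), "MI")
  expect_equal(monotonic_direction(c(2, 2, 2, 2)), "none")
  expect_error(monotonic_direction(c(1, NA, 2, 3)), "non-finite")
  expect_error(monotonic_direction(1), "at least 2")

  # exhaustive: all 27 sign patterns of the 3 step differences at K = 4
  steps <- expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1)
  for (i in seq_len(nrow(steps))) {
    means <- cumsum(c(5, as.numeric(steps[i, ])))
    expect_equal(monotonic_direction(means), oracle_direction(means),
                 info = paste(steps[i, ], collapse = ","))
  }
})

test_that("identify_megs recovers planted monotone genes", {
  sim <- simulate_expression(500, c(15, 15, 15, 15), n_mi = 50, n_md = 0,
                             effect_step = 1, noise_sd = 1, seed = 7)
  tab <- identify_megs(sim$expr, sim$design, alpha = 0.1)
  planted_mi <- sum(tab$direction == "MI" & tab$gene %in% sim$truth$mi_genes)
  expect_gte(planted_mi, 45)
  # planted increasing genes are never called decreasing
  expect_equal(sum(tab$direction == "MD" & tab$gene %in% sim$truth$mi_genes),
               0)
})

test_that("identify_megs is well-behaved under the null", {
  sim <- simulate_expression(500, c(12, 12, 12, 12), n_mi = 0, n_md = 0,
                             seed = 13)
  tab <- identify_megs(sim$expr, sim$design, alpha = 0.05)
  expect_lte(attr(tab, "mi_count") + attr(tab, "md_count"), 50)
})

test_that("meg_table satisfies its internal consistency invariants", {
  sim <- simulate_expression(300, c(10, 10, 10, 10), n_mi = 20, n_md = 20,
                             seed = 5)
  tab <- identify_megs(sim$expr, sim$design, alpha = 0.1)
  means <- as.matrix(tab[, grep("^mean_stage", names(tab))])
  # labels are re-derivable from the stored stage means alone
  for (i in seq_len(nrow(tab))) {
    if (tab$direction[i] != "none") {
      expect_equal(tab$direction[i], oracle_direction(means[i, ]))
      expect_lte(tab$p_adjusted[i], attr(tab, "alpha"))
    }
  }
  expect_true(all(tab$p_adjusted >= tab$p_raw))
  # shuffling samples (with the design) changes nothing
  set.seed(2)
  perm <- sample(ncol(sim$expr))
  des_p <- stage_design(sim$design$sample[perm], sim$design$stage[perm])
  tab_p <- identify_megs(sim$expr[, perm], des_p, alpha = 0.1)
  expect_equal(as.data.frame(tab_p), as.data.frame(tab))
  # MI/MD counts grow monotonically with the threshold
  s <- meg_summary(tab)
  expect_true(all(diff(s$MI) >= 0))
  expect_true(all(diff(s$MD) >= 0))
})

test_that("control group can enter or leave the test but stays in the chain", {
  sim <- simulate_expression(100, c(6, 10, 10, 10, 10), n_mi = 10, n_md = 0,
                             include_control = TRUE, effect_step = 2,
                             seed = 21)
  with_ctl <- identify_megs(sim$expr, sim$design, alpha = 0.1)
  no_ctl <- identify_megs(sim$expr, sim$design, alpha = 0.1,
                          control_in_test = FALSE)
  expect_true("mean_stage0" %in% names(with_ctl))
  expect_true("mean_stage0" %in% names(no_ctl))
  # means identical, statistics differ (different grouping)
  expect_equal(no_ctl$mean_stage0, with_ctl$mean_stage0)
  expect_false(isTRUE(all.equal(no_ctl$kw_statistic,
                                with_ctl$kw_statistic)))
  # excluding the control drops the first term of the monotone chain:
  # recompute directions from the remaining means and compare
  means <- as.matrix(no_ctl[, grep("^mean_stage[1-9]", names(no_ctl))])
  for (i in which(no_ctl$direction != "none")) {
    expect_true(oracle_direction(means[i, ]) %in%
                  c(no_ctl$direction[i], "none"))
  }
})
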