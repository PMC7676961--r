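test_that("split_error matches exhaustive threshold enumeration", {
  # perfectly separated
  expect_equal(split_error(c(1, 2, 3, 4), c(1, 1, 2, 2), k = 1),
               list(misclassified = 0L, line = 2))
  # fully reversed and interleaved cases against the brute-force oracle
  cases <- list(
    list(v = c(3, 4, 1, 2), s = c(1, 1, 2, 2)),
    list(v = c(1, 5, 2, 3, 6), s = c(1, 1, 2, 2, 2))
  )
  for (cs in cases) {
    got <- split_error(cs$v, cs$s, k = 1)
    want <- oracle_split_error(cs$v, cs$s == 1)
    expect_equal(got, want)
  }
  set.seed(4)
  for (i in 1:30) {
    n <- sample(5:25, 1)
    v <- sample(round(rnorm(n), 1))  # ties likely
    s <- sort(sample(1:3, n, replace = TRUE))
    if (length(unique(s)) < 2) next
    for (k in seq_len(length(unique(s)) - 1)) {
      lev <- sort(unique(s))
      for (dir in c("increasing", "decreasing")) {
        expect_equal(split_error(v, s, k, dir),
                     oracle_split_error(v, s %in% lev[seq_len(k)], dir))
      }
    }
  }
  expect_error(split_error(c(1, 2), c(1, 1, 2), 1), "same length")
  expect_error(split_error(c(1, 2, 3), c(1, 1, 2), 2), "K-1")
})

test_that("detotal sums split errors and flags perfect monotone genes", {
  d <- detotal(c(1, 2, 3, 4, 5, 6), c(1, 1, 2, 2, 3, 3))
  expect_equal(d$detotal, 0L)
  expect_true(d$perfect_monotone)
  expect_equal(d$detotal, sum(d$split_errors))

  # same gene tested against the trend: brute-force value
  dd <- detotal(c(1, 2, 3, 4, 5, 6), c(1, 1, 2, 2, 3, 3), "decreasing")
  expect_equal(dd$detotal,
               oracle_detotal(c(1, 2, 3, 4, 5, 6), c(1, 1, 2, 2, 3, 3),
                              "decreasing"))
  expect_false(dd$perfect_monotone)

  # constant gene: every line misclassifies one full side of each split
  dc <- detotal(rep(2, 6), c(1, 1, 2, 2, 3, 3))
  expect_equal(dc$detotal, oracle_detotal(rep(2, 6), c(1, 1, 2, 2, 3, 3)))
  expect_false(dc$perfect_monotone)

  # ties across a split boundary cost an error (boundary counts as below),
  # so a zero total forces strictly increasing lines: 0 <=> perfect
  dt <- detotal(c(1, 1, 2, 2), c(1, 1, 2, 3))
  expect_equal(dt$detotal,
               oracle_detotal(c(1, 1, 2, 2), c(1, 1, 2, 3)))
  expect_equal(dt$detotal, 1L)
  expect_false(dt$perfect_monotone)
  dt2 <- detotal(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(dt2$detotal, 0L)
  expect_true(dt2$perfect_monotone)
})

test_that("detotal obeys order-invariance, duality and split bounds", {
  set.seed(8)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    K <- sample(2:4, 1)
    s <- sort(sample(seq_len(K), n, replace = TRUE))
    if (length(unique(s)) < 2) next
    v <- round(rnorm(n), 1)
    d_inc <- detotal(v, s)$detotal
    # strictly increasing transforms leave the score unchanged
    expect_equal(detotal(exp(v), s)$detotal, d_inc)
    # sign-flip duality
    expect_equal(detotal(-v, s, "decreasing")$detotal, d_inc)
    # per-split error is bounded by the smaller side
    lev <- sort(unique(s))
    errs <- detotal(v, s)$split_errors
    for (k in seq_along(errs)) {
      n_low <- sum(s %in% lev[seq_len(k)])
      expect_lte(errs[k], min(n_low, n - n_low))
    }
  }
  # appending a sample that respects perfect ordering never increases detotal
  v <- c(1, 2, 3, 4); s <- c(1, 1, 2, 2)
  base <- detotal(v, s)$detotal
  expect_lte(detotal(c(v, 9), c(s, 3))$detotal, base)
})

test_that("permutation p-values are exact, floored and reproducible", {
  # perfectly separated 2+2: only 1 of the 6 distinct assignments does
  # as well, so the exact p is 1/6
  v <- c(1, 2, 3, 4); s <- c(1, 1, 2, 2)
  expect_equal(mf_permutation_test(v, s, exact = TRUE), 1 / 6)
  # independent enumeration over the 6 lower-group choices
  obs <- oracle_detotal(v, s)
  stats <- apply(combn(4, 2), 2, function(idx) {
    sp <- rep(2L, 4); sp[idx] <- 1L
    oracle_detotal(v, sp)
  })
  expect_equal(mf_permutation_test(v, s, exact = TRUE),
               mean(stats <= obs))

  # sampled estimator: add-one floor and determinism
  p1 <- mf_permutation_test(v, s, n_perm = 50, seed = 3)
  expect_gte(p1, 1 / 51)
  expect_equal(p1, mf_permutation_test(v, s, n_perm = 50, seed = 3))
  expect_error(mf_permutation_test(v, s, n_perm = 0), "n_perm")
})

test_that("mfselect separates planted monotone genes from noise", {
  sim <- simulate_expression(60, c(8, 8, 8), n_mi = 10, n_md = 0,
                             effect_step = 8, noise_sd = 0.5, seed = 17)
  res <- mfselect(sim$expr, sim$design, direction = "increasing",
                  alpha = 0.05, n_perm = 200, seed = 9)
  planted <- res$gene %in% sim$truth$mi_genes
  # planted genes sit at the estimator floor, and their detotal is lower
  expect_true(all(res$p_perm[planted] == 1 / 201))
  expect_lt(mean(res$detotal[planted]), mean(res$detotal[!planted]))
  expect_true(all(res$perfect_monotone[planted]))
  # every reported detotal equals the brute-force oracle
  for (i in seq_len(nrow(res))) {
    expect_equal(res$detotal[i],
                 oracle_detotal(sim$expr[i, ], sim$design$stage))
  }
  # determinism: identical rerun
  res2 <- mfselect(sim$expr, sim$design, direction = "increasing",
                   alpha = 0.05, n_perm = 200, seed = 9)
  expect_equal(as.data.frame(res2), as.data.frame(res))
})

test_that("mfselect is quiet under the null and supports both directions", {
  sim <- simulate_expression(100, c(8, 8, 8), n_mi = 0, n_md = 0, seed = 23)
  res <- mfselect(sim$expr, sim$design, direction = "both",
                  alpha = 0.05, n_perm = 100, seed = 2)
  expect_lte(sum(res$significant), 10)
  expect_true(all(res$direction %in% c("increasing", "decreasing")))
  # per-gene independent permutations are also reproducible
  res_pg <- mfselect(sim$expr[1:5, ], sim$design, n_perm = 50, seed = 4,
                     per_gene_perms = TRUE)
  res_pg2 <- mfselect(sim$expr[1:5, ], sim$design, n_perm = 50, seed = 4,
                      per_gene_perms = TRUE)
  expect_equal(as.data.frame(res_pg), as.data.frame(res_pg2))
})
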