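test_that("contingency tables validate their counts", {
  expect_error(contingency_table(5, 4, 0, 10), "exceed")
  expect_error(contingency_table(1, 0, 0, 10), "positive")
  expect_error(contingency_table(-1, 4, 0, 10), "non-negative")
})

test_that("two-sided exact P matches an explicit enumeration oracle", {
  # independent oracle: enumerate the conditional distribution with choose()
  oracle <- function(a, n1, b, n2) {
    m <- a + b
    xs <- max(0, m - n2):min(m, n1)
    pr <- choose(n1, xs) * choose(n2, m - xs) / choose(n1 + n2, m)
    sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
  }
  set.seed(5)
  for (i in 1:100) {
    tab <- random_table()
    expect_equal(fisher_two_sided(tab),
                 oracle(tab$a, tab$n1, tab$b, tab$n2), tolerance = 1e-12)
  }
})

test_that("two-sided exact P agrees with the reference implementation", {
  set.seed(6)
  for (i in 1:50) {
    tab <- random_table()
    ref <- stats::fisher.test(matrix(c(tab$a, tab$n1 - tab$a,
                                       tab$b, tab$n2 - tab$b), 2,
                                     byrow = TRUE))$p.value
    expect_equal(fisher_two_sided(tab), ref, tolerance = 1e-10)
  }
  expect_equal(fisher_two_sided(contingency_table(5, 10, 5, 10)), 1)
})

test_that("the exact P is invariant under simultaneous row and column swap", {
  set.seed(8)
  for (i in 1:30) {
    tab <- random_table()
    swapped <- contingency_table(tab$n1 - tab$a, tab$n1, tab$n2 - tab$b, tab$n2)
    expect_equal(fisher_two_sided(tab), fisher_two_sided(swapped),
                 tolerance = 1e-12)
  }
})

test_that("P decreases as the case excess grows", {
  n1 <- 50; b <- 2; n2 <- 200
  start <- ceiling(n1 * b / n2) + 1  # a/n1 above b/n2 from here on
  ps <- vapply(start:20, function(a)
    fisher_two_sided(contingency_table(a, n1, b, n2)), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("sample odds ratio handles zero cells and group-swap symmetry", {
  expect_equal(odds_ratio_sample(contingency_table(3, 419, 4, 4523)),
               3 * 4519 / (416 * 4))
  expect_identical(odds_ratio_sample(contingency_table(2, 10, 0, 10)), Inf)
  expect_identical(odds_ratio_sample(contingency_table(0, 10, 2, 10)), 0)
  expect_true(is.nan(odds_ratio_sample(contingency_table(0, 100, 0, 100))))
  set.seed(9)
  for (i in 1:20) {
    tab <- random_table()
    if (tab$a == 0 || tab$b == 0 || tab$a == tab$n1 || tab$b == tab$n2) next
    swapped <- contingency_table(tab$b, tab$n2, tab$a, tab$n1)
    expect_equal(odds_ratio_sample(swapped), 1 / odds_ratio_sample(tab),
                 tolerance = 1e-12)
  }
})

test_that("conditional MLE matches the reference implementation", {
  set.seed(10)
  for (i in 1:30) {
    tab <- random_table()
    ref <- stats::fisher.test(matrix(c(tab$a, tab$n1 - tab$a,
                                       tab$b, tab$n2 - tab$b), 2,
                                     byrow = TRUE))$estimate
    mine <- odds_ratio_cmle(tab)
    if (!is.finite(mine) || mine == 0) {
      expect_true(!is.finite(ref) || ref == 0 || is.na(ref) ||
                    mine %in% c(0, Inf))
    } else {
      # fisher.test maximizes with a looser optimizer tolerance than the
      # root solve here; agreement to ~1e-3 relative is its precision
      expect_equal(unname(mine), unname(ref), tolerance = 1e-3)
    }
  }
})

test_that("exact conditional CI bounds solve the tail equations (bisection oracle)", {
  # independent oracle: bisection on the noncentral tail computed from
  # first principles with choose() weights; margins stay fixed at the
  # observed table's
  cond_tail <- function(a, n1, b, n2, psi, side) {
    m <- a + b
    xs <- max(0, m - n2):min(m, n1)
    w <- choose(n1, xs) * choose(n2, m - xs) * psi^xs
    sum(w[if (side == "ge") xs >= a else xs <= a]) / sum(w)
  }
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  set.seed(12)
  for (i in 1:25) {
    tab <- random_table()
    if (tab$a + tab$b == 0 || tab$a + tab$b >= tab$n1 + tab$n2) next
    ci <- odds_ratio_ci(tab)
    m <- tab$a + tab$b
    sup_min <- max(0, m - tab$n2); sup_max <- min(m, tab$n1)
    if (tab$a > sup_min) {
      low <- bisect(function(p)
        cond_tail(tab$a, tab$n1, tab$b, tab$n2, p, "ge") - 0.025, 1e-4, 1e3)
      if (low > 2e-4 && low < 999) expect_equal(ci[1], low, tolerance = 1e-3)
    } else expect_identical(ci[1], 0)
    if (tab$a < sup_max) {
      high <- bisect(function(p)
        cond_tail(tab$a, tab$n1, tab$b, tab$n2, p, "le") - 0.025, 1e-3, 1e3)
      if (high < 999) expect_equal(ci[2], high, tolerance = 1e-3)
    } else expect_identical(ci[2], Inf)
  }
})

test_that("a null table's confidence interval contains 1", {
  for (m in c("exact-conditional", "log-woolf")) {
    ci <- odds_ratio_ci(contingency_table(5, 20, 5, 20), method = m)
    expect_lt(ci[1], 1); expect_gt(ci[2], 1)
  }
})

test_that("log-woolf interval matches its closed form and rejects empty cells", {
  tab <- contingency_table(10, 50, 5, 60)
  ci <- odds_ratio_ci(tab, method = "log-woolf")
  se <- sqrt(1 / 10 + 1 / 40 + 1 / 5 + 1 / 55)
  expect_equal(ci, exp(log((10 * 55) / (40 * 5)) + c(-1, 1) * qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_error(odds_ratio_ci(contingency_table(0, 10, 2, 10),
                             method = "log-woolf"), "empty cell")
})

test_that("burden_test composes counts, P, OR and CI", {
  res <- burden_test(25, 793, 46, 4523, class_label = "missense")
  expect_s3_class(res, "burden_result")
  expect_equal(res$p_two_sided, 2.56e-5, tolerance = 2e-3)
  expect_equal(res$or_sample, 25 * 4477 / (768 * 46), tolerance = 1e-12)
  expect_lt(res$ci_low, res$or); expect_gt(res$ci_high, res$or)
  degenerate <- burden_test(0, 100, 0, 100)
  expect_equal(degenerate$p_two_sided, 1)
  expect_true(is.nan(degenerate$or_sample))
})

test_that("meta pooling sums counts and is the identity on one cohort", {
  expect_equal(unname(meta_pool(list(c(4, 793), c(3, 419)))), c(7, 1212))
  expect_equal(unname(meta_pool(list(c(25, 793), c(15, 419)))), c(40, 1212))
  expect_equal(unname(meta_pool(list(c(4, 793)))), c(4, 793))
  expect_error(meta_pool(list(c(5, 4))), "valid")
  expect_error(meta_pool(list(c(1, 10), c(1, 10)),
                         sample_ids = list(c("a", "b"), c("b", "c"))),
               "double counting")
})

test_that("pooling identical cohorts preserves the sample odds ratio", {
  one <- contingency_table(6, 100, 3, 200)
  pooled <- meta_pool(list(c(6, 100), c(6, 100)))
  tab2 <- contingency_table(pooled["carriers"], pooled["total"], 6, 400)
  expect_equal(odds_ratio_sample(tab2),
               odds_ratio_sample(contingency_table(6, 100, 3, 200)),
               tolerance = 1e-12)
})

test_that("synonymous calibration attaches the comparability verdict", {
  res <- calibration_synonymous(6, 793, 15, 4523)
  expect_true(res$calibrated)
  expect_equal(res$p_two_sided, 0.11, tolerance = 0.05)
  expect_true(calibration_synonymous(2, 419, 15, 4523)$calibrated)
  expect_false(calibration_synonymous(50, 100, 5, 100)$calibrated)
})

test_that("forest_table flattens results into figure columns", {
  res <- list(study = burden_test(4, 793, 4, 4523, class_label = "truncating"),
              meta = burden_test(7, 1212, 4, 4523, class_label = "truncating"))
  ft <- forest_table(res)
  expect_equal(nrow(ft), 2)
  expect_identical(ft$n_cases, c("4/793", "7/1212"))
  expect_true(all(c("or", "ci_low", "ci_high", "p") %in% names(ft)))
})
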