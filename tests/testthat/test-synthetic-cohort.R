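test_that("site and carrier simulation is fully deterministic under a seed", {
  cfg <- sim_config(seed = 123)
  s1 <- simulate_sites(cfg); s2 <- simulate_sites(cfg)
  expect_identical(s1, s2)
  c1 <- simulate_carriers(s1, cfg); c2 <- simulate_carriers(s2, cfg)
  expect_identical(c1$variants$carriers, c2$variants$carriers)
  s3 <- simulate_sites(sim_config(seed = 124))
  expect_false(identical(s1$pos, s3$pos))
})

test_that("a zero deleterious fraction yields no deleterious missense site", {
  cfg <- sim_config(seed = 5, score_model = list(deleterious_fraction = 0,
                                                 del_range = c(0.75, 0.95),
                                                 benign_range = c(0.05, 0.35)))
  sites <- simulate_sites(cfg)
  mis <- sites[sites$class == "MISSENSE", ]
  fcfg <- filter_config()
  expect_false(any(vapply(seq_len(nrow(mis)), function(i)
    is_deleterious_missense(mis$revel[i], mis$vest3[i], fcfg), logical(1))))
})

test_that("the configured common fraction is removed by the rarity filter", {
  cfg <- sim_config(seed = 17,
                    n_sites = c(truncating = 10, missense = 1000, synonymous = 10),
                    af_spectrum = list(shape1 = 0.5, shape2 = 1, max_af = 1e-4,
                                       common_fraction = 0.1, novel_fraction = 0))
  sites <- simulate_sites(cfg)
  mis <- sites[sites$class == "MISSENSE", ]
  kept <- select_qualifying(mis, cfg$gene, "missense")$variants
  frac_removed <- 1 - nrow(kept) / nrow(mis)
  # binomial(1000, 0.1): +-4 sd band around 0.1
  expect_gt(frac_removed, 0.1 - 4 * sqrt(0.1 * 0.9 / 1000))
  expect_lt(frac_removed, 0.1 + 4 * sqrt(0.1 * 0.9 / 1000))
})

test_that("carrier probabilities follow the configured odds scaling", {
  # theta = 1: case and control carrier rates equal in expectation
  cfg <- sim_config(seed = 77, n_cases = 20000, n_controls = 20000,
                    p0 = c(missense = 0.01), or = c(missense = 1),
                    n_sites = c(missense = 5))
  cohort <- simulate_carriers(simulate_sites(cfg), cfg)
  qs <- select_qualifying(cohort$variants, cfg$gene, "missense")
  case_ids <- cohort$roster$sample_id[cohort$roster$group == "case"]
  a <- sum(qs$carrier_ids %in% case_ids); b <- qs$carrier_count - a
  expect_lt(abs(a - b) / max(a, b), 0.35)  # both ~ Binomial(20000, 0.01)
  # p0 = 0: no carriers at all
  cfg0 <- sim_config(seed = 78, p0 = c(missense = 0), or = c(missense = 2),
                     n_sites = c(missense = 3))
  cohort0 <- simulate_carriers(simulate_sites(cfg0), cfg0)
  expect_equal(oracle_count_carriers(cohort0$variants), 0)
})

test_that("the realized sample OR approaches the generative OR at large n", {
  cfg <- sim_config(seed = 99, n_cases = 100000, n_controls = 100000,
                    p0 = c(missense = 0.001), or = c(missense = 5),
                    n_sites = c(missense = 5))
  cohort <- simulate_carriers(simulate_sites(cfg), cfg)
  qs <- select_qualifying(cohort$variants, cfg$gene, "missense")
  case_ids <- cohort$roster$sample_id[cohort$roster$group == "case"]
  a <- sum(qs$carrier_ids %in% case_ids); b <- qs$carrier_count - a
  or_hat <- odds_ratio_sample(contingency_table(a, 100000, b, 100000))
  expect_lt(abs(or_hat - 5) / 5, 0.2)
})

test_that("every simulated carrier is on the roster", {
  cfg <- sim_config(seed = 41)
  cohort <- simulate_carriers(simulate_sites(cfg), cfg)
  carriers <- unique(unlist(cohort$variants$carriers))
  expect_true(all(carriers %in% cohort$roster$sample_id))
  for (cl in c("truncating", "missense", "synonymous"))
    expect_silent(count_carriers(select_qualifying(cohort$variants, cfg$gene, cl),
                                 cohort$roster$sample_id))
})

test_that("clinical simulation is summary-consistent and seeded", {
  params <- list(
    list(label = "wall", type = "cont",
         groups = list(g1 = c(19.4, 5.1, 30), g2 = c(17.2, 3.7, 60))),
    list(label = "male", type = "cat",
         groups = list(g1 = c(0.6, 30), g2 = c(0.7, 60))))
  sim1 <- simulate_clinical(params, seed = 9)
  sim2 <- simulate_clinical(params, seed = 9)
  expect_identical(sim1, sim2)
  # summary of the raw draws equals the emitted summary row: identical P
  raw <- sim1$raw$wall
  p_raw <- stats::t.test(raw$g1, raw$g2, var.equal = TRUE)$p.value
  row <- sim1$rows[[1]]
  p_sum <- pooled_t_from_summary(row$groups$g1, row$groups$g2)$p_two_sided
  expect_equal(p_sum, p_raw, tolerance = 1e-10)
})

test_that("null pooled-t P values are uniform across replicates", {
  set.seed(2026)
  n <- 60
  ps <- replicate(2000, {
    x <- rnorm(n); y <- rnorm(n)
    pooled_t_from_summary(c(mean(x), sd(x), n), c(mean(y), sd(y), n))$p_two_sided
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("recovery_experiment aggregates and handles a single replicate", {
  cfg <- sim_config(seed = 15)
  rep1 <- recovery_experiment(cfg, 1, classes = "missense")
  expect_equal(nrow(rep1$summary), 1)
  expect_equal(nrow(rep1$replicates), 1)
  expect_true(all(c("coverage", "rejection_rate") %in% names(rep1$summary)))
})

test_that("the inference recovers a strong enrichment within a factor of two", {
  cfg <- sim_config(seed = 207,
                    p0 = c(truncating = 0.0009), or = c(truncating = 8),
                    n_sites = c(truncating = 3))
  rec <- recovery_experiment(cfg, 150, classes = "truncating")
  finite <- is.finite(rec$replicates$or) & rec$replicates$or > 0
  med <- stats::median(rec$replicates$or[finite])
  expect_gt(med, 4); expect_lt(med, 16)
  expect_gte(rec$summary$coverage, 0.93)
})

test_that("the synonymous negative control is calibrated on null cohorts", {
  cfg <- sim_config(seed = 301)
  rec <- recovery_experiment(cfg, 200, classes = "synonymous")
  verdicts <- rec$replicates$p >= 0.05
  expect_gte(mean(verdicts), 0.94)
})
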