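# Seeded generator of case/control cohorts with the statistical structure
# the burden pipeline assumes: per-class carrier probabilities in controls,
# class-specific enrichment odds ratios in cases, a rare-tail allele
# frequency spectrum, and a two-score deleteriousness model for missense
# sites. Enrichment is injected at the carrier level (per-individual
# Bernoulli), because the collapsing statistic only sees carrier status;
# per-site realism is unnecessary for testing the inference chain.

SUBPOPULATIONS <- c("afr", "amr", "eas", "nfe", "sas")

#' Simulation configuration
#'
#' Generative parameters of the synthetic cohorts. The defaults emulate the
#' conditions of a single-gene case-control burden study: 793 cases versus
#' 4,523 reference controls; control carrier probabilities taken from the
#' observed control carrier fractions (truncating 4/4523, missense 46/4523,
#' synonymous 15/4523); enrichment odds ratios near the observed case
#' enrichment (truncating ~5.7, missense ~3.2) and a null synonymous class
#' (OR = 1, the negative control); site counts per class matching the
#' discovery cohort's qualifying-variant breakdown (3 truncating, 22
#' missense, 6 synonymous).
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param p0 Named per-class carrier probability in controls.
#' @param or Named per-class enrichment odds ratio (cases carry with
#'   probability `or*p0 / (1 - p0 + or*p0)`).
#' @param n_sites Named per-class number of variant sites.
#' @param af_spectrum Rare-tail allele-frequency model: a beta(`shape1`,
#'   `shape2`) draw scaled to `(0, max_af)`; `common_fraction` of sites
#'   instead get a frequency at or above `max_af` (to exercise the rarity
#'   filter); `novel_fraction` of sites are absent from all frequency
#'   resources (`NA` frequencies).
#' @param score_model Missense deleteriousness model: each missense site is
#'   deleterious with probability `deleterious_fraction`; deleterious sites
#'   draw REVEL and VEST3 uniformly from `del_range`, others from
#'   `benign_range`. The default ranges keep the deleterious call stable for
#'   any score threshold between the two ranges.
#' @param gene,transcript Labels stamped on the generated sites.
#' @param seed Master seed; expanded into independent per-stage child seeds
#'   (sites, carriers, clinical) by drawing from the master-seeded stream,
#'   so stages can be re-run independently and reproducibly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 793L, n_controls = 4523L,
                       p0 = c(truncating = 4 / 4523, missense = 46 / 4523,
                              synonymous = 15 / 4523),
                       or = c(truncating = 5.73, missense = 3.17,
                              synonymous = 1),
                       n_sites = c(truncating = 3L, missense = 22L,
                                   synonymous = 6L),
                       af_spectrum = list(shape1 = 0.5, shape2 = 1,
                                          max_af = 1e-4, common_fraction = 0,
                                          novel_fraction = 0.3),
                       score_model = list(deleterious_fraction = 3 / 22,
                                          del_range = c(0.75, 0.95),
                                          benign_range = c(0.05, 0.35)),
                       gene = "GENE1", transcript = "NM_000001.1",
                       seed = 1L) {
  classes <- names(p0)
  stopifnot(length(classes) >= 1L, !is.null(classes),
            setequal(classes, names(or)), setequal(classes, names(n_sites)),
            all(p0 >= 0), all(p0 <= 1), all(or > 0),
            all(n_sites >= 1), all(n_sites == round(n_sites)),
            n_cases >= 1, n_controls >= 1,
            af_spectrum$max_af > 0, af_spectrum$common_fraction >= 0,
            af_spectrum$common_fraction <= 1,
            score_model$deleterious_fraction >= 0,
            score_model$deleterious_fraction <= 1,
            is.numeric(seed), length(seed) == 1L, seed == round(seed))
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              classes = classes, p0 = p0, or = or[classes],
              n_sites = as.integer(n_sites[classes]),
              af_spectrum = af_spectrum, score_model = score_model,
              gene = gene, transcript = transcript, seed = as.integer(seed))
  names(cfg$n_sites) <- classes
  class(cfg) <- "sim_config"
  cfg
}

# Master seed -> named child seeds, one per simulation stage. Drawn from the
# master-seeded integer stream so each stage is independently reproducible.
child_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(2147483646L, 4L)
  names(s) <- c("sites", "carriers", "clinical", "replicates")
  s
}

class_tokens <- c(truncating = "stop_gained", missense = "missense_variant",
                  synonymous = "synonymous_variant")

#' Simulate variant sites
#'
#' Generates the per-class variant sites of a synthetic gene: SNV
#' coordinates, consequence tokens matching the class, subpopulation allele
#' frequencies from the configured rare-tail spectrum (optionally with a
#' fraction of common sites and a fraction of novel sites), and REVEL/VEST3
#' scores for missense sites. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [variant_table()] with empty carrier lists.
#' @export
simulate_sites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seeds(config$seed)[["sites"]])
  n_total <- sum(config$n_sites)
  cls <- rep(config$classes, config$n_sites)
  pos <- sort(sample.int(200000L, n_total)) + 84000000L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  sp <- config$af_spectrum
  af <- matrix(NA_real_, n_total, length(SUBPOPULATIONS),
               dimnames = list(NULL, paste0("af_", SUBPOPULATIONS)))
  novel <- stats::runif(n_total) < sp$novel_fraction
  common <- !novel & stats::runif(n_total) < sp$common_fraction
  for (i in seq_len(n_total)) {
    if (novel[i]) next
    if (common[i]) {
      # push one subpopulation to/above the rarity threshold
      v <- sp$max_af * stats::rbeta(length(SUBPOPULATIONS), sp$shape1, sp$shape2)
      v[sample.int(length(v), 1L)] <- stats::runif(1, sp$max_af,
                                                   min(10 * sp$max_af, 0.01))
      af[i, ] <- v
    } else {
      af[i, ] <- sp$max_af *
        stats::rbeta(length(SUBPOPULATIONS), sp$shape1, sp$shape2) *
        (1 - 1e-9)  # keep strictly below the threshold
    }
  }
  sm <- config$score_model
  revel <- vest3 <- rep(NA_real_, n_total)
  mis <- cls == "missense"
  if (any(mis)) {
    del <- stats::runif(sum(mis)) < sm$deleterious_fraction
    lo <- ifelse(del, sm$del_range[1], sm$benign_range[1])
    hi <- ifelse(del, sm$del_range[2], sm$benign_range[2])
    revel[mis] <- stats::runif(sum(mis), lo, hi)
    vest3[mis] <- stats::runif(sum(mis), lo, hi)
  }
  variant_table(chrom = "15", pos = pos, ref = ref, alt = alt,
                gene = config$gene, transcript = config$transcript,
                consequence = unname(class_tokens[cls]),
                af = as.data.frame(af), revel = revel, vest3 = vest3)
}

#' Simulate carrier status and assemble a synthetic cohort
#'
#' Draws per-individual carrier status per class: controls carry with the
#' baseline probability `p0(c)`, cases with the odds-scaled probability
#' `p1(c) = or*p0 / (1 - p0 + or*p0)`, and each carrier is attached to one
#' concrete site of that class chosen uniformly. Deterministic given
#' `config$seed`.
#'
#' @param sites A [variant_table()] from [simulate_sites()].
#' @param config The same [sim_config()].
#' @return A list of class `synthetic_cohort`: `roster` (data frame with
#'   `sample_id`, `group`), `variants` (sites with populated carrier lists),
#'   and `config` (the true generative parameters).
#' @export
simulate_carriers <- function(sites, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seeds(config$seed)[["carriers"]])
  case_ids <- sprintf("case_%05d", seq_len(config$n_cases))
  ctrl_ids <- sprintf("ctrl_%05d", seq_len(config$n_controls))
  carriers <- lapply(seq_len(nrow(sites)), function(i) character(0))
  site_class <- names(class_tokens)[match(sites$class,
                                          classify_consequence(class_tokens))]
  for (cl in config$classes) {
    p0 <- config$p0[[cl]]
    theta <- config$or[[cl]]
    p1 <- theta * p0 / (1 - p0 + theta * p0)
    if (is.na(p1) || p1 < 0 || p1 >= 1 + 1e-12)
      stop("case carrier probability outside [0,1) for class ", cl)
    rows <- which(site_class == cl)
    if (!length(rows)) stop("no sites of class ", cl)
    hit_case <- case_ids[stats::runif(config$n_cases) < p1]
    hit_ctrl <- ctrl_ids[stats::runif(config$n_controls) < p0]
    hits <- c(hit_case, hit_ctrl)
    if (length(hits)) {
      at <- rows[sample.int(length(rows), length(hits), replace = TRUE)]
      for (j in seq_along(hits))
        carriers[[at[j]]] <- c(carriers[[at[j]]], hits[j])
    }
  }
  sites$carriers <- I(carriers)
  out <- list(roster = data.frame(
                sample_id = c(case_ids, ctrl_ids),
                group = rep(c("case", "control"),
                            c(config$n_cases, config$n_controls)),
                stringsAsFactors = FALSE),
              variants = sites, config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cases, %d controls, %d sites (seed %d)\n",
              x$config$n_cases, x$config$n_controls, nrow(x$variants),
              x$config$seed))
  invisible(x)
}

#' Simulate a baseline clinical table
#'
#' Draws raw values for each row of a baseline-characteristics table —
#' normal samples for continuous rows, binomial event counts for categorical
#' rows — and emits both the raw draws and the realized summary rows, so the
#' summary-statistic tests can be validated against tests on the raw data.
#'
#' @param group_params A list of rows; each row is a list with `label`,
#'   `type` (`"cont"` or `"cat"`), and `groups`, a named list of
#'   `c(mean, sd, n)` (continuous) or `c(prob, n)` (categorical) parameters.
#' @param seed Integer seed.
#' @return A list with `raw` (per row, per group: numeric draws or event
#'   count) and `rows` (realized summaries in the [compare_baseline()]
#'   dialect).
#' @export
simulate_clinical <- function(group_params, seed = 1L) {
  set.seed(child_seeds(seed)[["clinical"]])
  raw <- list(); rows <- list()
  for (row in group_params) {
    stopifnot(!is.null(row$label), row$type %in% c("cont", "cat"))
    raw_g <- list(); sum_g <- list()
    for (g in names(row$groups)) {
      p <- as.numeric(row$groups[[g]])
      if (row$type == "cont") {
        if (p[2] <= 0) stop("sd must be positive in row ", sQuote(row$label))
        x <- stats::rnorm(p[3], p[1], p[2])
        raw_g[[g]] <- x
        sum_g[[g]] <- c(mean(x), stats::sd(x), length(x))
      } else {
        if (p[1] < 0 || p[1] > 1) stop("probability outside [0,1] in row ",
                                       sQuote(row$label))
        k <- stats::rbinom(1L, p[2], p[1])
        raw_g[[g]] <- k
        sum_g[[g]] <- c(k, p[2])
      }
    }
    raw[[row$label]] <- raw_g
    rows[[length(rows) + 1L]] <- list(label = row$label, type = row$type,
                                      groups = sum_g)
  }
  list(raw = raw, rows = rows)
}

#' Parameter-recovery and calibration experiment
#'
#' Repeatedly simulates cohorts under the configured truth, runs the full
#' filter -> collapse -> burden pipeline on each replicate, and summarizes
#' how well the inference recovers the generative odds ratios: mean
#' estimated log-OR versus truth, median OR, empirical coverage of the
#' confidence interval, and the rejection rate at `alpha` (the type-I error
#' when the true OR is 1).
#'
#' @param config A [sim_config()] (its `or` entries are the truth).
#' @param n_replicates Number of simulated cohorts.
#' @param classes Which qualifying classes to evaluate; defaults to the
#'   classes in `config`.
#' @param alpha Rejection threshold on the two-sided P.
#' @param level Confidence level of the interval whose coverage is scored.
#' @param filter A [filter_config()] used by the per-replicate pipeline.
#' @return A list of class `recovery_report`: `summary` (one row per class)
#'   and `replicates` (one row per class per replicate: counts, P, OR, CI).
#' @export
recovery_experiment <- function(config, n_replicates, classes = config$classes,
                                alpha = 0.05, level = 0.95,
                                filter = filter_config()) {
  stopifnot(n_replicates >= 1)
  rep_seeds <- {
    set.seed(child_seeds(config$seed)[["replicates"]])
    sample.int(2147483646L, n_replicates)
  }
  reps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg_i <- config
    cfg_i$seed <- rep_seeds[i]
    cohort <- simulate_carriers(simulate_sites(cfg_i), cfg_i)
    case_ids <- cohort$roster$sample_id[cohort$roster$group == "case"]
    rows <- lapply(classes, function(cl) {
      qs <- select_qualifying(cohort$variants, config$gene, cl, config = filter)
      a <- sum(qs$carrier_ids %in% case_ids)
      b <- qs$carrier_count - a
      bt <- burden_test(a, config$n_cases, b, config$n_controls,
                        class_label = cl, level = level)
      data.frame(replicate = i, class_label = cl, a = a, b = b,
                 p = bt$p_two_sided, or = bt$or_cmle,
                 ci_low = bt$ci_low, ci_high = bt$ci_high,
                 stringsAsFactors = FALSE)
    })
    reps[[i]] <- do.call(rbind, rows)
  }
  reps <- do.call(rbind, reps)
  summ <- do.call(rbind, lapply(classes, function(cl) {
    r <- reps[reps$class_label == cl, ]
    truth <- config$or[[cl]]
    finite <- is.finite(r$or) & r$or > 0
    covered <- r$ci_low <= truth & truth <= r$ci_high
    data.frame(class_label = cl, true_or = truth,
               n_replicates = nrow(r),
               mean_log_or = mean(log(r$or[finite])),
               median_or = stats::median(r$or, na.rm = TRUE),
               coverage = mean(covered, na.rm = TRUE),
               rejection_rate = mean(r$p < alpha),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, replicates = reps,
                 alpha = alpha, level = level),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery experiment (%d replicate(s), alpha = %.3g, %d%% CI)\n",
              max(x$replicates$replicate), x$alpha, round(100 * x$level)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
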