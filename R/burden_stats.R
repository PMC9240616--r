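# Exact 2x2 inference on carrier counts. The conditional machinery (Fisher
# two-sided P, conditional-MLE odds ratio, exact conditional confidence
# limits) is implemented here from the (noncentral) hypergeometric
# distribution; stats::fisher.test serves only as an independent cross-check
# in the test suite.

#' Carrier-count contingency table
#'
#' The unit of all burden inference: carriers and non-carriers of a
#' qualifying-variant class in cases versus controls.
#'
#' @param a Case carriers. @param n1 Case total.
#' @param b Control carriers. @param n2 Control total.
#' @return A list of class `contingency_table` with fields `a`, `n1`, `b`, `n2`.
#' @export
contingency_table <- function(a, n1, b, n2) {
  v <- c(a = a, n1 = n1, b = b, n2 = n2)
  if (any(is.na(v)) || any(v != round(v)) || any(v < 0))
    stop("all counts must be non-negative integers")
  if (n1 <= 0 || n2 <= 0) stop("group totals must be positive")
  if (a > n1 || b > n2) stop("carriers cannot exceed the group total")
  out <- list(a = as.integer(a), n1 = as.integer(n1),
              b = as.integer(b), n2 = as.integer(n2))
  class(out) <- "contingency_table"
  out
}

as_contingency <- function(table) {
  if (inherits(table, "contingency_table")) return(table)
  if (is.matrix(table) && all(dim(table) == 2L))
    return(contingency_table(table[1, 1], sum(table[1, ]),
                             table[2, 1], sum(table[2, ])))
  do.call(contingency_table, as.list(table)[c("a", "n1", "b", "n2")])
}

# Support and log central-hypergeometric weights of X = case carriers given
# fixed margins (m = a + b total carriers).
hyper_support <- function(tab) {
  m <- tab$a + tab$b
  x <- max(0L, m - tab$n2):min(m, tab$n1)
  list(x = x, m = m,
       logw = lchoose(tab$n1, x) + lchoose(tab$n2, m - x))
}

#' Two-sided Fisher exact P-value
#'
#' Exact conditional test of association in a 2x2 carrier table, using the
#' minimum-likelihood two-sided rule: the sum of the probabilities of all
#' tables (with the observed margins) whose point probability does not
#' exceed that of the observed table. This is the rule used by mainstream
#' statistical software; a small relative tolerance guards the comparison of
#' equal point probabilities against floating-point noise.
#'
#' @param table A [contingency_table()] (or 2x2 matrix with groups in rows).
#' @return Two-sided P-value in [0, 1].
#' @examples
#' fisher_two_sided(contingency_table(4, 793, 4, 4523))
#' @export
fisher_two_sided <- function(table) {
  tab <- as_contingency(table)
  sup <- hyper_support(tab)
  d <- exp(sup$logw - max(sup$logw))
  d <- d / sum(d)
  obs <- d[match(tab$a, sup$x)]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Sample (cross-product) odds ratio
#'
#' The unconditional cross-product estimate `a*(n2-b) / ((n1-a)*b)`.
#' Returns `Inf` when only the control cell is empty, `0` when only the case
#' cell is empty, and `NaN` (degenerate table) when no carriers were observed
#' in either group.
#'
#' @inheritParams fisher_two_sided
#' @return Non-negative number, possibly `Inf` or `NaN`.
#' @export
odds_ratio_sample <- function(table) {
  tab <- as_contingency(table)
  a <- tab$a; b <- tab$b; c_ <- tab$n1 - tab$a; d <- tab$n2 - tab$b
  if (a == 0 && b == 0) return(NaN)
  if (b == 0 || c_ == 0) return(if (a == 0 || d == 0) NaN else Inf)
  (a * d) / (c_ * b)
}

# Fisher noncentral hypergeometric log-likelihood pieces at odds ratio psi,
# returned as normalized probabilities over the support.
nchg_pmf <- function(sup, log_psi) {
  lw <- sup$logw + sup$x * log_psi
  w <- exp(lw - max(lw))
  w / sum(w)
}

nchg_mean <- function(sup, log_psi) {
  p <- nchg_pmf(sup, log_psi)
  sum(p * sup$x)
}

# P(X >= a | psi) and P(X <= a | psi) under the noncentral hypergeometric.
nchg_tail_ge <- function(sup, a, log_psi) sum(nchg_pmf(sup, log_psi)[sup$x >= a])
nchg_tail_le <- function(sup, a, log_psi) sum(nchg_pmf(sup, log_psi)[sup$x <= a])

# Solve f(log_psi) = 0 for monotone f by expanding a bracket then uniroot.
solve_log_psi <- function(f, tol = 1e-12) {
  lo <- -1; hi <- 1
  while (f(lo) * f(hi) > 0 && hi < 745) { lo <- lo * 2; hi <- hi * 2 }
  if (f(lo) * f(hi) > 0) stop("root bracketing failed")
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Conditional maximum-likelihood odds ratio
#'
#' The odds ratio maximizing the Fisher noncentral hypergeometric likelihood
#' of the table with both margins fixed, found by solving `E[X | psi] = a`.
#' This is the estimate printed by `fisher.test()` and the package's default
#' point estimate, because it is consistent with the exact conditional
#' confidence limits. At the boundary of the conditional support the estimate
#' is `0` or `Inf`; a table with no carriers anywhere is degenerate (`NaN`).
#'
#' @inheritParams fisher_two_sided
#' @return Non-negative number, possibly `Inf` or `NaN`.
#' @export
odds_ratio_cmle <- function(table) {
  tab <- as_contingency(table)
  sup <- hyper_support(tab)
  if (length(sup$x) == 1L) return(NaN)       # margins pin the table
  if (tab$a == min(sup$x)) return(0)
  if (tab$a == max(sup$x)) return(Inf)
  exp(solve_log_psi(function(lp) nchg_mean(sup, lp) - tab$a))
}

#' Confidence interval for the odds ratio
#'
#' Two methods. `"exact-conditional"` inverts the one-sided exact tests: the
#' lower limit is the odds ratio at which `P(X >= a)` equals `(1-level)/2`
#' and the upper limit the one at which `P(X <= a)` equals `(1-level)/2`,
#' each found by monotone root-finding on the noncentral hypergeometric
#' tails. When the observed count sits at the edge of the conditional
#' support, the corresponding limit is one-sided (0 or `Inf`). `"log-woolf"`
#' is the asymptotic interval `exp(log OR +/- z * sqrt(1/a + 1/(n1-a) + 1/b +
#' 1/(n2-b)))` and requires all four cells positive.
#'
#' @inheritParams fisher_two_sided
#' @param level Confidence level in (0, 1); default 0.95.
#' @param method `"exact-conditional"` (default) or `"log-woolf"`.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' odds_ratio_ci(contingency_table(3, 419, 4, 4523))  # 1.19 - 48.30
#' @export
odds_ratio_ci <- function(table, level = 0.95,
                          method = c("exact-conditional", "log-woolf")) {
  method <- match.arg(method)
  tab <- as_contingency(table)
  stopifnot(level > 0, level < 1)
  alpha <- (1 - level) / 2
  if (method == "log-woolf") {
    cells <- c(tab$a, tab$n1 - tab$a, tab$b, tab$n2 - tab$b)
    if (any(cells == 0))
      stop("log-woolf interval undefined with an empty cell; use exact-conditional")
    z <- stats::qnorm(1 - alpha)
    lor <- log(odds_ratio_sample(tab))
    se <- sqrt(sum(1 / cells))
    return(exp(lor + c(-1, 1) * z * se))
  }
  sup <- hyper_support(tab)
  if (length(sup$x) == 1L) return(c(0, Inf))  # margins carry no information
  low <- if (tab$a == min(sup$x)) 0 else
    exp(solve_log_psi(function(lp) nchg_tail_ge(sup, tab$a, lp) - alpha))
  high <- if (tab$a == max(sup$x)) Inf else
    exp(solve_log_psi(function(lp) nchg_tail_le(sup, tab$a, lp) - alpha))
  c(low, high)
}

#' Gene-burden exact test on carrier counts
#'
#' Assembles the 2x2 carrier table and computes the two-sided Fisher exact
#' P-value, the odds-ratio point estimate (conditional MLE by default, the
#' cross-product sample OR as an option) and its confidence interval. A pure
#' function of the four counts.
#'
#' @param case_carriers,n_cases Carriers and total among cases.
#' @param ctrl_carriers,n_ctrls Carriers and total among controls.
#' @param class_label Qualifying-class label carried into the result.
#' @param or_method Point estimate: `"cmle"` (default) or `"sample"`.
#' @param ci_method,level Passed to [odds_ratio_ci()].
#' @return A list of class `burden_result`: `table`, `p_two_sided`,
#'   `or` (the chosen point estimate), `or_sample`, `or_cmle`, `ci_low`,
#'   `ci_high`, `level`, `class_label`, `or_method`, `ci_method`.
#' @examples
#' burden_test(25, 793, 46, 4523, class_label = "missense")
#' @export
burden_test <- function(case_carriers, n_cases, ctrl_carriers, n_ctrls,
                        class_label = NA_character_,
                        or_method = c("cmle", "sample"),
                        ci_method = c("exact-conditional", "log-woolf"),
                        level = 0.95) {
  or_method <- match.arg(or_method)
  ci_method <- match.arg(ci_method)
  tab <- contingency_table(case_carriers, n_cases, ctrl_carriers, n_ctrls)
  or_s <- odds_ratio_sample(tab)
  or_c <- odds_ratio_cmle(tab)
  ci <- odds_ratio_ci(tab, level = level, method = ci_method)
  out <- list(table = tab,
              p_two_sided = fisher_two_sided(tab),
              or = if (or_method == "cmle") or_c else or_s,
              or_sample = or_s, or_cmle = or_c,
              ci_low = ci[1], ci_high = ci[2], level = level,
              class_label = class_label,
              or_method = or_method, ci_method = ci_method)
  class(out) <- "burden_result"
  out
}

#' @export
print.burden_result <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Carrier burden (%s): %d/%d cases vs %d/%d controls\n",
              ifelse(is.na(x$class_label), "unlabelled", x$class_label),
              tab$a, tab$n1, tab$b, tab$n2))
  cat(sprintf("  OR = %.4g (%s), %d%% CI %.4g - %.4g (%s), P = %.3g\n",
              x$or, x$or_method, round(100 * x$level), x$ci_low, x$ci_high,
              x$ci_method, x$p_two_sided))
  if (!is.null(x$calibrated))
    cat(sprintf("  negative-control verdict: %s (threshold P >= %.2f)\n",
                ifelse(x$calibrated, "calibrated", "NOT calibrated"),
                x$calibration_threshold))
  invisible(x)
}

#' Pool cohorts by summing carrier counts
#'
#' Naive count pooling for the combined-cohort analysis: carriers and totals
#' are summed across cohorts, and the pooled pair feeds [burden_test()]
#' unchanged. When per-cohort sample identifier lists are supplied, an
#' identifier appearing in more than one cohort is an error (double
#' counting), since pooling assumes disjoint cohorts.
#'
#' @param cohorts A list of `c(carriers, total)` pairs (or a 2-column
#'   matrix/data frame with columns carriers, total).
#' @param sample_ids Optional list of per-cohort sample-identifier vectors.
#' @return Named numeric vector `c(carriers, total)`.
#' @examples
#' meta_pool(list(c(4, 793), c(3, 419)))  # 7 / 1212
#' @export
meta_pool <- function(cohorts, sample_ids = NULL) {
  if (is.matrix(cohorts) || is.data.frame(cohorts))
    cohorts <- lapply(seq_len(nrow(cohorts)), function(i) as.numeric(cohorts[i, 1:2]))
  stopifnot(length(cohorts) >= 1L)
  m <- vapply(cohorts, function(x) {
    x <- as.numeric(x)
    if (length(x) != 2L || any(x < 0) || x[1] > x[2])
      stop("each cohort must be a valid (carriers, total) pair")
    x
  }, numeric(2))
  if (!is.null(sample_ids)) {
    all_ids <- unlist(sample_ids)
    dup <- unique(all_ids[duplicated(all_ids)])
    if (length(dup))
      stop("sample identifier(s) shared across cohorts (double counting): ",
           paste(utils::head(dup, 5), collapse = ", "))
  }
  c(carriers = sum(m[1, ]), total = sum(m[2, ]))
}

#' Synonymous-variant negative-control calibration
#'
#' Runs the burden test on rare synonymous carrier counts and attaches a
#' calibration verdict: the cohorts are comparable ("calibrated") when the
#' synonymous burden shows no significant difference (P at or above the
#' threshold). Synonymous variants are not expected to carry disease risk,
#' so a significant synonymous burden flags systematic case-control bias
#' (ancestry, coverage, calling) rather than biology.
#'
#' @inheritParams burden_test
#' @param case_syn_carriers,ctrl_syn_carriers Synonymous carrier counts.
#' @param threshold Verdict threshold on the two-sided P (default 0.05).
#' @return A `burden_result` with extra fields `calibrated` (logical) and
#'   `calibration_threshold`.
#' @examples
#' calibration_synonymous(6, 793, 15, 4523)  # P = 0.11, calibrated
#' @export
calibration_synonymous <- function(case_syn_carriers, n_cases,
                                   ctrl_syn_carriers, n_ctrls,
                                   threshold = 0.05, ...) {
  res <- burden_test(case_syn_carriers, n_cases, ctrl_syn_carriers, n_ctrls,
                     class_label = "synonymous", ...)
  res$calibrated <- res$p_two_sided >= threshold
  res$calibration_threshold <- threshold
  res
}

#' Forest-plot-ready burden table
#'
#' Flattens a list of `burden_result`s into the columns of a forest plot:
#' cohort, class, carrier fractions, OR, confidence limits and P.
#'
#' @param results A named list of `burden_result` objects (names become the
#'   `analysis` column).
#' @return A data frame with one row per result.
#' @export
forest_table <- function(results) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(analysis = if (!is.null(names(results))) names(results)[i] else i,
               class_label = r$class_label,
               n_cases = sprintf("%d/%d", r$table$a, r$table$n1),
               n_controls = sprintf("%d/%d", r$table$b, r$table$n2),
               or = r$or, ci_low = r$ci_low, ci_high = r$ci_high,
               p = r$p_two_sided, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
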