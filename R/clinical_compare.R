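# Reconstruction of baseline-characteristics comparisons from published
# summary rows: pooled-variance Student's t-tests from mean/SD/n, and
# chi-square or Fisher tests from event-count/n pairs. Only summary
# statistics are needed, so a printed table is sufficient input.

#' Continuous-variable group summary
#'
#' @param mean Group mean (row units).
#' @param sd Group standard deviation, > 0.
#' @param n Group size, >= 2.
#' @param label Optional row name.
#' @return A list of class `continuous_summary`.
#' @export
continuous_summary <- function(mean, sd, n, label = NA_character_) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0, n == round(n), n >= 2)
  structure(list(label = label, mean = mean, sd = sd, n = as.integer(n)),
            class = "continuous_summary")
}

#' Categorical-variable group summary (events / group size)
#'
#' @param k Event count, `0 <= k <= n`. For a multi-level variable, a vector
#'   of per-level counts summing to at most `n`.
#' @param n Group size, >= 1.
#' @param label Optional row name.
#' @return A list of class `categorical_summary`.
#' @export
categorical_summary <- function(k, n, label = NA_character_) {
  stopifnot(all(k == round(k)), all(k >= 0), n == round(n), n >= 1, sum(k) <= n)
  structure(list(label = label, k = as.integer(k), n = as.integer(n)),
            class = "categorical_summary")
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' The unpaired Student's t-test reconstructed from per-group mean, SD and n:
#' pooled variance `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`,
#' statistic `t = (m1-m2) / (sp sqrt(1/n1 + 1/n2))` on `n1+n2-2` degrees of
#' freedom, two-sided P. Identical to `t.test(..., var.equal = TRUE)` on raw
#' data with those summaries.
#'
#' @param g1,g2 [continuous_summary()] objects (or `c(mean, sd, n)` vectors).
#' @return A list of class `comparison_result` with `statistic`, `df`,
#'   `p_two_sided`, `method = "pooled-t"`.
#' @examples
#' pooled_t_from_summary(c(19.36, 5.09, 28), c(17.16, 3.69, 621))
#' @export
pooled_t_from_summary <- function(g1, g2) {
  g1 <- as_continuous(g1); g2 <- as_continuous(g2)
  n1 <- g1$n; n2 <- g2$n
  if (n1 + n2 < 3) stop("need n1 + n2 >= 3 for a pooled t-test")
  sp2 <- ((n1 - 1) * g1$sd^2 + (n2 - 1) * g2$sd^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (g1$mean == g2$mean)
      return(comparison_result(0, n1 + n2 - 2L, 1, "pooled-t"))
    stop("zero pooled variance with unequal means: degenerate input")
  }
  t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2L
  comparison_result(t, df, 2 * stats::pt(-abs(t), df), "pooled-t")
}

as_continuous <- function(g) {
  if (inherits(g, "continuous_summary")) return(g)
  g <- as.numeric(g)
  continuous_summary(g[1], g[2], g[3])
}

as_categorical <- function(g) {
  if (inherits(g, "categorical_summary")) return(g)
  g <- as.numeric(g)
  categorical_summary(g[-length(g)], g[length(g)])
}

comparison_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df,
                 p_two_sided = min(1, max(0, p)), method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, P = %.3g\n", x$method, x$statistic,
              if (is.na(x$df)) "" else sprintf(" (df = %s)", x$df),
              x$p_two_sided))
  invisible(x)
}

#' Categorical comparison from event counts
#'
#' Builds the R x 2 contingency table from per-group event counts and applies
#' either the uncorrected Pearson chi-square test or Fisher's exact test.
#' Under `method_rule = "auto"`, the classical expected-count rule is used:
#' chi-square when every expected cell is at least 5, Fisher otherwise. The
#' rule is configurable because published tables do not always follow it;
#' forcing `"chisq"` reproduces tables computed with the uncorrected
#' chi-square throughout. Multi-level rows (vector `k`) are compared with the
#' same machinery on the R x 2 table.
#'
#' @param g1,g2 [categorical_summary()] objects (or `c(k, n)` vectors;
#'   multi-level rows as `c(k1, k2, ..., n)`).
#' @param method_rule `"auto"`, `"chisq"` (uncorrected) or `"fisher"`.
#' @return A `comparison_result`; `method` records the test actually used.
#' @examples
#' categorical_test(c(6, 28), c(3, 82), method_rule = "chisq")   # stroke row
#' categorical_test(c(16, 28), c(439, 621), method_rule = "chisq")
#' @export
categorical_test <- function(g1, g2, method_rule = c("auto", "chisq", "fisher")) {
  method_rule <- match.arg(method_rule)
  g1 <- as_categorical(g1); g2 <- as_categorical(g2)
  if (length(g1$k) != length(g2$k))
    stop("groups must have the same number of event levels")
  # columns = groups; rows = levels (+ remainder row for binary summaries)
  tab <- cbind(c(g1$k, g1$n - sum(g1$k)), c(g2$k, g2$n - sum(g2$k)))
  if (length(g1$k) > 1L && sum(g1$k) == g1$n && sum(g2$k) == g2$n)
    tab <- tab[seq_along(g1$k), , drop = FALSE]  # exhaustive multi-level row
  if (any(rowSums(tab) == 0)) tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L)  # no variation across levels at all
    return(comparison_result(0, NA_integer_, 1, "chi-square"))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_chisq <- switch(method_rule,
                      auto = all(expected >= 5),
                      chisq = TRUE,
                      fisher = FALSE)
  if (use_chisq) {
    if (all(tab[, 1] / sum(tab[, 1]) == tab[, 2] / sum(tab[, 2])))
      return(comparison_result(0, (nrow(tab) - 1L), 1, "chi-square"))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    comparison_result(unname(ct$statistic), unname(ct$parameter),
                      ct$p.value, "chi-square")
  } else {
    ft <- stats::fisher.test(tab)
    comparison_result(NA_real_, NA_integer_, ft$p.value, "fisher-exact")
  }
}

#' Reconstruct a baseline-comparisons table
#'
#' Applies [pooled_t_from_summary()] / [categorical_test()] across the rows
#' of a published-style baseline table for each requested pair of groups,
#' producing one P-value per (row, pair) — the shape of a three-column
#' clinical Table 1 with two pairwise comparison columns.
#'
#' @param rows A list; each element is a list with `label`, `type`
#'   (`"cont"`, `"cat"` or `"multi-cat"`), and `groups`, a named list of
#'   per-group summaries (`c(mean, sd, n)` for `cont`; `c(k, n)` or
#'   `c(k1, ..., n)` for categorical). Rows may carry their own per-group `n`
#'   (missing data make row-level n differ from the column header n).
#' @param group_pairs A list of `c(group1, group2)` name pairs to compare.
#' @param method_rule Categorical rule, see [categorical_test()]; default
#'   `"chisq"` (uncorrected chi-square throughout, the convention that
#'   reproduces published clinical baseline tables).
#' @return A data frame: `label`, `type`, `pair`, `method`, `statistic`,
#'   `p`. Rows lacking a summary for a requested group are skipped with a
#'   warning.
#' @export
compare_baseline <- function(rows, group_pairs,
                             method_rule = c("chisq", "auto", "fisher")) {
  method_rule <- match.arg(method_rule)
  out <- list()
  for (row in rows) {
    for (pair in group_pairs) {
      pair_id <- paste(pair, collapse = " vs ")
      if (!all(pair %in% names(row$groups))) {
        warning("row ", sQuote(row$label), ": no summary for pair ", pair_id,
                "; skipped", call. = FALSE)
        next
      }
      g1 <- row$groups[[pair[1]]]; g2 <- row$groups[[pair[2]]]
      res <- if (identical(row$type, "cont"))
        pooled_t_from_summary(g1, g2)
      else
        categorical_test(g1, g2, method_rule = method_rule)
      out[[length(out) + 1L]] <- data.frame(
        label = row$label, type = row$type, pair = pair_id,
        method = res$method, statistic = res$statistic, p = res$p_two_sided,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(label = character(0), type = character(0),
                      pair = character(0), method = character(0),
                      statistic = numeric(0), p = numeric(0)))
  do.call(rbind, out)
}
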