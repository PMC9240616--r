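# Qualifying-variant selection: rarity filter across reference
# subpopulations, deleteriousness intersection for missense variants, and
# collapsing to per-individual carrier status.

QUALIFYING_CLASSES <- c("truncating", "missense", "deleterious_missense",
                        "synonymous")

#' Filtering configuration
#'
#' Thresholds and missing-data policies for qualifying-variant selection.
#' A variant is rare when its allele frequency is strictly below
#' `maf_threshold` in every reference subpopulation where it is observed;
#' a missense variant is deleterious when both its REVEL and VEST3 scores
#' reach their thresholds.
#'
#' @param maf_threshold Rarity cutoff, strict `<`; default `1e-4`.
#' @param revel_threshold,vest3_threshold Deleteriousness cutoffs in [0, 1]
#'   (`>=`); defaults 0.5. The score cutoffs are deliberately configurable:
#'   they are conventional midpoints, not published constants.
#' @param missing_af_policy What to do with a variant absent from every
#'   frequency resource: `"treat-as-rare"` (default; novel variants count as
#'   rare) or `"exclude"`.
#' @param missing_score_policy What to do with a missense variant lacking a
#'   score: `"not-deleterious"` (default) or `"exclude"` (same effect for the
#'   deleterious intersection).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 1e-4,
                          revel_threshold = 0.5,
                          vest3_threshold = 0.5,
                          missing_af_policy = c("treat-as-rare", "exclude"),
                          missing_score_policy = c("not-deleterious", "exclude")) {
  stopifnot(is.numeric(maf_threshold), length(maf_threshold) == 1L,
            maf_threshold > 0, maf_threshold <= 0.5,
            revel_threshold >= 0, revel_threshold <= 1,
            vest3_threshold >= 0, vest3_threshold <= 1)
  cfg <- list(maf_threshold = maf_threshold,
              revel_threshold = revel_threshold,
              vest3_threshold = vest3_threshold,
              missing_af_policy = match.arg(missing_af_policy),
              missing_score_policy = match.arg(missing_score_policy))
  class(cfg) <- "filter_config"
  cfg
}

#' Rarity test across reference subpopulations
#'
#' TRUE iff every observed subpopulation allele frequency is strictly below
#' the threshold. A variant absent from all resources (all `NA` or an empty
#' mapping) follows `missing_af_policy`: treat-as-rare keeps it (novel
#' variants are rare by definition), exclude drops it.
#'
#' @param subpop_af Numeric vector (possibly named by subpopulation) of
#'   allele frequencies in [0, 1]; `NA` = not observed in that resource.
#' @param maf_threshold Strict upper bound on every frequency.
#' @param missing_af_policy `"treat-as-rare"` or `"exclude"`.
#' @return Logical scalar.
#' @examples
#' is_rare(c(EAS = 0, NFE = 0))                  # TRUE
#' is_rare(c(EAS = 2e-4, NFE = 0))               # FALSE
#' is_rare(c(EAS = 1e-4), maf_threshold = 1e-4)  # FALSE (strict boundary)
#' @export
is_rare <- function(subpop_af, maf_threshold = 1e-4,
                    missing_af_policy = c("treat-as-rare", "exclude")) {
  missing_af_policy <- match.arg(missing_af_policy)
  af <- as.numeric(subpop_af)
  af <- af[!is.na(af)]
  if (any(af < 0 | af > 1)) stop("allele frequencies must lie in [0,1]")
  if (length(af) == 0L) return(missing_af_policy == "treat-as-rare")
  all(af < maf_threshold)
}

#' Deleteriousness intersection for a missense variant
#'
#' TRUE iff the REVEL score and the VEST3 score both reach their thresholds
#' (the intersection of the two predictors minimizes false-positive
#' deleterious calls). A missing score follows `missing_score_policy`
#' (default: not deleterious).
#'
#' @param revel,vest3 Scores in [0, 1], `NA` when absent.
#' @param config A [filter_config()].
#' @return Logical scalar.
#' @export
is_deleterious_missense <- function(revel, vest3, config = filter_config()) {
  for (s in list(revel, vest3))
    if (!is.na(s) && (s < 0 || s > 1)) stop("scores must lie in [0,1]")
  if (is.na(revel) || is.na(vest3)) {
    # both policies make an unscored variant non-deleterious for the
    # intersection; "exclude" exists for symmetry with the AF policy
    return(FALSE)
  }
  revel >= config$revel_threshold && vest3 >= config$vest3_threshold
}

#' Select qualifying variants for one analysis class
#'
#' Filters a [variant_table()] to the variants of gene `gene` that qualify
#' for the requested burden class: the class's consequence categories
#' intersected with the rarity filter, and, for `deleterious_missense`, the
#' REVEL & VEST3 intersection. Inframe indels and `OTHER` consequences never
#' qualify for any burden class.
#'
#' @param variants A `variant_table` (normalized, classified).
#' @param gene Gene symbol.
#' @param class_label One of `"truncating"`, `"missense"`,
#'   `"deleterious_missense"`, `"synonymous"`.
#' @param config A [filter_config()].
#' @param n_samples Cohort size (used for the carrier proportion); optional.
#' @return A list of class `qualifying_set` with elements `gene`,
#'   `class_label`, `variants` (the qualifying rows), `carrier_count`
#'   (distinct carriers across the qualifying variants, from the `carriers`
#'   column), and `n_samples`.
#' @export
select_qualifying <- function(variants, gene, class_label,
                              config = filter_config(), n_samples = NA_integer_) {
  if (!class_label %in% QUALIFYING_CLASSES)
    stop("unknown class_label ", sQuote(class_label), "; expected one of ",
         paste(QUALIFYING_CLASSES, collapse = ", "))
  validate_variants(variants)
  target_class <- switch(class_label,
                         truncating = "TRUNCATING",
                         missense = "MISSENSE",
                         deleterious_missense = "MISSENSE",
                         synonymous = "SYNONYMOUS")
  keep <- variants$gene == gene & variants$class == target_class
  afc <- af_columns(variants)
  if (any(keep)) {
    rare <- vapply(which(keep), function(i) {
      is_rare(unlist(variants[i, afc, drop = FALSE]),
              config$maf_threshold, config$missing_af_policy)
    }, logical(1))
    keep[keep] <- rare
  }
  if (class_label == "deleterious_missense" && any(keep)) {
    del <- vapply(which(keep), function(i) {
      is_deleterious_missense(variants$revel[i], variants$vest3[i], config)
    }, logical(1))
    keep[keep] <- del
  }
  qual <- variants[keep, , drop = FALSE]
  carriers <- unique(unlist(qual$carriers))
  out <- list(gene = gene, class_label = class_label, variants = qual,
              carrier_count = length(carriers),
              carrier_ids = carriers,
              n_samples = as.integer(n_samples))
  class(out) <- "qualifying_set"
  out
}

#' @export
print.qualifying_set <- function(x, ...) {
  cat(sprintf("Qualifying set: %s / %s\n", x$gene, x$class_label))
  cat(sprintf("  %d variant(s), %d distinct carrier(s)", nrow(x$variants),
              x$carrier_count))
  if (!is.na(x$n_samples)) cat(sprintf(" of %d samples", x$n_samples))
  cat("\n")
  invisible(x)
}

#' Count distinct carriers of a qualifying set
#'
#' Collapses genotypes to the individual level: the number of distinct
#' samples carrying at least one alternate allele at at least one qualifying
#' variant. An individual carrying several qualifying variants counts once.
#'
#' @param qualifying A `qualifying_set` from [select_qualifying()].
#' @param roster Character vector of all sample identifiers in the cohort.
#'   Every carrier must appear on the roster; a carrier off the roster is a
#'   consistency error, not silently dropped.
#' @return Non-negative integer carrier count.
#' @export
count_carriers <- function(qualifying, roster) {
  carriers <- unique(unlist(qualifying$variants$carriers))
  stray <- setdiff(carriers, roster)
  if (length(stray))
    stop("carrier sample(s) absent from the cohort roster: ",
         paste(utils::head(stray, 5), collapse = ", "))
  length(carriers)
}
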