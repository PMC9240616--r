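---
title: "Methods: exact carrier-collapsing burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact carrier-collapsing burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneburden)
```

## The model

The collapsing burden test treats a gene, within one variant class, as a
single binary exposure. Let $a$ of $n_1$ cases and $b$ of $n_2$ controls
carry at least one qualifying variant. Under the null hypothesis of no
association, and conditioning on both margins of the 2×2 table, the
case-carrier count $X$ follows the hypergeometric distribution; under an
odds ratio $\psi \ne 1$ it follows Fisher's noncentral hypergeometric
distribution

$$\Pr(X = x \mid \psi) \;=\;
\frac{\binom{n_1}{x}\binom{n_2}{m-x}\,\psi^x}
     {\sum_u \binom{n_1}{u}\binom{n_2}{m-u}\,\psi^u},
\qquad m = a + b .$$

Everything the package reports about a table is a functional of this
distribution:

* `fisher_two_sided()` — the two-sided exact P by the minimum-likelihood
  rule: the sum of $\Pr(X = u \mid \psi = 1)$ over all $u$ whose point
  probability does not exceed the observed one. This is the convention of
  mainstream statistical software; the alternatives (doubling the smaller
  tail, the central rule) give systematically different values for
  asymmetric margins.
* `odds_ratio_cmle()` — the conditional MLE, the root of
  $\mathbb{E}[X \mid \psi] = a$.
* `odds_ratio_ci()` — exact conditional limits: the lower limit solves
  $\Pr(X \ge a \mid \psi) = \alpha/2$ and the upper limit
  $\Pr(X \le a \mid \psi) = \alpha/2$.
* `odds_ratio_sample()` — the unconditional cross-product estimate,
  available because some published tables report it.

**Assumptions.** Individuals are independent; carrier status is correctly
ascertained on both sides (comparable sequencing depth, calling and
annotation between cases and the reference controls — exactly what the
synonymous negative control probes); cohorts pooled by `meta_pool()` are
disjoint (the function refuses shared sample identifiers when identifier
lists are available). Conditioning on both margins makes the inference
exact at any cell count, at the price of conservatism — relevant here,
where a typical table has single-digit carrier cells.

## Qualifying variants

`classify_consequence()` maps annotation tokens (Sequence-Ontology and
ANNOVAR spellings) deterministically onto five classes. Only canonical
splice acceptor/donor annotations count as truncating; extended
splice-region tokens map to `OTHER`, because their loss-of-function status
is not established. Inframe indels form their own class and never qualify
for burden testing: their pathogenicity is hard to ascertain, and silently
folding them into missense or truncating classes would contaminate both.
Unknown tokens are an error, never a silent `OTHER`: a typo in an
annotation pipeline should fail loudly.

`filter_config()` holds the tunable thresholds:

| parameter | default | meaning |
|---|---|---|
| `maf_threshold` | $10^{-4}$ | strict `<` bound on the allele frequency in **every** reference subpopulation |
| `revel_threshold`, `vest3_threshold` | 0.5 | a missense variant is deleterious only if **both** scores reach their cutoff |
| `missing_af_policy` | treat-as-rare | a variant absent from every frequency resource is novel, hence rare |
| `missing_score_policy` | not-deleterious | an unscored missense variant cannot enter the deleterious class |

The score cutoffs are conventional midpoints, not published constants, so
they are configurable; analyses whose conclusions depend on the exact
cutoff should report a sensitivity range. The rarity bound is strict
because the class definition is "frequency below the threshold", and a
boundary value in any one subpopulation disqualifies the variant.

Carrier collapsing (`count_carriers()`) counts distinct individuals with at
least one alternate allele at at least one qualifying variant; zygosity is
not distinguished, and a carrier identifier absent from the cohort roster
is a consistency error rather than a dropped record.

## Numerical choices

All noncentral-hypergeometric computations work on log-scale weights
normalized by their maximum, so tables with large margins (thousands of
controls) neither overflow nor underflow. The CMLE and the CI limits are
found by `uniroot()` on $\log\psi$ with a bracket that doubles until it
straddles the root and a tolerance of $10^{-12}$; the tail functions are
monotone in $\psi$, so the root is unique. This precision matters: a bound
found with a loose inversion tolerance can shift in its second decimal,
which is visible when confidence limits are reported to two decimals. The
minimum-likelihood comparison in the P-value uses a relative guard of
$1+10^{-7}$ so outcomes with equal point probability are not split by
floating-point noise.

Degenerate tables are signalled, not crashed on: $a = b = 0$ yields an
`NaN` odds ratio and P = 1; a zero cell yields a one-sided exact limit
(0 or $\infty$) with the other limit finite; the log-Woolf interval simply
refuses empty cells.

The point estimate defaults to the conditional MLE rather than the
cross-product, for internal consistency: it maximizes the same conditional
likelihood whose tails define the exact interval, so estimate and interval
can never disagree about direction. The two differ only in the third
significant figure for the tables this package targets, but reported
decimals should be reproducible from the stated method.

## Clinical baseline reconstruction

`pooled_t_from_summary()` implements the pooled-variance (Student) t-test
— not Welch — because published baseline tables that state "unpaired
Student's t-test" are reproducible only under equal-variance pooling, and
because the summary rows carry no information to support anything richer.
`categorical_test()` builds the $R \times 2$ event table and applies the
uncorrected Pearson chi-square or Fisher's exact test. The classical
expected-count rule (chi-square only when all expected cells are at least
5) is available as `method_rule = "auto"`, but `compare_baseline()`
defaults to `"chisq"`: published clinical tables are, in practice,
computed with the uncorrected chi-square across the board, small cells
included, and reproducing a printed table requires following that
convention rather than the textbook rule. Both behaviours are exposed and
the method actually used is recorded in every result.

Each row carries its own per-group $n$: missing data make row-level
denominators differ from the column-header cohort sizes, and percentages
in published tables are the way to recover them.

## The synthetic-cohort generator

`sim_config()` defaults define the reference study conditions: 793 cases
versus 4,523 controls; control carrier probabilities 4/4523 (truncating),
46/4523 (missense) and 15/4523 (synonymous); enrichment odds ratios 5.73
and 3.17 for truncating and missense and 1 for the null synonymous class;
and 3/22/6 sites per class. Enrichment is injected at the carrier level —
each case is a carrier of class $c$ with probability
$p_1 = \psi p_0 / (1 - p_0 + \psi p_0)$ — because the collapsing statistic
observes only carrier status; carriers are then attached to concrete sites
uniformly. Allele frequencies follow a beta distribution scaled to
$(0, 10^{-4})$, with configurable fractions of common sites (to exercise
the rarity filter) and of novel sites (absent from all resources); missense
scores are drawn from disjoint "deleterious" and "benign" uniform ranges so
that the deleterious call is invariant to any threshold between the ranges.

One master seed expands into named per-stage child seeds (sites, carriers,
clinical, replicates) drawn from the master-seeded stream, so each stage is
independently reproducible.

What the generator does **not** emulate: linkage and haplotype structure,
per-site allele-frequency-dependent carrier probabilities, sequencing or
calling error, relatedness, and population stratification beyond what the
synonymous control would catch. Passing tests therefore demonstrate that
the inference chain is correct and calibrated under the stated sampling
model — not that any particular real dataset satisfies that model.

## Validation experiments

`recovery_experiment()` repeatedly simulates cohorts, runs the full
filter → collapse → burden pipeline, and reports the mean estimated
log-odds-ratio, empirical CI coverage, and the rejection rate. The shipped
test suite runs 1,000 replicates under the null (type-I error, expected
conservative: observed rejection well below 0.05) and 600–700 replicates
at odds ratios 5 and 8 (coverage at or above the nominal 95% up to
simulation noise); those sizes give Monte-Carlo standard errors below one
percentage point on the quantities checked while keeping the suite quick
to run. The exactness of the P-value itself is checked against full
hypergeometric enumeration over every table with group sizes up to 12, and
the CI limits against an independent bisection oracle.

## Limitations

* The burden framework detects aggregate enrichment only; it has no power
  against bidirectional effects within a class and does not rank
  individual variants (no SKAT-style variance-component alternative is
  provided).
* Count-level control data preclude any covariate adjustment; the
  synonymous calibration is the only bias check available.
* Confidence-interval coverage of the exact method is conservative, so
  intervals are wide at single-digit counts; that is inherent to exact
  conditional inference, not a defect of the implementation.
* The consequence vocabulary is a fixed mapping table; annotations from
  tools with other spellings must be added to it (or pre-normalized)
  before classification.
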