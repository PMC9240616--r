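# Fixtures built in code: a discovery-cohort-like variant table (31 rare
# variants: 6 synonymous, 22 missense of which 3 deleterious, 1 frameshift
# insertion and 2 stop-gained; 6 / 25 / 4 distinct carriers among 793, the
# recurrent stop-gained site carried twice), plus small random tables for
# property checks.

study_roster <- function(n = 793) sprintf("case_%05d", seq_len(n))

make_study_fixture <- function() {
  roster <- study_roster()
  syn_carriers <- as.list(roster[1:6])                      # 6 carriers
  # 19 benign missense: 16 single-carrier + 3 double-carrier = 22 carriers;
  # 3 deleterious missense: single-carrier = 3 carriers; 25 in total
  benign_carriers <- c(as.list(roster[7:22]),
                       list(roster[23:24], roster[25:26], roster[27:28]))
  del_carriers <- as.list(roster[29:31])
  # truncating: frameshift (1) + stop-gained (1) + recurrent stop-gained (2)
  trunc_carriers <- list(roster[32], roster[33], roster[34:35])
  revel <- c(runif(19, 0.05, 0.35), runif(3, 0.75, 0.95))
  vest3 <- c(runif(19, 0.05, 0.35), runif(3, 0.75, 0.95))
  n_all <- 6 + 22 + 3
  af <- t(replicate(n_all, {
    v <- runif(5, 0, 9e-5)
    v[runif(5) < 0.4] <- NA
    v
  }))
  colnames(af) <- paste0("af_", c("afr", "amr", "eas", "nfe", "sas"))
  variant_table(
    chrom = "15", pos = 85000000 + seq_len(n_all) * 50,
    ref = "C", alt = "T", gene = "ALPK3", transcript = "NM_020778.5",
    consequence = c(rep("synonymous SNV", 6),
                    rep("nonsynonymous SNV", 22),
                    "frameshift insertion", "stop_gained", "stop_gained"),
    af = as.data.frame(af),
    revel = c(rep(NA, 6), revel, rep(NA, 3)),
    vest3 = c(rep(NA, 6), vest3, rep(NA, 3)),
    carriers = c(syn_carriers, benign_carriers, del_carriers, trunc_carriers))
}

# Independent carrier-count oracle: union of carrier id sets.
oracle_count_carriers <- function(variants) {
  ids <- character(0)
  for (i in seq_len(nrow(variants))) ids <- union(ids, variants$carriers[[i]])
  length(ids)
}

# Random small contingency table.
random_table <- function() {
  n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
  contingency_table(sample(0:n1, 1), n1, sample(0:n2, 1), n2)
}
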