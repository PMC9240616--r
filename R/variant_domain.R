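# Analysis classes used throughout the package.
CONSEQUENCE_CLASSES <- c("TRUNCATING", "MISSENSE", "SYNONYMOUS", "INFRAME_INDEL", "OTHER")

#' Consequence-token vocabulary
#'
#' The mapping from annotation consequence tokens to the analysis classes used
#' by the burden pipeline. Both Sequence-Ontology-style (`stop_gained`,
#' `missense_variant`, `splice_acceptor_variant`) and ANNOVAR-style
#' (`stopgain`, `nonsynonymous SNV`, `frameshift insertion`) spellings are
#' covered. Tokens are matched case-insensitively after collapsing spaces,
#' hyphens and underscores.
#'
#' Truncating means frameshift, stop-gained, or canonical splice
#' acceptor/donor; only the canonical +/-1,2 splice-site annotations count —
#' extended splice-region tokens map to `OTHER`. Inframe (non-frameshift)
#' insertions and deletions form their own class because their pathogenicity
#' is hard to ascertain and they are excluded from burden classes.
#'
#' @return A data frame with columns `token` (normalized spelling) and
#'   `class` (one of `TRUNCATING`, `MISSENSE`, `SYNONYMOUS`, `INFRAME_INDEL`,
#'   `OTHER`).
#' @examples
#' head(consequence_vocabulary())
#' @export
consequence_vocabulary <- function() {
  vocab <- c(
    # truncating
    stop_gained = "TRUNCATING", stopgain = "TRUNCATING",
    stopgain_snv = "TRUNCATING",
    frameshift_insertion = "TRUNCATING", frameshift_deletion = "TRUNCATING",
    frameshift_variant = "TRUNCATING", frameshift_substitution = "TRUNCATING",
    frameshift_block_substitution = "TRUNCATING",
    splice_acceptor = "TRUNCATING", splice_acceptor_variant = "TRUNCATING",
    splice_donor = "TRUNCATING", splice_donor_variant = "TRUNCATING",
    splicing = "TRUNCATING",
    # missense
    missense = "MISSENSE", missense_variant = "MISSENSE",
    nonsynonymous_snv = "MISSENSE", nonsynonymous = "MISSENSE",
    # synonymous
    synonymous = "SYNONYMOUS", synonymous_variant = "SYNONYMOUS",
    synonymous_snv = "SYNONYMOUS",
    # inframe indel
    inframe_insertion = "INFRAME_INDEL", inframe_deletion = "INFRAME_INDEL",
    nonframeshift_insertion = "INFRAME_INDEL",
    nonframeshift_deletion = "INFRAME_INDEL",
    nonframeshift_substitution = "INFRAME_INDEL",
    nonframeshift_block_substitution = "INFRAME_INDEL",
    # documented "other" tokens: consumed but never qualifying
    splice_region_variant = "OTHER", intron_variant = "OTHER",
    intronic = "OTHER", utr3 = "OTHER", utr5 = "OTHER",
    x3_prime_utr_variant = "OTHER", x5_prime_utr_variant = "OTHER",
    stop_lost = "OTHER", stoploss = "OTHER", start_lost = "OTHER",
    startloss = "OTHER", stop_retained_variant = "OTHER",
    upstream_gene_variant = "OTHER", downstream_gene_variant = "OTHER",
    upstream = "OTHER", downstream = "OTHER",
    intergenic = "OTHER", intergenic_variant = "OTHER",
    ncrna_exonic = "OTHER", unknown = "OTHER"
  )
  data.frame(token = names(vocab), class = unname(vocab),
             stringsAsFactors = FALSE)
}

# Collapse a raw consequence token to the vocabulary's canonical spelling:
# lower case, runs of spaces/hyphens/underscores -> single underscore, and a
# leading digit prefixed with "x" (for 3'/5' UTR SO terms).
normalize_token <- function(raw) {
  tok <- tolower(trimws(raw))
  tok <- gsub("[ _\\-]+", "_", tok)
  tok <- sub("^([0-9])", "x\\1", tok)
  tok
}

#' Classify a consequence token into an analysis class
#'
#' Deterministic, case-insensitive mapping of annotation tokens to the classes
#' `TRUNCATING` (frameshift, stop-gained, canonical splice acceptor/donor),
#' `MISSENSE`, `SYNONYMOUS`, `INFRAME_INDEL`, or `OTHER`. Tokens outside the
#' shipped vocabulary ([consequence_vocabulary()]) raise an error naming the
#' token rather than silently falling through to `OTHER`.
#'
#' @param raw_consequence Character vector of consequence tokens (e.g.
#'   `"stop_gained"`, `"nonsynonymous SNV"`, `"frameshift insertion"`).
#' @return Character vector of classes, same length as the input.
#' @examples
#' classify_consequence(c("stop_gained", "synonymous SNV", "nonframeshift deletion"))
#' @export
classify_consequence <- function(raw_consequence) {
  if (length(raw_consequence) == 0L) return(character(0))
  if (!is.character(raw_consequence) || anyNA(raw_consequence) ||
      any(!nzchar(trimws(raw_consequence)))) {
    stop("raw_consequence must be non-empty, non-missing character tokens")
  }
  vocab <- consequence_vocabulary()
  idx <- match(normalize_token(raw_consequence), vocab$token)
  if (anyNA(idx)) {
    bad <- unique(raw_consequence[is.na(idx)])
    stop("unknown consequence token(s): ", paste(sQuote(bad), collapse = ", "),
         "; see consequence_vocabulary() for the accepted spellings")
  }
  vocab$class[idx]
}

#' Normalize variant coordinates
#'
#' Trims bases shared between the reference and alternate alleles and
#' left-aligns the position accordingly (VCF-style 1-based, fully closed
#' coordinates): shared leading bases are removed first, advancing `pos`, then
#' shared trailing bases are removed while both alleles retain at least one
#' base. SNVs are returned unchanged, and the operation is idempotent.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position (>= 1).
#' @param ref,alt Non-empty allele strings; must differ.
#' @return A list with elements `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant(1, 100, "CAG", "CG")  # -> pos 101, AG/G
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  stopifnot(length(pos) == 1L, !is.na(pos), pos >= 1L,
            is.character(ref) || is.character(alt) || TRUE)
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (!nzchar(ref) || !nzchar(alt)) stop("alleles must be non-empty strings")
  if (ref == alt) stop("ref and alt are identical at ", chrom, ":", pos,
                       " (not a variant)")
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # leading trim, advancing pos; keep at least one base on each side
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  # trailing trim with the same one-base guard
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  list(chrom = chrom, pos = pos,
       ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Construct a table of annotated variant records
#'
#' Builds the package's canonical per-variant-allele table: one row per
#' biallelic variant with its gene, transcript, raw consequence token, derived
#' analysis class, per-subpopulation allele frequencies (columns prefixed
#' `af_`), in-silico pathogenicity scores (`revel`, `vest3`, `NA` when
#' absent), and an optional list-column `carriers` of sample identifiers
#' carrying at least one alternate allele. Coordinates are normalized and
#' consequences classified on construction; invariants (positions >= 1,
#' frequencies and scores in [0, 1]) are enforced.
#'
#' @param chrom,pos,ref,alt Coordinate fields (recycled to a common length).
#' @param gene,transcript Gene symbol and transcript identifier.
#' @param consequence Raw consequence tokens (see [classify_consequence()]).
#' @param af Data frame or named list of per-subpopulation allele-frequency
#'   vectors in [0, 1]; `NA` means the variant is absent from that resource.
#' @param revel,vest3 Pathogenicity scores in [0, 1], `NA` when unavailable.
#' @param carriers Optional list of character vectors of carrier sample IDs.
#' @return A `data.frame` of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, gene, transcript = NA_character_,
                          consequence, af = NULL, revel = NA_real_,
                          vest3 = NA_real_, carriers = NULL) {
  n <- max(length(chrom), length(pos), length(ref), length(alt),
           length(gene), length(consequence))
  norm <- mapply(normalize_variant, rep_len(chrom, n), rep_len(pos, n),
                 rep_len(ref, n), rep_len(alt, n), SIMPLIFY = FALSE)
  df <- data.frame(
    chrom = vapply(norm, function(x) as.character(x$chrom), character(1)),
    pos = vapply(norm, function(x) x$pos, integer(1)),
    ref = vapply(norm, function(x) x$ref, character(1)),
    alt = vapply(norm, function(x) x$alt, character(1)),
    gene = rep_len(as.character(gene), n),
    transcript = rep_len(as.character(transcript), n),
    consequence = rep_len(as.character(consequence), n),
    stringsAsFactors = FALSE
  )
  df$class <- classify_consequence(df$consequence)
  if (!is.null(af)) {
    af <- as.data.frame(af, stringsAsFactors = FALSE)
    if (nrow(af) != n) stop("af must have one row per variant")
    bad <- vapply(af, function(v) any(!is.na(v) & (v < 0 | v > 1)), logical(1))
    if (any(bad)) stop("allele frequencies outside [0,1] in subpopulation(s): ",
                       paste(names(af)[bad], collapse = ", "))
    names(af) <- ifelse(grepl("^af_", names(af)), names(af),
                        paste0("af_", tolower(names(af))))
    df <- cbind(df, af)
  }
  for (sc in c("revel", "vest3")) {
    v <- rep_len(as.numeric(get(sc)), n)
    if (any(!is.na(v) & (v < 0 | v > 1))) stop(sc, " scores must lie in [0,1]")
    df[[sc]] <- v
  }
  if (!is.null(carriers)) {
    stopifnot(is.list(carriers), length(carriers) == n)
    df$carriers <- I(lapply(carriers, as.character))
  } else {
    df$carriers <- I(rep(list(character(0)), n))
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

# Names of the subpopulation allele-frequency columns of a variant table.
af_columns <- function(variants) grep("^af_", names(variants), value = TRUE)

#' Validate a variant table
#'
#' Checks the domain invariants of a [variant_table()]: positions >= 1,
#' non-empty differing alleles, frequencies and scores in [0, 1], exactly one
#' analysis class per row. Returns the table invisibly or raises an error
#' naming the first offending row.
#'
#' @param variants A `variant_table` (or plain data frame in that dialect).
#' @export
validate_variants <- function(variants) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "class")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(variants) == 0L) return(invisible(variants))
  if (any(variants$pos < 1)) stop("row ", which(variants$pos < 1)[1], ": pos < 1")
  if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt)))
    stop("empty allele string")
  same <- variants$ref == variants$alt
  if (any(same)) stop("row ", which(same)[1], ": ref == alt")
  for (col in c(af_columns(variants), intersect(c("revel", "vest3"), names(variants)))) {
    v <- variants[[col]]
    bad <- !is.na(v) & (v < 0 | v > 1)
    if (any(bad)) stop("row ", which(bad)[1], ": ", col, " outside [0,1]")
  }
  if (any(!variants$class %in% CONSEQUENCE_CLASSES))
    stop("unrecognized analysis class")
  invisible(variants)
}
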