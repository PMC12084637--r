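#' Find directly adjacent polarized variant pairs
#'
#' Scans the (position-sorted) polarized variants and emits every
#' same-chromosome pair at distance exactly 1. SDM analysis needs haplotype
#' phase: by default an unphased heterozygous genotype at a pair site is an
#' error; `unphased = "drop"` instead drops the offending pairs.
#'
#' @param pv a `polarized_variants` object.
#' @param unphased `"error"` (default) or `"drop"`.
#' @return data.frame with columns `i`, `j` (row indices of the left and
#'   right site in `pv$variants`), `chrom`, `pos` (left position).
#' @export
find_adjacent_pairs <- function(pv, unphased = c("error", "drop")) {
  unphased <- match.arg(unphased)
  v <- pv$variants
  ord <- order(v$chrom, v$pos)
  adj <- which(v$chrom[ord][-1] == v$chrom[ord][-length(ord)] &
                 diff(v$pos[ord]) == 1L)
  pairs <- data.frame(i = ord[adj], j = ord[adj + 1L],
                      chrom = v$chrom[ord][adj], pos = v$pos[ord][adj],
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(pairs)
  # a het genotype with unknown phase makes co-carriage ambiguous
  het <- function(idx) pv$hapA[idx, , drop = FALSE] != pv$hapB[idx, , drop = FALSE]
  bad <- (het(pairs$i) & !pv$phased[pairs$i, , drop = FALSE]) |
    (het(pairs$j) & !pv$phased[pairs$j, , drop = FALSE])
  bad[is.na(bad)] <- FALSE
  flag <- rowSums(bad) > 0
  if (any(flag)) {
    if (unphased == "error")
      stop(sum(flag), " adjacent pair(s) involve unphased heterozygous ",
           "genotypes; phase the VCF or use unphased = \"drop\"")
    pairs <- pairs[!flag, , drop = FALSE]
  }
  pairs
}

# logical matrices of per-haplotype derived carriage for one variant row
carriage <- function(pv, idx) {
  d <- derived_index(pv)[idx]
  c(pv$hapA[idx, ] == d, pv$hapB[idx, ] == d)
}

#' Classify adjacent pairs as MNP or SDM
#'
#' A pair is an MNP (multi-nucleotide polymorphism, one mutational event)
#' when the two derived alleles sit on identical haplotype sets; otherwise it
#' is an SDM (two sequential events), ordered by derived allele frequency:
#' the higher-DAF site mutated first. An exact DAF tie with non-identical
#' carriage leaves the order `"unresolved"`. Haplotypes missing at either
#' site are dropped from the carriage comparison.
#'
#' @param pv a `polarized_variants` object.
#' @param pairs data.frame from [find_adjacent_pairs()].
#' @return `pairs` with added columns `class` (`"SDM"`/`"MNP"`), `order`
#'   (`"left_first"`, `"right_first"`, `"unresolved"`, `NA` for MNPs),
#'   `daf_left`, `daf_right`.
#' @export
classify_pairs <- function(pv, pairs) {
  n <- nrow(pairs)
  cls <- character(n); ord <- rep(NA_character_, n)
  for (p in seq_len(n)) {
    c1 <- carriage(pv, pairs$i[p])
    c2 <- carriage(pv, pairs$j[p])
    obs <- !is.na(c1) & !is.na(c2)
    if (identical(c1[obs], c2[obs])) {
      cls[p] <- "MNP"
    } else {
      cls[p] <- "SDM"
      d1 <- pv$variants$daf[pairs$i[p]]
      d2 <- pv$variants$daf[pairs$j[p]]
      ord[p] <- if (d1 > d2) "left_first" else if (d2 > d1) "right_first"
      else "unresolved"
    }
  }
  pairs$class <- cls
  pairs$order <- ord
  pairs$daf_left <- pv$variants$daf[pairs$i]
  pairs$daf_right <- pv$variants$daf[pairs$j]
  pairs
}

#' SDM channel label for a classified pair
#'
#' Builds the mutational path ancestral dinucleotide -> intermediate (first
#' change applied) -> derived dinucleotide and renders it `"CA>TA>TG"`-style.
#' Pairs with unresolved order use `"*"` for the intermediate. Each label is
#' canonicalised against its reverse-complement path (same events read on the
#' other strand): the lexicographically smaller label is kept, so every
#' physical event maps to exactly one channel.
#'
#' @param anc ancestral dinucleotide (left base, right base).
#' @param der derived dinucleotide.
#' @param order `"left_first"`, `"right_first"` or `"unresolved"`.
#' @return character channel label.
#' @export
sdm_label <- function(anc, der, order) {
  mid <- switch(order,
    left_first = paste0(substr(der, 1, 1), substr(anc, 2, 2)),
    right_first = paste0(substr(anc, 1, 1), substr(der, 2, 2)),
    unresolved = "*")
  fwd <- paste0(anc, ">", mid, ">", der)
  rc_mid <- if (mid == "*") "*" else revcomp(mid)
  rev <- paste0(revcomp(anc), ">", rc_mid, ">", revcomp(der))
  if (rev < fwd) rev else fwd
}

#' SDM types for classified pairs
#'
#' @param pv a `polarized_variants` object.
#' @param pairs classified pairs from [classify_pairs()].
#' @param ancestral ancestral genome (source of the ancestral dinucleotide).
#' @return character vector of labels; `NA` for MNP-classified pairs and for
#'   pairs whose ancestral dinucleotide is not fully defined.
#' @export
sdm_types <- function(pv, pairs, ancestral) {
  n <- nrow(pairs)
  out <- rep(NA_character_, n)
  for (p in seq_len(n)) {
    if (pairs$class[p] != "SDM") next
    chrom <- pairs$chrom[p]
    anc <- paste0(pv$variants$ancestral[pairs$i[p]],
                  pv$variants$ancestral[pairs$j[p]])
    der <- paste0(pv$variants$derived[pairs$i[p]],
                  pv$variants$derived[pairs$j[p]])
    if (grepl("[^ACGT]", anc) || grepl("[^ACGT]", der)) next
    out[p] <- sdm_label(anc, der, pairs$order[p])
  }
  out
}

#' Count per-sample SDM spectra
#'
#' For every SDM-classified adjacent pair, a sample's cell for the pair's
#' channel increases by the number of that sample's haplotypes carrying both
#' derived alleles. MNP-classified pairs are excluded (single events, not
#' sequential mutations); they remain visible in the pair classification
#' table. Haplotypes missing at either site contribute 0.
#'
#' @param pv a `polarized_variants` object.
#' @param ancestral ancestral genome.
#' @param pairs optional pre-classified pairs (computed when `NULL`).
#' @param unphased passed to [find_adjacent_pairs()] when pairs are computed.
#' @return numeric matrix (samples x observed SDM channels, sorted); attribute
#'   `pairs` carries the classification table with the assigned channel.
#' @export
count_sdm_spectra <- function(pv, ancestral, pairs = NULL,
                              unphased = c("error", "drop")) {
  if (is.null(pairs)) {
    pairs <- classify_pairs(pv, find_adjacent_pairs(pv, unphased))
  }
  types <- sdm_types(pv, pairs, ancestral)
  pairs$channel <- types
  nsamp <- length(pv$samples)
  use <- which(!is.na(types))
  channels <- sort(unique(types[use]))
  mat <- matrix(0, nrow = nsamp, ncol = length(channels),
                dimnames = list(pv$samples, channels))
  for (p in use) {
    di <- derived_index(pv)[pairs$i[p]]
    dj <- derived_index(pv)[pairs$j[p]]
    bothA <- pv$hapA[pairs$i[p], ] == di & pv$hapA[pairs$j[p], ] == dj
    bothB <- pv$hapB[pairs$i[p], ] == di & pv$hapB[pairs$j[p], ] == dj
    bothA[is.na(bothA)] <- FALSE; bothB[is.na(bothB)] <- FALSE
    mat[, types[p]] <- mat[, types[p]] + as.numeric(bothA) + as.numeric(bothB)
  }
  structure(mat, pairs = pairs)
}
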