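#' Assign K-mer mutation types to polarized variants
#'
#' Extracts the K-mer centred on each variant from the ancestral genome; when
#' the central ancestral base is G or T the K-mer and the derived base are
#' reverse-complemented (strand collapse), so every type has a central
#' ancestral base of A or C. Variants whose window contains a base outside
#' `{A,C,G,T}` or runs past a chromosome end are rejected.
#'
#' @param pv a `polarized_variants` object.
#' @param ancestral ancestral genome ([Biostrings::DNAStringSet]).
#' @param k odd window size (default 3).
#' @return character vector of channel labels (see [snv_channel_label()]);
#'   `NA` where the context was rejected. Attribute `n_rejected` carries the
#'   rejection count.
#' @export
mutation_types <- function(pv, ancestral, k = 3) {
  stopifnot(k >= 1, k %% 2 == 1)
  f <- (k - 1L) / 2L
  v <- pv$variants
  n <- nrow(v)
  kmer <- rep(NA_character_, n)
  lens <- setNames(Biostrings::width(ancestral), names(ancestral))
  inside <- v$pos - f >= 1L & v$pos + f <= lens[v$chrom]
  for (chrom in unique(v$chrom)) {
    sel <- which(v$chrom == chrom & inside)
    if (!length(sel)) next
    seq_chr <- as.character(ancestral[[chrom]])
    kmer[sel] <- substring(seq_chr, v$pos[sel] - f, v$pos[sel] + f)
  }
  valid <- !is.na(kmer) & !grepl("[^ACGT]", kmer)
  central <- substr(kmer, f + 1L, f + 1L)
  bad_central <- valid & central != v$ancestral
  if (any(bad_central))
    stop("ancestral genome base disagrees with polarized ancestral allele at ",
         v$chrom[bad_central][1], ":", v$pos[bad_central][1],
         "; were the variants polarized against this genome?")
  out <- rep(NA_character_, n)
  if (any(valid)) {
    km <- kmer[valid]
    der <- v$derived[valid]
    flip <- central[valid] %in% c("G", "T")
    km[flip] <- revcomp(km[flip])
    der[flip] <- comp_base(der[flip])
    out[valid] <- vapply(seq_along(km), function(i)
      snv_channel_label(km[i], der[i]), character(1))
  }
  structure(out, n_rejected = sum(!valid))
}

#' Count per-sample K-mer mutation spectra
#'
#' Accumulates a samples-by-channels count matrix. In the default
#' `"carrier-copies"` mode each sample's cell for a variant's type increases
#' by the number of derived allele copies that sample carries (het = 1,
#' homozygous derived = 2; missing haplotypes contribute 0). In
#' `"random-allocation"` mode each variant contributes a single count to one
#' carrier sample drawn with probability proportional to its derived copies.
#'
#' @param pv a `polarized_variants` object.
#' @param ancestral ancestral genome.
#' @param k odd window size (default 3).
#' @param mode counting mode, `"carrier-copies"` (default) or
#'   `"random-allocation"`.
#' @param seed integer seed used only by `"random-allocation"`.
#' @param samples optional character vector restricting/ordering samples;
#'   requested samples absent from the data are skipped with a warning.
#' @return numeric matrix (samples x channels) with full channel set from
#'   [snv_channels()]; attributes `k` and `mode`.
#' @export
count_spectra <- function(pv, ancestral, k = 3,
                          mode = c("carrier-copies", "random-allocation"),
                          seed = NULL, samples = NULL) {
  mode <- match.arg(mode)
  if (is.null(samples)) samples <- pv$samples
  missing <- setdiff(samples, pv$samples)
  if (length(missing)) {
    warning("samples not in the data were skipped: ",
            paste(missing, collapse = ", "))
    samples <- setdiff(samples, missing)
  }
  types <- mutation_types(pv, ancestral, k)
  channels <- snv_channels(k)
  mat <- matrix(0, nrow = length(samples), ncol = length(channels),
                dimnames = list(samples, channels))
  usable <- !is.na(types)
  if (any(usable)) {
    didx <- derived_index(pv)
    sA <- pv$hapA[, samples, drop = FALSE] == didx
    sB <- pv$hapB[, samples, drop = FALSE] == didx
    sA[is.na(sA)] <- FALSE; sB[is.na(sB)] <- FALSE
    copies <- (sA + sB)[usable, , drop = FALSE]
    if (mode == "random-allocation") {
      if (!is.null(seed)) set.seed(seed)
      alloc <- matrix(0, nrow(copies), ncol(copies))
      for (i in seq_len(nrow(copies))) {
        w <- copies[i, ]
        if (sum(w) > 0) alloc[i, sample.int(length(w), 1L, prob = w)] <- 1
      }
      copies <- alloc
    }
    agg <- rowsum(copies, group = types[usable])
    mat[, rownames(agg)] <- t(agg)
  }
  structure(mat, k = k, mode = mode)
}

#' Ancestral K-mer target counts
#'
#' Slides a K-window over every position of every ancestral chromosome and
#' counts occurrences of each strand-collapsed K-mer (central base A or C).
#' Windows containing any base outside `{A,C,G,T}` are skipped. These counts
#' are the denominators for [target_normalize()].
#'
#' @param ancestral ancestral genome ([Biostrings::DNAStringSet]).
#' @param k odd window size (default 3).
#' @return named numeric vector over all `2 * 4^(k-1)` collapsed K-mers
#'   (zeros included).
#' @export
kmer_targets <- function(ancestral, k = 3) {
  stopifnot(k >= 1, k %% 2 == 1)
  raw <- colSums(Biostrings::oligonucleotideFrequency(ancestral, width = k))
  keys <- collapse_kmer(names(raw))
  out <- tapply(raw, keys, sum)
  counts <- setNames(as.numeric(out), names(out))
  all_keys <- sort(unique(collapse_kmer(names(raw))))
  full <- setNames(numeric(length(all_keys)), all_keys)
  full[names(counts)] <- counts
  full
}

#' Ancestral dinucleotide target counts
#'
#' Counts every overlapping dinucleotide of the ancestral genome under the
#' canonical (lexicographic reverse-complement) collapse; denominators for
#' normalizing SDM spectra.
#'
#' @param ancestral ancestral genome.
#' @return named numeric vector over the 10 canonical dinucleotides.
#' @export
dinuc_targets <- function(ancestral) {
  raw <- colSums(Biostrings::oligonucleotideFrequency(ancestral, width = 2))
  keys <- canonical_dinuc(names(raw))
  out <- tapply(raw, keys, sum)
  setNames(as.numeric(out), names(out))
}

#' Pool CpG>TpG channels with their reverse change
#'
#' For a `k = 3` spectrum, pools each CpG-context C>T channel (`N[C>T]G`)
#' with the channel of the reverse-direction change (TpG>CpG, which after
#' strand collapse is `C[A>G]N'` with `N'` the complement of `N`). Used to
#' check that apparent CpG deamination differences are not polarization
#' artefacts. All other channels pass through untouched.
#'
#' @param mat samples x channels matrix over the 96 `k = 3` channels.
#' @return matrix with the four channel pairs replaced by pooled columns
#'   labelled `"N[C>T]G+C[A>G]N'"`.
#' @export
collapse_cpg <- function(mat) {
  if (ncol(mat) != 96)
    stop("collapse_cpg() supports k = 3 (96-channel) matrices only")
  pairs <- lapply(BASES, function(x)
    c(fwd = paste0(x, "[C>T]G"),
      rev = paste0("C[A>G]", comp_base(x))))
  drop <- unlist(pairs)
  if (!all(drop %in% colnames(mat))) stop("expected k = 3 channel labels")
  keepmat <- mat[, setdiff(colnames(mat), drop), drop = FALSE]
  pooled <- vapply(pairs, function(p) mat[, p["fwd"]] + mat[, p["rev"]],
                   numeric(nrow(mat)))
  if (nrow(mat) == 1L) pooled <- matrix(pooled, nrow = 1L)
  colnames(pooled) <- vapply(pairs, function(p) paste0(p["fwd"], "+", p["rev"]),
                             character(1))
  rownames(pooled) <- rownames(mat)
  cbind(keepmat, pooled)
}
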