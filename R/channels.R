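#' @import methods
#' @importFrom stats median prcomp chisq.test p.adjust rbinom runif setNames
#' @importFrom utils read.delim write.table head tail packageVersion
NULL

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of character DNA strings
#'
#' Vectorised reverse complement backed by Biostrings. Accepts strings over
#' `{A,C,G,T,N}` (case-insensitive); used throughout for strand collapsing.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements, uppercased.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

comp_base <- function(x) unname(COMPLEMENT[toupper(x)])

#' Strand-collapse a K-mer context
#'
#' Canonicalises K-mer ancestral contexts so the central base is A or C: a
#' context whose central base is G or T is replaced by its reverse complement.
#' K must be odd.
#'
#' @param kmers character vector of K-mers (equal, odd length).
#' @return character vector of collapsed K-mers.
#' @export
collapse_kmer <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  k <- nchar(kmers[1])
  stopifnot(k %% 2L == 1L)
  mid <- (k + 1L) / 2L
  central <- substr(kmers, mid, mid)
  flip <- central %in% c("G", "T")
  kmers[flip] <- revcomp(kmers[flip])
  kmers
}

#' Enumerate strand-collapsed SNV channel labels
#'
#' All K-mer mutation-type labels for an odd window size `k`, with central
#' ancestral base A or C. For `k = 3` this is the 96-channel set (rendered
#' `"A[C>T]G"`); for `k = 1` the 6-channel set (rendered `"C>T"`). Channels
#' are ordered by substitution (A>C, A>G, A>T, C>A, C>G, C>T) then
#' alphabetically by flanking context.
#'
#' @param k odd window size >= 1.
#' @return character vector of `6 * 4^(k-1)` channel labels.
#' @export
snv_channels <- function(k = 3) {
  stopifnot(k >= 1, k %% 2 == 1)
  f <- (k - 1L) / 2L
  subs <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")
  if (f == 0L) return(subs)
  flank <- sort(apply(expand.grid(rep(list(BASES), f))[, f:1, drop = FALSE],
                      1, paste0, collapse = ""))
  out <- character(0)
  for (s in subs) {
    anc <- substr(s, 1, 1); der <- substr(s, 3, 3)
    grid <- expand.grid(right = flank, left = flank, stringsAsFactors = FALSE)
    grid <- grid[order(grid$left, grid$right), ]
    out <- c(out, paste0(grid$left, "[", anc, ">", der, "]", grid$right))
  }
  out
}

#' Render an SNV channel label
#' @param anc_kmer collapsed ancestral K-mer (central base A or C).
#' @param derived derived central base (already collapsed).
#' @return character label, `"A[C>T]G"`-style (`"C>T"` for k = 1).
#' @export
snv_channel_label <- function(anc_kmer, derived) {
  k <- nchar(anc_kmer)
  mid <- (k + 1L) / 2L
  central <- substr(anc_kmer, mid, mid)
  if (k == 1L) return(paste0(central, ">", derived))
  paste0(substr(anc_kmer, 1L, mid - 1L), "[", central, ">", derived, "]",
         substr(anc_kmer, mid + 1L, k))
}

#' Ancestral context of channel labels
#'
#' Maps channel labels back to the ancestral target key used for K-mer target
#' normalization: SNV labels (`"A[C>T]G"`, `"C>T"`) yield the collapsed
#' ancestral K-mer (`"ACG"`, `"C"`); SDM labels (`"CA>TA>TG"`, `"CA>*>TG"`)
#' yield the canonical ancestral dinucleotide.
#'
#' @param labels character vector of channel labels.
#' @return character vector of ancestral contexts.
#' @export
channel_context <- function(labels) {
  out <- character(length(labels))
  is_snv3 <- grepl("\\[", labels)
  if (any(is_snv3)) {
    out[is_snv3] <- sub("^(.*)\\[([ACGT])>[ACGT]\\](.*)$", "\\1\\2\\3",
                        labels[is_snv3])
  }
  is_sdm <- !is_snv3 & grepl("^[ACGT]{2}>", labels)
  if (any(is_sdm)) {
    anc <- substr(labels[is_sdm], 1, 2)
    out[is_sdm] <- canonical_dinuc(anc)
  }
  is_k1 <- !is_snv3 & !is_sdm & grepl("^[ACGT]>[ACGT]$", labels)
  out[is_k1] <- substr(labels[is_k1], 1, 1)
  bad <- out == ""
  if (any(bad)) stop("unrecognised channel labels: ",
                     paste(labels[bad], collapse = ", "))
  out
}

#' Canonical form of a dinucleotide
#'
#' The lexicographically smaller of a dinucleotide and its reverse complement;
#' used as the strand-collapsed key for ancestral dinucleotide target counts.
#'
#' @param d character vector of 2-mers.
#' @return character vector of canonical 2-mers.
#' @export
canonical_dinuc <- function(d) {
  rc <- revcomp(d)
  ifelse(rc < d, rc, d)
}

#' COSMIC-style SBS96 channel labels
#'
#' The 96 pyrimidine-centred trinucleotide substitution labels in COSMIC
#' catalogue order (substitution C>A, C>G, C>T, T>A, T>C, T>G; contexts
#' alphabetical within substitution).
#'
#' @return character vector of 96 labels.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    anc <- substr(s, 1, 1); der <- substr(s, 3, 3)
    for (l in BASES) for (r in BASES)
      out <- c(out, paste0(l, "[", anc, ">", der, "]", r))
  }
  out
}

#' Relabel an A/C-collapsed spectrum to COSMIC SBS96 convention
#'
#' The A/C-central channel set used internally and the COSMIC pyrimidine
#' (C/T-central) set are related by a reverse-complement bijection: channels
#' with central base A map to their reverse-complement label with central T.
#' This relabels a 96-channel spectrum (vector or samples-by-channels matrix)
#' into COSMIC SBS96 order so it can be compared against SBS catalogues.
#'
#' @param x named numeric vector, or matrix with channel column names, over
#'   the 96 A/C-collapsed `k = 3` channels.
#' @return same shape as `x`, with COSMIC SBS96 labels in catalogue order.
#' @export
as_sbs96 <- function(x) {
  labs <- if (is.matrix(x)) colnames(x) else names(x)
  if (is.null(labs) || length(labs) != 96)
    stop("as_sbs96() expects 96 labelled k = 3 channels")
  parts <- regmatches(labs, regexec("^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", labs))
  if (any(lengths(parts) != 5)) stop("unrecognised channel labels")
  m <- do.call(rbind, parts)
  central <- m[, 3]
  newlab <- labs
  flip <- central == "A"
  if (any(flip)) {
    newlab[flip] <- paste0(comp_base(m[flip, 5]), "[", comp_base(m[flip, 3]),
                           ">", comp_base(m[flip, 4]), "]", comp_base(m[flip, 2]))
  }
  target <- sbs96_channels()
  if (!setequal(newlab, target)) stop("channels do not form the full SBS96 set")
  ord <- match(target, newlab)
  if (is.matrix(x)) {
    out <- x[, ord, drop = FALSE]
    colnames(out) <- target
  } else {
    out <- x[ord]
    names(out) <- target
  }
  out
}
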