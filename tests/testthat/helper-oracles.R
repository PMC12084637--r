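# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths (and Biostrings): reverse complements use chartr on
# reversed character vectors, counting uses plain double loops.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_collapse <- function(kmer) {
  mid <- (nchar(kmer) + 1L) %/% 2L
  if (substr(kmer, mid, mid) %in% c("G", "T")) oracle_revcomp(kmer) else kmer
}

oracle_label <- function(kmer, derived) {
  mid <- (nchar(kmer) + 1L) %/% 2L
  if (substr(kmer, mid, mid) %in% c("G", "T")) {
    kmer <- oracle_revcomp(kmer)
    derived <- chartr("ACGT", "TGCA", derived)
  }
  k <- nchar(kmer)
  central <- substr(kmer, mid, mid)
  if (k == 1L) return(paste0(central, ">", derived))
  paste0(substr(kmer, 1, mid - 1), "[", central, ">", derived, "]",
         substr(kmer, mid + 1, k))
}

# per-(sample, variant) enumeration of derived-copy counts
oracle_count_spectra <- function(pv, ancestral, k) {
  f <- (k - 1L) %/% 2L
  channels <- snv_channels(k)
  mat <- matrix(0, length(pv$samples), length(channels),
                dimnames = list(pv$samples, channels))
  for (i in seq_len(nrow(pv$variants))) {
    v <- pv$variants[i, ]
    s <- as.character(ancestral[[v$chrom]])
    if (v$pos - f < 1 || v$pos + f > nchar(s)) next
    kmer <- substr(s, v$pos - f, v$pos + f)
    if (grepl("[^ACGT]", kmer)) next
    lab <- oracle_label(kmer, v$derived)
    didx <- if (v$derived_is_alt) 1L else 0L
    for (j in seq_along(pv$samples)) {
      copies <- 0L
      if (!is.na(pv$hapA[i, j]) && pv$hapA[i, j] == didx) copies <- copies + 1L
      if (!is.na(pv$hapB[i, j]) && pv$hapB[i, j] == didx) copies <- copies + 1L
      mat[j, lab] <- mat[j, lab] + copies
    }
  }
  mat
}

oracle_kmer_targets <- function(ancestral, k) {
  counts <- list()
  for (chrom in names(ancestral)) {
    s <- as.character(ancestral[[chrom]])
    for (p in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, p, p + k - 1L)
      if (grepl("[^ACGT]", w)) next
      w <- oracle_collapse(w)
      counts[[w]] <- (counts[[w]] %||% 0) + 1
    }
  }
  unlist(counts)
}

oracle_dinuc_targets <- function(ancestral) {
  counts <- list()
  for (chrom in names(ancestral)) {
    s <- as.character(ancestral[[chrom]])
    for (p in seq_len(nchar(s) - 1L)) {
      w <- substr(s, p, p + 1L)
      if (grepl("[^ACGT]", w)) next
      rc <- oracle_revcomp(w)
      if (rc < w) w <- rc
      counts[[w]] <- (counts[[w]] %||% 0) + 1
    }
  }
  unlist(counts)
}

# direct transcription of the printed median-of-ratios formula (raw factors)
oracle_median_of_ratios <- function(mat) {
  m <- nrow(mat)
  g <- numeric(ncol(mat))
  for (i in seq_len(ncol(mat))) g[i] <- prod(mat[, i])^(1 / m)
  s <- numeric(m)
  for (j in seq_len(m)) {
    r <- mat[j, g > 0] / g[g > 0]
    s[j] <- median(r)
  }
  norm <- mat
  for (j in seq_len(m)) norm[j, ] <- mat[j, ] / s[j]
  list(factors = s, matrix = norm)
}

# naive SDM path construction + per-haplotype counting
oracle_sdm_label <- function(anc, der, order) {
  mid <- switch(order,
    left_first = paste0(substr(der, 1, 1), substr(anc, 2, 2)),
    right_first = paste0(substr(anc, 1, 1), substr(der, 2, 2)),
    unresolved = "*")
  fwd <- paste0(anc, ">", mid, ">", der)
  rmid <- if (mid == "*") "*" else oracle_revcomp(mid)
  bwd <- paste0(oracle_revcomp(anc), ">", rmid, ">", oracle_revcomp(der))
  min(fwd, bwd)
}

oracle_sdm_spectra <- function(pv, pairs_df) {
  cells <- list()
  for (p in seq_len(nrow(pairs_df))) {
    if (pairs_df$class[p] != "SDM") next
    i <- pairs_df$i[p]; j <- pairs_df$j[p]
    anc <- paste0(pv$variants$ancestral[i], pv$variants$ancestral[j])
    der <- paste0(pv$variants$derived[i], pv$variants$derived[j])
    lab <- oracle_sdm_label(anc, der, pairs_df$order[p])
    di <- if (pv$variants$derived_is_alt[i]) 1L else 0L
    dj <- if (pv$variants$derived_is_alt[j]) 1L else 0L
    for (s in seq_along(pv$samples)) {
      n <- 0L
      for (h in c("hapA", "hapB")) {
        ai <- pv[[h]][i, s]; aj <- pv[[h]][j, s]
        if (!is.na(ai) && !is.na(aj) && ai == di && aj == dj) n <- n + 1L
      }
      if (n > 0)
        cells[[paste(pv$samples[s], lab)]] <-
          (cells[[paste(pv$samples[s], lab)]] %||% 0L) + n
    }
  }
  cells
}

`%||%` <- function(a, b) if (is.null(a)) b else a
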