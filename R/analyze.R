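#' Principal component analysis of a spectrum matrix
#'
#' PCA of a normalized samples x channels matrix via [stats::prcomp()]
#' (exact singular value decomposition of the centred, optionally
#' unit-scaled, matrix). Zero-variance channels are dropped before scaling
#' (with a message); an entirely constant matrix is an error.
#'
#' @param mat normalized samples x channels matrix (>= 2 samples).
#' @param n_components number of components to return (default: all).
#' @param standardize centre and scale each channel to unit variance
#'   (default TRUE).
#' @return list with `scores` (samples x PCs), `loadings` (channels x PCs),
#'   `variance_fraction`.
#' @export
spectrum_pca <- function(mat, n_components = NULL, standardize = TRUE) {
  if (nrow(mat) < 2) stop("PCA needs at least two samples")
  v <- apply(mat, 2, stats::var)
  if (all(v == 0)) stop("constant matrix: no variance to decompose")
  if (standardize && any(v == 0)) {
    message("dropping ", sum(v == 0), " zero-variance channel(s)")
    mat <- mat[, v > 0, drop = FALSE]
  }
  p <- prcomp(mat, center = TRUE, scale. = standardize)
  frac <- p$sdev^2 / sum(p$sdev^2)
  k <- if (is.null(n_components)) ncol(p$x) else min(n_components, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       variance_fraction = frac[seq_len(k)])
}

#' Per-population derived allele frequency
#'
#' Recomputes DAF over the allele copies observed in one subset of samples.
#'
#' @param pv a `polarized_variants` object.
#' @param samples character vector of sample names.
#' @return numeric vector (one DAF per variant; `NaN` when no alleles are
#'   observed in the subset).
#' @export
pop_daf <- function(pv, samples) {
  d <- derived_index(pv)
  hA <- pv$hapA[, samples, drop = FALSE]
  hB <- pv$hapB[, samples, drop = FALSE]
  copies <- rowSums(hA == d, na.rm = TRUE) + rowSums(hB == d, na.rm = TRUE)
  nonmiss <- rowSums(!is.na(hA)) + rowSums(!is.na(hB))
  copies / nonmiss
}

#' DAF-binned mutation-type fractions (pulse analysis)
#'
#' For each population, recomputes derived allele frequencies over that
#' population's alleles, drops variants not segregating there, bins the
#' segregating variants into the given DAF intervals `(lo, hi]`, and within
#' each bin reports the fraction of variants of each mutation type. A
#' transient excess of one type in a narrow frequency band (a mutation
#' pulse) shows up as that type's fraction peaking in the corresponding bins.
#'
#' @param pv a `polarized_variants` object.
#' @param types per-variant channel labels (e.g. from [mutation_types()]);
#'   variants with `NA` type are ignored.
#' @param populations data.frame with columns `sample`, `population`.
#' @param edges strictly increasing DAF bin edges; bins are `(e[k], e[k+1]]`.
#' @return data.frame with `population`, `bin`, `bin_lo`, `bin_hi`, `type`,
#'   `n`, `bin_n`, `fraction`. Empty bins appear with `bin_n = 0` rows only
#'   in the attribute `bin_counts`.
#' @export
daf_fractions <- function(pv, types, populations, edges) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  pops <- split(populations$sample, populations$population)
  out <- list()
  bin_counts <- list()
  nb <- length(edges) - 1L
  bin_lab <- paste0("(", format(edges[-length(edges)], trim = TRUE), ",",
                    format(edges[-1], trim = TRUE), "]")
  for (pop in names(pops)) {
    daf <- pop_daf(pv, pops[[pop]])
    sel <- which(!is.na(types) & is.finite(daf) & daf > 0)
    bin <- cut(daf[sel], breaks = edges, labels = FALSE)
    ok <- !is.na(bin)
    tab <- table(bin = factor(bin[ok], levels = seq_len(nb)),
                 type = types[sel][ok])
    bn <- rowSums(tab)
    bin_counts[[pop]] <- data.frame(population = pop, bin = bin_lab,
                                    bin_n = as.integer(bn))
    if (sum(tab) == 0) next
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0 | bn[as.integer(df$bin)] > 0, , drop = FALSE]
    b <- as.integer(df$bin)
    keep <- bn[b] > 0
    df <- df[keep, , drop = FALSE]; b <- b[keep]
    out[[pop]] <- data.frame(population = pop, bin = bin_lab[b],
                             bin_lo = edges[b], bin_hi = edges[b + 1L],
                             type = df$type, n = df$Freq,
                             bin_n = as.integer(bn[b]),
                             fraction = df$Freq / bn[b],
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(population = character(0),
                                      bin = character(0), bin_lo = numeric(0),
                                      bin_hi = numeric(0), type = character(0),
                                      n = integer(0), bin_n = integer(0),
                                      fraction = numeric(0))
  rownames(res) <- NULL
  structure(res, bin_counts = do.call(rbind, bin_counts))
}

#' Logarithmically spaced DAF bin edges
#'
#' Default binning for pulse analysis: log-spaced edges spanning
#' `(daf_min, daf_max)`, fine enough to resolve a pulse near 1% frequency.
#'
#' @param n_bins number of bins (default 8).
#' @param daf_min lower edge (default 1e-3).
#' @param daf_max upper edge (default 0.98).
#' @return numeric vector of `n_bins + 1` edges.
#' @export
daf_bins <- function(n_bins = 8, daf_min = 1e-3, daf_max = 0.98) {
  exp(seq(log(daf_min), log(daf_max), length.out = n_bins + 1L))
}

#' Per-type enrichment test between two populations
#'
#' Tests whether mutation type `type` makes up a different fraction of the
#' variants in population A than in population B: a 1-df chi-square test
#' (no continuity correction) on the 2x2 table of (type, all other types) x
#' (A, B). Any expected cell below 5 flags the result `low_count` (the test
#' is still computed).
#'
#' @param counts_a,counts_b named per-type variant counts for the two
#'   populations.
#' @param type channel label to test.
#' @return list with `type`, `table`, `statistic`, `p_value`, `low_count`.
#' @export
enrichment_test <- function(counts_a, counts_b, type) {
  ta <- sum(counts_a); tb <- sum(counts_b)
  if (ta == 0 || tb == 0) stop("both populations need positive total counts")
  a <- if (type %in% names(counts_a)) counts_a[[type]] else 0
  b <- if (type %in% names(counts_b)) counts_b[[type]] else 0
  tab <- matrix(c(a, ta - a, b, tb - b), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c(type, "other")))
  if (a == 0 && b == 0) {
    stat <- 0; p <- 1
    expected <- matrix(0, 2, 2)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- unname(ct$p.value)
    if (is.nan(stat)) { stat <- 0; p <- 1 }
    expected <- ct$expected
  }
  list(type = type, table = tab, statistic = stat, p_value = p,
       low_count = any(expected < 5))
}

#' Enrichment scan over all mutation types
#'
#' Runs [enrichment_test()] for every channel present in either population
#' and adjusts p-values for multiple testing (Bonferroni by default).
#'
#' @param counts_a,counts_b named per-type variant counts.
#' @param adjust `"bonferroni"` (default), `"BH"`, or `"none"`.
#' @return data.frame sorted by p-value with `type`, `count_a`, `count_b`,
#'   `statistic`, `p_value`, `p_adjusted`, `low_count`.
#' @export
enrichment_scan <- function(counts_a, counts_b,
                            adjust = c("bonferroni", "BH", "none")) {
  adjust <- match.arg(adjust)
  types <- union(names(counts_a), names(counts_b))
  rows <- lapply(types, function(t) {
    r <- enrichment_test(counts_a, counts_b, t)
    data.frame(type = t, count_a = r$table[1, 1], count_b = r$table[2, 1],
               statistic = r$statistic, p_value = r$p_value,
               low_count = r$low_count, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$p_adjusted <- if (adjust == "none") df$p_value
  else p.adjust(df$p_value, method = adjust)
  df[order(df$p_value), ]
}

#' Per-type segregating-variant counts for a population
#'
#' Counts, for each channel, the variants segregating (derived copies > 0)
#' in the given sample subset; the count construction used by
#' [enrichment_scan()] and [daf_fractions()].
#'
#' @param pv a `polarized_variants` object.
#' @param types per-variant channel labels.
#' @param samples sample names of the population.
#' @return named integer vector of counts.
#' @export
type_counts <- function(pv, types, samples) {
  daf <- pop_daf(pv, samples)
  sel <- !is.na(types) & is.finite(daf) & daf > 0
  tab <- table(types[sel])
  setNames(as.integer(tab), names(tab))
}

#' Rank-1 nonnegative matrix factorization of a pooled spectrum
#'
#' Factorizes a nonnegative channels-profile as `V ~ w h` with `V` the
#' channels x samples matrix, `w >= 0` the signature and `h >= 0` the
#' per-sample exposures. Initialised from the leading singular pair (which
#' for a nonnegative matrix is itself nonnegative and is the global rank-1
#' optimum) and polished with multiplicative updates until the relative
#' change in reconstruction error falls below `tol`. The signature is
#' normalized to sum 1 and exposures absorb the scale.
#'
#' @param mat samples x channels nonnegative matrix.
#' @param tol relative reconstruction-error tolerance (default 1e-9).
#' @param max_iter maximum multiplicative updates (default 200).
#' @return list with `signature` (named, sums to 1), `exposures` (named per
#'   sample), `reconstruction_error` (Frobenius).
#' @export
rank1_signature <- function(mat, tol = 1e-9, max_iter = 200) {
  if (!any(mat > 0)) stop("all-zero matrix")
  if (any(mat < 0)) stop("matrix must be nonnegative")
  V <- t(mat)                       # channels x samples
  sv <- svd(V, nu = 1, nv = 1)
  w <- abs(sv$u[, 1]) * sqrt(sv$d[1])
  h <- abs(sv$v[, 1]) * sqrt(sv$d[1])
  err <- function(w, h) sqrt(sum((V - outer(w, h))^2))
  e0 <- err(w, h)
  for (it in seq_len(max_iter)) {
    h <- h * as.numeric(crossprod(V, w)) / (h * sum(w^2) + 1e-300)
    w <- w * as.numeric(V %*% h) / (w * sum(h^2) + 1e-300)
    e1 <- err(w, h)
    if (abs(e0 - e1) <= tol * max(e0, 1e-300)) break
    e0 <- e1
  }
  s <- sum(w)
  list(signature = setNames(w / s, colnames(mat)),
       exposures = setNames(h * s, rownames(mat)),
       reconstruction_error = err(w, h))
}

#' Cosine similarity between two nonnegative vectors
#' @param a,b numeric vectors of equal length.
#' @return cosine of the angle between `a` and `b` (0 when either is zero).
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match a signature against a catalogue by cosine similarity
#'
#' Computes the cosine similarity of the signature against every catalogue
#' column and reports the best match; similarities below `cutoff` yield a
#' no-match (the best candidate is still reported).
#'
#' @param signature named numeric vector over channels.
#' @param catalog channels x signatures matrix with matching row names
#'   (channel order may differ; labels must form the same set).
#' @param cutoff minimum similarity to accept a match (default 0.8).
#' @return list with `match` (name or `NA`), `similarity` (best), `matched`
#'   (logical), `similarities` (all, sorted decreasing).
#' @export
cosine_match <- function(signature, catalog, cutoff = 0.8) {
  if (is.null(names(signature)) || is.null(rownames(catalog)))
    stop("signature and catalogue must carry channel labels")
  if (!setequal(names(signature), rownames(catalog)) ||
      length(signature) != nrow(catalog))
    stop("channel labels of signature and catalogue do not match")
  cat_m <- catalog[names(signature), , drop = FALSE]
  sims <- apply(cat_m, 2, cosine_sim, a = signature)
  sims <- sort(sims, decreasing = TRUE)
  best <- sims[1]
  list(match = if (best >= cutoff) names(sims)[1] else NA_character_,
       similarity = unname(best), matched = best >= cutoff,
       similarities = sims)
}

#' Read a signature catalogue table
#'
#' Reads a channels x signatures TSV in COSMIC SBS layout: first column the
#' channel label (`"A[C>A]A"`-style), one column per signature, nonnegative
#' values.
#'
#' @param path TSV path.
#' @return numeric matrix with channel row names.
#' @export
read_signature_catalog <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("catalogue entries must be nonnegative")
  m
}
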