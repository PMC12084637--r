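# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# hand-build a polarized_variants object from explicit fields
make_pv <- function(chrom, pos, anc, der, hapA, hapB, samples = NULL,
                    derived_is_alt = NULL, phased = TRUE) {
  n <- length(pos)
  if (is.null(dim(hapA))) hapA <- matrix(hapA, nrow = n)
  if (is.null(dim(hapB))) hapB <- matrix(hapB, nrow = n)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(hapA)))
  colnames(hapA) <- colnames(hapB) <- samples
  if (is.null(derived_is_alt)) derived_is_alt <- rep(TRUE, n)
  ref <- ifelse(derived_is_alt, anc, der)
  alt <- ifelse(derived_is_alt, der, anc)
  didx <- ifelse(derived_is_alt, 1L, 0L)
  copies <- rowSums(hapA == didx, na.rm = TRUE) +
    rowSums(hapB == didx, na.rm = TRUE)
  nonmiss <- rowSums(!is.na(hapA)) + rowSums(!is.na(hapB))
  if (length(phased) == 1L)
    phased <- matrix(phased, n, ncol(hapA), dimnames = dimnames(hapA))
  structure(list(
    variants = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                          ancestral = anc, derived = der,
                          derived_is_alt = derived_is_alt,
                          daf = copies / nonmiss, stringsAsFactors = FALSE),
    hapA = hapA, hapB = hapB, phased = phased, samples = samples,
    rejections = integer(0)), class = "polarized_variants")
}

# reverse-complement a whole study: genome coordinates flip, alleles
# complement; used for strand-invariance properties
rc_genome <- function(g) {
  out <- Biostrings::reverseComplement(g)
  names(out) <- names(g)
  out
}

rc_pv <- function(pv, lens) {
  v <- pv$variants
  comp <- function(x) chartr("ACGT", "TGCA", x)
  v$pos <- lens[v$chrom] - v$pos + 1L
  v$ref <- comp(v$ref); v$alt <- comp(v$alt)
  v$ancestral <- comp(v$ancestral); v$derived <- comp(v$derived)
  ord <- order(v$chrom, v$pos)
  structure(list(variants = v[ord, ],
                 hapA = pv$hapA[ord, , drop = FALSE],
                 hapB = pv$hapB[ord, , drop = FALSE],
                 phased = pv$phased[ord, , drop = FALSE],
                 samples = pv$samples, rejections = integer(0)),
            class = "polarized_variants")
}

# default seeded cohort reused by several files (10 kb, 10 samples, ~500
# variants -- the package's default study conditions)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sim_cohort(sim_config(seed = 20240915,
                                      sdm = list(n_mnp = 6, n_sdm = 10)))
    cache
  }
})
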