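#' Site-level variant filters
#'
#' Applies the pre-polarization site filters: biallelic SNVs only (single-base
#' REF and a single single-base ALT), per-site genotype call rate strictly
#' greater than `call_rate_min`, and minor allele count at least `mac_min`.
#' The defaults retain biallelic SNPs with call rate > 90% and MAC > 2.
#' Rejection is a value, not an error: every site receives either `"keep"` or
#' a machine-readable reason code.
#'
#' @param vcf a `mut_vcf` object.
#' @param call_rate_min call-rate threshold; sites are kept when the fraction
#'   of non-missing genotypes is strictly greater than this.
#' @param mac_min minimum minor allele count (kept when MAC >= `mac_min`).
#' @return character vector, one of `"keep"`, `"not_snv"`, `"multiallelic"`,
#'   `"call_rate"`, `"mac"` per site.
#' @export
filter_sites <- function(vcf, call_rate_min = 0.9, mac_min = 3) {
  sites <- vcf$sites
  n <- nrow(sites)
  reason <- rep("keep", n)
  multi <- grepl(",", sites$alt)
  snv <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    sites$ref %in% BASES & sites$alt %in% BASES & !multi
  reason[!snv] <- "not_snv"
  reason[multi] <- "multiallelic"
  called <- !is.na(vcf$hapA) & !is.na(vcf$hapB)
  call_rate <- rowMeans(called)
  reason[reason == "keep" & !(call_rate > call_rate_min)] <- "call_rate"
  alt_copies <- rowSums(vcf$hapA == 1L, na.rm = TRUE) +
    rowSums(vcf$hapB == 1L, na.rm = TRUE)
  nonmiss <- rowSums(!is.na(vcf$hapA)) + rowSums(!is.na(vcf$hapB))
  mac <- pmin(alt_copies, nonmiss - alt_copies)
  reason[reason == "keep" & mac < mac_min] <- "mac"
  reason
}

#' Polarize filtered sites against an ancestral genome
#'
#' For each site passing [filter_sites()], looks up the ancestral-genome base
#' at its position: if it equals REF the derived allele is ALT, if it equals
#' ALT the derived allele is REF; an `N` (or non-ACGT) ancestral base rejects
#' the site as `ancestral_undefined`, any other base as `ancestral_mismatch`.
#' The derived allele frequency is the count of derived allele copies over
#' non-missing allele copies. Sites with DAF >= `daf_max` are rejected
#' (`daf`); the default keeps DAF < 0.98.
#'
#' @param vcf a `mut_vcf` object.
#' @param ancestral ancestral genome ([Biostrings::DNAStringSet]) in the same
#'   coordinates as the VCF.
#' @param call_rate_min,mac_min passed to [filter_sites()].
#' @param daf_max strict upper bound on derived allele frequency.
#' @return an object of class `polarized_variants`: list with `variants`
#'   (data.frame `chrom`, `pos`, `ref`, `alt`, `ancestral`, `derived`,
#'   `derived_is_alt`, `daf`), `hapA`, `hapB`, `phased`, `samples` (kept rows
#'   only), and `rejections` (named count per reason code).
#' @export
polarize_sites <- function(vcf, ancestral, call_rate_min = 0.9, mac_min = 3,
                           daf_max = 0.98) {
  reason <- filter_sites(vcf, call_rate_min, mac_min)
  sites <- vcf$sites
  chrom_ok <- sites$chrom %in% names(ancestral)
  if (any(!chrom_ok & reason == "keep"))
    stop("sites on chromosomes absent from the ancestral genome: ",
         paste(unique(sites$chrom[!chrom_ok]), collapse = ", "))
  lens <- setNames(Biostrings::width(ancestral), names(ancestral))
  idx <- which(reason == "keep")
  if (length(idx)) {
    beyond <- sites$pos[idx] > lens[sites$chrom[idx]] | sites$pos[idx] < 1L
    if (any(beyond))
      stop("variant position beyond ancestral sequence length at ",
           sites$chrom[idx[beyond][1]], ":", sites$pos[idx[beyond][1]])
  }
  anc_base <- rep(NA_character_, nrow(sites))
  for (chrom in unique(sites$chrom[idx])) {
    sel <- idx[sites$chrom[idx] == chrom]
    seq_chr <- as.character(ancestral[[chrom]])
    anc_base[sel] <- substring(seq_chr, sites$pos[sel], sites$pos[sel])
  }
  is_ref <- anc_base == sites$ref
  is_alt <- anc_base == sites$alt
  undef <- !(anc_base %in% BASES)
  reason[reason == "keep" & undef] <- "ancestral_undefined"
  reason[reason == "keep" & !undef & !is_ref & !is_alt] <- "ancestral_mismatch"

  keep <- reason == "keep"
  derived_is_alt <- is_ref[keep]
  alt_copies <- rowSums(vcf$hapA[keep, , drop = FALSE] == 1L, na.rm = TRUE) +
    rowSums(vcf$hapB[keep, , drop = FALSE] == 1L, na.rm = TRUE)
  nonmiss <- rowSums(!is.na(vcf$hapA[keep, , drop = FALSE])) +
    rowSums(!is.na(vcf$hapB[keep, , drop = FALSE]))
  daf <- ifelse(derived_is_alt, alt_copies, nonmiss - alt_copies) / nonmiss
  pass_daf <- daf_filter(daf, daf_max)
  reason[which(keep)[!pass_daf]] <- "daf"

  sel <- which(reason == "keep")
  ord <- sel[order(sites$chrom[sel], sites$pos[sel])]
  variants <- data.frame(
    chrom = sites$chrom[ord], pos = sites$pos[ord],
    ref = sites$ref[ord], alt = sites$alt[ord],
    ancestral = anc_base[ord],
    derived = ifelse(anc_base[ord] == sites$ref[ord], sites$alt[ord],
                     sites$ref[ord]),
    derived_is_alt = anc_base[ord] == sites$ref[ord],
    daf = daf[match(ord, which(keep))],
    stringsAsFactors = FALSE)
  rej <- table(factor(reason[reason != "keep"],
                      levels = c("not_snv", "multiallelic", "call_rate", "mac",
                                 "ancestral_undefined", "ancestral_mismatch",
                                 "daf")))
  structure(list(variants = variants,
                 hapA = vcf$hapA[ord, , drop = FALSE],
                 hapB = vcf$hapB[ord, , drop = FALSE],
                 phased = vcf$phased[ord, , drop = FALSE],
                 samples = vcf$samples,
                 rejections = c(rej)),
            class = "polarized_variants")
}

#' Derived-allele-frequency filter
#'
#' Keep rule for polarized variants: strictly `daf < daf_max`; a DAF exactly
#' at the bound is rejected.
#'
#' @param daf numeric vector of derived allele frequencies.
#' @param daf_max strict upper bound (default 0.98).
#' @return logical keep vector.
#' @export
daf_filter <- function(daf, daf_max = 0.98) {
  daf < daf_max
}

#' @export
print.polarized_variants <- function(x, ...) {
  cat("polarized_variants:", nrow(x$variants), "variants,",
      length(x$samples), "samples\n")
  if (sum(x$rejections) > 0) {
    cat("rejected:", sum(x$rejections), "(",
        paste(names(x$rejections)[x$rejections > 0],
              x$rejections[x$rejections > 0], collapse = ", "), ")\n")
  }
  invisible(x)
}

#' Rejection summary table
#' @param pv a `polarized_variants` object.
#' @return data.frame with `reason` and `count` (includes `kept` row).
#' @export
rejection_summary <- function(pv) {
  data.frame(reason = c(names(pv$rejections), "kept"),
             count = c(as.integer(pv$rejections), nrow(pv$variants)),
             stringsAsFactors = FALSE)
}

# per-variant index of the derived allele (0 = REF, 1 = ALT)
derived_index <- function(pv) ifelse(pv$variants$derived_is_alt, 1L, 0L)

#' Write polarized variants as a VCF with AA and DAF INFO fields
#'
#' @param pv a `polarized_variants` object.
#' @param path output path.
#' @param contig_lengths optional named vector of chromosome lengths.
#' @return `path`, invisibly.
#' @export
write_polarized_vcf <- function(pv, path, contig_lengths = NULL) {
  sites <- pv$variants[, c("chrom", "pos", "ref", "alt")]
  sites$id <- "."
  sites$info <- sprintf("AA=%s;DAF=%.6g", pv$variants$ancestral,
                        pv$variants$daf)
  vcf <- make_vcf(sites, pv$hapA, pv$hapB, phased = pv$phased)
  write_vcf(vcf, path, contig_lengths)
}

#' Read a polarized VCF back into a `polarized_variants` object
#'
#' Reconstructs polarization from the `AA` INFO field written by
#' [write_polarized_vcf()]; DAF is recomputed from the genotypes.
#'
#' @param path path to a VCF with `AA` INFO annotations.
#' @return a `polarized_variants` object.
#' @export
read_polarized_vcf <- function(path) {
  vcf <- read_vcf(path)
  aa <- sub("^.*AA=([ACGTN]).*$", "\\1", vcf$sites$info)
  if (any(!aa %in% BASES))
    stop("missing or undefined AA INFO field; run polarization first")
  derived_is_alt <- aa == vcf$sites$ref
  mismatch <- !derived_is_alt & aa != vcf$sites$alt
  if (any(mismatch))
    stop("AA matches neither REF nor ALT at ",
         vcf$sites$chrom[mismatch][1], ":", vcf$sites$pos[mismatch][1])
  alt_copies <- rowSums(vcf$hapA == 1L, na.rm = TRUE) +
    rowSums(vcf$hapB == 1L, na.rm = TRUE)
  nonmiss <- rowSums(!is.na(vcf$hapA)) + rowSums(!is.na(vcf$hapB))
  daf <- ifelse(derived_is_alt, alt_copies, nonmiss - alt_copies) / nonmiss
  variants <- data.frame(
    chrom = vcf$sites$chrom, pos = vcf$sites$pos, ref = vcf$sites$ref,
    alt = vcf$sites$alt, ancestral = aa,
    derived = ifelse(derived_is_alt, vcf$sites$alt, vcf$sites$ref),
    derived_is_alt = derived_is_alt, daf = daf, stringsAsFactors = FALSE)
  structure(list(variants = variants, hapA = vcf$hapA, hapB = vcf$hapB,
                 phased = vcf$phased, samples = vcf$samples,
                 rejections = integer(0)),
            class = "polarized_variants")
}
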