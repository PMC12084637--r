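#' Read a VCF into a site table and genotype matrices
#'
#' Thin wrapper over [vcfR::read.vcfR()] that extracts the fixed fields and
#' parses diploid GT strings into two per-haplotype allele-index matrices
#' (`0` = REF, `1..` = ALT index, `NA` = missing), plus a per-genotype phase
#' indicator.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return an object of class `mut_vcf`: list with `sites` (data.frame
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `info`), `hapA`, `hapB` (integer
#'   matrices, variants x samples), `phased` (logical matrix), `samples`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
                      info = fix[, "INFO"], stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  parse_gt(sites, gt)
}

parse_gt <- function(sites, gt) {
  samples <- colnames(gt)
  a1 <- sub("^([0-9.]+)[|/].*$", "\\1", gt)
  a2 <- sub("^[0-9.]+[|/]([0-9.]+)$", "\\1", gt)
  haploid <- !grepl("[|/]", gt) & !is.na(gt)
  a1[haploid] <- gt[haploid]
  a2[haploid] <- gt[haploid]
  hapA <- suppressWarnings(matrix(as.integer(a1), nrow = nrow(gt)))
  hapB <- suppressWarnings(matrix(as.integer(a2), nrow = nrow(gt)))
  hapA[is.na(gt) | a1 == "."] <- NA_integer_
  hapB[is.na(gt) | a2 == "."] <- NA_integer_
  phased <- grepl("|", gt, fixed = TRUE)
  phased[is.na(gt)] <- TRUE   # missing genotypes impose no phase constraint
  dim(phased) <- dim(gt)
  dimnames(hapA) <- dimnames(hapB) <- dimnames(phased) <-
    list(NULL, samples)
  structure(list(sites = sites, hapA = hapA, hapB = hapB, phased = phased,
                 samples = samples), class = "mut_vcf")
}

#' Assemble a `mut_vcf` object in memory
#'
#' Constructor used by the simulator and tests. Homozygous-reference cells may
#' simply be 0 in both haplotype matrices.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` (and optionally
#'   `id`, `info`).
#' @param hapA,hapB integer allele-index matrices (variants x samples).
#' @param phased logical scalar or matrix.
#' @return a `mut_vcf` object.
#' @export
make_vcf <- function(sites, hapA, hapB, phased = TRUE) {
  if (is.null(sites$id)) sites$id <- "."
  if (is.null(sites$info)) sites$info <- "."
  samples <- colnames(hapA)
  if (is.null(samples)) stop("hapA must have sample column names")
  if (length(phased) == 1L)
    phased <- matrix(phased, nrow(hapA), ncol(hapA), dimnames = dimnames(hapA))
  structure(list(sites = sites, hapA = hapA, hapB = hapB, phased = phased,
                 samples = samples), class = "mut_vcf")
}

#' @export
print.mut_vcf <- function(x, ...) {
  cat("mut_vcf:", nrow(x$sites), "sites,", length(x$samples), "samples\n")
  invisible(x)
}

#' Write a `mut_vcf` object as VCF text
#'
#' Emits a minimal VCF 4.2 file with GT genotypes (phased separator where the
#' phase matrix says so). Contig lengths are written when supplied.
#'
#' @param vcf a `mut_vcf` object.
#' @param path output path (plain text; use a `.vcf` name).
#' @param contig_lengths optional named vector of chromosome lengths.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=mutspectra-", as.character(packageVersion("mutspectra"))))
  if (!is.null(contig_lengths))
    hdr <- c(hdr, paste0("##contig=<ID=", names(contig_lengths),
                         ",length=", contig_lengths, ">"))
  hdr <- c(hdr,
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##INFO=<ID=DAF,Number=1,Type=Float,Description="Derived allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vcf$samples), collapse = "\t"))
  sep <- ifelse(vcf$phased, "|", "/")
  a1 <- ifelse(is.na(vcf$hapA), ".", as.character(vcf$hapA))
  a2 <- ifelse(is.na(vcf$hapB), ".", as.character(vcf$hapB))
  gt <- matrix(paste0(a1, sep, a2), nrow = nrow(vcf$sites))
  body <- paste(vcf$sites$chrom, vcf$sites$pos, vcf$sites$id, vcf$sites$ref,
                vcf$sites$alt, ".", "PASS", vcf$sites$info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
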