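#' Read alignment blocks from a MAF file
#'
#' Parses a multiple-alignment-format (MAF) file, as produced by hal2maf, and
#' extracts every block that contains both the named reference row and the
#' named ancestor row. MAF `s` lines carry `src start size strand srcSize
#' text`; `src` is matched as `"<name>.<chrom>"` (or the bare name when no dot
#' is present). Reference rows on the `-` strand are converted to forward
#' strand: the start becomes `srcSize - start - size` and both aligned texts
#' are reverse-complemented, so all returned blocks use forward-strand 0-based
#' reference coordinates.
#'
#' @param path path to a MAF file (plain text).
#' @param ref_name genome name of the reference rows.
#' @param anc_name genome name of the ancestor rows.
#' @return an object of class `maf_blocks`: a list of blocks, each a list with
#'   `ref_chrom`, `ref_start` (0-based), `ref_size`, `src_size`, `ref_text`,
#'   `anc_text`; attribute `skipped` counts blocks lacking either row.
#' @export
read_maf <- function(path, ref_name, anc_name) {
  lines <- readLines(path)
  blocks <- list()
  skipped <- 0L
  cur <- NULL
  cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$ref) || is.null(cur$anc)) {
      skipped <<- skipped + 1L
    } else {
      r <- cur$ref; a <- cur$anc
      if (nchar(r$text) != nchar(a$text))
        stop("malformed MAF block at line ", cur_line,
             ": row length mismatch (", nchar(r$text), " vs ", nchar(a$text), ")")
      ref_text <- r$text; anc_text <- a$text
      start <- r$start
      if (r$strand == "-") {
        start <- r$src_size - r$start - r$size
        ref_text <- revcomp_gapped(r$text)
        anc_text <- revcomp_gapped(a$text)
      }
      ungapped <- nchar(gsub("-", "", ref_text))
      if (ungapped != r$size)
        stop("malformed MAF block at line ", cur_line,
             ": ungapped reference length ", ungapped,
             " does not match stated size ", r$size)
      blocks[[length(blocks) + 1L]] <<- list(
        ref_chrom = r$chrom, ref_start = start, ref_size = r$size,
        src_size = r$src_size, ref_text = ref_text, anc_text = anc_text)
    }
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^a", ln)) {
      flush()
      cur <- list()
      cur_line <- i
    } else if (grepl("^s", ln) && !is.null(cur)) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7) stop("malformed MAF 's' line at line ", i)
      src <- f[2]
      name <- sub("\\..*$", "", src)
      chrom <- if (grepl("\\.", src)) sub("^[^.]*\\.", "", src) else src
      row <- list(chrom = chrom, start = as.integer(f[3]),
                  size = as.integer(f[4]), strand = f[5],
                  src_size = as.integer(f[6]), text = toupper(f[7]))
      if (name == ref_name) cur$ref <- row
      if (name == anc_name) cur$anc <- row
    }
  }
  flush()
  structure(blocks, class = "maf_blocks", skipped = skipped)
}

# reverse-complement an aligned (gapped) string, preserving gap columns in
# mirrored positions
revcomp_gapped <- function(x) {
  ch <- rev(strsplit(x, "")[[1]])
  gap <- ch == "-"
  ch[!gap] <- unname(COMPLEMENT[ch[!gap]])
  paste0(ch, collapse = "")
}

#' Write alignment blocks as a MAF file
#'
#' Emits `maf_blocks` (or the bare list form produced by [sim_maf()]) as MAF
#' text. The ancestor row is written with dummy coordinates (its text is the
#' only part consumed downstream).
#'
#' @param blocks a `maf_blocks` object.
#' @param path output path.
#' @param ref_name,anc_name genome names to write in the `src` fields.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path, ref_name = "ref", anc_name = "anc") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    anc_ungapped <- nchar(gsub("-", "", b$anc_text))
    writeLines(c(
      "a score=0",
      paste("s", paste0(ref_name, ".", b$ref_chrom), b$ref_start, b$ref_size,
            "+", b$src_size, b$ref_text),
      paste("s", paste0(anc_name, ".", b$ref_chrom), 0L, anc_ungapped,
            "+", anc_ungapped, b$anc_text),
      ""), con)
  }
  invisible(path)
}

#' Build an ancestral genome from alignment blocks
#'
#' Assigns an ancestral base to every reference position from the aligned
#' ancestor rows. Each covering block casts one vote per position: the aligned
#' ancestor base (uppercased; anything outside `{A,C,G,T}`, including an
#' alignment gap, votes `N`). A position receives a base only when that base
#' is the unique modal vote and is in `{A,C,G,T}`; positions with no covering
#' block, a tied vote, or an `N`-modal vote receive `N`.
#'
#' @param blocks a `maf_blocks` object (see [read_maf()]).
#' @param reference_lengths named integer vector of chromosome lengths; when
#'   `NULL`, lengths are taken from the blocks' `srcSize` fields.
#' @return a [Biostrings::DNAStringSet] of per-chromosome ancestral sequences
#'   in reference coordinates, over `{A,C,G,T,N}`.
#' @export
build_ancestral <- function(blocks, reference_lengths = NULL) {
  if (is.null(reference_lengths)) {
    reference_lengths <- integer(0)
    for (b in blocks) {
      if (is.null(reference_lengths[b$ref_chrom]) ||
          is.na(reference_lengths[b$ref_chrom]))
        reference_lengths[b$ref_chrom] <- b$src_size
    }
    if (length(reference_lengths) == 0L)
      stop("no blocks and no reference_lengths given")
  }
  symbols <- c(BASES, "N")
  votes <- lapply(reference_lengths, function(L)
    matrix(0L, nrow = L, ncol = 5L, dimnames = list(NULL, symbols)))
  for (b in blocks) {
    if (!b$ref_chrom %in% names(votes))
      stop("block on unknown chromosome: ", b$ref_chrom)
    L <- reference_lengths[[b$ref_chrom]]
    if (b$ref_start + b$ref_size > L)
      stop("block on ", b$ref_chrom, " extends beyond chromosome length ", L)
    rch <- strsplit(b$ref_text, "")[[1]]
    ach <- strsplit(b$anc_text, "")[[1]]
    ungapped <- rch != "-"
    pos <- b$ref_start + cumsum(ungapped)  # 1-based reference positions
    pos <- pos[ungapped]
    anc <- ach[ungapped]
    anc[!anc %in% BASES] <- "N"
    idx <- cbind(pos, match(anc, symbols))
    v <- votes[[b$ref_chrom]]
    # accumulate (positions may repeat within a block only via gaps, which are
    # excluded, so plain assignment-with-increment is safe per block)
    for (s in seq_len(5L)) {
      sel <- idx[idx[, 2] == s, 1]
      if (length(sel)) {
        tab <- tabulate(sel, nbins = nrow(v))
        v[, s] <- v[, s] + tab
      }
    }
    votes[[b$ref_chrom]] <- v
  }
  seqs <- vapply(names(votes), function(chrom) {
    v <- votes[[chrom]]
    tot <- rowSums(v)
    mx <- do.call(pmax, as.data.frame(v))
    nties <- rowSums(v == mx)
    win <- max.col(v, ties.method = "first")
    base <- symbols[win]
    base[tot == 0L | nties > 1L | base == "N"] <- "N"
    paste0(base, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(votes)))
}

#' Ancestral coverage report
#'
#' Fraction of non-`N` bases per chromosome and genome-wide, computed exactly
#' as `covered / length`.
#'
#' @param ancestral a [Biostrings::DNAStringSet] ancestral genome.
#' @return a `data.frame` with columns `chrom`, `length`, `covered`,
#'   `fraction`; the final row (`chrom == "TOTAL"`) is genome-wide.
#' @export
coverage_report <- function(ancestral) {
  lens <- Biostrings::width(ancestral)
  ncount <- as.integer(Biostrings::letterFrequency(ancestral, "N"))
  covered <- lens - ncount
  df <- data.frame(chrom = names(ancestral), length = lens, covered = covered,
                   fraction = covered / lens, stringsAsFactors = FALSE)
  rbind(df, data.frame(chrom = "TOTAL", length = sum(lens),
                       covered = sum(covered),
                       fraction = sum(covered) / sum(lens)))
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet], names truncated at the first space.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
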