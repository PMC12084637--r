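#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with the package's
#' default study conditions: a 10 kb single-chromosome genome at GC 0.42,
#' two populations of 5 diploids, ~500 SNV sites with a neutral-like (1/x)
#' derived-allele-frequency distribution, a minimum of 3 derived copies per
#' site (so default sites pass the MAC filter), 10% of sites with the
#' reference carrying the derived allele, and no injected adjacent pairs.
#'
#' @param chrom_length length of each chromosome (>= 1000).
#' @param n_chrom number of chromosomes.
#' @param gc GC fraction of the ancestral genome.
#' @param samples_per_pop named integer vector, population -> diploid count.
#' @param k K-mer size of the rate table channels (odd).
#' @param n_sites expected total SNV site count across the cohort.
#' @param rate_table named list population -> named nonnegative vector over
#'   [snv_channels()] of relative per-target mutation rates; `NULL` means
#'   all channels rate 1 in every population.
#' @param min_copies minimum derived allele copies per site.
#' @param daf_dist `"neutral"` (discretised 1/x) or `"uniform"` copy counts.
#' @param ref_flip_frac fraction of sites where the reference genome carries
#'   the derived allele (REF = derived, ALT = ancestral).
#' @param fixed_diff_rate per-base probability of a fixed ancestral/reference
#'   substitution at non-variant positions.
#' @param pulse optional list (`population`, `channel`, `multiplier`,
#'   `daf_max`): adds `(multiplier - 1)` times the baseline expected sites of
#'   one channel to one population, confined to population DAF below
#'   `daf_max` (a low-frequency mutation pulse).
#' @param sdm list (`n_mnp`, `n_sdm`): numbers of adjacent variant pairs to
#'   inject as single-event MNPs (identical haplotype carriage) and
#'   two-event SDMs (nested carriage, distinct DAFs).
#' @param seed integer seed fixing every draw.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(chrom_length = 10000, n_chrom = 1, gc = 0.42,
                       samples_per_pop = c(pop1 = 5, pop2 = 5), k = 3,
                       n_sites = 500, rate_table = NULL, min_copies = 3,
                       daf_dist = c("neutral", "uniform"),
                       ref_flip_frac = 0.1, fixed_diff_rate = 0.002,
                       pulse = NULL, sdm = list(n_mnp = 0, n_sdm = 0),
                       seed = 1) {
  daf_dist <- match.arg(daf_dist)
  stopifnot(chrom_length >= 1000, n_chrom >= 1, gc > 0, gc < 1,
            all(samples_per_pop >= 2), k %% 2 == 1)
  if (is.null(rate_table)) {
    ch <- snv_channels(k)
    rate_table <- lapply(samples_per_pop, function(n)
      setNames(rep(1, length(ch)), ch))
    names(rate_table) <- names(samples_per_pop)
  }
  stopifnot(all(unlist(rate_table) >= 0))
  structure(list(chrom_length = chrom_length, n_chrom = n_chrom, gc = gc,
                 samples_per_pop = samples_per_pop, k = k, n_sites = n_sites,
                 rate_table = rate_table, min_copies = min_copies,
                 daf_dist = daf_dist, ref_flip_frac = ref_flip_frac,
                 fixed_diff_rate = fixed_diff_rate, pulse = pulse, sdm = sdm,
                 seed = seed),
            class = "sim_config")
}

#' Load a simulation configuration from YAML
#' @param path YAML file whose keys match the [sim_config()] arguments.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$samples_per_pop)) y$samples_per_pop <- unlist(y$samples_per_pop)
  if (!is.null(y$rate_table)) y$rate_table <- lapply(y$rate_table, unlist)
  do.call(sim_config, y)
}

#' Simulate an ancestral genome (and a diverged reference)
#'
#' Draws an ancestral genome at the configured GC fraction and derives a
#' reference genome by substituting a random different base at fixed sites
#' (per-base probability `fixed_diff_rate`). The substitution truth table is
#' returned. When called from [sim_cohort()] the reference is further patched
#' at ref-flipped variant sites.
#'
#' @param config a [sim_config()].
#' @param seed optional seed (set only when non-`NULL`, so the orchestrating
#'   [sim_cohort()] seed governs every draw).
#' @return list with `ancestral`, `reference` ([Biostrings::DNAStringSet]),
#'   `substitutions` (data.frame `chrom`, `pos`, `anc`, `ref`).
#' @export
sim_ancestral <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  anc <- list(); ref <- list(); subs <- list()
  for (chrom in chroms) {
    bases <- sample(BASES, config$chrom_length, replace = TRUE, prob = p)
    rbases <- bases
    hit <- which(runif(config$chrom_length) < config$fixed_diff_rate)
    if (length(hit)) {
      rbases[hit] <- vapply(bases[hit], function(b)
        sample(setdiff(BASES, b), 1L), character(1))
      subs[[chrom]] <- data.frame(chrom = chrom, pos = hit, anc = bases[hit],
                                  ref = rbases[hit], stringsAsFactors = FALSE)
    }
    anc[[chrom]] <- paste0(bases, collapse = "")
    ref[[chrom]] <- paste0(rbases, collapse = "")
  }
  list(ancestral = Biostrings::DNAStringSet(unlist(anc)),
       reference = Biostrings::DNAStringSet(unlist(ref)),
       substitutions = if (length(subs)) do.call(rbind, subs)
       else data.frame(chrom = character(0), pos = integer(0),
                       anc = character(0), ref = character(0)))
}

# table of genome positions with a valid k-window: chrom, pos, ctx (collapsed
# context), flip (TRUE when the forward-strand central base is G/T)
eligible_positions <- function(ancestral, k) {
  f <- (k - 1L) / 2L
  out <- list()
  for (chrom in names(ancestral)) {
    s <- as.character(ancestral[[chrom]])
    L <- nchar(s)
    if (L < k) next
    pos <- (f + 1L):(L - f)
    km <- substring(s, pos - f, pos + f)
    ok <- !grepl("[^ACGT]", km)
    central <- substr(km[ok], f + 1L, f + 1L)
    out[[chrom]] <- data.frame(chrom = chrom, pos = pos[ok],
                               ctx = collapse_kmer(km[ok]),
                               flip = central %in% c("G", "T"),
                               stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# draw derived-copy counts: neutral-like 1/x or uniform over [lo, hi]
draw_copies <- function(n, lo, hi, dist) {
  if (hi < lo) stop("population too small for the requested copy range")
  supp <- lo:hi
  pr <- if (dist == "neutral") 1 / supp else rep(1, length(supp))
  supp[sample.int(length(supp), n, replace = TRUE, prob = pr)]
}

# haplotype bookkeeping: populations own contiguous sample (and haplotype)
# column ranges in cohort matrices
pop_layout <- function(samples_per_pop) {
  pops <- names(samples_per_pop)
  ends <- cumsum(samples_per_pop)
  starts <- ends - samples_per_pop + 1L
  samples <- unlist(lapply(pops, function(p)
    paste0(p, "_s", seq_len(samples_per_pop[[p]]))))
  list(pops = pops, starts = setNames(starts, pops), ends = setNames(ends, pops),
       samples = samples, n_total = sum(samples_per_pop))
}

#' Simulate a truth-tracked population cohort
#'
#' The master generator: draws an ancestral genome, places SNV sites per
#' population from the channel rate table (expected counts proportional to
#' rate times ancestral target abundance), injects adjacent MNP/SDM variant
#' pairs, assigns phased genotypes with the configured DAF distribution, and
#' assembles a multi-sample VCF plus exact truth tables. Variant placements
#' avoid adjacency except for the injected pairs, keeping SNV and SDM truth
#' independent. Everything is deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `ancestral`, `reference`, `vcf` (`mut_vcf`),
#'   `populations` (data.frame `sample`, `population`), `truth_snv`
#'   (data.frame, one row per SNV site: position, channel, population, copy
#'   count, population DAF, carrier haplotype columns as a comma-separated
#'   string), `truth_sdm` (one row per injected pair).
#' @export
sim_cohort <- function(config) {
  set.seed(config$seed)
  g <- sim_ancestral(config, seed = NULL)
  ancestral <- g$ancestral
  lay <- pop_layout(config$samples_per_pop)
  elig <- eligible_positions(ancestral, config$k)
  lens <- setNames(Biostrings::width(ancestral), names(ancestral))
  used <- lapply(lens, function(L) logical(L))
  chrom_str <- setNames(as.character(ancestral), names(ancestral))
  e_chrom <- elig$chrom; e_pos <- elig$pos; e_flip <- elig$flip
  mark <- function(chrom, pos, pad = 1L) {
    lo <- max(1L, min(pos) - pad); hi <- min(lens[[chrom]], max(pos) + pad)
    used[[chrom]][lo:hi] <<- TRUE
  }
  free_at <- function(chrom, pos) {
    ok <- logical(length(pos))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      ok[sel] <- !used[[ch]][pos[sel]]
    }
    ok
  }
  free_idx <- function(idx) free_at(e_chrom[idx], e_pos[idx])

  truth_sdm <- list()
  sdm_sites <- list()
  n_mnp <- config$sdm$n_mnp %||% 0L
  n_sdm <- config$sdm$n_sdm %||% 0L
  if (n_mnp + n_sdm > 0) {
    key <- paste(elig$chrom, elig$pos)
    pairable <- which(paste(elig$chrom, elig$pos + 1L) %in% key)
    for (q in seq_len(n_mnp + n_sdm)) {
      is_sdm <- q > n_mnp
      avail <- pairable[free_idx(pairable) &
                          free_at(e_chrom[pairable], e_pos[pairable] + 1L)]
      if (!length(avail)) stop("no eligible adjacent positions left to inject")
      ii <- if (length(avail) == 1L) avail else sample(avail, 1L)
      r <- list(chrom = e_chrom[ii], pos = e_pos[ii])
      mark(r$chrom, c(r$pos, r$pos + 1L))
      pop <- sample(lay$pops, 1L)
      n2 <- 2L * config$samples_per_pop[[pop]]
      maxc <- max(config$min_copies, floor(0.97 * n2))
      anc2 <- substr(chrom_str[[r$chrom]], r$pos, r$pos + 1L)
      der2 <- paste0(vapply(strsplit(anc2, "")[[1]], function(b)
        sample(setdiff(BASES, b), 1L), character(1)), collapse = "")
      if (is_sdm) {
        if (maxc <= config$min_copies)
          stop("population too small to give SDM sites distinct DAFs")
        c1 <- draw_copies(1L, config$min_copies + 1L, maxc, config$daf_dist)
        c2 <- draw_copies(1L, config$min_copies, c1 - 1L, config$daf_dist)
        first_left <- runif(1) < 0.5
        haps1 <- sample.int(n2, c1)
        haps2 <- sample(haps1, c2)
        orderlab <- if (first_left) "left_first" else "right_first"
        copies <- if (first_left) c(c1, c2) else c(c2, c1)
        carriers <- if (first_left) list(haps1, haps2) else list(haps2, haps1)
        label <- sdm_label(anc2, der2, orderlab)
        cls <- "SDM"
      } else {
        c1 <- draw_copies(1L, config$min_copies, maxc, config$daf_dist)
        haps1 <- sample.int(n2, c1)
        copies <- c(c1, c1)
        carriers <- list(haps1, haps1)
        orderlab <- NA_character_
        label <- NA_character_
        cls <- "MNP"
      }
      truth_sdm[[length(truth_sdm) + 1L]] <- data.frame(
        chrom = r$chrom, pos = r$pos, class = cls, order = orderlab,
        channel = label, population = pop,
        anc_dinuc = anc2, der_dinuc = der2,
        copies_left = copies[1], copies_right = copies[2],
        both_copies = min(copies), stringsAsFactors = FALSE)
      for (side in 1:2) {
        sdm_sites[[length(sdm_sites) + 1L]] <- list(
          chrom = r$chrom, pos = r$pos + side - 1L, pop = pop,
          anc = substr(anc2, side, side), der = substr(der2, side, side),
          carriers = carriers[[side]])
      }
    }
  }

  # expected SNV count per (population, channel) proportional to
  # rate x ancestral target abundance, scaled so the cohort expectation is
  # n_sites
  ctx_n <- table(elig$ctx)
  channels <- names(config$rate_table[[1]])
  ctx_of <- channel_context(channels)
  lam <- vapply(lay$pops, function(p) {
    r <- config$rate_table[[p]][channels]
    r * as.numeric(ctx_n[ctx_of])
  }, numeric(length(channels)))  # channels x pops
  lam <- matrix(lam, nrow = length(channels))
  lam[is.na(lam)] <- 0
  if (sum(lam) == 0) stop("rate table is all zero")
  theta <- config$n_sites / sum(lam)
  snv_rows <- list()
  elig_by_ctx <- split(seq_len(nrow(elig)), elig$ctx)
  for (pi in seq_along(lay$pops)) {
    pop <- lay$pops[pi]
    n2 <- 2L * config$samples_per_pop[[pop]]
    maxc <- max(config$min_copies, floor(0.97 * n2))
    for (ci in seq_along(channels)) {
      chn <- channels[ci]
      n_draw <- stats::rpois(1L, theta * lam[ci, pi])
      n_extra <- 0L
      if (!is.null(config$pulse) && config$pulse$population == pop &&
          config$pulse$channel == chn) {
        n_extra <- stats::rpois(1L, (config$pulse$multiplier - 1) *
                                  theta * lam[ci, pi])
      }
      if (n_draw + n_extra == 0L) next
      need <- n_draw + n_extra
      pool <- elig_by_ctx[[ctx_of[ci]]]
      pick <- integer(0)
      # accept draws one batch at a time, marking as we go so that two draws
      # from the same batch can never end up adjacent
      while (length(pick) < need) {
        pool <- pool[free_idx(pool)]
        if (length(pool) < need - length(pick))
          stop("requested sites exceed eligible positions for context ",
               ctx_of[ci])
        cand <- if (length(pool) <= need - length(pick)) pool
        else sample(pool, need - length(pick))
        for (p1 in cand) {
          if (!used[[e_chrom[p1]]][e_pos[p1]]) {
            mark(e_chrom[p1], e_pos[p1])
            pick <- c(pick, p1)
          }
        }
        pool <- setdiff(pool, cand)
      }
      der_col <- substr(chn, regexpr(">", chn) + 1L, regexpr(">", chn) + 1L)
      if (grepl("\\[", chn)) {
        mm <- regexec("\\[([ACGT])>([ACGT])\\]", chn)[[1]]
        der_col <- substr(chn, mm[3], mm[3])
      }
      pulse_hi <- if (n_extra > 0)
        max(config$min_copies, floor(config$pulse$daf_max * n2))
      for (ri in seq_along(pick)) {
        p1 <- pick[ri]
        copies <- if (ri <= n_draw)
          draw_copies(1L, config$min_copies, maxc, config$daf_dist)
        else  # pulse sites: confined to low population DAF
          draw_copies(1L, config$min_copies, pulse_hi, config$daf_dist)
        der <- if (e_flip[p1]) comp_base(der_col) else der_col
        snv_rows[[length(snv_rows) + 1L]] <- list(
          chrom = e_chrom[p1], pos = e_pos[p1], pop = pop, channel = chn,
          anc = substr(chrom_str[[e_chrom[p1]]], e_pos[p1], e_pos[p1]),
          der = der, carriers = sample.int(n2, copies),
          pulse = ri > n_draw)
      }
    }
  }
  for (s in sdm_sites) {
    # injected pair sites also contribute to the SNV truth, under the channel
    # their own ancestral context implies
    f <- (config$k - 1L) / 2L
    km <- substr(chrom_str[[s$chrom]], s$pos - f, s$pos + f)
    chn <- NA_character_
    if (nchar(km) == config$k && !grepl("[^ACGT]", km)) {
      der <- s$der
      if (substr(km, f + 1L, f + 1L) %in% c("G", "T")) {
        km <- revcomp(km); der <- comp_base(der)
      }
      chn <- snv_channel_label(km, der)
    }
    snv_rows[[length(snv_rows) + 1L]] <- list(
      chrom = s$chrom, pos = s$pos, pop = s$pop, channel = chn,
      anc = s$anc, der = s$der, carriers = s$carriers, pulse = FALSE)
  }
  if (!length(snv_rows)) stop("simulation produced no variant sites")

  n2pop <- setNames(2L * as.integer(config$samples_per_pop), lay$pops)
  truth_snv <- data.frame(
    chrom = vapply(snv_rows, `[[`, character(1), "chrom"),
    pos = vapply(snv_rows, `[[`, integer(1), "pos"),
    population = vapply(snv_rows, `[[`, character(1), "pop"),
    channel = vapply(snv_rows, `[[`, character(1), "channel"),
    anc = vapply(snv_rows, `[[`, character(1), "anc"),
    der = vapply(snv_rows, `[[`, character(1), "der"),
    copies = vapply(snv_rows, function(r) length(r$carriers), integer(1)),
    pulse = vapply(snv_rows, `[[`, logical(1), "pulse"),
    carriers = vapply(snv_rows, function(r)
      paste(sort(r$carriers), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  truth_snv$daf_pop <- truth_snv$copies / n2pop[truth_snv$population]

  # reference alleles: mostly ancestral; a fraction flipped to the derived
  flip_ref <- runif(nrow(truth_snv)) < config$ref_flip_frac
  truth_snv$ref <- ifelse(flip_ref, truth_snv$der, truth_snv$anc)
  truth_snv$alt <- ifelse(flip_ref, truth_snv$anc, truth_snv$der)
  truth_snv$derived_is_alt <- !flip_ref

  # assemble genotypes (cohort haplotype columns; populations private)
  ord <- order(truth_snv$chrom, truth_snv$pos)
  truth_snv <- truth_snv[ord, ]
  snv_rows <- snv_rows[ord]
  nvar <- nrow(truth_snv)
  nsamp <- lay$n_total
  anc_idx <- ifelse(truth_snv$derived_is_alt, 0L, 1L)
  hapA <- matrix(rep(anc_idx, nsamp), nrow = nvar,
                 dimnames = list(NULL, lay$samples))
  hapB <- hapA
  for (i in seq_len(nvar)) {
    pop <- truth_snv$population[i]
    offset <- lay$starts[[pop]] - 1L
    h <- snv_rows[[i]]$carriers           # haplotypes 1..2n within the pop
    samp <- offset + (h + 1L) %/% 2L
    isA <- h %% 2L == 1L
    d <- 1L - anc_idx[i]
    if (any(isA)) hapA[i, samp[isA]] <- d
    if (any(!isA)) hapB[i, samp[!isA]] <- d
  }
  sites <- data.frame(chrom = truth_snv$chrom, pos = truth_snv$pos,
                      id = ".", ref = truth_snv$ref, alt = truth_snv$alt,
                      info = ".", stringsAsFactors = FALSE)
  vcf <- make_vcf(sites, hapA, hapB, phased = TRUE)

  # patch the reference genome so REF alleles match it
  reference <- g$reference
  need <- which(truth_snv$ref != substring_at(reference, truth_snv$chrom,
                                              truth_snv$pos))
  if (length(need)) {
    reference <- patch_genome(reference, truth_snv$chrom[need],
                              truth_snv$pos[need], truth_snv$ref[need])
  }
  populations <- data.frame(
    sample = lay$samples,
    population = rep(lay$pops, config$samples_per_pop),
    stringsAsFactors = FALSE)
  list(config = config, ancestral = ancestral, reference = reference,
       vcf = vcf, populations = populations, truth_snv = truth_snv,
       truth_sdm = if (length(truth_sdm)) do.call(rbind, truth_sdm)
       else data.frame())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

substring_at <- function(genome, chrom, pos) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- substring(as.character(genome[[ch]]), pos[sel], pos[sel])
  }
  out
}

patch_genome <- function(genome, chrom, pos, base) {
  seqs <- setNames(as.character(genome), names(genome))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- strsplit(seqs[[ch]], "")[[1]]
    s[pos[sel]] <- base[sel]
    seqs[[ch]] <- paste0(s, collapse = "")
  }
  Biostrings::DNAStringSet(seqs)
}

#' Build a MAF fixture aligning reference and ancestral genomes
#'
#' Emits identity-alignment blocks (no gaps) over the requested reference
#' spans, with the ancestor row taken from the ancestral genome, so
#' [build_ancestral()] on the result reconstructs the ancestral truth over
#' covered spans and `N` elsewhere. Blocks may overlap (exercising the vote
#' rule); tests can edit block texts to create gaps or conflicts.
#'
#' @param reference,ancestral [Biostrings::DNAStringSet] genomes in the same
#'   coordinates.
#' @param blocks data.frame with `chrom`, `start`, `end` (1-based inclusive
#'   reference spans); `NULL` covers every chromosome end to end.
#' @return a `maf_blocks` object (see [read_maf()]).
#' @export
sim_maf <- function(reference, ancestral, blocks = NULL) {
  lens <- setNames(Biostrings::width(reference), names(reference))
  if (is.null(blocks))
    blocks <- data.frame(chrom = names(reference), start = 1L,
                         end = as.integer(lens), stringsAsFactors = FALSE)
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$end > lens[[b$chrom]] || b$start < 1L)
      stop("block outside chromosome ", b$chrom)
    out[[i]] <- list(
      ref_chrom = b$chrom, ref_start = b$start - 1L,
      ref_size = b$end - b$start + 1L, src_size = unname(lens[[b$chrom]]),
      ref_text = substring(as.character(reference[[b$chrom]]), b$start, b$end),
      anc_text = substring(as.character(ancestral[[b$chrom]]), b$start, b$end))
  }
  structure(out, class = "maf_blocks", skipped = 0L)
}
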