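# two-sample fixture with adjacent sites at 5/6, a distant site at 9
adj_fixture <- function(hapA1 = c(1L, 0L), hapB1 = c(1L, 0L),
                        hapA2 = c(1L, 0L), hapB2 = c(0L, 0L)) {
  make_pv(chrom = rep("chr1", 3), pos = c(5L, 6L, 9L),
          anc = c("C", "A", "A"), der = c("T", "G", "C"),
          hapA = rbind(hapA1, hapA2, c(1L, 0L)),
          hapB = rbind(hapB1, hapB2, c(0L, 0L)))
}

test_that("find_adjacent_pairs emits exactly the distance-1 pairs", {
  pv <- adj_fixture()
  pairs <- find_adjacent_pairs(pv)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$pos, 5L)
  # distance 2 is not a pair
  pv2 <- make_pv(chrom = c("chr1", "chr1"), pos = c(100L, 102L),
                 anc = c("C", "C"), der = c("T", "T"),
                 hapA = rbind(c(1L, 0L), c(1L, 0L)),
                 hapB = rbind(c(0L, 0L), c(0L, 0L)))
  expect_equal(nrow(find_adjacent_pairs(pv2)), 0)
  # chromosome boundaries do not pair
  pv3 <- make_pv(chrom = c("chr1", "chr2"), pos = c(7L, 8L),
                 anc = c("C", "C"), der = c("T", "T"),
                 hapA = rbind(c(1L, 0L), c(1L, 0L)),
                 hapB = rbind(c(0L, 0L), c(0L, 0L)))
  expect_equal(nrow(find_adjacent_pairs(pv3)), 0)
})

test_that("unphased heterozygous genotypes at pairs error or drop", {
  pv <- adj_fixture()
  pv$phased[2, 1] <- FALSE      # het at site 2, sample 1
  expect_error(find_adjacent_pairs(pv), "unphased")
  expect_equal(nrow(find_adjacent_pairs(pv, unphased = "drop")), 0)
  # unphased homozygous genotypes are harmless
  pv2 <- adj_fixture()
  pv2$phased[1, 2] <- FALSE     # 0/0 genotype
  expect_equal(nrow(find_adjacent_pairs(pv2)), 1)
})

test_that("identical haplotype carriage is an MNP, nested carriage an SDM", {
  # same carriers at both sites -> MNP
  pv_mnp <- adj_fixture(hapA1 = c(1L, 0L), hapB1 = c(0L, 1L),
                        hapA2 = c(1L, 0L), hapB2 = c(0L, 1L))
  cl <- classify_pairs(pv_mnp, find_adjacent_pairs(pv_mnp))
  expect_equal(cl$class, "MNP")
  expect_true(is.na(cl$order))
  # left site on more haplotypes -> SDM, left first
  pv_sdm <- adj_fixture(hapA1 = c(1L, 1L), hapB1 = c(1L, 0L),
                        hapA2 = c(1L, 0L), hapB2 = c(0L, 0L))
  cl2 <- classify_pairs(pv_sdm, find_adjacent_pairs(pv_sdm))
  expect_equal(cl2$class, "SDM")
  expect_equal(cl2$order, "left_first")
  expect_gt(cl2$daf_left, cl2$daf_right)
  # equal DAFs on different haplotypes -> unresolved order
  pv_tie <- adj_fixture(hapA1 = c(1L, 0L), hapB1 = c(0L, 0L),
                        hapA2 = c(0L, 1L), hapB2 = c(0L, 0L))
  cl3 <- classify_pairs(pv_tie, find_adjacent_pairs(pv_tie))
  expect_equal(cl3$class, "SDM")
  expect_equal(cl3$order, "unresolved")
})

test_that("sdm_label builds the event path dictated by the order", {
  # ancestral CA -> derived TG: left change first passes through TA
  expect_equal(sdm_label("CA", "TG", "left_first"), "CA>TA>TG")
  # right change first passes through CG
  expect_equal(sdm_label("CA", "TG", "right_first"), "CA>CG>TG")
  expect_equal(sdm_label("CA", "TG", "unresolved"), "CA>*>TG")
  # canonical orientation keeps the lexicographically smaller strand reading
  set.seed(17)
  for (i in 1:200) {
    anc <- paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = "")
    der <- vapply(strsplit(anc, "")[[1]], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    der <- paste(der, collapse = "")
    ord <- sample(c("left_first", "right_first", "unresolved"), 1)
    expect_equal(sdm_label(anc, der, ord), oracle_sdm_label(anc, der, ord))
  }
})

test_that("SDM counting increments per double-carrier haplotype", {
  # sample 1: hapA carries both derived alleles -> 1; hapB only the left
  pv <- adj_fixture(hapA1 = c(1L, 0L), hapB1 = c(1L, 0L),
                    hapA2 = c(1L, 0L), hapB2 = c(0L, 0L))
  anc <- genome(chr1 = "AAAACAAAAA")
  m <- count_sdm_spectra(pv, anc)
  expect_equal(nrow(attr(m, "pairs")), 1)
  expect_equal(sum(m), 1)
  expect_equal(unname(m["s1", ]), 1)
  expect_equal(unname(m["s2", ]), 0)
  # carrying only one of the two derived alleles never increments
  pv1 <- adj_fixture(hapA1 = c(1L, 0L), hapB1 = c(0L, 0L),
                     hapA2 = c(0L, 1L), hapB2 = c(0L, 0L))
  m1 <- count_sdm_spectra(pv1, anc)
  expect_equal(sum(m1), 0)
})

test_that("injected pairs are recalled and classified at 100%", {
  sim <- default_sim()
  pv <- polarize_sites(sim$vcf, sim$ancestral)
  m <- count_sdm_spectra(pv, sim$ancestral)
  pairs <- attr(m, "pairs")
  truth <- sim$truth_sdm
  expect_equal(nrow(pairs), nrow(truth))
  key <- paste(pairs$chrom, pairs$pos)
  tkey <- paste(truth$chrom, truth$pos)
  expect_setequal(key, tkey)
  ord <- match(key, tkey)
  expect_equal(pairs$class, truth$class[ord])
  sdm <- pairs$class == "SDM"
  expect_equal(pairs$order[sdm], truth$order[ord][sdm])
  expect_equal(pairs$channel[sdm], truth$channel[ord][sdm])
  # per-channel totals match the injected double-carrier counts
  want <- tapply(truth$both_copies[truth$class == "SDM"],
                 truth$channel[truth$class == "SDM"], sum)
  expect_equal(colSums(m)[names(want)], want, ignore_attr = TRUE)
})

test_that("SDM spectra equal the brute-force haplotype oracle", {
  sim <- default_sim()
  pv <- polarize_sites(sim$vcf, sim$ancestral)
  pairs <- classify_pairs(pv, find_adjacent_pairs(pv))
  m <- count_sdm_spectra(pv, sim$ancestral, pairs = pairs)
  cells <- oracle_sdm_spectra(pv, pairs)
  got <- unclass(m)
  expect_equal(sum(got), sum(unlist(cells)))
  for (key in names(cells)) {
    parts <- strsplit(key, " ")[[1]]
    expect_equal(got[parts[1], parts[2]], cells[[key]], ignore_attr = TRUE)
  }
})

test_that("every adjacent pair is exactly one of SDM or MNP", {
  sim <- default_sim()
  pv <- polarize_sites(sim$vcf, sim$ancestral)
  pairs <- classify_pairs(pv, find_adjacent_pairs(pv))
  expect_true(all(pairs$class %in% c("SDM", "MNP")))
  expect_equal(sum(pairs$class == "SDM") + sum(pairs$class == "MNP"),
               nrow(pairs))
})

test_that("SDM labels are invariant under genome-wide reverse complementation", {
  sim <- default_sim()
  pv <- polarize_sites(sim$vcf, sim$ancestral)
  lens <- setNames(Biostrings::width(sim$ancestral), names(sim$ancestral))
  m <- count_sdm_spectra(pv, sim$ancestral)
  m_rc <- count_sdm_spectra(rc_pv(pv, lens), rc_genome(sim$ancestral))
  expect_equal(sort(colnames(m)), sort(colnames(m_rc)))
  expect_equal(unclass(m_rc)[, colnames(m)], unclass(m), ignore_attr = TRUE)
})
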