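# unit vector orthogonal to x, used to build a vector at an exact target
# cosine against x
residual_unit <- function(x) {
  y <- seq_along(x) %% 2
  y <- y - sum(y * x) / sum(x * x) * x
  y / sqrt(sum(y^2))
}

test_that("PCA separates groups differing in one channel, loading on it", {
  set.seed(2)
  base <- matrix(rnorm(20 * 10, mean = 10, sd = 0.01), 20, 10,
                 dimnames = list(paste0("s", 1:20), paste0("ch", 1:10)))
  base[1:10, 3] <- base[1:10, 3] + 5     # group shift on one channel
  p <- spectrum_pca(base, standardize = FALSE)
  expect_true(all(sign(p$scores[1:10, 1]) == sign(p$scores[1, 1])))
  expect_true(all(sign(p$scores[11:20, 1]) == -sign(p$scores[1, 1])))
  expect_equal(which.max(abs(p$loadings[, 1])), 3L, ignore_attr = TRUE)
  expect_gt(abs(p$loadings[3, 1]), 0.99)
  # variance fractions nonincreasing and summing to <= 1
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_lte(sum(p$variance_fraction), 1 + 1e-12)
})

test_that("PCA scores equal an eigendecomposition oracle up to sign", {
  set.seed(3)
  m <- matrix(rexp(12 * 8), 12, 8,
              dimnames = list(paste0("s", 1:12), paste0("ch", 1:8)))
  p <- spectrum_pca(m, standardize = TRUE)
  x <- scale(m, center = TRUE, scale = TRUE)
  ev <- eigen(crossprod(x) / (nrow(m) - 1), symmetric = TRUE)
  oracle_scores <- x %*% ev$vectors
  for (j in 1:5) {
    s <- sign(sum(p$scores[, j] * oracle_scores[, j]))
    expect_equal(unname(p$scores[, j]), unname(s * oracle_scores[, j]),
                 tolerance = 1e-8)
  }
  expect_equal(p$variance_fraction,
               (ev$values / sum(ev$values))[seq_along(p$variance_fraction)],
               tolerance = 1e-10)
  # sample reordering permutes scores (up to global sign)
  ord <- sample(nrow(m))
  p2 <- spectrum_pca(m[ord, ], standardize = TRUE)
  s <- sign(p2$scores[1, 1] * p$scores[ord, 1][1])
  expect_equal(unname(p2$scores[, 1]), unname(s * p$scores[ord, 1]),
               tolerance = 1e-8)
})

test_that("constant matrices are a zero-variance error", {
  m <- matrix(1, 3, 4)
  expect_error(spectrum_pca(m), "variance")
  expect_error(spectrum_pca(m[1, , drop = FALSE]), "two samples")
})

test_that("daf_fractions computes per-bin type fractions", {
  # 3 variants in one bin: 2 of one type, 1 of another
  pv <- make_pv(chrom = rep("chr1", 3), pos = c(10L, 20L, 30L),
                anc = rep("C", 3), der = rep("T", 3),
                hapA = rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L)),
                hapB = rbind(c(0L, 0L), c(0L, 0L), c(0L, 0L)))
  pops <- data.frame(sample = c("s1", "s2"), population = "p")
  types <- c("X", "X", "Y")
  df <- daf_fractions(pv, types, pops, edges = c(0, 0.5, 1))
  expect_equal(df$fraction[df$type == "X"], 2 / 3)
  expect_equal(df$fraction[df$type == "Y"], 1 / 3)
  expect_equal(unique(df$bin_n), 3L)
  expect_error(daf_fractions(pv, types, pops, edges = c(0.5, 0.5)),
               "strictly increasing")
})

test_that("fractions sum to one per nonempty bin and conserve counts", {
  sim <- default_sim()
  pv <- polarize_sites(sim$vcf, sim$ancestral)
  types <- mutation_types(pv, sim$ancestral, 3)
  df <- daf_fractions(pv, types, sim$populations, edges = daf_bins(6, 0.01, 0.98))
  sums <- tapply(df$fraction, paste(df$population, df$bin), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # summing fraction x bin count over bins and types conserves variant totals
  for (pop in unique(sim$populations$population)) {
    sub <- df[df$population == pop, ]
    daf <- pop_daf(pv, sim$populations$sample[sim$populations$population == pop])
    expected <- sum(!is.na(types) & daf > 0.01 & daf <= 0.98)
    per_bin <- tapply(sub$fraction * sub$bin_n, sub$bin, sum)
    expect_equal(sum(per_bin), expected, tolerance = 1e-9)
    expect_equal(sum(sub$n), expected)
  }
})

test_that("enrichment test matches the textbook chi-square", {
  # identical proportions: statistic 0, p 1
  r0 <- enrichment_test(c(a = 30, b = 70), c(a = 30, b = 70), "a")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # [[30,70],[10,90]]: hand-computed n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d)) = 12.5
  r <- enrichment_test(c(t = 30, o = 70), c(t = 10, o = 90), "t")
  expect_equal(r$statistic, 12.5, tolerance = 1e-12)
  expect_equal(r$p_value, stats::pchisq(12.5, 1, lower.tail = FALSE))
  expect_false(r$low_count)
  # symmetry in the two populations
  r_sw <- enrichment_test(c(t = 10, o = 90), c(t = 30, o = 70), "t")
  expect_equal(r_sw$statistic, r$statistic)
  # low expected counts are flagged but still computed
  r_low <- enrichment_test(c(t = 2, o = 98), c(t = 0, o = 100), "t")
  expect_true(r_low$low_count)
  expect_true(is.finite(r_low$statistic))
})

test_that("enrichment scan adjusts over channels and sorts by p", {
  set.seed(8)
  a <- setNames(rpois(20, 50), paste0("ch", 1:20))
  b <- a; b["ch7"] <- b["ch7"] * 3
  scan <- enrichment_scan(a, b)
  expect_equal(scan$type[1], "ch7")
  expect_equal(scan$p_adjusted, pmin(1, scan$p_value * 20))
  scan_bh <- enrichment_scan(a, b, adjust = "BH")
  expect_equal(scan_bh$p_adjusted, p.adjust(scan_bh$p_value, "BH"))
})

test_that("rank-1 NMF recovers an exact rank-1 factorization", {
  set.seed(12)
  sig <- runif(96); sig <- sig / sum(sig)
  expo <- runif(15, 10, 100)
  m <- outer(expo, sig)
  dimnames(m) <- list(paste0("s", 1:15), snv_channels(3))
  r <- rank1_signature(m)
  expect_equal(sum(r$signature), 1)
  expect_gt(cosine_sim(r$signature, sig), 0.999)
  expect_equal(unname(r$exposures), expo, tolerance = 1e-6)
  expect_lt(r$reconstruction_error, 1e-8 * sqrt(sum(m^2)))
  expect_error(rank1_signature(matrix(0, 2, 2)), "all-zero")
})

test_that("rank-1 NMF attains the leading-singular-pair error bound", {
  set.seed(13)
  m <- matrix(rexp(10 * 96), 10, 96,
              dimnames = list(paste0("s", 1:10), snv_channels(3)))
  r <- rank1_signature(m)
  sv <- svd(t(m))
  best <- sqrt(sum(sv$d[-1]^2))   # Frobenius error of the best rank-1 fit
  expect_lte(r$reconstruction_error, best + 1e-6)
})

test_that("cosine matching applies the 0.8 cutoff", {
  channels <- paste0("ch", 1:10)
  sig <- setNames(c(5, rep(1, 9)), channels)
  catalog <- cbind(SBSX = sig, SBSY = setNames(rep(1, 10), channels))
  r <- cosine_match(sig / sum(sig), catalog)
  expect_equal(r$match, "SBSX")
  expect_equal(r$similarity, 1)
  expect_true(r$matched)
  # orthogonal vectors score zero and do not match
  a <- setNames(c(1, 0), c("x", "y")); cat2 <- cbind(S = c(0, 1))
  rownames(cat2) <- c("x", "y")
  r2 <- cosine_match(a, cat2)
  expect_equal(r2$similarity, 0)
  expect_false(r2$matched)
  # a similarity just below the cutoff is a no-match with a named candidate
  r3 <- cosine_match(sig, catalog, cutoff = 0.8)
  sims <- r3$similarities
  expect_true(all(sims <= 1))
  mixed <- 0.79 * sig / sqrt(sum(sig^2)) +
    sqrt(1 - 0.79^2) * residual_unit(sig)
  r4 <- cosine_match(mixed, cbind(SBSX = sig), cutoff = 0.8)
  expect_equal(r4$similarity, 0.79, tolerance = 1e-10)
  expect_false(r4$matched)
  expect_true(is.na(r4$match))
  # label mismatch is an error
  bad <- catalog; rownames(bad)[1] <- "zz"
  expect_error(cosine_match(sig, bad), "labels")
})

test_that("signature catalogues round-trip through TSV", {
  channels <- sbs96_channels()
  set.seed(21)
  catalog <- cbind(SBS_A = runif(96), SBS_B = runif(96))
  rownames(catalog) <- channels
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(Type = channels, catalog, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_signature_catalog(path)
  expect_equal(back, catalog[, colnames(back)], tolerance = 1e-12)
  sig <- setNames(catalog[, 1] / sum(catalog[, 1]), channels)
  expect_equal(cosine_match(sig, back)$match, "SBS_A")
})

test_that("the bundled synthetic catalogue works end to end with as_sbs96", {
  path <- system.file("extdata", "toy_signatures_synthetic.tsv",
                      package = "mutspectra")
  catalog <- read_signature_catalog(path)
  expect_equal(rownames(catalog), sbs96_channels())
  expect_equal(unname(colSums(catalog)), rep(1, ncol(catalog)),
               tolerance = 1e-3)
  # a cohort dominated by CpG deamination matches the CpG-like entry:
  # exposures x signature, relabelled from the internal A/C-central channels
  internal <- snv_channels(3)
  y <- as_sbs96(setNames(seq_len(96), internal))  # y[j] = internal index
  sbs_label <- character(96)
  sbs_label[y] <- names(y)                        # per internal channel
  sig_internal <- setNames(catalog[sbs_label, "SYN_CPG"], internal)
  m <- outer(c(s1 = 40, s2 = 80), sig_internal)
  r <- rank1_signature(m)
  res <- cosine_match(as_sbs96(r$signature), catalog)
  expect_equal(res$match, "SYN_CPG")
  expect_gte(res$similarity, 0.999)
})
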