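test_that("pairwise TMRCA matches the analytic mean E[T2] = 2N", {
  m <- one_deme(1000)
  ac <- simulate_allele_counts(m, c(A = 1), 10000, seed = 1,
                               site_weighting = "none")
  se <- stats::sd(ac$tmrca) / sqrt(length(ac$tmrca))
  expect_lt(abs(mean(ac$tmrca) - 2000), 3 * se)
})

test_that("unfolded SFS of a constant deme is proportional to 1/i", {
  m <- one_deme(1000)
  ac <- simulate_allele_counts(m, c(A = 5), 50000, seed = 2)
  counts <- table(factor(ac$counts[, 1], levels = 1:9))
  expect_equal(sum(counts), 50000)
  p_exp <- (1 / (1:9)) / sum(1 / (1:9))
  gof <- stats::chisq.test(as.numeric(counts), p = p_exp)
  expect_gt(gof$p.value, 0.01)
})

test_that("a single haplotype cannot coalesce", {
  m <- one_deme(1000)
  expect_error(simulate_allele_counts(m, c(A = 0.5), 10, seed = 1))
  # one diploid = 2 haplotypes is fine
  expect_silent(simulate_allele_counts(m, c(A = 1), 10, seed = 1))
})

test_that("seed determinism: identical inputs give bit-identical output", {
  m <- miyako_model()
  ss <- c(OKI = 3, MYNE = 3, IKM = 3)
  a <- simulate_allele_counts(m, ss, 500, seed = 77)
  b <- simulate_allele_counts(m, ss, 500, seed = 77)
  expect_identical(a$counts, b$counts)
  expect_identical(a$tmrca, b$tmrca)
  p1 <- simulate_sites(m, ss, 200, seed = 5)
  p2 <- simulate_sites(m, ss, 200, seed = 5)
  expect_identical(p1$haps, p2$haps)
  expect_identical(p1$pos_bp, p2$pos_bp)
})

test_that("simulated panels satisfy the haplotype-panel contract", {
  m <- miyako_model()
  p <- simulate_sites(m, c(MYNE = 4, IKM = 4), 300, seed = 8)
  expect_s3_class(p, "haplotype_panel")
  expect_equal(nrow(p$haps), 16)
  expect_true(all(p$haps %in% 0:1))
  expect_false(is.unsorted(p$pos_bp, strictly = TRUE))
  expect_false(is.unsorted(p$pos_cM))
  # every site is segregating in the pooled sample
  cs <- colSums(p$haps)
  expect_true(all(cs >= 1 & cs <= nrow(p$haps) - 1))
  # panel-derived SFS marginals equal the counts route
  sf <- joint_sfs_from_panel(p)
  expect_equal(sfs_total(sf), 300)
})

test_that("joint SFS is symmetric under deme exchange for a symmetric split", {
  m <- two_deme_split(t = 100, N = 1000)
  sf <- simulate_joint_sfs(m, c(A = 5, B = 5), 30000, seed = 3)
  ct <- as.data.frame(sf$counts)
  sym <- merge(ct, ct, by.x = c("A", "B"), by.y = c("B", "A"),
               all = TRUE, suffixes = c("", "_swap"))
  sym[is.na(sym)] <- 0
  # exchange residuals behave like binomial noise: compare via z-scores
  z <- (sym$count - sym$count_swap) / sqrt(pmax(sym$count + sym$count_swap, 1))
  expect_lt(max(abs(z)), 5)
  expect_lt(abs(mean(z)), 0.2)
})

test_that("two-deme split matches expected Hudson F_ST = 1 - exp(-t/2N)", {
  t <- 60; N <- 2000
  m <- two_deme_split(t = t, N = N)
  ac <- simulate_allele_counts(m, c(A = 25, B = 25), 40000, seed = 4)
  f <- hudson_fst(ac$counts, "A", "B", n_hap = ac$n_hap)
  expected <- 1 - exp(-t / (2 * N))
  expect_lt(abs(f$fst - expected), 3 * f$se)
})

test_that("Patterson's D from the fitted model is positive for (CHB,OKI;IKM,MYNE)", {
  sf <- simulate_joint_sfs(miyako_model(),
                           c(CHB = 10, OKI = 10, MYNE = 10, MYSW = 10, IKM = 10),
                           30000, seed = 6)
  expect_gt(dstat_from_sfs(sf, c("CHB", "OKI", "IKM", "MYNE")), 0)
})

test_that("IBD truth segments tile the chromosome before thresholding", {
  tr <- ne_trajectory(rep(3000, 40))
  seg <- simulate_pairwise_ibd(tr, n_pairs = 6, chrom_length_cM = 25, seed = 4)
  tot <- tapply(seg$end_cM - seg$start_cM, seg$sample1, sum)
  expect_equal(as.numeric(tot), rep(25, 6), tolerance = 1e-9)
  expect_true(all(seg$tmrca >= 1))
  expect_true(all(seg$end_cM > seg$start_cM))
  # zero-length chromosome yields no segments
  seg0 <- simulate_pairwise_ibd(tr, n_pairs = 3, chrom_length_cM = 0, seed = 4)
  expect_equal(nrow(seg0), 0)
})

test_that("segment counts above 6 cM match the closed-form expectation", {
  tr <- ne_trajectory(rep(5000, 50))
  seg <- simulate_pairwise_ibd(tr, n_pairs = 500, chrom_length_cM = 3000,
                               seed = 5, min_emit_cM = 5)
  obs <- sum(seg$end_cM - seg$start_cM >= 6)
  expected <- expected_spectrum(tr, edges_cM = c(6, Inf), n_pairs = 500,
                                genome_length_cM = 3000)
  expect_lt(abs(obs - expected), 4 * sqrt(expected))
})

test_that("larger populations yield fewer long IBD segments", {
  n_long <- function(N, seed) {
    tr <- ne_trajectory(rep(N, 50))
    seg <- simulate_pairwise_ibd(tr, n_pairs = 30, chrom_length_cM = 500,
                                 seed = seed, min_emit_cM = 6)
    nrow(seg)
  }
  seeds <- 1:20
  big <- vapply(seeds, function(s) n_long(50000, s), numeric(1))
  small <- vapply(seeds, function(s) n_long(1000, s + 100), numeric(1))
  expect_lt(mean(big), mean(small))
})

test_that("deep-split demes share essentially no long segments", {
  m <- demographic_model(
    demes = list(A = data.frame(start = 0, end = 1e5, size = 5000),
                 B = data.frame(start = 0, end = 1e5, size = 5000),
                 R = data.frame(start = 1e5, end = Inf, size = 5000)),
    splits = data.frame(time = c(1e5, 1e5), derived = c("A", "B"),
                        ancestral = c("R", "R")),
    size_units = "diploid")
  p <- simulate_sites(m, c(A = 5, B = 5), 4000, seed = 10,
                      chrom_length_bp = 4e7)
  seg <- detect_ibd(p, min_cM = 6)
  cross <- startsWith(seg$sample1, "A") != startsWith(seg$sample2, "B")
  n_cross_pairs <- 10 * 10
  expect_lt(nrow(seg[!cross, , drop = FALSE]) / n_cross_pairs, 0.05)
})

test_that("Poisson mutation mode emits length-weighted sites with random totals", {
  m <- one_deme(1000)
  m$mutation_rate <- 1e-4   # per-locus rate so trees carry ~0.4 mutations
  ac <- simulate_allele_counts(m, c(A = 5), 4000, seed = 17,
                               mutation = "poisson", locus_bp = 1)
  expect_gt(nrow(ac$counts), 500)          # many trees emit nothing
  expect_true(all(ac$counts[, 1] >= 1 & ac$counts[, 1] <= 9))
  # singletons dominate roughly as 1/i
  frac1 <- mean(ac$counts[, 1] == 1)
  expect_gt(frac1, 0.25); expect_lt(frac1, 0.45)
})

test_that("unknown demes and invalid models are rejected", {
  m <- one_deme(500)
  expect_error(simulate_allele_counts(m, c(Z = 2), 10), "unknown")
  expect_error(simulate_pairwise_ibd(miyako_model(), "NOPE", 2, 10), "not found")
  bad <- demographic_model(
    list(A = data.frame(start = c(0, 12), end = c(10, Inf), size = 100)),
    splits = NULL)
  expect_error(simulate_allele_counts(bad, c(A = 2), 10), "invalid")
})
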