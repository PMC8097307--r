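test_that("Hudson F_ST hand-computed single-locus pieces are reproduced", {
  # p1 = p2 = 0.5, n1 = n2 = 10: num = -2 * 0.25/9, den = 0.5
  cnt <- cbind(A = c(5, 5, 5), B = c(5, 5, 5))
  f <- hudson_fst(cnt, "A", "B", n_hap = c(A = 10, B = 10),
                  blocks = c(1, 2, 3))
  expect_equal(f$fst, (-2 * 0.25 / 9) / 0.5, tolerance = 1e-12)
  # fixed opposite alleles at every locus: F_ST = 1
  cnt2 <- cbind(A = c(10, 10, 10, 10), B = c(0, 0, 0, 0))
  f2 <- hudson_fst(cnt2, "A", "B", n_hap = c(A = 10, B = 10),
                   blocks = c(1, 1, 2, 2))
  expect_equal(f2$fst, 1)
  expect_equal(f2$se, 0, tolerance = 1e-12)
})

test_that("F_ST bookkeeping: zero-denominator loci are skipped and counted", {
  cnt <- cbind(A = c(0, 10, 5, 4), B = c(0, 10, 0, 2))  # loci 1-2 fixed same
  f <- hudson_fst(cnt, "A", "B", n_hap = c(A = 10, B = 10),
                  blocks = c(1, 2, 3, 4))
  expect_equal(f$n_skipped, 2)
  expect_equal(f$n_loci, 2)
  # fewer than 2 usable loci is an error, not a number
  expect_error(hudson_fst(cnt[c(1, 2, 3), ], "A", "B",
                          n_hap = c(A = 10, B = 10), blocks = 1:3),
               "fewer than 2 usable")
})

test_that("Weir-Cockerham alternative agrees with Hudson on balanced designs", {
  m <- two_deme_split(t = 80, N = 1000)
  ac <- simulate_allele_counts(m, c(A = 20, B = 20), 20000, seed = 14)
  fh <- hudson_fst(ac$counts, "A", "B", n_hap = ac$n_hap)
  fw <- hudson_fst(ac$counts, "A", "B", n_hap = ac$n_hap, estimator = "wc")
  expect_equal(fh$fst, fw$fst, tolerance = 0.15)
})

test_that("Patterson's D hand examples and symmetries hold", {
  # single site (0, 1, 0, 1) -> d = 1
  d1 <- patterson_d(c(0, 0), c(1, 1), c(0, 0), c(1, 1), blocks = c(1, 2))
  expect_equal(d1$d, 1)
  # p3 == p4 everywhere -> d = 0 exactly
  set.seed(5)
  p1 <- runif(50); p2 <- runif(50); p3 <- runif(50)
  d0 <- patterson_d(p1, p2, p3, p3, blocks = rep(1:5, each = 10))
  expect_equal(d0$d, 0)
  # swapping P3 and P4 flips the sign, |z| unchanged
  p4 <- runif(50)
  da <- patterson_d(p1, p2, p3, p4, blocks = rep(1:5, each = 10))
  db <- patterson_d(p1, p2, p4, p3, blocks = rep(1:5, each = 10))
  expect_equal(da$d, -db$d, tolerance = 1e-12)
  expect_equal(abs(da$z), abs(db$z), tolerance = 1e-9)
  # ABBA/BABA accumulators reproduce the ratio
  expect_equal(da$d, (da$baba_sum - da$abba_sum) / (da$abba_sum + da$baba_sum),
               tolerance = 1e-12)
})

test_that("site-wise D equals D computed from the joint SFS", {
  sf <- simulate_joint_sfs(miyako_model(),
                           c(CHB = 6, OKI = 6, MYNE = 6, IKM = 6),
                           20000, seed = 9)
  ac <- simulate_allele_counts(miyako_model(),
                               c(CHB = 6, OKI = 6, MYNE = 6, IKM = 6),
                               20000, seed = 9)
  fr <- sweep(ac$counts, 2, ac$n_hap, "/")
  d_site <- patterson_d(fr[, "CHB"], fr[, "OKI"], fr[, "IKM"], fr[, "MYNE"],
                        blocks = rep(1:2, length.out = nrow(fr)))
  d_sfs <- dstat_from_sfs(sf, c("CHB", "OKI", "IKM", "MYNE"))
  expect_equal(d_site$d, d_sfs, tolerance = 1e-12)
})

test_that("D is null-calibrated: |Z| < 3 in >= 99% of symmetric-model replicates", {
  m <- symmetric_quartet()
  ss <- c(P1 = 6, P2 = 6, P3 = 6, P4 = 6)
  set.seed(1234)
  zs <- vapply(1:200, function(r) {
    ac <- simulate_allele_counts(m, ss, 3000, seed = 5000 + r)
    fr <- sweep(ac$counts, 2, ac$n_hap, "/")
    patterson_d(fr[, "P1"], fr[, "P2"], fr[, "P3"], fr[, "P4"],
                n_blocks = 50)$z
  }, numeric(1))
  expect_gte(mean(abs(zs) < 3), 0.99)
  # roughly standard-normal scale
  expect_equal(stats::sd(zs), 1, tolerance = 0.35)
})

test_that("joint SFS bookkeeping: totals, order invariance, folding", {
  # one site, 1 derived copy in A only
  cm <- matrix(c(1L, 0L), nrow = 1, dimnames = list(NULL, c("A", "B")))
  sf <- sfs_from_counts(cm, c(A = 4, B = 4))
  expect_equal(sf$counts$count[sf$counts$A == 1 & sf$counts$B == 0], 1)
  # site-order permutation leaves the SFS unchanged
  m <- two_deme_split()
  ac <- simulate_allele_counts(m, c(A = 4, B = 4), 2000, seed = 31)
  s1 <- sfs_from_counts(ac$counts, ac$n_hap)
  s2 <- sfs_from_counts(ac$counts[sample(nrow(ac$counts)), ], ac$n_hap)
  expect_equal(data.table::setkeyv(data.table::copy(s1$counts), s1$demes),
               data.table::setkeyv(data.table::copy(s2$counts), s2$demes))
  # folding is invariant to a global allele-label flip
  flipped <- sweep(-ac$counts, 2, ac$n_hap, "+")
  f1 <- fold_sfs(sfs_from_counts(ac$counts, ac$n_hap))
  f2 <- fold_sfs(sfs_from_counts(flipped, ac$n_hap))
  expect_equal(data.table::setkeyv(data.table::copy(f1$counts), f1$demes),
               data.table::setkeyv(data.table::copy(f2$counts), f2$demes))
})

test_that("ROH scan finds planted tracts and nothing in heterozygous noise", {
  # fully heterozygous genome: no ROH
  expect_equal(nrow(roh_detect(rep(1L, 3000), seq_len(3000) * 1000)), 0)
  # planted 5-Mb homozygous tract (sites every 1 kb) in a noisy background
  set.seed(21)
  S <- 12000
  pos <- seq_len(S) * 1000
  g <- rbinom(S, 2, 0.5)
  tract <- 4001:9000  # 5 Mb
  g[tract] <- ifelse(runif(5000) < 0.5, 0L, 2L)
  segs <- roh_detect(g, pos)
  expect_equal(nrow(segs), 1)
  expect_lt(abs(segs$start_bp - pos[4001]), 51 * 1000)
  expect_lt(abs(segs$end_bp - pos[9000]), 51 * 1000)
  # totals are additive over chromosomes (two identical chromosomes)
  tot2 <- sum(roh_detect(g, pos)$length_bp) + sum(roh_detect(g, pos)$length_bp)
  expect_equal(tot2, 2 * segs$length_bp)
})

test_that("recent bottlenecks increase total ROH", {
  # runs of homozygosity need linkage: each individual's two haplotypes are
  # IBD over the recent-TMRCA tracts of an SMC walk, homozygous there and
  # Hardy-Weinberg elsewhere
  roh_cohort <- function(Ne_vec, seed, n_ind = 8) {
    tr <- ne_trajectory(Ne_vec)
    truth <- simulate_pairwise_ibd(tr, n_pairs = n_ind,
                                   chrom_length_cM = 100, seed = seed)
    S <- 5000
    pos <- seq(1, by = 20000, length.out = S)   # 0.02 cM spacing, 1 cM/Mb
    cm <- pos / 1e6
    total <- 0
    for (i in seq_len(n_ind)) {
      segs <- truth[truth$sample1 == sprintf("pair%05d_a", i), ]
      set.seed(seed * 1000 + i)
      p <- runif(S, 0.1, 0.9)
      g <- rbinom(S, 2, p)
      young <- segs[segs$tmrca <= 100, , drop = FALSE]
      for (j in seq_len(nrow(young))) {
        idx <- which(cm >= young$start_cM[j] & cm < young$end_cM[j])
        g[idx] <- ifelse(runif(length(idx)) < p[idx], 2L, 0L)
      }
      total <- total + sum(roh_detect(g, pos)$length_bp)
    }
    total
  }
  const <- rep(20000, 50)
  bott <- rep(20000, 50); bott[5:15] <- 300
  seeds <- 1:10
  t_const <- vapply(seeds, function(s) roh_cohort(const, s), numeric(1))
  t_bott <- vapply(seeds, function(s) roh_cohort(bott, 100 + s), numeric(1))
  expect_gt(mean(t_bott), mean(t_const))
})

test_that("PCA separates deep splits and respects basic invariances", {
  m <- two_deme_split(t = 400, N = 1000)  # F_ST ~ 0.18
  p <- simulate_sites(m, c(A = 15, B = 15), 2000, seed = 41)
  gm <- panel_genotypes(p)
  sc <- pca_projection(gm, k = 2)
  pops <- gm$samples$population
  # PC1 separates the demes with zero overlap
  r1 <- range(sc[pops == "A", 1])
  r2 <- range(sc[pops == "B", 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])
  # duplicated sample projects to identical scores
  g2 <- rbind(gm$geno, gm$geno[1, ])
  gm2 <- toy_gm(g2, pops = c(pops, "A"))
  sc2 <- pca_projection(gm2, k = 2)
  expect_equal(unname(sc2[1, ]), unname(sc2[nrow(sc2), ]), tolerance = 1e-8)
  # site-order permutation leaves scores unchanged up to sign
  perm <- sample(ncol(gm$geno))
  gm3 <- toy_gm(gm$geno[, perm], pops = pops)
  sc3 <- pca_projection(gm3, k = 2)
  for (k in 1:2)
    expect_equal(abs(stats::cor(sc[, k], sc3[, k])), 1, tolerance = 1e-8)
  # k beyond rank errors
  expect_error(pca_projection(toy_gm(matrix(c(0L, 2L), 2, 10)), k = 2),
               "rank")
})
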