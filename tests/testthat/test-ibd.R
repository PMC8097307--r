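test_that("bp_to_cM interpolates and extrapolates linearly", {
  gm <- genetic_map(c("1", "1"), c(1e6, 2e6), c(1, 3))
  expect_equal(bp_to_cM(gm, "1", 1e6), 1)        # at an anchor
  expect_equal(bp_to_cM(gm, "1", 2e6), 3)
  expect_equal(bp_to_cM(gm, "1", 1.5e6), 2)      # interpolation
  expect_equal(bp_to_cM(gm, "1", 2.5e6), 4)      # terminal-rate extrapolation
  expect_equal(bp_to_cM(gm, "1", 0.5e6), 0)      # leading extrapolation
  expect_error(bp_to_cM(gm, "7", 1e6), "not in map")
})

test_that("genetic maps round-trip through 3-column and PLINK formats", {
  gm <- genetic_map(rep("2", 3), c(1e5, 5e5, 2e6), c(0, 0.6, 2.2))
  f <- tempfile(fileext = ".tsv")
  write_genetic_map(gm, f)
  gm2 <- read_genetic_map(f)
  expect_equal(gm2$anchors, gm$anchors)
  # PLINK .map: chrom, id, cM, bp
  fp <- tempfile(fileext = ".map")
  writeLines(c("2\tsnp1\t0\t100000", "2\tsnp2\t0.6\t500000",
               "2\tsnp3\t2.2\t2000000"), fp)
  gm3 <- read_genetic_map(fp)
  expect_equal(gm3$anchors$pos_cM, gm$anchors$pos_cM)
  unlink(c(f, fp))
})

test_that("identical haplotypes are detected as one near-full-length segment", {
  p <- planted_panel(n_hap = 8, n_sites = 5000, plant =
                       list(list(h1 = 1, h2 = 5, from = 1, to = 5000)),
                     seed = 2)
  seg <- detect_ibd(p, min_cM = 6)
  expect_equal(nrow(seg), 1)
  expect_gt((seg$end_cM - seg$start_cM) / diff(range(p$pos_cM)), 0.99)
  expect_equal(seg$sample1, "s01")
  expect_equal(seg$sample2, "s03")
})

test_that("a planted 8 cM tract is recovered with endpoint error < 0.5 cM", {
  # 50 cM chromosome at 1 site / 0.01 cM; tract spans 20-28 cM
  p <- planted_panel(n_hap = 8, n_sites = 5000, plant =
                       list(list(h1 = 1, h2 = 3, from = 2001, to = 2800)),
                     seed = 7)
  seg <- detect_ibd(p, min_cM = 6)
  expect_equal(nrow(seg), 1)
  expect_lt(abs(seg$start_cM - 20), 0.5)
  expect_lt(abs(seg$end_cM - 28), 0.5)
  expect_equal(seg$hap1, 1L)
  expect_equal(seg$hap2, 1L)
})

test_that("detector recall/precision >= 0.9 on many planted tracts with discordance", {
  # 30 independent pairs, each with one planted 8-12 cM tract carrying a
  # 0.2% discordance rate; site density 1 / 0.02 cM
  set.seed(99)
  n_pairs <- 30
  S <- 2500  # 50 cM at 0.02 cM spacing
  plants <- list()
  truth <- list()
  for (i in seq_len(n_pairs)) {
    len <- sample(400:600, 1)           # 8-12 cM in sites
    from <- sample(200:(S - len - 200), 1)
    h1 <- 4 * (i - 1) + 1
    h2 <- 4 * (i - 1) + 3              # hap 1 of the pair's second sample
    plants[[i]] <- list(h1 = h1, h2 = h2, from = from, to = from + len - 1)
    truth[[i]] <- c(from, from + len - 1)
  }
  p <- planted_panel(n_hap = 4 * n_pairs, n_sites = S, spacing_cM = 0.02,
                     plant = plants, seed = 100, discord_rate = 0.002)
  seg <- detect_ibd(p, min_cM = 6)
  hap_of <- function(s, h) 2 * (match(s, p$samples$sample_id) - 1) + h
  hits <- 0; false <- 0
  matched <- logical(n_pairs)
  for (j in seq_len(nrow(seg))) {
    a <- hap_of(seg$sample1[j], seg$hap1[j])
    b <- hap_of(seg$sample2[j], seg$hap2[j])
    hit <- FALSE
    for (i in seq_len(n_pairs)) {
      pl <- plants[[i]]
      if (a == pl$h1 && b == pl$h2) {
        tr_s <- p$pos_cM[pl$from]; tr_e <- p$pos_cM[pl$to]
        ov <- min(seg$end_cM[j], tr_e) - max(seg$start_cM[j], tr_s)
        if (ov > 0.5 * (tr_e - tr_s)) {
          hit <- TRUE; matched[i] <- TRUE
          expect_lt(abs(seg$start_cM[j] - tr_s), 0.5)
          expect_lt(abs(seg$end_cM[j] - tr_e), 0.5)
        }
      }
    }
    if (!hit) false <- false + 1
  }
  recall <- mean(matched)
  precision <- 1 - false / max(1, nrow(seg))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("segment merging follows the gap rules and is idempotent", {
  seg1 <- data.frame(sample1 = "a", sample2 = "b", hap1 = 1L, hap2 = 1L,
                     chrom = "1", start_bp = 1, end_bp = 4e6,
                     start_cM = 0, end_cM = 4, n_discordant = 0L,
                     stringsAsFactors = FALSE)
  # one segment: unchanged
  expect_equal(merge_segments(seg1), seg1)
  # two 4-cM segments, 0.4 cM clean gap -> one 8.4 cM segment
  seg2 <- rbind(seg1, within(seg1, {
    start_cM <- 4.4; end_cM <- 8.4; start_bp <- 4.4e6; end_bp <- 8.4e6
  }))
  mg <- merge_segments(seg2)
  expect_equal(nrow(mg), 1)
  expect_equal(mg$end_cM - mg$start_cM, 8.4)
  # a 2-cM gap is not merged
  seg3 <- rbind(seg1, within(seg1, {
    start_cM <- 6; end_cM <- 10; start_bp <- 6e6; end_bp <- 10e6
  }))
  expect_equal(nrow(merge_segments(seg3)), 2)
  # merge then re-threshold is idempotent
  mg2 <- merge_segments(mg)
  expect_equal(mg2, mg)
  # different haplotype pairs never merge
  seg4 <- rbind(seg1, within(seg1, { hap2 <- 2L; start_cM <- 4.2; end_cM <- 8 }))
  expect_equal(nrow(merge_segments(seg4)), 2)
})

test_that("gap discordance vetoes merging when a panel is supplied", {
  p <- planted_panel(n_hap = 4, n_sites = 1000, spacing_cM = 0.01, seed = 3)
  # force haplotypes 1 and 3 identical except a dirty 0.3 cM gap at 5 cM
  p$haps[3, ] <- p$haps[1, ]
  gap <- 490:520
  p$haps[3, gap] <- 1L - p$haps[1, gap]
  seg <- detect_ibd(p, min_cM = 2)
  expect_equal(nrow(seg), 2)
  merged <- merge_segments(seg, max_gap_cM = 0.6, max_gap_discordant = 1,
                           panel = p)
  expect_equal(nrow(merged), 2)  # 31 discordant sites in the gap: no merge
  merged2 <- merge_segments(seg, max_gap_cM = 0.6, max_gap_discordant = 100,
                            panel = p)
  expect_equal(nrow(merged2), 1)
})

test_that("sharing index matches the worked example and its symmetries", {
  # n = 2, m = 2, every cross pair shares exactly 10 cM -> (40/4)*100 = 1000
  seg <- expand.grid(sample1 = c("i1", "i2"), sample2 = c("j1", "j2"),
                     stringsAsFactors = FALSE)
  seg$hap1 <- 1L; seg$hap2 <- 1L; seg$chrom <- "1"
  seg$start_bp <- 1; seg$end_bp <- 1e7
  seg$start_cM <- 0; seg$end_cM <- 10; seg$n_discordant <- 0L
  si <- sharing_index(seg, c("i1", "i2"), c("j1", "j2"))
  expect_equal(si$index, 1000)
  # symmetry in (I, J)
  si2 <- sharing_index(seg, c("j1", "j2"), c("i1", "i2"))
  expect_equal(si2$index, si$index)
  # sample-order invariance
  si3 <- sharing_index(seg, c("i2", "i1"), c("j2", "j1"))
  expect_equal(si3$index, si$index)
  # linearity: doubling every segment length doubles the index
  seg2 <- seg; seg2$end_cM <- 20
  expect_equal(sharing_index(seg2, c("i1", "i2"), c("j1", "j2"))$index,
               2 * si$index)
  # no segments -> 0
  expect_equal(sharing_index(seg[0, ], "a", "b")$index, 0)
  expect_error(sharing_index(seg, character(0), "b"), "empty")
  expect_error(sharing_index(seg, c("i1", "x"), c("x", "j1")), "disjoint")
  # within-population mode divides by n(n-1)/2
  segw <- seg[1, ]; segw$sample1 <- "i1"; segw$sample2 <- "i2"
  siw <- sharing_index(segw, c("i1", "i2", "i3"), c("i1", "i2", "i3"))
  expect_equal(siw$index, 10 / 3 * 100)
})

test_that("detection against SMC truth: recall and precision >= 0.9 at 6 cM", {
  # haplotype pairs whose shared tracts are the >= 6 cM truth segments of an
  # SMC walk under a small constant population (N = 400 so such tracts are
  # common); pair i shares between hap 1 of samples s(2i-1) and s(2i)
  n_pairs <- 20
  tr <- ne_trajectory(rep(150, 50))
  truth <- simulate_pairwise_ibd(tr, n_pairs = n_pairs, chrom_length_cM = 200,
                                 seed = 13, min_emit_cM = 6)
  set.seed(14)
  S <- 10000
  freq <- runif(S, 0.05, 0.95)
  n_hap <- 4 * n_pairs
  haps <- matrix(rbinom(n_hap * S, 1, rep(freq, each = n_hap)), nrow = n_hap)
  pos_cM <- seq(0.02, by = 0.02, length.out = S)
  truth$row1 <- 4 * (as.integer(sub("pair(\\d+)_a", "\\1", truth$sample1)) - 1) + 1
  truth$row2 <- truth$row1 + 2
  for (j in seq_len(nrow(truth))) {
    idx <- which(pos_cM >= truth$start_cM[j] & pos_cM < truth$end_cM[j])
    haps[truth$row2[j], idx] <- haps[truth$row1[j], idx]
  }
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n_hap / 2)),
                        population = "A", stringsAsFactors = FALSE)
  panel <- haplotype_panel(haps, samples, "1", round(pos_cM * 1e6), pos_cM)
  seg <- detect_ibd(panel, min_cM = 6)
  hap_of <- function(s, h) 2 * (match(s, samples$sample_id) - 1) + h
  matched_truth <- logical(nrow(truth))
  n_false <- 0
  for (j in seq_len(nrow(seg))) {
    a <- hap_of(seg$sample1[j], seg$hap1[j])
    b <- hap_of(seg$sample2[j], seg$hap2[j])
    hit <- FALSE
    for (k in seq_len(nrow(truth))) {
      if (a == truth$row1[k] && b == truth$row2[k]) {
        ov <- min(seg$end_cM[j], truth$end_cM[k]) -
          max(seg$start_cM[j], truth$start_cM[k])
        if (ov > 0.5 * (truth$end_cM[k] - truth$start_cM[k])) {
          hit <- TRUE; matched_truth[k] <- TRUE
        }
      }
    }
    if (!hit) n_false <- n_false + 1
  }
  expect_gt(nrow(truth), 5)  # the design actually exercises the check
  expect_gte(mean(matched_truth), 0.9)
  expect_gte(1 - n_false / max(1, nrow(seg)), 0.9)
})
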