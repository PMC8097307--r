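test_that("expected spectrum reproduces the hand-computed single-generation term", {
  # g = 10, L = 30 Morgans, bin [6 cM, Inf): L * 2g * exp(-2g*0.06) = 180.72
  # the g = 10 term of the full sum carries weight P(10)
  N <- 5000
  tr <- ne_trajectory(rep(N, 10))
  P <- (1 / (2 * N)) * (1 - 1 / (2 * N))^(0:9)
  hand_g10 <- 30 * 2 * 10 * exp(-2 * 10 * 0.06)
  expect_equal(hand_g10, 600 * exp(-1.2), tolerance = 1e-12)
  full <- expected_spectrum(tr, edges_cM = c(6, Inf), n_pairs = 1,
                            genome_length_cM = 3000)
  # subtracting all non-g10 terms leaves P(10) * hand term
  tr9 <- ne_trajectory(rep(N, 10))
  manual <- sum(P * (3000 / 100) * 2 * (1:10) * exp(-2 * (1:10) * 0.06))
  expect_equal(full, manual, tolerance = 1e-10)
  expect_equal(P[10] * hand_g10, manual -
                 sum(P[-10] * 30 * 2 * (1:10)[-10] * exp(-2 * (1:10)[-10] * 0.06)),
               tolerance = 1e-10)
})

test_that("expected counts vanish as population sizes grow to infinity", {
  tr <- ne_trajectory(rep(1e12, 50))
  e <- expected_spectrum(tr, n_pairs = 1000, genome_length_cM = 3000)
  expect_lt(sum(e), 1e-4)
})

test_that("expected counts decrease in every per-generation size (finite differences)", {
  base <- rep(3000, 30)
  tr0 <- ne_trajectory(base)
  e0 <- sum(expected_spectrum(tr0, n_pairs = 100, genome_length_cM = 3000))
  for (g in c(1, 5, 15, 30)) {
    Ne <- base; Ne[g] <- Ne[g] * 1.5
    eg <- sum(expected_spectrum(ne_trajectory(Ne), n_pairs = 100,
                                genome_length_cM = 3000))
    expect_lt(eg, e0)
  }
})

test_that("bins below the detection threshold are rejected", {
  tr <- ne_trajectory(rep(5000, 50))
  expect_error(expected_spectrum(tr, edges_cM = c(4, 6, Inf), n_pairs = 10,
                                 genome_length_cM = 100), "threshold")
})

test_that("expected spectrum matches Monte-Carlo segment counts", {
  tr <- ne_trajectory(rep(5000, 50))
  seg <- simulate_pairwise_ibd(tr, n_pairs = 300, chrom_length_cM = 3000,
                               seed = 55, min_emit_cM = 5)
  sp <- segment_spectrum(seg, edges_cM = c(6, 8, 10, 14, 20, Inf),
                         n_pairs = 300, genome_length_cM = 3000)
  expe <- expected_spectrum(tr, sp$edges_cM, 300, 3000)
  for (b in seq_along(expe))
    expect_lt(abs(sp$counts[b] - expe[b]), 3 * sqrt(expe[b]) + 3)
})

test_that("fit_ne is self-consistent on a noiseless expected spectrum", {
  # spectrum set exactly to the model expectation: the optimum reproduces
  # the expectations themselves (the trajectory is only weakly identified
  # per generation, so compare in observation space plus a summary)
  tr_true <- ne_trajectory(round(seq(8000, 3000, length.out = 50)))
  edges <- c(seq(6, 30, 2), Inf)
  E <- expected_spectrum(tr_true, edges, n_pairs = 2000,
                         genome_length_cM = 3000)
  sp <- structure(list(edges_cM = edges, counts = E, n_pairs = 2000,
                       genome_length_cM = 3000), class = "segment_spectrum")
  fit <- fit_ne(sp, G = 50)
  expect_true(fit$converged)
  Ef <- expected_spectrum(fit, edges, 2000, 3000)
  expect_lt(max(abs(Ef - E) / pmax(E, 1)), 0.02)
  hm <- function(x) 1 / mean(1 / x)
  expect_equal(hm(fit$Ne[4:50]), hm(tr_true$Ne[4:50]), tolerance = 0.02)
})

test_that("constant N = 5000 is recovered within 15% (harmonic mean, g in 4..50)", {
  tr <- ne_trajectory(rep(5000, 50))
  seg <- simulate_pairwise_ibd(tr, n_pairs = 500, chrom_length_cM = 3000,
                               seed = 5, min_emit_cM = 5)
  sp <- segment_spectrum(seg, n_pairs = 500, genome_length_cM = 3000)
  fit <- fit_ne(sp)
  hm <- function(x) 1 / mean(1 / x)
  expect_lt(abs(hm(fit$Ne[4:50]) - 5000) / 5000, 0.15)
})

test_that("a 10-generation-old five-fold bottleneck is localized in g in [5, 20]", {
  Ne <- rep(5000, 50); Ne[8:12] <- 1000
  tr <- ne_trajectory(Ne)
  hits <- vapply(1:10, function(s) {
    seg <- simulate_pairwise_ibd(tr, n_pairs = 300, chrom_length_cM = 3000,
                                 seed = s, min_emit_cM = 5)
    sp <- segment_spectrum(seg, n_pairs = 300, genome_length_cM = 3000)
    fit <- fit_ne(sp)
    g_min <- which.min(fit$Ne)
    g_min >= 5 && g_min <= 20
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("fit_ne is invariant to replicating the data", {
  tr <- ne_trajectory(rep(4000, 50))
  seg <- simulate_pairwise_ibd(tr, n_pairs = 400, chrom_length_cM = 2000,
                               seed = 6, min_emit_cM = 5)
  sp <- segment_spectrum(seg, n_pairs = 400, genome_length_cM = 2000)
  sp2 <- sp
  sp2$counts <- 2L * sp$counts
  sp2$n_pairs <- 2L * sp$n_pairs
  f1 <- fit_ne(sp)
  f2 <- fit_ne(sp2)
  # the per-generation trajectory has flat directions (weakly identified),
  # so compare the well-identified functionals: the harmonic mean and the
  # implied expected spectrum
  hm <- function(x) 1 / mean(1 / x)
  expect_equal(hm(f1$Ne[4:50]), hm(f2$Ne[4:50]), tolerance = 0.01)
  e1 <- expected_spectrum(f1, sp$edges_cM, sp$n_pairs, sp$genome_length_cM)
  e2 <- expected_spectrum(f2, sp2$edges_cM, sp2$n_pairs, sp2$genome_length_cM)
  expect_equal(2 * e1, e2, tolerance = 0.01)
})

test_that("empty spectra are rejected", {
  sp <- segment_spectrum(numeric(0), n_pairs = 10, genome_length_cM = 100)
  expect_error(fit_ne(sp), "no segments")
})
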