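# shared fixtures built in code

# constant-size single deme
one_deme <- function(N = 1000, units = "diploid") {
  demographic_model(list(A = data.frame(start = 0, end = Inf, size = N)),
                    splits = NULL, size_units = units)
}

# clean two-deme split at time t, equal sizes, no migration
two_deme_split <- function(t = 100, N = 1000, units = "diploid") {
  demographic_model(
    demes = list(A = data.frame(start = 0, end = t, size = N),
                 B = data.frame(start = 0, end = t, size = N),
                 R = data.frame(start = t, end = Inf, size = N)),
    splits = data.frame(time = c(t, t), derived = c("A", "B"),
                        ancestral = c("R", "R")),
    size_units = units)
}

# symmetric four demes + outgroup hanging off a balanced tree, used for the
# Patterson's D null (no gene flow, exchangeable P1/P2 and P3/P4)
symmetric_quartet <- function(t1 = 50, t2 = 200, N = 2000) {
  demographic_model(
    demes = list(P1 = data.frame(start = 0, end = t1, size = N),
                 P2 = data.frame(start = 0, end = t1, size = N),
                 P3 = data.frame(start = 0, end = t1, size = N),
                 P4 = data.frame(start = 0, end = t1, size = N),
                 A12 = data.frame(start = t1, end = t2, size = N),
                 A34 = data.frame(start = t1, end = t2, size = N),
                 R = data.frame(start = t2, end = Inf, size = N)),
    splits = data.frame(time = c(t1, t1, t1, t1, t2, t2),
                        derived = c("P1", "P2", "P3", "P4", "A12", "A34"),
                        ancestral = c("A12", "A12", "A34", "A34", "R", "R")),
    size_units = "diploid")
}

# panel with planted IBD tracts: n_hap haplotypes of iid sites at given
# frequencies; `plant` is a list of list(h1=, h2=, from=, to=) site ranges
# where h2 copies h1
planted_panel <- function(n_hap = 8, n_sites = 5000, spacing_cM = 0.01,
                          plant = list(), seed = 1, discord_rate = 0) {
  set.seed(seed)
  freq <- runif(n_sites, 0.05, 0.95)
  haps <- matrix(rbinom(n_hap * n_sites, 1, rep(freq, each = n_hap)),
                 nrow = n_hap)
  for (p in plant) {
    idx <- p$from:p$to
    haps[p$h2, idx] <- haps[p$h1, idx]
    if (discord_rate > 0) {
      flip <- idx[runif(length(idx)) < discord_rate]
      haps[p$h2, flip] <- 1L - haps[p$h2, flip]
    }
  }
  stopifnot(n_hap %% 2 == 0)
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n_hap / 2)),
                        population = "A", stringsAsFactors = FALSE)
  pos <- seq(1, by = round(spacing_cM * 1e6), length.out = n_sites)
  haplotype_panel(haps, samples, "1", pos, pos / 1e6)
}

# toy genotype matrix from explicit dosages
toy_gm <- function(geno, pops = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); s <- ncol(geno)
  genotype_matrix(geno,
                  sites = data.frame(chrom = "1", pos = seq_len(s) * 1000,
                                     ref = "A", alt = "G"),
                  samples = data.frame(sample_id = sprintf("i%02d", seq_len(n)),
                                       population = pops %||% rep("A", n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Levene-Haldane probabilities via log-gamma, independent of the
# recurrence used by hwe_exact_test
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- vapply(hs, function(h) {
    a <- (nA - h) / 2
    b <- (2 * n - nA - h) / 2
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  sum(p[p <= p[hs == nAa] * (1 + 1e-12)])
}

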