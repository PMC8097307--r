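#' Diploid genotype matrices
#'
#' @param geno samples x sites matrix of alternate-allele dosages
#'   (0/1/2, `NA` = missing).
#' @param sites `data.frame` with columns `chrom`, `pos`, `ref`, `alt`.
#' @param samples `data.frame` with columns `sample_id`, `population`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(all(geno %in% c(0:2, NA)),
            nrow(geno) == nrow(samples), ncol(geno) == nrow(sites))
  rownames(geno) <- samples$sample_id
  structure(list(geno = geno, sites = as.data.frame(sites),
                 samples = as.data.frame(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%.2f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' QC filter thresholds
#'
#' Defaults follow SNP-array practice: sites and samples must be >= 98%
#' called, sites must be consistent with Hardy-Weinberg equilibrium at
#' p > 1e-6 and polymorphic (MAF strictly above `maf_min_exclusive`), and one
#' member of every sample pair with relatedness `pi_hat > pi_hat_max` is
#' removed.
#'
#' @param snp_call_rate_min,sample_call_rate_min,hwe_p_min,maf_min_exclusive,pi_hat_max
#'   thresholds, all in `[0, 1]`.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(snp_call_rate_min = 0.98, sample_call_rate_min = 0.98,
                      hwe_p_min = 1e-6, maf_min_exclusive = 0,
                      pi_hat_max = 0.25) {
  cfg <- list(snp_call_rate_min = snp_call_rate_min,
              sample_call_rate_min = sample_call_rate_min,
              hwe_p_min = hwe_p_min, maf_min_exclusive = maf_min_exclusive,
              pi_hat_max = pi_hat_max)
  stopifnot(all(unlist(cfg) >= 0), all(unlist(cfg) <= 1))
  structure(cfg, class = "qc_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional (Levene-Haldane) exact test: given the observed allele counts,
#' the two-sided p-value sums the probabilities of all heterozygote counts
#' whose conditional probability does not exceed that of the observed count.
#' Probabilities are computed by the standard recurrence and normalized, so
#' the result is exact to numerical precision.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, positive total).
#' @return two-sided p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(3, 4, 3)
#' hwe_exact_test(25, 0, 25)  # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no called genotypes at this site")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  # heterozygote counts share the parity of the rare allele count
  hs <- seq(rare %% 2, rare, by = 2)
  # recurrence in log space from the smallest het count upwards:
  # P(h+2)/P(h) = (nhom1 * nhom2 * 4) / ((h+2)(h+1)) with hom counts at h
  lp <- numeric(length(hs))
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1]
    hom_rare <- (rare - h) / 2          # rare-allele homozygotes at h hets
    hom_common <- n - h - hom_rare      # common-allele homozygotes
    lp[i] <- lp[i - 1] + log(4 * hom_rare * hom_common) -
      log((h + 2) * (h + 1))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- which(hs == n_Aa)
  if (!length(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Method-of-moments relatedness (pi-hat)
#'
#' PLINK-style genome-wide IBD estimate for a sample pair from
#' identity-by-state counts: `pi_hat = P(IBD=1)/2 + P(IBD=2)`, with the
#' IBD-state proportions solved from the observed IBS distribution and the
#' expected IBS-given-IBD probabilities under the supplied allele
#' frequencies. Estimates are truncated to `[0, 1]`.
#'
#' @param g1,g2 genotype dosage vectors (0/1/2, NA missing).
#' @param p per-site alternate-allele frequencies (estimated from the panel).
#' @param min_overlap warn below this many overlapping called sites.
#' @return pi-hat estimate.
#' @export
pi_hat <- function(g1, g2, p, min_overlap = 1000) {
  stopifnot(length(g1) == length(g2), length(g1) == length(p))
  ok <- !is.na(g1) & !is.na(g2) & p > 0 & p < 1
  if (!any(ok)) stop("no overlapping called polymorphic sites")
  if (sum(ok) < min_overlap)
    warning("only ", sum(ok), " overlapping sites; pi-hat will be noisy")
  g1 <- g1[ok]; g2 <- g2[ok]; p <- p[ok]; q <- 1 - p
  ibs <- 2 - abs(g1 - g2)
  ibs[g1 == 1 & g2 == 1] <- 2
  # expected per-site IBS probabilities given IBD state
  e0_0 <- 2 * p^2 * q^2
  e1_0 <- 4 * p^3 * q + 4 * p * q^3
  e2_0 <- 1 - e0_0 - e1_0
  e1_1 <- 2 * p^2 * q + 2 * p * q^2
  e2_1 <- 1 - e1_1
  N0 <- sum(ibs == 0); N1 <- sum(ibs == 1); N2 <- sum(ibs == 2)
  L <- length(p)
  k0 <- N0 / sum(e0_0)
  k1 <- (N1 - k0 * sum(e1_0)) / sum(e1_1)
  k2 <- (N2 - k0 * sum(e2_0) - k1 * sum(e2_1)) / L
  k0 <- max(0, k0); k1 <- max(0, k1); k2 <- max(0, k2)
  min(1, k1 / 2 + k2)
}

#' Apply the QC filter chain
#'
#' Filters are applied in a fixed, documented order: (1) site call rate,
#' (2) sample call rate, (3) Hardy-Weinberg exact test, (4) minor-allele
#' frequency, (5) greedy relatedness pruning (for every remaining pair with
#' `pi_hat > pi_hat_max`, the member with the lower call rate -- ties broken
#' towards the lexicographically larger id -- is removed). Re-running on its
#' own output changes nothing. Allele frequencies for the relatedness step
#' are estimated from the post-MAF panel.
#'
#' @param gm a [genotype_matrix()].
#' @param config a [qc_config()].
#' @return list of class `qc_result`: `matrix` (filtered
#'   [genotype_matrix()], possibly with 0 rows/columns), `report`
#'   (`data.frame` step/removed/remaining), `empty` (logical).
#' @export
apply_qc <- function(gm, config = qc_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno; sites <- gm$sites; samples <- gm$samples
  rep_rows <- list()
  log_step <- function(step, removed) {
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(
      step = step, removed = removed,
      remaining_samples = nrow(g), remaining_sites = ncol(g),
      stringsAsFactors = FALSE)
  }
  # 1. site call rate
  keep <- colMeans(!is.na(g)) >= config$snp_call_rate_min
  g <- g[, keep, drop = FALSE]; sites <- sites[keep, , drop = FALSE]
  log_step("snp_call_rate", sum(!keep))
  # 2. sample call rate
  if (ncol(g)) {
    keep <- rowMeans(!is.na(g)) >= config$sample_call_rate_min
  } else keep <- rep(TRUE, nrow(g))
  g <- g[keep, , drop = FALSE]; samples <- samples[keep, , drop = FALSE]
  log_step("sample_call_rate", sum(!keep))
  # 3. HWE
  if (nrow(g) && ncol(g)) {
    pvals <- vapply(seq_len(ncol(g)), function(j) {
      x <- g[, j]
      hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                     sum(x == 2, na.rm = TRUE))
    }, numeric(1))
    keep <- pvals > config$hwe_p_min
  } else keep <- rep(TRUE, ncol(g))
  g <- g[, keep, drop = FALSE]; sites <- sites[keep, , drop = FALSE]
  log_step("hwe", sum(!keep))
  # 4. MAF
  if (nrow(g) && ncol(g)) {
    p <- colMeans(g, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    keep <- maf > config$maf_min_exclusive
  } else keep <- rep(TRUE, ncol(g))
  g <- g[, keep, drop = FALSE]; sites <- sites[keep, , drop = FALSE]
  log_step("maf", sum(!keep))
  # 5. relatedness pruning (greedy)
  removed_rel <- 0L
  if (nrow(g) >= 2 && ncol(g)) {
    p <- colMeans(g, na.rm = TRUE) / 2
    call_rate <- rowMeans(!is.na(g))
    drop <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(g) - 1)) {
      if (drop[i]) next
      for (j in seq(i + 1, nrow(g))) {
        if (drop[j]) next
        ph <- suppressWarnings(pi_hat(g[i, ], g[j, ], p))
        if (ph > config$pi_hat_max) {
          pick <- if (call_rate[i] < call_rate[j]) i
                  else if (call_rate[j] < call_rate[i]) j
                  else if (samples$sample_id[i] > samples$sample_id[j]) i else j
          drop[pick] <- TRUE
          if (pick == i) break
        }
      }
    }
    removed_rel <- sum(drop)
    g <- g[!drop, , drop = FALSE]; samples <- samples[!drop, , drop = FALSE]
  }
  log_step("relatedness", removed_rel)
  report <- do.call(rbind, rep_rows)
  out <- genotype_matrix(g, sites, samples)
  structure(list(matrix = out, report = report,
                 empty = nrow(g) == 0 || ncol(g) == 0),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report, row.names = FALSE)
  invisible(x)
}
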