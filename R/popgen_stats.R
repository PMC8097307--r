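#' Site frequency spectra
#'
#' Sparse joint site-frequency spectrum over one or more labelled
#' populations: a table of joint derived-allele-count vectors and the number
#' of sites observed at each, plus the per-population haplotype sample sizes.
#'
#' @param counts `data.frame`/`data.table` with one integer column per
#'   population (derived copies) and a `count` column (sites).
#' @param n_hap named integer vector of haplotype sample sizes, names
#'   matching the count columns.
#' @return an object of class `sfs`.
#' @export
sfs <- function(counts, n_hap) {
  counts <- data.table::as.data.table(counts)
  demes <- setdiff(names(counts), "count")
  stopifnot(length(demes) >= 1, "count" %in% names(counts),
            setequal(demes, names(n_hap)))
  data.table::setcolorder(counts, c(demes, "count"))
  counts <- counts[, .(count = sum(count)), by = demes]
  for (d in demes) {
    if (any(counts[[d]] < 0 | counts[[d]] > n_hap[[d]]))
      stop("derived count outside [0, n_hap] for population ", d)
  }
  structure(list(counts = counts, demes = demes,
                 n_hap = as.integer(n_hap[demes])),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("sfs over {%s} (n_hap = %s): %d occupied entries, %d sites\n",
              paste(x$demes, collapse = ", "),
              paste(x$n_hap, collapse = ", "),
              nrow(x$counts), sum(x$counts$count)))
  invisible(x)
}

# number of sites in an sfs
sfs_total <- function(x) sum(x$counts$count)

#' @describeIn sfs Build an `sfs` from a per-site derived-count matrix
#'   (sites x populations).
#' @param count_matrix integer matrix of derived counts, columns named by
#'   population.
#' @export
sfs_from_counts <- function(count_matrix, n_hap) {
  dt <- data.table::as.data.table(count_matrix)
  dt <- dt[, .(count = .N), by = names(dt)]
  sfs(dt, n_hap)
}

#' Marginalize a joint SFS onto a subset of populations
#'
#' @param x an [sfs()].
#' @param demes character vector of populations to keep.
#' @return an [sfs()] over `demes`.
#' @export
marginal_sfs <- function(x, demes) {
  stopifnot(all(demes %in% x$demes))
  ct <- x$counts[, .(count = sum(count)), by = demes]
  sfs(ct, stats::setNames(x$n_hap, x$demes)[demes])
}

#' Fold a joint SFS
#'
#' Removes dependence on ancestral-allele polarization: each entry whose
#' total derived count exceeds half the total sample is relabelled by its
#' complement (ties broken towards the lexicographically smaller vector), so
#' the folded spectrum is invariant to a global allele-label flip.
#'
#' @param x an [sfs()].
#' @return a folded [sfs()].
#' @export
fold_sfs <- function(x) {
  ct <- data.table::copy(x$counts)
  m <- as.matrix(ct[, x$demes, with = FALSE])
  comp <- sweep(-m, 2, x$n_hap, "+")
  tot <- rowSums(m); N <- sum(x$n_hap)
  flip <- tot > N / 2
  tie <- tot == N / 2
  if (any(tie)) {
    # lexicographic comparison for ties
    for (i in which(tie)) {
      cmpv <- sign(comp[i, ] - m[i, ])
      nz <- which(cmpv != 0)
      if (length(nz) && cmpv[nz[1]] < 0) flip[i] <- TRUE
    }
  }
  m[flip, ] <- comp[flip, , drop = FALSE]
  out <- data.table::as.data.table(m)
  out$count <- ct$count
  sfs(out, stats::setNames(x$n_hap, x$demes))
}

#' Joint SFS of a panel or genotype matrix
#'
#' Counts sites by their joint derived-allele-count vector over populations;
#' the derived allele is the non-reference (alternate) allele. Phased panels
#' count haplotypes; genotype matrices sum dosages. Sites with missing
#' genotypes are dropped (with a message when any are).
#'
#' @param x a [haplotype_panel()] or [genotype_matrix()].
#' @param demes populations to include (default: all present).
#' @return an [sfs()].
#' @export
joint_sfs_from_panel <- function(x, demes = NULL) {
  if (inherits(x, "haplotype_panel")) {
    pops <- rep(x$samples$population, each = 2)
    mat <- x$haps
  } else if (inherits(x, "genotype_matrix")) {
    pops <- x$samples$population
    mat <- x$geno
  } else stop("x must be a haplotype_panel or genotype_matrix")
  if (is.null(demes)) demes <- unique(pops)
  if (!all(demes %in% pops)) stop("population with zero samples requested")
  keep <- pops %in% demes
  mat <- mat[keep, , drop = FALSE]
  pops <- pops[keep]
  bad <- colSums(is.na(mat)) > 0
  if (any(bad)) {
    message(sum(bad), " sites with missing genotypes dropped")
    mat <- mat[, !bad, drop = FALSE]
  }
  counts <- t(rowsum(mat, group = factor(pops, levels = demes)))
  colnames(counts) <- demes
  n_per <- as.integer(table(factor(pops, levels = demes)))
  # panel rows are haplotypes; genotype rows are diploid samples
  n_hap <- stats::setNames(
    if (inherits(x, "haplotype_panel")) n_per else 2L * n_per, demes)
  sfs_from_counts(counts, n_hap)
}

# ---------------------------------------------------------------------------
# block jackknife
# ---------------------------------------------------------------------------

#' Assign contiguous jackknife blocks
#'
#' Contiguous 5 cM blocks when genetic positions are available, otherwise
#' `n_blocks` equal-count blocks of consecutive sites.
#'
#' @param n_sites number of sites.
#' @param pos_cM optional genetic positions.
#' @param block_cM block width in cM.
#' @param n_blocks number of equal-count blocks without a map.
#' @return integer block id per site.
#' @export
jackknife_blocks <- function(n_sites, pos_cM = NULL, block_cM = 5,
                             n_blocks = 200) {
  if (!is.null(pos_cM)) {
    stopifnot(length(pos_cM) == n_sites)
    b <- floor((pos_cM - min(pos_cM)) / block_cM)
    return(as.integer(factor(b)))
  }
  n_blocks <- min(n_blocks, n_sites)
  as.integer(cut(seq_len(n_sites), breaks = n_blocks, labels = FALSE))
}

# Weighted delete-one-block jackknife for a ratio-of-sums estimator
# (Busing et al. 1999, as used for D and F_ST standard errors).
ratio_jackknife <- function(num, den, blocks) {
  keep <- is.finite(num) & is.finite(den)
  num <- num[keep]; den <- den[keep]; blocks <- blocks[keep]
  Sn <- sum(num); Sd <- sum(den)
  if (Sd == 0) stop("zero denominator: statistic undefined")
  theta <- Sn / Sd
  bn <- rowsum(num, blocks); bd <- rowsum(den, blocks)
  mb <- as.vector(table(blocks))
  ok <- (Sd - bd) != 0
  bn <- bn[ok]; bd <- bd[ok]; mb <- mb[ok]
  g <- length(mb)
  if (g < 2) stop("need at least 2 jackknife blocks")
  n <- sum(mb)
  theta_mb <- (Sn - bn) / (Sd - bd)
  hb <- n / mb
  theta_J <- g * theta - sum((1 - mb / n) * theta_mb)
  varhat <- sum((hb * theta - (hb - 1) * theta_mb - theta_J)^2 / (hb - 1)) / g
  list(est = theta, se = sqrt(varhat), n_blocks = g)
}

# ---------------------------------------------------------------------------
# F_ST
# ---------------------------------------------------------------------------

#' Hudson's F_ST (ratio of averages) with block-jackknife SE
#'
#' Per-locus numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`, each averaged over loci before taking
#' the ratio. This estimator is robust to unequal sample sizes; a
#' Weir-Cockerham alternative is available via `estimator = "wc"`. The
#' standard error is a weighted delete-one-block jackknife over contiguous
#' blocks. Loci with a zero denominator or fewer than 2 haplotypes in either
#' population are skipped and counted.
#'
#' @param x a [haplotype_panel()], or a matrix/list of derived-allele counts
#'   (see `pop1`/`pop2`).
#' @param pop1,pop2 population labels (panel input) or, for matrix input,
#'   column names/indices of the two populations.
#' @param n_hap named haplotype sample sizes (matrix input only).
#' @param blocks optional block id per site; defaults to
#'   [jackknife_blocks()].
#' @param estimator `"hudson"` or `"wc"`.
#' @param n_blocks blocks used when no map/blocks are given.
#' @return list of class `fst_result`: `fst`, `se`, `z`, `n_loci` (used),
#'   `n_skipped`, `n_blocks`, `estimator`.
#' @examples
#' m <- miyako_model()
#' ac <- simulate_allele_counts(m, c(MYNE = 20, IKM = 20), 2000, seed = 1)
#' hudson_fst(ac$counts, "MYNE", "IKM", n_hap = ac$n_hap)
#' @export
hudson_fst <- function(x, pop1, pop2, n_hap = NULL, blocks = NULL,
                       estimator = c("hudson", "wc"), n_blocks = 200) {
  estimator <- match.arg(estimator)
  if (inherits(x, "haplotype_panel")) {
    pops <- rep(x$samples$population, each = 2)
    ac1 <- colSums(x$haps[pops == pop1, , drop = FALSE])
    ac2 <- colSums(x$haps[pops == pop2, , drop = FALSE])
    n1 <- sum(pops == pop1); n2 <- sum(pops == pop2)
    if (is.null(blocks)) blocks <- jackknife_blocks(ncol(x$haps), x$pos_cM)
  } else {
    ac1 <- x[, pop1]; ac2 <- x[, pop2]
    if (is.null(n_hap)) stop("n_hap required for count input")
    n1 <- n_hap[[pop1]]; n2 <- n_hap[[pop2]]
    if (is.null(blocks)) blocks <- jackknife_blocks(length(ac1),
                                                    n_blocks = n_blocks)
  }
  if (n1 < 2 || n2 < 2) stop("need >= 2 haplotypes per population")
  p1 <- ac1 / n1; p2 <- ac2 / n2
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    # Weir & Cockerham (1984) theta, two populations, haplotype data
    r <- 2; nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
    num <- a
    den <- a + b
  }
  usable <- den != 0
  if (sum(usable) < 2) stop("fewer than 2 usable loci")
  res <- ratio_jackknife(num[usable], den[usable], blocks[usable])
  structure(list(fst = res$est, se = res$se,
                 z = res$est / res$se,
                 n_loci = sum(usable), n_skipped = sum(!usable),
                 n_blocks = res$n_blocks, estimator = estimator),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("F_ST (%s) = %.4g +/- %.3g (%d loci, %d skipped, %d blocks)\n",
              x$estimator, x$fst, x$se, x$n_loci, x$n_skipped, x$n_blocks))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Patterson's D
# ---------------------------------------------------------------------------

#' Patterson's D (ABBA-BABA) with weighted block-jackknife Z
#'
#' `D = sum (p1-p2)(p3-p4) / sum (p1+p2-2 p1 p2)(p3+p4-2 p3 p4)` over sites,
#' with derived-allele frequencies `p1..p4` for the quartet `(P1, P2; P3,
#' P4)`. Positive D indicates excess allele sharing between P2 and P4 (or P1
#' and P3). The Z score divides D by its weighted block-jackknife standard
#' error, which is robust to linkage within blocks.
#'
#' @param p1,p2,p3,p4 per-site derived-allele frequencies in `[0, 1]`.
#' @param blocks block id per site (>= 2 blocks required); defaults to
#'   [jackknife_blocks()] equal-count blocks.
#' @param n_blocks default block count.
#' @return list of class `dstat_result`: `d`, `z`, `se`, `n_blocks`,
#'   `abba_sum`, `baba_sum`, `n_sites`.
#' @export
patterson_d <- function(p1, p2, p3, p4, blocks = NULL, n_blocks = 200) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(p4))
  pall <- c(p1, p2, p3, p4)
  if (any(pall < 0 | pall > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  if (is.null(blocks)) blocks <- jackknife_blocks(length(p1), n_blocks = n_blocks)
  num <- (p1 - p2) * (p3 - p4)
  den <- (p1 + p2 - 2 * p1 * p2) * (p3 + p4 - 2 * p3 * p4)
  if (sum(den, na.rm = TRUE) == 0) stop("zero denominator: D undefined")
  res <- ratio_jackknife(num, den, blocks)
  baba <- sum(p1 * (1 - p2) * p3 * (1 - p4) + (1 - p1) * p2 * (1 - p3) * p4,
              na.rm = TRUE)
  abba <- sum((1 - p1) * p2 * p3 * (1 - p4) + p1 * (1 - p2) * (1 - p3) * p4,
              na.rm = TRUE)
  structure(list(d = res$est, z = res$est / res$se, se = res$se,
                 n_blocks = res$n_blocks, abba_sum = abba, baba_sum = baba,
                 n_sites = length(p1)),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4g, Z = %.3g (SE %.3g, %d blocks, %d sites)\n",
              x$d, x$z, x$se, x$n_blocks, x$n_sites))
  invisible(x)
}

#' @describeIn patterson_d Compute D from a joint SFS (no Z; algebraically
#'   identical to the site-wise D of the generating panel).
#' @param x an [sfs()].
#' @param pops character vector of four population names `(P1, P2, P3, P4)`.
#' @export
dstat_from_sfs <- function(x, pops) {
  stopifnot(inherits(x, "sfs"), length(pops) == 4, all(pops %in% x$demes))
  ct <- marginal_sfs(x, pops)$counts
  n <- stats::setNames(x$n_hap, x$demes)[pops]
  p <- lapply(seq_len(4), function(i) ct[[pops[i]]] / n[i])
  w <- ct$count
  num <- sum(w * (p[[1]] - p[[2]]) * (p[[3]] - p[[4]]))
  den <- sum(w * (p[[1]] + p[[2]] - 2 * p[[1]] * p[[2]]) *
               (p[[3]] + p[[4]] - 2 * p[[3]] * p[[4]]))
  if (den == 0) stop("zero denominator: D undefined")
  num / den
}

# ---------------------------------------------------------------------------
# runs of homozygosity
# ---------------------------------------------------------------------------

#' Detect runs of homozygosity in one genome
#'
#' Sliding-window scan in the PLINK style: windows of `window_sites`
#' consecutive sites pass when they contain at most `max_het_per_window`
#' heterozygous and at most `max_missing_per_window` missing calls; a site is
#' in a candidate run when at least one window covering it passes; maximal
#' candidate runs are trimmed to homozygous non-missing endpoints and kept
#' when they span at least `min_sites` sites and `min_length_bp` base pairs.
#'
#' @param geno genotype dosage vector (0/1/2, NA missing) for one sample.
#' @param pos physical positions (bp), increasing.
#' @param chrom chromosome id recorded in the output.
#' @param min_sites,min_length_bp,window_sites,max_het_per_window,max_missing_per_window
#'   scan parameters (PLINK-like defaults).
#' @return `data.frame` with columns `chrom`, `start_bp`, `end_bp`,
#'   `length_bp`, `n_sites` (possibly 0 rows).
#' @export
roh_detect <- function(geno, pos, chrom = "1", min_sites = 50,
                       min_length_bp = 1e6, window_sites = 50,
                       max_het_per_window = 1, max_missing_per_window = 5) {
  stopifnot(length(geno) == length(pos), !is.unsorted(pos))
  S <- length(geno)
  empty <- data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), length_bp = integer(0),
                      n_sites = integer(0), stringsAsFactors = FALSE)
  if (S < max(min_sites, window_sites)) return(empty)
  het <- as.integer(!is.na(geno) & geno == 1)
  mis <- as.integer(is.na(geno))
  w <- window_sites
  ch <- c(0, cumsum(het)); cm <- c(0, cumsum(mis))
  nh <- ch[(w + 1):(S + 1)] - ch[1:(S - w + 1)]
  nm <- cm[(w + 1):(S + 1)] - cm[1:(S - w + 1)]
  wpass <- nh <= max_het_per_window & nm <= max_missing_per_window
  # site i is covered by windows starting in [i-w+1, i]
  cp <- c(0, cumsum(as.integer(wpass)))
  lo <- pmax(1, seq_len(S) - w + 1)
  hi <- pmin(S - w + 1, seq_len(S))
  covered <- hi >= lo & (cp[hi + 1] - cp[lo]) > 0
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- list()
  for (i in which(r$values)) {
    a <- starts[i]; b <- ends[i]
    hom <- which(!is.na(geno[a:b]) & geno[a:b] != 1)
    if (!length(hom)) next
    a2 <- a + hom[1] - 1; b2 <- a + hom[length(hom)] - 1
    n_run <- b2 - a2 + 1
    len <- pos[b2] - pos[a2] + 1
    if (n_run >= min_sites && len >= min_length_bp)
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start_bp = pos[a2], end_bp = pos[b2],
        length_bp = len, n_sites = n_run, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Total ROH length per sample of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param ... passed to [roh_detect()].
#' @return `data.frame` with `sample_id`, `population`, `total_roh_bp`,
#'   `n_segments`.
#' @export
roh_table <- function(gm, ...) {
  stopifnot(inherits(gm, "genotype_matrix"))
  res <- lapply(seq_len(nrow(gm$geno)), function(i) {
    segs <- roh_detect(gm$geno[i, ], gm$sites$pos,
                       chrom = gm$sites$chrom[1], ...)
    data.frame(sample_id = gm$samples$sample_id[i],
               population = gm$samples$population[i],
               total_roh_bp = sum(segs$length_bp),
               n_segments = nrow(segs), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# ---------------------------------------------------------------------------
# PCA
# ---------------------------------------------------------------------------

#' PCA of a genotype matrix
#'
#' Mean-imputes missing genotypes, standardizes each site by its estimated
#' allele frequency (`(g - 2p) / sqrt(2p(1-p))`), and returns the leading
#' sample scores from the singular value decomposition. Monomorphic sites
#' are dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components (must not exceed the matrix rank).
#' @return samples x k score matrix (`U %*% diag(d)`), rownames = sample ids.
#' @export
pca_projection <- function(gm, k = 2) {
  stopifnot(inherits(gm, "genotype_matrix"), k >= 1)
  g <- gm$geno
  cm <- colMeans(g, na.rm = TRUE)
  na <- which(is.na(g), arr.ind = TRUE)
  if (nrow(na)) g[na] <- cm[na[, 2]]
  p <- cm / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic sites")
  x <- sweep(g[, keep, drop = FALSE], 2, 2 * p[keep], "-")
  x <- sweep(x, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  sv <- svd(x)
  rank <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1])
  if (k > rank) stop(sprintf("k = %d exceeds matrix rank %d", k, rank))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- gm$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}
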