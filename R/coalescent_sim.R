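#' Phased haplotype panels
#'
#' Container for phased biallelic haplotypes: an integer 0/1 matrix with one
#' row per haplotype (two consecutive rows per diploid sample) and one column
#' per site, plus physical (bp, 1-based) and genetic (cM) coordinates and
#' per-sample population labels.
#'
#' @param haps integer matrix (haplotypes x sites) with values in \{0, 1\}.
#' @param samples `data.frame` with columns `sample_id`, `population`;
#'   `nrow(samples) * 2 == nrow(haps)`.
#' @param chrom chromosome id (single value).
#' @param pos_bp strictly increasing integer physical positions.
#' @param pos_cM non-decreasing genetic positions.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haps, samples, chrom, pos_bp, pos_cM) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  stopifnot(all(haps %in% 0:1), nrow(haps) == 2L * nrow(samples),
            ncol(haps) == length(pos_bp), length(pos_bp) == length(pos_cM),
            !is.unsorted(pos_bp, strictly = TRUE), !is.unsorted(pos_cM))
  rownames(haps) <- paste0(rep(samples$sample_id, each = 2), c("_1", "_2"))
  structure(list(haps = haps,
                 samples = as.data.frame(samples),
                 chrom = as.character(chrom)[1],
                 pos_bp = as.integer(pos_bp),
                 pos_cM = as.numeric(pos_cM)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d samples (%d haplotypes) x %d sites on chrom %s\n",
              nrow(x$samples), nrow(x$haps), ncol(x$haps), x$chrom))
  cat("  populations:", paste(sprintf("%s (%d)", names(table(x$samples$population)),
                                      table(x$samples$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Diploid genotype dosages of a panel
#'
#' Collapses the phased haplotypes to a samples x sites matrix of alternate
#' allele dosages in \{0, 1, 2\}, the input expected by the QC, ROH and PCA
#' functions.
#'
#' @param panel a `haplotype_panel`.
#' @return a [genotype_matrix()].
#' @export
panel_genotypes <- function(panel) {
  h <- panel$haps
  g <- h[seq(1, nrow(h), 2), , drop = FALSE] + h[seq(2, nrow(h), 2), , drop = FALSE]
  rownames(g) <- panel$samples$sample_id
  genotype_matrix(g, sites = data.frame(chrom = panel$chrom,
                                        pos = panel$pos_bp,
                                        ref = "A", alt = "G",
                                        stringsAsFactors = FALSE),
                  samples = panel$samples)
}

.sim_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

.check_sample_sizes <- function(sample_sizes) {
  if (is.null(names(sample_sizes)) || any(!nzchar(names(sample_sizes))))
    stop("sample_sizes must be a named vector: deme -> diploid sample count")
  ss <- sample_sizes[sample_sizes > 0]
  if (!length(ss)) stop("no deme has a positive sample size")
  ss
}

#' Simulate independent biallelic sites under a demographic model
#'
#' Each site is an independent genealogy drawn from the discrete-generation
#' structured coalescent implied by `model` (size epochs, splits, symmetric
#' migration), and carries exactly one mutation placed uniformly on the total
#' branch length, mimicking ascertained SNP-array sites (every simulated site
#' is segregating in the pooled sample). Physical positions are drawn
#' uniformly on a single chromosome and genetic positions follow a constant
#' 1 cM/Mb map unless `map` is supplied.
#'
#' @param model a valid [demographic_model()].
#' @param sample_sizes named vector of diploid sample counts per deme; demes
#'   with zero samples may be omitted.
#' @param n_sites number of segregating sites to simulate.
#' @param seed integer seed (`set.seed` is called when non-NULL).
#' @param chrom chromosome id for the emitted panel.
#' @param chrom_length_bp physical length positions are drawn from.
#' @param map optional [genetic_map()] used to assign genetic positions.
#' @return a [haplotype_panel()].
#' @examples
#' m <- miyako_model()
#' p <- simulate_sites(m, c(MYNE = 5, IKM = 5), n_sites = 100, seed = 1)
#' @export
simulate_sites <- function(model, sample_sizes, n_sites, seed = NULL,
                           chrom = "1", chrom_length_bp = 2.5e8, map = NULL) {
  .sim_seed(seed)
  ss <- .check_sample_sizes(sample_sizes)
  plan <- compile_sim_plan(model, ss)
  if (sum(plan$sample_sizes) * 2L < 2L)
    stop("at least 2 haplotypes are required (no coalescence possible)")
  res <- cpp_simulate_sites(plan$epochs, plan$splits,
                            .mig_df(plan), plan$sample_demes,
                            plan$sample_sizes, as.integer(n_sites), 1L, 0, 1L)
  pos <- sort(sample.int(chrom_length_bp, n_sites))
  cm <- if (is.null(map)) pos / 1e6 else bp_to_cM(map, chrom, pos)
  demes <- plan$ids[plan$sample_demes + 1L]
  samples <- data.frame(
    sample_id = unlist(lapply(seq_along(demes), function(i)
      sprintf("%s_%03d", demes[i], seq_len(plan$sample_sizes[i])))),
    population = rep(demes, plan$sample_sizes),
    stringsAsFactors = FALSE)
  haplotype_panel(res$geno, samples, chrom, pos, cm)
}

.mig_df <- function(plan) {
  if (is.null(plan$migrations) || !nrow(plan$migrations))
    data.frame(a = integer(0), b = integer(0), rate = numeric(0),
               start = numeric(0), end = numeric(0))
  else plan$migrations
}

#' Simulate per-site derived allele counts
#'
#' Like [simulate_sites()] but returns only, per site, the derived-allele
#' count in each sampled deme (plus the genealogy TMRCA) -- the sufficient
#' statistic for F_ST, Patterson's D and the site frequency spectrum -- which
#' is far cheaper than materializing haplotypes.
#'
#' @inheritParams simulate_sites
#' @param mutation `"single"` (default): exactly one mutation per genealogy,
#'   one emitted site per tree. `"poisson"`: `n_sites` genealogies are drawn
#'   and each receives `Poisson(mutation_rate * locus_bp * total branch
#'   length)` mutations, so the number of emitted sites is random and
#'   genealogies may emit none (monomorphic draws are dropped).
#' @param locus_bp locus width for the Poisson mode.
#' @param site_weighting `"length"` (default) draws each site's genealogy
#'   length-weighted -- the distribution of the tree underlying a random
#'   segregating site (the unfolded SFS is then proportional to `1/i` for a
#'   constant-size deme); `"none"` draws plain genealogies, appropriate when
#'   the per-tree quantities themselves (e.g. TMRCA) are under study.
#' @return list with `counts` (sites x demes integer matrix, columns named by
#'   deme), `n_hap` (haplotypes per deme) and `tmrca` (per-site root time,
#'   generations).
#' @export
simulate_allele_counts <- function(model, sample_sizes, n_sites, seed = NULL,
                                   mutation = c("single", "poisson"),
                                   locus_bp = 1,
                                   site_weighting = c("length", "none")) {
  mutation <- match.arg(mutation)
  site_weighting <- match.arg(site_weighting)
  .sim_seed(seed)
  ss <- .check_sample_sizes(sample_sizes)
  plan <- compile_sim_plan(model, ss)
  mode <- if (mutation == "single") 0L else 2L
  mu <- if (mutation == "single") 0 else model$mutation_rate * locus_bp
  res <- cpp_simulate_sites(plan$epochs, plan$splits, .mig_df(plan),
                            plan$sample_demes, plan$sample_sizes,
                            as.integer(n_sites), mode, mu,
                            if (site_weighting == "length") 1L else 0L)
  counts <- res$counts
  colnames(counts) <- plan$ids[plan$sample_demes + 1L]
  n_hap <- 2L * plan$sample_sizes
  names(n_hap) <- colnames(counts)
  list(counts = counts, n_hap = n_hap, tmrca = res$tmrca)
}

#' Simulate a joint site-frequency spectrum
#'
#' Simulates `n_sites` independent segregating sites under `model` and
#' tabulates the joint derived-allele-count spectrum over the sampled demes.
#'
#' @inheritParams simulate_allele_counts
#' @return an [sfs()] object; its counts sum to `n_sites`.
#' @export
simulate_joint_sfs <- function(model, sample_sizes, n_sites, seed = NULL) {
  ac <- simulate_allele_counts(model, sample_sizes, n_sites, seed)
  sfs_from_counts(ac$counts, ac$n_hap)
}

#' Simulate ground-truth IBD segments for haplotype pairs
#'
#' Draws, for each of `n_pairs` haplotype pairs sampled in `deme`, the
#' piecewise-constant TMRCA process along a chromosome under the sequentially
#' Markov coalescent with the deme's (and, further back, its ancestors')
#' size history; maximal spans of constant TMRCA are returned as segments.
#' Before any length filtering the segments of a pair exactly tile
#' `[0, chrom_length_cM)`.
#'
#' @param model a [demographic_model()] (the segment-generating size history
#'   follows `deme` through its split chain; migration is ignored), or an
#'   [ne_trajectory()] whose per-generation diploid sizes (extended as
#'   constant beyond its horizon) define the history directly.
#' @param deme deme id (ignored for a trajectory).
#' @param n_pairs number of haplotype pairs.
#' @param chrom_length_cM chromosome genetic length.
#' @param seed integer seed.
#' @param min_emit_cM drop segments shorter than this (0 keeps the tiling).
#' @return `data.frame` with columns `sample1`, `sample2`, `hap1`, `hap2`,
#'   `chrom`, `start_bp`, `end_bp`, `start_cM`, `end_cM`, `tmrca`
#'   (half-open intervals; bp via a constant 1 cM/Mb map).
#' @export
simulate_pairwise_ibd <- function(model, deme = NULL, n_pairs, chrom_length_cM,
                                  seed = NULL, min_emit_cM = 0) {
  .sim_seed(seed)
  if (chrom_length_cM < 0) stop("chrom_length_cM must be >= 0")
  pw <- coalescence_pieces(model, deme)
  seg <- cpp_smc_ibd(pw$starts, pw$q, chrom_length_cM,
                     as.integer(n_pairs), min_emit_cM)
  n <- length(seg$pair)
  data.frame(
    sample1 = sprintf("pair%05d_a", seg$pair),
    sample2 = sprintf("pair%05d_b", seg$pair),
    hap1 = rep(1L, n), hap2 = rep(1L, n), chrom = rep("1", n),
    start_bp = floor(seg$start_cM * 1e6) + 1,
    end_bp = floor(seg$end_cM * 1e6) + 1,
    start_cM = seg$start_cM, end_cM = seg$end_cM,
    tmrca = seg$tmrca, stringsAsFactors = FALSE)
}

# Piecewise-constant per-generation pairwise coalescence probability q(g) for
# two lineages sampled in `deme`, following the split chain to the root.
# Generation g (>= 1) uses the deme occupied over backward time [g-1, g).
coalescence_pieces <- function(model, deme) {
  if (inherits(model, "ne_trajectory")) {
    n <- model$Ne
    starts <- seq_along(n)
    q <- 1 / (2 * n)
    return(list(starts = as.numeric(starts), q = q))
  }
  val <- validate_model(model)
  if (!val$ok) stop("invalid demographic model")
  if (is.null(deme) || is.null(model$demes[[deme]]))
    stop("deme not found: ", deme)
  if (deme_interval(model, deme)[1] != 0)
    stop("deme ", deme, " does not exist at generation 0")
  starts <- numeric(0); q <- numeric(0)
  cur <- deme; t_from <- 0
  repeat {
    e <- model$demes[[cur]]
    for (i in seq_len(nrow(e))) {
      if (e$end[i] <= t_from) next
      s <- max(e$start[i], t_from)
      starts <- c(starts, s + 1)
      q <- c(q, 1 / gene_copies_at(model, cur, s))
    }
    hit <- model$splits$derived == cur
    if (!any(hit)) break
    t_from <- model$splits$time[hit]
    cur <- model$splits$ancestral[hit]
  }
  stopifnot(starts[1] == 1, !is.unsorted(starts, strictly = TRUE))
  list(starts = starts, q = q)
}
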