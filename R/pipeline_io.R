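#' Read a VCF into a haplotype panel or genotype matrix
#'
#' Consumes the GT field of a VCF (v4.x) via `VariantAnnotation::readVcf`.
#' Only biallelic SNPs are used; other records are skipped and counted.
#' When every genotype is phased (`|` separator) a [haplotype_panel()] is
#' returned; otherwise (including mixed phasing, which warns) a
#' [genotype_matrix()] of dosages.
#'
#' @param path VCF file.
#' @param labels optional `data.frame` (`sample_id`, `population`) attaching
#'   population labels; unknown samples get `"unknown"`.
#' @param map optional [genetic_map()] for genetic positions (panel output
#'   only); defaults to a constant 1 cM/Mb.
#' @return a [haplotype_panel()] or [genotype_matrix()]; the number of
#'   skipped records is attached as attribute `n_skipped`.
#' @export
read_vcf <- function(path, labels = NULL, map = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  for (pkg in c("VariantAnnotation", "GenomicRanges"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("package ", pkg, " is required to read VCF")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  ok <- n_alt == 1 & nchar(ref) == 1 & !is.na(alt) & nchar(alt) == 1 &
    alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!ok)
  if (!any(ok)) stop("no usable biallelic SNPs in ", path)
  gt <- VariantAnnotation::geno(vcf)$GT[ok, , drop = FALSE]
  chrom <- as.character(GenomicRanges::seqnames(rr))[ok]
  pos <- GenomicRanges::start(rr)[ok]
  samp <- colnames(gt)
  pops <- rep("unknown", length(samp))
  if (!is.null(labels)) {
    i <- match(samp, labels$sample_id)
    pops[!is.na(i)] <- labels$population[i[!is.na(i)]]
  }
  samples <- data.frame(sample_id = samp, population = pops,
                        stringsAsFactors = FALSE)
  phased <- grepl("|", gt, fixed = TRUE)
  missing <- gt %in% c(".", "./.", ".|.")
  if (all(phased | missing) && !any(missing)) {
    a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt))
    a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt))
    haps <- matrix(0L, nrow = 2 * ncol(gt), ncol = nrow(gt))
    haps[seq(1, nrow(haps), 2), ] <- t(a1)
    haps[seq(2, nrow(haps), 2), ] <- t(a2)
    cm <- if (is.null(map)) pos / 1e6 else bp_to_cM(map, chrom[1], pos)
    out <- haplotype_panel(haps, samples, chrom[1], pos, cm)
  } else {
    if (any(phased) && any(!phased & !missing))
      warning("mixed phased/unphased genotypes; returning a genotype matrix")
    a1 <- suppressWarnings(matrix(as.integer(substr(gt, 1, 1)),
                                  nrow(gt), ncol(gt)))
    a2 <- suppressWarnings(matrix(as.integer(substr(gt, 3, 3)),
                                  nrow(gt), ncol(gt)))
    g <- t(a1 + a2)
    out <- genotype_matrix(g, data.frame(chrom = chrom, pos = pos, ref = ref[ok],
                                         alt = alt[ok], stringsAsFactors = FALSE),
                           samples)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a panel or genotype matrix as VCF
#'
#' Serializes to a minimal VCF v4.2 with a GT field; panels are written
#' phased (`0|1` style), genotype matrices unphased with `./.` for missing.
#' `read_vcf(write_vcf(x, f))` round-trips the genotypes, positions and
#' sample ids exactly.
#'
#' @param x a [haplotype_panel()] or [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "haplotype_panel")) {
    h <- x$haps
    gt <- matrix(paste0(t(h[seq(1, nrow(h), 2), , drop = FALSE]), "|",
                        t(h[seq(2, nrow(h), 2), , drop = FALSE])),
                 nrow = ncol(h))
    chrom <- rep(x$chrom, ncol(h)); pos <- x$pos_bp
    ref <- rep("A", ncol(h)); alt <- rep("G", ncol(h))
    ids <- x$samples$sample_id
  } else if (inherits(x, "genotype_matrix")) {
    codes <- c("0/0", "0/1", "1/1")
    g <- x$geno
    gt <- matrix("./.", nrow = ncol(g), ncol = nrow(g))
    nz <- !is.na(t(g))
    gt[nz] <- codes[t(g)[nz] + 1L]
    chrom <- x$sites$chrom; pos <- x$sites$pos
    ref <- x$sites$ref; alt <- x$sites$alt
    ids <- x$samples$sample_id
  } else stop("x must be a haplotype_panel or genotype_matrix")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=islandpopgen",
           sprintf("##contig=<ID=%s>", unique(chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- data.table::data.table(
    CHROM = chrom, POS = pos, ID = sprintf("snp%06d", seq_along(pos)),
    REF = ref, ALT = alt, QUAL = ".", FILTER = "PASS", INFO = ".",
    FORMAT = "GT")
  body <- cbind(body, data.table::as.data.table(gt))
  writeLines(hdr, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read / write sample-population label tables
#'
#' Two-column TSV (`sample_id`, `population`), header required.
#'
#' @param path file path.
#' @return `data.frame` with `sample_id` and `population`.
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "population") %in% names(dt)))
    stop("label file must have a header with columns sample_id, population")
  as.data.frame(dt[, c("sample_id", "population")])
}

#' @rdname read_labels
#' @param labels `data.frame` with `sample_id`, `population`.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(labels[, c("sample_id", "population")], path, sep = "\t")
  invisible(path)
}

# TSV with '# key=value' provenance lines and a row-count trailer check.
write_prov_tsv <- function(df, path, prov = character(0)) {
  lines <- c(sprintf("# islandpopgen %s",
                     as.character(utils::packageVersion("islandpopgen"))),
             sprintf("# %s", prov),
             sprintf("# rows=%d", nrow(df)))
  writeLines(lines, path)
  suppressWarnings(data.table::fwrite(df, path, sep = "\t", append = TRUE,
                                      col.names = TRUE))
  invisible(path)
}

read_prov_tsv <- function(path) {
  lines <- readLines(path)
  nprov <- which(!startsWith(lines, "#"))[1] - 1L
  hdr <- lines[seq_len(nprov)]
  rows <- sub("^# rows=", "", grep("^# rows=", hdr, value = TRUE))
  df <- data.table::fread(path, skip = nprov, header = TRUE, sep = "\t")
  if (length(rows) && nrow(df) != as.integer(rows[1]))
    stop("truncated file: ", path, " (expected ", rows[1], " rows, got ",
         nrow(df), ")")
  attr(df, "provenance") <- hdr
  df
}

#' Demo pipeline configuration
#'
#' A small end-to-end configuration: simulate a panel under the fitted
#' island model, run QC, the statistics battery, IBD detection/sharing and
#' the Ne fit. Intended to complete in well under a minute.
#'
#' @param out_dir artifact directory.
#' @param seed global seed.
#' @return a configuration list for [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("islandpopgen_run_"), seed = 1) {
  list(
    out_dir = out_dir, seed = seed,
    simulate = list(sample_sizes = c(CHB = 10, OKI = 10, MYNE = 10,
                                     MYSW = 10, IKM = 10),
                    n_sites = 3000, chrom_length_bp = 5e7),
    vcf = NULL, labels = NULL, map = NULL,
    qc = qc_config(),
    fst_pairs = list(c("MYNE", "IKM"), c("MYSW", "IKM"), c("MYNE", "MYSW")),
    dstat_quadruples = list(c("CHB", "OKI", "IKM", "MYNE")),
    roh = TRUE, pca_k = 2,
    ibd = list(min_cM = 3, seed_sites = 64, max_mismatch = 2,
               merge_gap_cM = 0.6),
    ne = list(G = 50, edges_cM = c(seq(3, 20, 2), Inf), smoothing = 1)
  )
}

#' Run the end-to-end pipeline
#'
#' Executes: simulate (optional) -> QC -> statistics (F_ST, D, SFS, ROH,
#' PCA) -> IBD (detect, merge, sharing) -> Ne fit, writing every artifact
#' as TSV/JSON under `config$out_dir` with provenance headers (package
#' version, seed, config hash, row-count trailer). A failing stage halts
#' with the stage name; artifacts already written are preserved. Re-running
#' with the same config and seed reproduces every artifact bit-for-bit.
#'
#' @param config a configuration list, see [demo_config()].
#' @return the artifact directory, invisibly; a `log.txt` records
#'   per-stage counts.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "log.txt")
  logl <- character(0)
  note <- function(...) logl <<- c(logl, sprintf(...))
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  # hash the semantic configuration only (not the artifact location)
  hash_path <- tempfile()
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], hash_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  hash <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  prov <- c(sprintf("seed=%d", config$seed), sprintf("config_hash=%s", hash))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(logl, sprintf("FAILED at stage %s: %s", name,
                                 conditionMessage(e))), logf)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(config$seed)
  model <- if (!is.null(config$model)) config$model else miyako_model()

  panel <- stage("input", {
    if (!is.null(config$simulate)) {
      s <- config$simulate
      p <- simulate_sites(model, s$sample_sizes, s$n_sites,
                          seed = config$seed,
                          chrom_length_bp = s$chrom_length_bp %||% 2.5e8)
      write_vcf(p, file.path(config$out_dir, "simulated.vcf"))
      write_labels(p$samples, file.path(config$out_dir, "labels.tsv"))
      anchors <- genetic_map(p$chrom, range(p$pos_bp), range(p$pos_cM))
      write_genetic_map(anchors, file.path(config$out_dir, "map.tsv"))
      note("input: simulated %d sites x %d samples", ncol(p$haps),
           nrow(p$samples))
      p
    } else {
      if (!file.exists(config$vcf %||% ""))
        stop("input VCF missing: ", config$vcf)
      lab <- if (!is.null(config$labels)) read_labels(config$labels)
      map <- if (!is.null(config$map)) {
        if (!file.exists(config$map)) stop("genetic map file missing: ", config$map)
        read_genetic_map(config$map)
      }
      p <- read_vcf(config$vcf, labels = lab, map = map)
      note("input: read %d samples from %s", nrow(p$samples), config$vcf)
      p
    }
  })

  qc_res <- stage("qc", {
    r <- apply_qc(panel_genotypes(panel), config$qc %||% qc_config())
    write_prov_tsv(r$report, file.path(config$out_dir, "qc_report.tsv"), prov)
    note("qc: %d samples, %d sites pass", nrow(r$matrix$geno),
         ncol(r$matrix$geno))
    r
  })

  stage("stats", {
    if (length(config$fst_pairs)) {
      rows <- lapply(config$fst_pairs, function(pr) {
        f <- hudson_fst(panel, pr[1], pr[2])
        data.frame(pop1 = pr[1], pop2 = pr[2], fst = f$fst, se = f$se,
                   n_loci = f$n_loci, stringsAsFactors = FALSE)
      })
      write_prov_tsv(do.call(rbind, rows),
                     file.path(config$out_dir, "fst.tsv"), prov)
    }
    if (length(config$dstat_quadruples)) {
      sf <- joint_sfs_from_panel(panel)
      pops <- rep(panel$samples$population, each = 2)
      rows <- lapply(config$dstat_quadruples, function(qd) {
        fr <- lapply(qd, function(pp)
          colMeans(panel$haps[pops == pp, , drop = FALSE]))
        d <- patterson_d(fr[[1]], fr[[2]], fr[[3]], fr[[4]],
                         blocks = jackknife_blocks(ncol(panel$haps),
                                                   panel$pos_cM))
        data.frame(p1 = qd[1], p2 = qd[2], p3 = qd[3], p4 = qd[4],
                   d = d$d, z = d$z, n_blocks = d$n_blocks,
                   stringsAsFactors = FALSE)
      })
      write_prov_tsv(do.call(rbind, rows),
                     file.path(config$out_dir, "dstat.tsv"), prov)
    }
    sf <- joint_sfs_from_panel(panel)
    sfs_out <- as.data.frame(sf$counts)
    write_prov_tsv(sfs_out, file.path(config$out_dir, "sfs.tsv"),
                   c(prov, sprintf("n_hap=%s",
                                   paste(sf$demes, sf$n_hap, sep = ":",
                                         collapse = ","))))
    if (isTRUE(config$roh)) {
      rt <- roh_table(panel_genotypes(panel), min_sites = 25,
                      min_length_bp = 5e5)
      write_prov_tsv(rt, file.path(config$out_dir, "roh.tsv"), prov)
    }
    if (!is.null(config$pca_k)) {
      sc <- pca_projection(panel_genotypes(panel), k = config$pca_k)
      write_prov_tsv(data.frame(sample_id = rownames(sc), sc,
                                stringsAsFactors = FALSE),
                     file.path(config$out_dir, "pca.tsv"), prov)
    }
    note("stats: done")
  })

  segs <- stage("ibd", {
    ib <- config$ibd %||% list()
    s <- detect_ibd(panel, min_cM = ib$min_cM %||% 6,
                    seed_sites = ib$seed_sites %||% 64,
                    max_mismatch = ib$max_mismatch %||% 2)
    s <- merge_segments(s, max_gap_cM = ib$merge_gap_cM %||% 0.6,
                        panel = panel)
    write_prov_tsv(s, file.path(config$out_dir, "ibd_segments.tsv"), prov)
    pops <- unique(panel$samples$population)
    if (length(pops) >= 2) {
      prs <- utils::combn(pops, 2, simplify = FALSE)
      rows <- lapply(prs, function(pr) {
        si <- sharing_index(s,
                            panel$samples$sample_id[panel$samples$population == pr[1]],
                            panel$samples$sample_id[panel$samples$population == pr[2]])
        data.frame(pop_I = pr[1], pop_J = pr[2], index = si$index,
                   total_cM = si$total_cM, stringsAsFactors = FALSE)
      })
      write_prov_tsv(do.call(rbind, rows),
                     file.path(config$out_dir, "sharing.tsv"), prov)
    }
    note("ibd: %d segments", nrow(s))
    s
  })

  stage("nefit", {
    if (is.null(config$ne)) return(invisible(NULL))
    ne <- config$ne
    glen <- diff(range(panel$pos_cM))
    for (pop in unique(panel$samples$population)) {
      ids <- panel$samples$sample_id[panel$samples$population == pop]
      keep <- segs$sample1 %in% ids & segs$sample2 %in% ids
      n_pairs <- 4 * length(ids) * (length(ids) - 1) / 2
      if (!sum(keep) || n_pairs < 1) {
        note("nefit: %s skipped (no within-population segments)", pop)
        next
      }
      sp <- segment_spectrum(segs[keep, ], edges_cM = ne$edges_cM,
                             n_pairs = n_pairs, genome_length_cM = glen)
      if (sum(sp$counts) == 0) {
        note("nefit: %s skipped (empty spectrum)", pop)
        next
      }
      tr <- fit_ne(sp, G = ne$G %||% 50, smoothing = ne$smoothing %||% 1)
      write_prov_tsv(data.frame(generation = seq_len(tr$G), Ne = tr$Ne),
                     file.path(config$out_dir, sprintf("ne_%s.tsv", pop)),
                     c(prov, sprintf("converged=%s", tr$converged)))
      note("nefit: %s fitted over %d generations", pop, tr$G)
    }
  })

  writeLines(c(logl, "pipeline complete"), logf)
  invisible(config$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
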