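#' Genetic maps
#'
#' Piecewise-linear physical-to-genetic coordinate maps: per chromosome, a
#' set of anchor positions (bp, strictly increasing) with cumulative genetic
#' positions (cM, non-decreasing).
#'
#' @param chrom chromosome id per anchor.
#' @param pos_bp anchor physical positions.
#' @param pos_cM anchor genetic positions.
#' @return object of class `genetic_map`.
#' @export
genetic_map <- function(chrom, pos_bp, pos_cM) {
  df <- data.frame(chrom = as.character(chrom), pos_bp = as.numeric(pos_bp),
                   pos_cM = as.numeric(pos_cM), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos_bp), ]
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, ]
    if (nrow(s) < 2) stop("chromosome ", ch, " needs >= 2 anchors")
    if (is.unsorted(s$pos_bp, strictly = TRUE)) stop("anchors must be strictly increasing in bp")
    if (is.unsorted(s$pos_cM)) stop("genetic positions must be non-decreasing")
  }
  structure(list(anchors = df), class = "genetic_map")
}

#' Convert physical to genetic positions
#'
#' Linear interpolation between map anchors; queries beyond the terminal
#' anchors are extrapolated with the terminal interval's cM/bp rate.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome of the query positions.
#' @param pos_bp physical positions to convert.
#' @return genetic positions (cM).
#' @examples
#' gm <- genetic_map("1", c(1e6, 2e6), c(1, 3))
#' bp_to_cM(gm, "1", c(1e6, 1.5e6, 2.5e6))  # 1.0, 2.0, 4.0
#' @export
bp_to_cM <- function(map, chrom, pos_bp) {
  s <- map$anchors[map$anchors$chrom == as.character(chrom), ]
  if (!nrow(s)) stop("chromosome not in map: ", chrom)
  n <- nrow(s)
  out <- stats::approx(s$pos_bp, s$pos_cM, xout = pos_bp, rule = 1)$y
  lo <- pos_bp < s$pos_bp[1]
  hi <- pos_bp > s$pos_bp[n]
  r1 <- (s$pos_cM[2] - s$pos_cM[1]) / (s$pos_bp[2] - s$pos_bp[1])
  rn <- (s$pos_cM[n] - s$pos_cM[n - 1]) / (s$pos_bp[n] - s$pos_bp[n - 1])
  out[lo] <- s$pos_cM[1] + (pos_bp[lo] - s$pos_bp[1]) * r1
  out[hi] <- s$pos_cM[n] + (pos_bp[hi] - s$pos_bp[n]) * rn
  out
}

#' Read / write 3-column genetic maps
#'
#' Plain TSV with header `chrom pos_bp pos_cM`; PLINK-style `.map` files
#' (chrom, id, cM, bp) are also accepted on read.
#'
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  dt <- data.table::fread(path, header = "auto")
  if (ncol(dt) == 4 && !any(c("pos_bp", "pos_cM") %in% names(dt))) {
    # PLINK .map: chrom, snp id, cM, bp
    return(genetic_map(dt[[1]], dt[[4]], dt[[3]]))
  }
  genetic_map(dt$chrom, dt$pos_bp, dt$pos_cM)
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  data.table::fwrite(map$anchors, path, sep = "\t")
  invisible(path)
}

#' Detect IBD segments in a phased panel
#'
#' Hash seed-and-extend matcher: exact-match words of `seed_sites`
#' consecutive sites seed candidate haplotype pairs; each candidate pair's
#' mismatch profile is scanned for dense-mismatch breakpoints (more than
#' `max_mismatch` discordances within any `seed_sites`-site window), and the
#' spans between breakpoints that contain a seeded word and reach `min_cM`
#' genetic length are reported as segments (half-open in bp and cM).
#'
#' @param panel a [haplotype_panel()] with non-decreasing genetic positions.
#' @param min_cM minimum reported genetic length (the published analyses use
#'   a 6 cM threshold for SNP-array data).
#' @param seed_sites exact-match seed word length (sites).
#' @param max_mismatch discordant sites tolerated per extension window.
#' @param break_window sites spanned by `max_mismatch + 1` discordances for
#'   a breakpoint (tighter than the seed so isolated discordances near a
#'   boundary do not clip segment ends).
#' @return `data.frame`: `sample1`, `sample2`, `hap1`, `hap2` (1 or 2 within
#'   sample), `chrom`, `start_bp`, `end_bp`, `start_cM`, `end_cM`,
#'   `n_discordant`.
#' @export
detect_ibd <- function(panel, min_cM = 6, seed_sites = 64, max_mismatch = 2,
                       break_window = max(8L, seed_sites %/% 4L)) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.unsorted(panel$pos_cM)) stop("genetic positions must be sorted")
  seg <- cpp_detect_ibd(panel$haps, panel$pos_cM,
                        as.integer(seed_sites), as.integer(max_mismatch),
                        min_cM, as.integer(break_window))
  if (!nrow(seg)) {
    return(data.frame(sample1 = character(0), sample2 = character(0),
                      hap1 = integer(0), hap2 = integer(0),
                      chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), start_cM = numeric(0),
                      end_cM = numeric(0), n_discordant = integer(0),
                      stringsAsFactors = FALSE))
  }
  sid <- panel$samples$sample_id
  h2s <- function(h) sid[(h + 1L) %/% 2L]
  h2i <- function(h) ifelse(h %% 2L == 1L, 1L, 2L)
  # exclude within-individual haplotype pairs (same diploid sample)
  same <- h2s(seg$hap1) == h2s(seg$hap2)
  seg <- seg[!same, , drop = FALSE]
  end_site <- seg$end_site
  data.frame(
    sample1 = h2s(seg$hap1), sample2 = h2s(seg$hap2),
    hap1 = h2i(seg$hap1), hap2 = h2i(seg$hap2),
    chrom = panel$chrom,
    start_bp = panel$pos_bp[seg$start_site],
    end_bp = panel$pos_bp[end_site] + 1L,
    start_cM = panel$pos_cM[seg$start_site],
    end_cM = panel$pos_cM[end_site],
    n_discordant = seg$n_discordant,
    stringsAsFactors = FALSE)
}

#' Merge nearby IBD segments of the same haplotype pair
#'
#' Removes artificial breaks and short gaps: consecutive segments of one
#' haplotype pair on one chromosome are merged when the intervening gap is
#' at most `max_gap_cM` and (when a panel is supplied) the gap contains at
#' most `max_gap_discordant` discordant sites.
#'
#' @param segments a segment `data.frame` as from [detect_ibd()].
#' @param max_gap_cM largest gap bridged.
#' @param max_gap_discordant largest discordant-site count bridged.
#' @param panel optional [haplotype_panel()] used to count discordances in
#'   gaps; without it, gaps are merged on length alone.
#' @return merged segment `data.frame` with recomputed lengths.
#' @export
merge_segments <- function(segments, max_gap_cM = 0.6, max_gap_discordant = 1,
                           panel = NULL) {
  if (!nrow(segments)) return(segments)
  key <- paste(segments$sample1, segments$sample2, segments$hap1,
               segments$hap2, segments$chrom, sep = "\r")
  out <- lapply(split(seq_len(nrow(segments)), key), function(idx) {
    s <- segments[idx, , drop = FALSE]
    s <- s[order(s$start_cM), , drop = FALSE]
    acc <- s[1, , drop = FALSE]
    for (i in seq_len(nrow(s))[-1]) {
      gap <- s$start_cM[i] - acc$end_cM[nrow(acc)]
      nd_gap <- 0L
      if (!is.null(panel) && gap > 0) {
        h1 <- 2L * (match(acc$sample1[nrow(acc)], panel$samples$sample_id) - 1L) + acc$hap1[nrow(acc)]
        h2 <- 2L * (match(acc$sample2[nrow(acc)], panel$samples$sample_id) - 1L) + acc$hap2[nrow(acc)]
        inside <- panel$pos_cM > acc$end_cM[nrow(acc)] & panel$pos_cM < s$start_cM[i]
        nd_gap <- sum(panel$haps[h1, inside] != panel$haps[h2, inside])
      }
      if (gap <= max_gap_cM && nd_gap <= max_gap_discordant) {
        j <- nrow(acc)
        acc$end_cM[j] <- max(acc$end_cM[j], s$end_cM[i])
        acc$end_bp[j] <- max(acc$end_bp[j], s$end_bp[i])
        acc$n_discordant[j] <- acc$n_discordant[j] + s$n_discordant[i] + nd_gap
      } else {
        acc <- rbind(acc, s[i, , drop = FALSE])
      }
    }
    acc
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample1, out$sample2, out$start_cM), , drop = FALSE]
}

#' Haplotype-sharing index between two populations
#'
#' Mean total IBD sharing per cross-population individual pair, scaled by
#' 100: `index = (sum_i sum_j IBD_ij / (n m)) * 100` where `IBD_ij` is the
#' total genetic length (cM, over all chromosomes and haplotype pairs)
#' shared by individual `i` of population I and `j` of population J. With
#' `pop_I` and `pop_J` identical (same-population mode) the sum runs over
#' the `n(n-1)/2` unordered within-population pairs.
#'
#' @param segments IBD segment `data.frame` ([detect_ibd()] format).
#' @param pop_I,pop_J character vectors of sample ids (disjoint, or
#'   identical for the within-population index).
#' @return list of class `sharing_index_result`: `index`, `n`, `m`,
#'   `total_cM`, `n_pairs`.
#' @export
sharing_index <- function(segments, pop_I, pop_J) {
  if (!length(pop_I) || !length(pop_J)) stop("empty population")
  same <- setequal(pop_I, pop_J)
  if (!same && length(intersect(pop_I, pop_J)))
    stop("pop_I and pop_J must be disjoint (or identical for within-population mode)")
  len <- segments$end_cM - segments$start_cM
  cross <- (segments$sample1 %in% pop_I & segments$sample2 %in% pop_J) |
           (segments$sample1 %in% pop_J & segments$sample2 %in% pop_I)
  if (same) cross <- cross & segments$sample1 != segments$sample2
  total <- sum(len[cross])
  n <- length(unique(pop_I)); m <- length(unique(pop_J))
  n_pairs <- if (same) n * (n - 1) / 2 else n * m
  structure(list(index = total / n_pairs * 100, n = n, m = m,
                 total_cM = total, n_pairs = n_pairs),
            class = "sharing_index_result")
}

#' @export
print.sharing_index_result <- function(x, ...) {
  cat(sprintf("haplotype sharing index = %.4g (n = %d, m = %d, %g cM over %g pairs)\n",
              x$index, x$n, x$m, x$total_cM, x$n_pairs))
  invisible(x)
}
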