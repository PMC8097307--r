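#' Recent effective population size trajectories
#'
#' Per-generation diploid effective sizes for generations `1..G` before
#' present. Beyond `G` the trajectory is treated as constant at `Ne[G]`
#' wherever an extension is needed (e.g. by [simulate_pairwise_ibd()]).
#'
#' @param Ne positive numeric vector; `Ne[g]` is the diploid size at
#'   generation `g`.
#' @param converged,details optional fit metadata attached by [fit_ne()].
#' @return object of class `ne_trajectory`.
#' @export
ne_trajectory <- function(Ne, converged = NA, details = NULL) {
  stopifnot(is.numeric(Ne), length(Ne) >= 1, all(Ne > 0))
  structure(list(Ne = as.numeric(Ne), G = length(Ne),
                 converged = converged, details = details),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat(sprintf("ne_trajectory over %d generations; Ne range [%.3g, %.3g]%s\n",
              x$G, min(x$Ne), max(x$Ne),
              if (isFALSE(x$converged)) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' IBD segment-length spectra
#'
#' Binned counts of detected IBD segment genetic lengths above a detection
#' threshold, together with the design constants needed to form
#' expectations: the number of haplotype pairs scanned and the genome
#' length. Diploid sample pairs contribute 4 haplotype pairs.
#'
#' @param lengths_cM segment genetic lengths, or a segment `data.frame`
#'   with `start_cM`/`end_cM` columns.
#' @param edges_cM increasing bin edges; the last may be `Inf` (lengths at
#'   or above the last finite edge are right-censored into that bin).
#' @param n_pairs haplotype pairs scanned.
#' @param genome_length_cM total genetic length scanned per pair.
#' @return object of class `segment_spectrum` with `counts` per bin.
#' @export
segment_spectrum <- function(lengths_cM, edges_cM = c(seq(6, 30, by = 2), Inf),
                             n_pairs, genome_length_cM) {
  if (is.data.frame(lengths_cM))
    lengths_cM <- lengths_cM$end_cM - lengths_cM$start_cM
  stopifnot(!is.unsorted(edges_cM, strictly = TRUE), length(edges_cM) >= 2,
            edges_cM[1] > 0, n_pairs >= 1, genome_length_cM > 0)
  lengths_cM <- lengths_cM[lengths_cM >= edges_cM[1]]
  counts <- as.vector(table(cut(lengths_cM, edges_cM, right = FALSE)))
  structure(list(edges_cM = edges_cM, counts = counts,
                 n_pairs = n_pairs, genome_length_cM = genome_length_cM),
            class = "segment_spectrum")
}

# geometric coalescence mass P(g) for g = 1..G under a diploid trajectory
coal_mass <- function(Ne) {
  q <- 1 / (2 * Ne)
  q * cumprod(c(1, 1 - q[-length(q)]))
}

#' Expected IBD segment-length spectrum under a size trajectory
#'
#' For a haplotype pair, the probability of coalescing exactly `g`
#' generations ago is `P(g) = (1/(2N_g)) prod_{k<g}(1 - 1/(2N_k))`; given
#' TMRCA `g`, the expected number of maximal IBD spans with genetic length
#' in `[a, b)` Morgans on a genome of `L` Morgans is
#' `L * 2g * (exp(-2ga) - exp(-2gb))`. The expectation sums over
#' `g = 1..G` and multiplies by the number of pairs. Coalescences older
#' than `G` are ignored (they contribute negligibly above a 6 cM
#' threshold for the sizes considered here).
#'
#' @param traj an [ne_trajectory()] (diploid sizes).
#' @param edges_cM increasing bin edges (cM, last may be `Inf`); all must be
#'   at or above `threshold_cM`.
#' @param n_pairs haplotype pairs.
#' @param genome_length_cM genome length per pair.
#' @param threshold_cM detection threshold the bins must respect.
#' @return numeric expected counts, one per bin.
#' @examples
#' # single-generation term by hand: g = 10, L = 30 Morgans, bin [6, Inf) cM
#' # L * 2g * exp(-2g * 0.06) = 600 * exp(-1.2) = 180.72...
#' @export
expected_spectrum <- function(traj, edges_cM = c(seq(6, 30, by = 2), Inf),
                              n_pairs, genome_length_cM, threshold_cM = 6) {
  stopifnot(inherits(traj, "ne_trajectory"),
            !is.unsorted(edges_cM, strictly = TRUE))
  if (edges_cM[1] < threshold_cM)
    stop("bin edge below the detection threshold of ", threshold_cM, " cM")
  P <- coal_mass(traj$Ne)
  g <- seq_along(P)
  a <- edges_cM[-length(edges_cM)] / 100
  b <- edges_cM[-1] / 100
  L <- genome_length_cM / 100
  # C[g, bin] = L * 2g * (exp(-2g a) - exp(-2g b))
  Ea <- exp(-2 * outer(g, a))
  Eb <- exp(-2 * outer(g, ifelse(is.finite(b), b, Inf)))
  C <- L * 2 * g * (Ea - Eb)
  n_pairs * as.vector(P %*% C)
}

#' Fit a recent Ne trajectory to an IBD length spectrum
#'
#' IBDNe-style inverse problem: maximizes the Poisson composite
#' log-likelihood of the binned segment counts over per-generation log
#' diploid sizes, with a squared-second-difference smoothness penalty on
#' log Ne whose weight scales with the total observed count (so the fit is
#' invariant to replicating the data). Initialization is a constant
#' trajectory at the moment estimate matching the total count;
#' optimization is bounded L-BFGS with an analytic gradient. This is a
#' deliberately simplified single-population estimator: no detection-error
#' deconvolution and no chromosome-edge corrections.
#'
#' @param spectrum a [segment_spectrum()].
#' @param G number of generations to estimate.
#' @param smoothing penalty weight per observed segment.
#' @param max_iter L-BFGS iteration cap; non-convergence is flagged on the
#'   result, not silent.
#' @return an [ne_trajectory()] with `converged` and `details`
#'   (`logLik`, `penalty`, `counts`, `fitted`).
#' @export
fit_ne <- function(spectrum, G = 50, smoothing = 1, max_iter = 2000) {
  stopifnot(inherits(spectrum, "segment_spectrum"))
  O <- spectrum$counts
  if (sum(O) <= 0) stop("spectrum has no segments")
  edges <- spectrum$edges_cM
  a <- edges[-length(edges)] / 100
  b <- edges[-1] / 100
  L <- spectrum$genome_length_cM / 100
  g <- seq_len(G)
  C <- L * 2 * g * (exp(-2 * outer(g, a)) - exp(-2 * outer(g, ifelse(is.finite(b), b, Inf))))
  np <- spectrum$n_pairs
  lam <- smoothing * sum(O)
  # second-difference operator on log Ne
  D2 <- diff(diag(G), differences = 2)
  expected <- function(x) {           # x = log Ne
    Ne <- exp(x)
    P <- coal_mass(Ne)
    pmax(np * as.vector(P %*% C), 1e-12)
  }
  obj <- function(x) {
    E <- expected(x)
    sum(E - O * log(E)) + lam * sum((D2 %*% x)^2)
  }
  grad <- function(x) {
    Ne <- exp(x)
    q <- 1 / (2 * Ne)
    P <- coal_mass(Ne)
    M <- P * C                         # G x B
    E <- pmax(np * colSums(M), 1e-12)
    w <- 1 - O / E                     # dNLL/dE_b
    r <- as.vector(M %*% w)            # sum_b w_b M_gb
    Srev <- rev(cumsum(rev(r))) - r    # sum_{g' > g}
    dNLL <- np * (-r + q / (1 - q) * Srev)
    dPen <- 2 * lam * as.vector(crossprod(D2, D2 %*% x))
    dNLL + dPen
  }
  # moment initialization: constant N matching the total count
  tot <- function(lN) sum(expected(rep(lN, G))) - sum(O)
  lo <- log(10); hi <- log(1e8)
  l0 <- if (tot(lo) < 0) lo else if (tot(hi) > 0) hi else
    stats::uniroot(tot, c(lo, hi))$root
  fit <- stats::optim(rep(l0, G), obj, grad, method = "L-BFGS-B",
                      lower = lo, upper = hi,
                      control = list(maxit = max_iter,
                                     factr = 1e4, pgtol = 1e-10))
  ne_trajectory(exp(fit$par), converged = fit$convergence == 0,
                details = list(logLik = -fit$value, counts = O,
                               fitted = expected(fit$par),
                               smoothing = smoothing, message = fit$message))
}
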