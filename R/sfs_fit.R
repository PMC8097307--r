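#' Monte-Carlo expected SFS entry probabilities
#'
#' Estimates the probability of each joint SFS entry under `model` by
#' simulating `n_sim_sites` independent segregating sites. When the full
#' tensor is small enough to enumerate (at most `dense_limit` cells) a
#' pseudo-count of `0.5 / n_sim_sites` is added to every empty cell and the
#' tensor is renormalized; for larger problems the table stays sparse and
#' the same quantity acts as a probability floor for entries that were
#' observed in data but never simulated.
#'
#' @param model a [demographic_model()].
#' @param sample_sizes named diploid sample counts per deme.
#' @param n_sim_sites Monte-Carlo sites per evaluation.
#' @param seed integer seed; fixing it across evaluations gives common
#'   random numbers for optimization.
#' @param dense_limit cell-count cutoff for the dense (renormalized) path.
#' @return object of class `sfs_probs`: `probs` (data.table of entries and
#'   `p`), `demes`, `n_hap`, `n_sim_sites`, `floor_p`, `dense`.
#' @export
expected_sfs_probs <- function(model, sample_sizes, n_sim_sites, seed = NULL,
                               dense_limit = 2e6) {
  ac <- simulate_allele_counts(model, sample_sizes, n_sim_sites, seed)
  dt <- data.table::as.data.table(ac$counts)
  demes <- names(dt)
  dt <- dt[, .(n = .N), by = demes]
  n_hap <- ac$n_hap
  n_cells <- prod(n_hap + 1)
  floor_p <- 0.5 / n_sim_sites
  if (n_cells <= dense_limit) {
    full <- data.table::as.data.table(
      do.call(expand.grid, lapply(n_hap, function(k) 0:k)))
    data.table::setnames(full, demes)
    dt <- merge(full, dt, by = demes, all.x = TRUE)
    dt[is.na(dt$n), "n"] <- 0
    w <- dt$n + ifelse(dt$n == 0, 0.5, 0)  # pseudo-count on zero cells
    dt$p <- w / sum(w)
    dt$n <- NULL
    dense <- TRUE
  } else {
    dt$p <- dt$n / n_sim_sites
    dt$n <- NULL
    dense <- FALSE
  }
  structure(list(probs = dt, demes = demes, n_hap = n_hap,
                 n_sim_sites = n_sim_sites, floor_p = floor_p, dense = dense),
            class = "sfs_probs")
}

#' Multinomial composite log-likelihood of an observed SFS
#'
#' `CL = sum_entries m_e log p_e` over polymorphic entries (entries that are
#' monomorphic across the pooled sample -- all-ancestral or all-derived --
#' are excluded, matching a segregating-sites generator). Observed entries
#' absent from the probability table take the pseudo-count floor.
#'
#' @param observed an [sfs()].
#' @param probs an [expected_sfs_probs()] result over the same demes and
#'   sample sizes.
#' @param exclude_monomorphic drop entries with derived count 0 or 2N in
#'   every population. Keep the default for spectra over the full sample
#'   (a segregating-sites generator produces no such entries); set to
#'   `FALSE` for marginal spectra, whose all-zero cells are genuine
#'   observations (sites segregating only in other populations) -- dropping
#'   them without renormalizing would bias the objective.
#' @return composite log-likelihood (scalar).
#' @export
composite_log_likelihood <- function(observed, probs,
                                     exclude_monomorphic = TRUE) {
  stopifnot(inherits(observed, "sfs"), inherits(probs, "sfs_probs"))
  if (!identical(sort(observed$demes), sort(probs$demes)))
    stop("observed and probs cover different populations")
  nh <- stats::setNames(observed$n_hap, observed$demes)
  if (!all(nh[probs$demes] == probs$n_hap))
    stop("haplotype sample sizes differ between observed and probs")
  obs <- observed$counts
  if (exclude_monomorphic) {
    m <- as.matrix(obs[, observed$demes, with = FALSE])
    tot <- rowSums(m)
    poly <- tot > 0 & tot < sum(nh)
    obs <- obs[poly]
  }
  mg <- merge(obs, probs$probs, by = probs$demes, all.x = TRUE)
  p <- mg$p
  p[is.na(p) | p <= 0] <- probs$floor_p
  sum(mg$count * log(p))
}

#' Specification of an SFS fitting problem
#'
#' @param builder function taking the free parameters by name and returning
#'   a [demographic_model()] (fixed parameters are baked into the builder,
#'   e.g. via [miyako_model()] defaults).
#' @param free named list of `c(lower, upper)` bounds, one per free
#'   parameter; all bounds must be finite.
#' @param sample_sizes named diploid sample counts used for expectations.
#' @param n_sim_sites Monte-Carlo sites per likelihood evaluation.
#' @param integer_params names of free parameters restricted to integers
#'   (e.g. split times in generations); these are refined by a step-1 grid
#'   instead of Nelder-Mead.
#' @param n_grid coarse grid points per parameter.
#' @param n_sim_refine Monte-Carlo sites per evaluation in the refinement
#'   stage (defaults to `2 * n_sim_sites`; the fine grid needs less noise
#'   than the coarse sweep).
#' @param fit_demes populations entering the objective (default: all demes
#'   of the observed SFS). Restricting to the populations a parameter
#'   actually affects removes pure-noise terms from the composite
#'   likelihood; the simulation itself always uses the full sampling design
#'   so the site ascertainment matches the observed data.
#' @param focal_deme optional population name; in pairwise mode only the 2D
#'   marginals involving it enter the objective (pairs among the other
#'   populations are invariant to a parameter of the focal population and
#'   contribute Monte-Carlo noise without signal).
#' @param sfs_mode `"pairwise"` (sum of all 2D marginal composite
#'   log-likelihoods; the default for 3+ populations) or `"joint"`.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(builder, free, sample_sizes, n_sim_sites = 5e4,
                     integer_params = names(free), n_grid = 9,
                     n_sim_refine = 2 * n_sim_sites, fit_demes = NULL,
                     focal_deme = NULL,
                     sfs_mode = c("pairwise", "joint")) {
  sfs_mode <- match.arg(sfs_mode)
  stopifnot(is.function(builder), is.list(free))
  if (length(free)) {
    stopifnot(!is.null(names(free)),
              all(vapply(free, function(b) length(b) == 2 && all(is.finite(b)) &&
                           b[1] < b[2], logical(1))))
  }
  structure(list(builder = builder, free = free, sample_sizes = sample_sizes,
                 n_sim_sites = n_sim_sites, n_sim_refine = n_sim_refine,
                 integer_params = integer_params,
                 n_grid = n_grid, fit_demes = fit_demes,
                 focal_deme = focal_deme, sfs_mode = sfs_mode),
            class = "fit_spec")
}

# all 2D marginals of an sfs as a named list
.pair_marginals <- function(x) {
  prs <- utils::combn(x$demes, 2, simplify = FALSE)
  out <- lapply(prs, function(p) marginal_sfs(x, p))
  names(out) <- vapply(prs, paste, "", collapse = ":")
  out
}

# dense pseudo-count-normalized probability table from a simulated sfs
.probs_from_sfs <- function(sf, n_sim) {
  nh <- stats::setNames(sf$n_hap, sf$demes)
  full <- data.table::as.data.table(
    do.call(expand.grid, lapply(nh, function(k) 0:k)))
  data.table::setnames(full, sf$demes)
  mg <- merge(full, sf$counts, by = sf$demes, all.x = TRUE)
  cnt <- mg$count
  cnt[is.na(cnt)] <- 0
  w <- cnt + ifelse(cnt == 0, 0.5, 0)
  mg$p <- w / sum(w)
  mg$count <- NULL
  structure(list(probs = mg, demes = sf$demes, n_hap = nh,
                 n_sim_sites = n_sim, floor_p = 0.5 / n_sim, dense = TRUE),
            class = "sfs_probs")
}

# composite log-likelihood of observed under a model, with common random
# numbers (eval_seed). The simulation always uses the full sampling design
# (`sample_sizes`); marginal zero cells of the restricted objective are
# genuine observations, so monomorphic entries are retained throughout.
.fit_cl <- function(spec, observed_marg, theta, eval_seed,
                    n_sim = spec$n_sim_sites,
                    sample_sizes = spec$sample_sizes) {
  model <- do.call(spec$builder, as.list(theta))
  ac <- simulate_allele_counts(model, sample_sizes, n_sim, seed = eval_seed)
  sim <- sfs_from_counts(ac$counts, ac$n_hap)
  target <- observed_marg$joint$demes
  if (spec$sfs_mode == "joint" || length(target) <= 2) {
    smarg <- if (setequal(target, sim$demes)) sim else marginal_sfs(sim, target)
    n_cells <- prod(stats::setNames(smarg$n_hap, smarg$demes) + 1)
    if (n_cells <= 2e6) {
      probs <- .probs_from_sfs(smarg, n_sim)
    } else {
      dt <- data.table::copy(smarg$counts)
      dt$p <- dt$count / n_sim
      dt$count <- NULL
      probs <- structure(list(probs = dt, demes = smarg$demes,
                              n_hap = stats::setNames(smarg$n_hap, smarg$demes),
                              n_sim_sites = n_sim, floor_p = 0.5 / n_sim,
                              dense = FALSE), class = "sfs_probs")
    }
    return(composite_log_likelihood(observed_marg$joint, probs,
                                    exclude_monomorphic = FALSE))
  }
  tot <- 0
  for (nm in names(observed_marg$pairs)) {
    pd <- observed_marg$pairs[[nm]]$demes
    probs <- .probs_from_sfs(marginal_sfs(sim, pd), n_sim)
    tot <- tot + composite_log_likelihood(observed_marg$pairs[[nm]], probs,
                                          exclude_monomorphic = FALSE)
  }
  tot
}

#' Fit demographic parameters to an observed SFS
#'
#' fastsimcoal2-style composite-likelihood estimation: a coarse grid over
#' the free parameters, followed by local refinement (a step-1 grid for
#' integer parameters such as split times; Nelder-Mead otherwise), with
#' every likelihood evaluated by Monte-Carlo using common random numbers
#' (the same seed per evaluation) so the objective is a deterministic
#' function of the parameters.
#'
#' @param spec a [fit_spec()].
#' @param observed an [sfs()] (total of at least 10,000 sites recommended;
#'   a warning is issued below).
#' @param seed seed for the common-random-numbers evaluations.
#' @return object of class `fit_result`: `par` (named point estimates),
#'   `logCL`, `on_bound` (logical, optimum on a bound), `path`
#'   (evaluations), `spec`.
#' @export
fit_parameters <- function(spec, observed, seed = 1) {
  stopifnot(inherits(spec, "fit_spec"), inherits(observed, "sfs"))
  if (sfs_total(observed) < 1e4)
    warning("observed SFS has fewer than 10,000 sites; estimates will be noisy")
  obs_use <- observed
  ss_use <- spec$sample_sizes  # full design: the simulation must match the
                               # observed ascertainment even when the
                               # objective is restricted to fit_demes
  if (!is.null(spec$fit_demes)) {
    stopifnot(all(spec$fit_demes %in% observed$demes))
    if (length(spec$fit_demes) < length(observed$demes))
      obs_use <- marginal_sfs(observed, spec$fit_demes)
  }
  om <- list(joint = obs_use,
             pairs = if (length(obs_use$demes) > 2) .pair_marginals(obs_use))
  if (!is.null(spec$focal_deme) && !is.null(om$pairs)) {
    keep <- vapply(om$pairs, function(p) spec$focal_deme %in% p$demes,
                   logical(1))
    om$pairs <- om$pairs[keep]
  }
  path <- list()
  cl_fun <- function(theta, n_sim = spec$n_sim_sites) {
    v <- .fit_cl(spec, om, theta, eval_seed = seed, n_sim = n_sim,
                 sample_sizes = ss_use)
    path[[length(path) + 1]] <<- c(as.list(theta), logCL = v, n_sim = n_sim)
    v
  }
  if (!length(spec$free)) {
    v <- cl_fun(stats::setNames(numeric(0), character(0)))
    return(structure(list(par = numeric(0), logCL = v, on_bound = FALSE,
                          path = data.table::rbindlist(path), spec = spec),
                     class = "fit_result"))
  }
  nms <- names(spec$free)
  lower <- vapply(spec$free, `[`, 0, 1)
  upper <- vapply(spec$free, `[`, 0, 2)
  is_int <- nms %in% spec$integer_params
  grids <- lapply(seq_along(nms), function(i) {
    g <- seq(lower[i], upper[i], length.out = spec$n_grid)
    if (is_int[i]) unique(round(g)) else g
  })
  combos <- do.call(expand.grid, stats::setNames(grids, nms))
  vals <- apply(combos, 1, function(row) cl_fun(stats::setNames(row, nms)))
  best <- stats::setNames(as.numeric(combos[which.max(vals), ]), nms)
  best_v <- max(vals)
  # local refinement at higher Monte-Carlo effort
  if (all(is_int) && length(nms) == 1) {
    # step-1 sweep around the coarse optimum, then a quadratic fit to the
    # (noisy) profile -- the smoothed peak is a far steadier point estimate
    # than the raw argmax when adjacent evaluations differ mostly by
    # Monte-Carlo noise
    step <- max(1, round(diff(grids[[1]][1:2])))
    window <- max(step, 4)  # give the quadratic enough span to see curvature
    cand <- seq(max(lower, best - window), min(upper, best + window), by = 1)
    fine <- vapply(cand, function(cv)
      cl_fun(stats::setNames(cv, nms), n_sim = spec$n_sim_refine), numeric(1))
    qf <- stats::lm(fine ~ cand + I(cand^2))
    cc <- stats::coef(qf)
    peak <- if (is.finite(cc[3]) && cc[3] < 0) -cc[2] / (2 * cc[3]) else
      cand[which.max(fine)]
    peak <- round(min(max(peak, min(cand)), max(cand)))
    best <- stats::setNames(peak, nms)
    best_v <- if (peak %in% cand) fine[match(peak, cand)] else
      cl_fun(best, n_sim = spec$n_sim_refine)
  } else if (all(is_int)) {
    # iterated step-1 coordinate sweeps around the coarse optimum
    steps <- vapply(grids, function(g) max(1, diff(g[1:2])), 0)
    for (pass in 1:2) {
      for (i in seq_along(nms)) {
        cand <- seq(max(lower[i], best[i] - steps[i]),
                    min(upper[i], best[i] + steps[i]), by = 1)
        cand <- setdiff(round(cand), best[i])
        for (cv in cand) {
          th <- best; th[i] <- cv
          v <- cl_fun(th, n_sim = spec$n_sim_refine)
          if (v > best_v) { best <- th; best_v <- v }
        }
      }
      steps <- pmax(1, steps / 2)
    }
  } else {
    opt <- stats::optim(best, function(x) {
      x <- pmin(pmax(x, lower), upper)
      -cl_fun(stats::setNames(x, nms), n_sim = spec$n_sim_refine)
    }, method = "Nelder-Mead",
    control = list(maxit = 100, reltol = 1e-6))
    cand <- pmin(pmax(opt$par, lower), upper)
    if (-opt$value > best_v) { best <- stats::setNames(cand, nms); best_v <- -opt$value }
    if (any(is_int)) best[is_int] <- round(best[is_int])
  }
  on_bound <- any(best <= lower | best >= upper)
  structure(list(par = best, logCL = best_v, on_bound = on_bound,
                 path = data.table::rbindlist(path), spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: logCL =", format(x$logCL), "\n")
  if (length(x$par)) {
    for (nm in names(x$par)) cat(sprintf("  %s = %g\n", nm, x$par[nm]))
    if (x$on_bound) cat("  [optimum on a parameter bound]\n")
  }
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for SFS fits
#'
#' Simulates `n_boot` observed-SFS replicates under the fitted model,
#' refits each, and reports percentile intervals. Replicates whose refits
#' error out are dropped and counted.
#'
#' @param spec a [fit_spec()].
#' @param fitted_par named point estimates (as from [fit_parameters()]).
#' @param n_sites sites per simulated replicate (match the observed total).
#' @param n_boot bootstrap replicates (error below 2; at least 20
#'   recommended, warned otherwise).
#' @param level confidence level.
#' @param seed base seed; replicate r uses `seed + r` for data and
#'   `seed + 10000 + r` for its likelihood evaluations.
#' @return object of class `bootstrap_ci`: `ci` (`data.frame` parameter,
#'   lower, point, upper), `estimates` (replicates x parameters),
#'   `n_dropped`, `flagged` (TRUE when `n_boot < 20`).
#' @export
parametric_bootstrap_ci <- function(spec, fitted_par, n_sites, n_boot = 50,
                                    level = 0.95, seed = 1) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  flagged <- n_boot < 20
  if (flagged) warning("n_boot < 20: intervals are unreliable and flagged")
  gen_model <- do.call(spec$builder, as.list(fitted_par))
  ests <- list(); dropped <- 0L
  for (r in seq_len(n_boot)) {
    obs <- simulate_joint_sfs(gen_model, spec$sample_sizes, n_sites,
                              seed = seed + r)
    fit <- tryCatch(
      suppressWarnings(fit_parameters(spec, obs, seed = seed + 10000 + r)),
      error = function(e) NULL)
    if (is.null(fit)) dropped <- dropped + 1L
    else ests[[length(ests) + 1]] <- fit$par
  }
  if (length(ests) < 2) stop("fewer than 2 bootstrap replicates converged")
  em <- do.call(rbind, ests)
  alpha <- (1 - level) / 2
  ci <- data.frame(
    parameter = colnames(em),
    lower = apply(em, 2, stats::quantile, alpha),
    point = as.numeric(fitted_par[colnames(em)]),
    upper = apply(em, 2, stats::quantile, 1 - alpha),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(ci = ci, estimates = em, n_dropped = dropped,
                 flagged = flagged, level = level),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("parametric bootstrap (%d kept, %d dropped, level %.2f)%s\n",
              nrow(x$estimates), x$n_dropped, x$level,
              if (x$flagged) " [flagged: n_boot < 20]" else ""))
  print(x$ci, row.names = FALSE)
  invisible(x)
}
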