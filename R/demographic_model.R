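#' Declarative multi-deme demographic models
#'
#' A `demographic_model` describes a set of demes, each existing over an
#' interval of (backward) time measured in generations before present and
#' carrying a piecewise-constant effective size; population splits that merge
#' a derived deme into its ancestor (looking backwards in time); and symmetric
#' per-generation migration rates between coexisting demes.
#'
#' Conventions:
#' * Time runs backwards: generation 0 is the present, larger is older.
#' * Each deme's epochs are half-open intervals `[start, end)` that tile its
#'   existence interval; the last epoch of the root deme is open-ended
#'   (`end = Inf`).
#' * `size_units` declares whether epoch sizes are diploid individuals
#'   (haplotype pairs coalesce at rate `1/(2N)` per generation) or haploid
#'   gene copies (rate `1/N`), the fastsimcoal2 convention.
#'
#' @param demes named list; one entry per deme, each a `data.frame` with
#'   columns `start`, `end`, `size` (generations, generations, effective size).
#' @param splits `data.frame` with columns `time`, `derived`, `ancestral`:
#'   looking backwards, all lineages of `derived` join `ancestral` at `time`.
#' @param migrations `data.frame` with columns `deme_a`, `deme_b`, `rate`
#'   (symmetric per-generation backward migration probability per lineage),
#'   or `NULL` for none.
#' @param mutation_rate per-base per-generation mutation rate.
#' @param size_units `"diploid"` or `"gene-copies"`.
#' @param outgroup optional list with elements `deme`, `split_time`, `size`
#'   recording which deme plays the outgroup role (metadata only; the split
#'   itself must be present in `splits`).
#' @return an object of class `demographic_model`.
#' @seealso [miyako_model()], [validate_model()], [write_model_json()]
#' @export
demographic_model <- function(demes, splits, migrations = NULL,
                              mutation_rate = 1.25e-8,
                              size_units = c("diploid", "gene-copies"),
                              outgroup = NULL) {
  size_units <- match.arg(size_units)
  stopifnot(is.list(demes), length(demes) >= 1, !is.null(names(demes)))
  demes <- lapply(demes, function(e) {
    e <- as.data.frame(e)[, c("start", "end", "size")]
    e[order(e$start), , drop = FALSE]
  })
  if (is.null(splits)) {
    splits <- data.frame(time = numeric(0), derived = character(0),
                         ancestral = character(0), stringsAsFactors = FALSE)
  } else {
    splits <- as.data.frame(splits)[, c("time", "derived", "ancestral")]
    splits <- splits[order(splits$time), , drop = FALSE]
  }
  if (is.null(migrations)) {
    migrations <- data.frame(deme_a = character(0), deme_b = character(0),
                             rate = numeric(0), stringsAsFactors = FALSE)
  } else {
    migrations <- as.data.frame(migrations)[, c("deme_a", "deme_b", "rate")]
  }
  structure(list(demes = demes, splits = splits, migrations = migrations,
                 mutation_rate = mutation_rate, size_units = size_units,
                 outgroup = outgroup),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("demographic_model: %d demes, %d splits, %d migration pairs (%s sizes)\n",
              length(x$demes), nrow(x$splits), nrow(x$migrations), x$size_units))
  for (d in names(x$demes)) {
    e <- x$demes[[d]]
    cat(sprintf("  %-6s [%g, %g): N = %s\n", d, min(e$start), max(e$end),
                paste(signif(e$size, 5), collapse = " / ")))
  }
  if (nrow(x$splits))
    cat("  splits:", paste(sprintf("%s->%s@%g", x$splits$derived,
                                   x$splits$ancestral, x$splits$time),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Existence interval of a deme
#'
#' @param model a `demographic_model`.
#' @param deme deme id.
#' @return numeric `c(start, end)`, half-open in backward generations.
#' @export
deme_interval <- function(model, deme) {
  e <- model$demes[[deme]]
  if (is.null(e)) stop("unknown deme: ", deme)
  c(min(e$start), max(e$end))
}

#' Demes existing at a time point
#'
#' @inheritParams deme_interval
#' @param time_gen generations before present.
#' @return character vector of deme ids whose existence interval contains
#'   `time_gen`.
#' @export
demes_at <- function(model, time_gen) {
  keep <- vapply(names(model$demes), function(d) {
    iv <- deme_interval(model, d)
    time_gen >= iv[1] && time_gen < iv[2]
  }, logical(1))
  names(model$demes)[keep]
}

#' Effective size of a deme at a time point (in gene copies)
#'
#' Returns `2N` where `N` is the diploid size implied by the model's
#' `size_units`, i.e. the number of gene copies: a haplotype pair coalesces
#' with probability `1/gene_copies(...)` per generation.
#'
#' @inheritParams demes_at
#' @param deme deme id.
#' @return number of gene copies at `time_gen`.
#' @export
gene_copies_at <- function(model, deme, time_gen) {
  e <- model$demes[[deme]]
  if (is.null(e)) stop("unknown deme: ", deme)
  hit <- which(time_gen >= e$start & time_gen < e$end)
  if (!length(hit)) stop(sprintf("deme %s does not exist at generation %g", deme, time_gen))
  n <- e$size[hit[1]]
  if (model$size_units == "diploid") 2 * n else n
}

#' Validate a demographic model
#'
#' Checks structural invariants: positive sizes, per-deme epoch tiling
#' (no gaps or overlaps), split consistency (the derived deme's existence ends
#' exactly at the split time and the ancestral deme exists at that time),
#' tree consistency (every deme except a single root is consumed by exactly
#' one split), and that migration is declared only between demes that coexist
#' for at least one generation. Violations are returned as data, not thrown.
#'
#' @param model a `demographic_model`.
#' @return list with elements `ok` (logical) and `violations`
#'   (character vector, empty when `ok`).
#' @export
validate_model <- function(model) {
  v <- character(0)
  note <- function(...) v <<- c(v, sprintf(...))
  for (d in names(model$demes)) {
    e <- model$demes[[d]]
    if (any(e$size <= 0)) note("deme %s: non-positive epoch size", d)
    if (any(e$end <= e$start)) note("deme %s: epoch with end <= start", d)
    if (nrow(e) > 1) {
      gaps <- e$start[-1] - e$end[-nrow(e)]
      if (any(gaps > 0)) note("deme %s: gap between consecutive epochs", d)
      if (any(gaps < 0)) note("deme %s: overlapping epochs", d)
    }
  }
  sp <- model$splits
  for (i in seq_len(nrow(sp))) {
    t <- sp$time[i]; de <- sp$derived[i]; an <- sp$ancestral[i]
    if (t <= 0) note("split %s->%s: time must be > 0", de, an)
    if (is.null(model$demes[[de]])) { note("split references unknown derived deme %s", de); next }
    if (is.null(model$demes[[an]])) { note("split references unknown ancestral deme %s", an); next }
    if (!isTRUE(all.equal(deme_interval(model, de)[2], t)))
      note("split %s->%s@%g: derived deme exists beyond the split time", de, an, t)
    iva <- deme_interval(model, an)
    if (!(t >= iva[1] && t < iva[2]))
      note("split %s->%s@%g: ancestral deme does not exist at the split time", de, an, t)
  }
  # tree consistency: exactly one open-ended root; all others consumed once
  ends <- vapply(names(model$demes), function(d) deme_interval(model, d)[2], numeric(1))
  roots <- names(model$demes)[is.infinite(ends)]
  if (length(roots) != 1) {
    note("model must have exactly one root deme (open-ended epoch); found %d", length(roots))
  } else {
    for (d in setdiff(names(model$demes), roots)) {
      k <- sum(sp$derived == d)
      if (k != 1) note("deme %s must be the derived member of exactly one split (found %d)", d, k)
    }
  }
  mg <- model$migrations
  for (i in seq_len(nrow(mg))) {
    a <- mg$deme_a[i]; b <- mg$deme_b[i]
    if (mg$rate[i] < 0 || mg$rate[i] >= 1) note("migration %s-%s: rate must be in [0,1)", a, b)
    if (is.null(model$demes[[a]]) || is.null(model$demes[[b]])) {
      note("migration %s-%s references an unknown deme", a, b); next
    }
    iva <- deme_interval(model, a); ivb <- deme_interval(model, b)
    if (min(iva[2], ivb[2]) <= max(iva[1], ivb[1]))
      note("migration %s-%s: demes never coexist", a, b)
  }
  list(ok = length(v) == 0, violations = v)
}

#' The fitted five-population Okinawa/Miyako island model
#'
#' Builds the fitted demographic model for the five sampled populations
#' CHB (outgroup), OKI (Okinawajima), MYNE (Miyakojima northeast),
#' MYSW (Miyakojima southwest) and IKM (Irabu/Ikema). Looking backwards in
#' time, OKI and MYNE merge into the ancestral Ryukyu trunk (RYU) at
#' `TDIV_OKI`; MYSW joins the trunk at `TDIV_MYSW`; IKM at `TDIV_IKM`; the
#' trunk joins the root (ANC) at `TDIV_RYU`; and the outgroup joins the root
#' at `TDIV_CHB`. IKM carries three size epochs (most recent `N_IKM_1`) with
#' boundaries at `TINC_IKM` and `T_IKM_2`; OKI two epochs with a boundary at
#' `T_OKI_SIZE`. Recent symmetric migration connects the four Ryukyu demes
#' while they coexist. All defaults are the published point estimates; every
#' parameter is overridable, and epoch boundaries are clipped to the
#' (possibly overridden) split times so one-parameter refits stay valid.
#'
#' Sizes default to haploid gene copies (`size_units = "gene-copies"`), the
#' fastsimcoal2 convention under which the model's simulated F_ST between
#' MYNE and IKM matches the published pairwise estimate; pass
#' `size_units = "diploid"` to reinterpret the same numbers as diploid sizes.
#'
#' @param TDIV_OKI,TDIV_MYSW,TDIV_IKM,TDIV_RYU split times (generations).
#' @param TINC_IKM first IKM size-change time; second boundary `T_IKM_2`
#'   defaults to `2 * TINC_IKM`.
#' @param N_OKI_1,N_OKI_2,N_MYNE,N_MYSW,N_IKM_1,N_IKM_2,N_IKM_3,N_RYU
#'   effective sizes (units per `size_units`).
#' @param M_OKI_MYNE,M_OKI_MYSW,M_OKI_IKM,M_MYNE_MYSW,M_MYNE_IKM,M_MYSW_IKM
#'   symmetric per-generation migration rates.
#' @param TDIV_CHB,N_CHB fixed outgroup split time and size (the root deme
#'   also takes size `N_CHB`).
#' @param T_OKI_SIZE boundary between `N_OKI_1` and `N_OKI_2`.
#' @param T_IKM_2 boundary between `N_IKM_2` and `N_IKM_3`.
#' @param mutation_rate per-base per-generation mutation rate.
#' @param size_units `"gene-copies"` (default) or `"diploid"`.
#' @return a valid `demographic_model`.
#' @examples
#' m <- miyako_model()
#' validate_model(m)$ok
#' length(demes_at(m, 0))    # 5 sampled demes
#' length(demes_at(m, 120))  # trunk + outgroup
#' @export
miyako_model <- function(TDIV_OKI = 7, TDIV_MYSW = 16, TDIV_IKM = 41,
                         TDIV_RYU = 109, TINC_IKM = 10,
                         N_OKI_1 = 21892, N_OKI_2 = 21616, N_MYNE = 28429,
                         N_MYSW = 10226, N_IKM_1 = 16187, N_IKM_2 = 14513,
                         N_IKM_3 = 6085, N_RYU = 4083,
                         M_OKI_MYNE = 3.44e-4, M_OKI_MYSW = 8.95e-5,
                         M_OKI_IKM = 7.09e-8, M_MYNE_MYSW = 4.22e-6,
                         M_MYNE_IKM = 1.47e-6, M_MYSW_IKM = 1.64e-9,
                         TDIV_CHB = 3000, N_CHB = 20000,
                         T_OKI_SIZE = ceiling(TDIV_OKI / 2),
                         T_IKM_2 = 2 * TINC_IKM,
                         mutation_rate = 1.25e-8,
                         size_units = c("gene-copies", "diploid")) {
  size_units <- match.arg(size_units)
  stopifnot(TDIV_OKI > 0, TDIV_MYSW > TDIV_OKI, TDIV_IKM > TDIV_MYSW,
            TDIV_RYU > TDIV_IKM, TDIV_CHB > TDIV_RYU)
  epochs <- function(bounds, sizes) {
    # clip boundaries to the deme's existence end and drop empty epochs
    df <- data.frame(start = bounds[-length(bounds)], end = bounds[-1],
                     size = sizes)
    df <- df[df$end > df$start, , drop = FALSE]
    df
  }
  ikm_b <- sort(unique(pmin(c(0, TINC_IKM, T_IKM_2, TDIV_IKM), TDIV_IKM)))
  ikm_sizes <- c(N_IKM_1, N_IKM_2, N_IKM_3)[seq_len(length(ikm_b) - 1)]
  oki_b <- sort(unique(pmin(c(0, T_OKI_SIZE, TDIV_OKI), TDIV_OKI)))
  oki_sizes <- c(N_OKI_1, N_OKI_2)[seq_len(length(oki_b) - 1)]
  demes <- list(
    CHB  = epochs(c(0, TDIV_CHB), N_CHB),
    OKI  = epochs(oki_b, oki_sizes),
    MYNE = epochs(c(0, TDIV_OKI), N_MYNE),
    MYSW = epochs(c(0, TDIV_MYSW), N_MYSW),
    IKM  = epochs(ikm_b, ikm_sizes),
    RYU  = epochs(c(TDIV_OKI, TDIV_RYU), N_RYU),
    ANC  = data.frame(start = TDIV_RYU, end = Inf, size = N_CHB)
  )
  splits <- data.frame(
    time      = c(TDIV_OKI, TDIV_OKI, TDIV_MYSW, TDIV_IKM, TDIV_RYU, TDIV_CHB),
    derived   = c("OKI", "MYNE", "MYSW", "IKM", "RYU", "CHB"),
    ancestral = c("RYU", "RYU", "RYU", "RYU", "ANC", "ANC"),
    stringsAsFactors = FALSE
  )
  migrations <- data.frame(
    deme_a = c("OKI", "OKI", "OKI", "MYNE", "MYNE", "MYSW"),
    deme_b = c("MYNE", "MYSW", "IKM", "MYSW", "IKM", "IKM"),
    rate   = c(M_OKI_MYNE, M_OKI_MYSW, M_OKI_IKM,
               M_MYNE_MYSW, M_MYNE_IKM, M_MYSW_IKM),
    stringsAsFactors = FALSE
  )
  demographic_model(demes, splits, migrations,
                    mutation_rate = mutation_rate, size_units = size_units,
                    outgroup = list(deme = "CHB", split_time = TDIV_CHB,
                                    size = N_CHB))
}

#' Serialize a demographic model to JSON
#'
#' Round-trip exact: `read_model_json(write_model_json(m, f))` reproduces `m`
#' value-for-value (`Inf` epoch ends are encoded as the string `"Inf"`).
#'
#' @param model a `demographic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  x <- list(
    demes = lapply(model$demes, function(e) {
      e$end <- ifelse(is.finite(e$end), e$end, "Inf")
      e
    }),
    splits = model$splits,
    migrations = model$migrations,
    mutation_rate = model$mutation_rate,
    size_units = model$size_units,
    outgroup = model$outgroup
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  demes <- lapply(x$demes, function(e) {
    e <- as.data.frame(e)
    e$end <- suppressWarnings(as.numeric(ifelse(e$end == "Inf", Inf, e$end)))
    e$start <- as.numeric(e$start); e$size <- as.numeric(e$size)
    e
  })
  og <- x$outgroup
  if (!is.null(og)) og <- as.list(og)
  demographic_model(demes, x$splits,
                    if (length(x$migrations)) x$migrations else NULL,
                    mutation_rate = x$mutation_rate,
                    size_units = x$size_units, outgroup = og)
}

# Flatten a model + sample sizes into the arrays the C++ engine consumes.
# Returns integer deme indices (0-based), per-deme epoch tables, split events
# and migration windows, all with sizes converted to gene copies.
compile_sim_plan <- function(model, sample_sizes) {
  val <- validate_model(model)
  if (!val$ok)
    stop("invalid demographic model:\n  ", paste(val$violations, collapse = "\n  "))
  ids <- names(model$demes)
  sample_sizes <- sample_sizes[sample_sizes > 0]
  if (length(sample_sizes) && is.null(names(sample_sizes)))
    stop("sample_sizes must be a named vector (deme -> diploid count)")
  bad <- setdiff(names(sample_sizes), ids)
  if (length(bad)) stop("sample_sizes name unknown demes: ", paste(bad, collapse = ", "))
  for (d in names(sample_sizes)) {
    if (deme_interval(model, d)[1] != 0)
      stop("cannot sample from deme ", d, " which does not exist at generation 0")
  }
  fac <- if (model$size_units == "diploid") 2 else 1
  ep <- do.call(rbind, lapply(seq_along(ids), function(i) {
    e <- model$demes[[ids[i]]]
    data.frame(deme = i - 1L, start = e$start, end = e$end,
               gene_copies = fac * e$size)
  }))
  sp <- model$splits
  splits <- data.frame(time = sp$time,
                       derived = match(sp$derived, ids) - 1L,
                       ancestral = match(sp$ancestral, ids) - 1L)
  mg <- model$migrations
  mig <- NULL
  if (nrow(mg)) {
    w <- lapply(seq_len(nrow(mg)), function(i) {
      iva <- deme_interval(model, mg$deme_a[i])
      ivb <- deme_interval(model, mg$deme_b[i])
      c(start = max(iva[1], ivb[1]), end = min(iva[2], ivb[2]))
    })
    w <- do.call(rbind, w)
    mig <- data.frame(a = match(mg$deme_a, ids) - 1L,
                      b = match(mg$deme_b, ids) - 1L,
                      rate = mg$rate, start = w[, "start"], end = w[, "end"])
    mig <- mig[mig$rate > 0 & mig$end > mig$start, , drop = FALSE]
  }
  list(ids = ids, epochs = ep, splits = splits, migrations = mig,
       sample_demes = match(names(sample_sizes), ids) - 1L,
       sample_sizes = as.integer(sample_sizes))
}
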