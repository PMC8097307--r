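---
title: "Methods: fine-scale island demography from SNP genotypes"
author: "islandpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale island demography from SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandpopgen)
```

# Scope

`islandpopgen` implements a desk-scale version of the inference chain used in
fine-scale island demography studies of the southern Ryukyu archipelago: a
declarative multi-population demographic model; a coalescent simulator that
stands in for non-public biobank genotypes; SNP-array quality control; the
classical population-genetic statistics (Hudson's F_ST, Patterson's D, runs
of homozygosity, PCA); IBD segment detection and a haplotype-sharing index;
recent effective-size (Ne) estimation from IBD length spectra; and SFS
composite-likelihood demographic fitting with parametric-bootstrap intervals.

The shipped `miyako_model()` encodes the fitted five-population model for
CHB (outgroup), Okinawajima (OKI), Miyakojima northeast (MYNE), Miyakojima
southwest (MYSW) and Irabu/Ikema (IKM): backwards in time OKI and MYNE merge
into an ancestral Ryukyu trunk at generation 7, MYSW joins at 16, IKM at 41,
the trunk joins the root at 109, and the outgroup joins the root at a fixed
3000 generations. IKM carries three size epochs with boundaries at 10 and 20
generations; symmetric migration (rates of order 1e-4 and below) connects
the four island demes while they coexist.

# The demographic model and its conventions

Time runs backwards in integer generations; each deme's piecewise-constant
size history is a set of half-open epochs that tile its existence interval,
and `validate_model()` checks tiling, split consistency and tree topology,
returning violations as data.

**Size units.** Effective sizes can be declared as diploid individuals
(pairwise coalescence probability $1/(2N)$ per generation) or haploid gene
copies ($1/N$), and `miyako_model()` defaults to gene copies — the
fastsimcoal2 convention. This resolves a genuine factor-two ambiguity in
published parameter tables by an internal-consistency argument: simulating
100,000 sites under the fitted model and computing Hudson's F_ST between
MYNE and IKM gives $\approx 6.6\times10^{-3}$ under the gene-copies reading,
matching the published pairwise estimate $6.79\times10^{-3}$, whereas the
diploid reading gives $\approx 3.3\times10^{-3}$, a factor-two miss. The
`size_units` switch exposes both readings.

**Outgroup parameters.** The outgroup's split time (3000 generations) and
size (20,000) are fixed defaults, not estimates: published figures show them
only as fixed parenthetical values. Both are arguments of `miyako_model()`.

**Epoch boundaries.** The IKM size-change time of 10 generations is a point
estimate; the second boundary (between the middle and oldest IKM epochs) is
not separately published and defaults to twice the first. The OKI epoch
boundary defaults to `ceiling(TDIV_OKI / 2)`; the two OKI sizes differ by
about 1% so this choice is immaterial. All boundaries are arguments and are
clipped to the (possibly overridden) split times, so one-parameter refits
always produce valid models.

# The coalescent simulator

Two engines are used instead of one ancestral-recombination-graph simulator,
because none of the statistics in scope needs a full multi-sample ARG.

**Independent sites.** Each site is an independent genealogy from the
discrete-generation structured coalescent: per generation, each pair of
lineages in a deme coalesces with probability $1/\mathrm{gc}$ (gene copies),
and lineages migrate with the per-generation rates. The implementation steps
generation-by-generation while the total event intensity is large (binomial
numbers of events per generation, so multiple mergers in one generation are
possible, as in a Wright-Fisher population) and switches to geometric
waiting-time jumps when the intensity drops below 0.1 per generation; epoch
boundaries and splits bound every jump. One mutation per genealogy is placed
uniformly on the total branch length, so every emitted site is segregating
in the pooled sample — the behaviour of SNP-array-like data conditioned on
polymorphism.

**Site weighting.** The genealogy underlying a random *segregating site* is
not a plain draw from the coalescent: trees with more total branch length
carry more mutations, so the correct marginal weights trees proportionally
to total length (the $\theta \to 0$ limit of the infinite-sites model).
`simulate_sites()` and `simulate_allele_counts()` therefore sample each
site's genealogy length-weighted, by rejection against an envelope
calibrated on 200 pilot genealogies (truncation above the envelope
contributes a relative bias well under $10^{-3}$). Without this weighting
the unfolded SFS of a constant-size deme is visibly singleton-inflated
($E[\ell_i/L]$ instead of $E[\ell_i]/E[L] \propto 1/i$). The
`site_weighting = "none"` mode draws plain genealogies and is the right
choice when per-tree quantities such as the TMRCA are themselves under
study; the package's tests exercise both against analytic expectations and
against msprime as an independent oracle. A Poisson-mutation mode
(`mutation = "poisson"`) drops `Poisson(mu * L)` mutations on each of a
fixed number of genealogies, in which case sites sharing a tree are
correlated but each site's tree is length-weighted by construction.

**IBD truth.** `simulate_pairwise_ibd()` runs the sequentially Markov
coalescent for a haplotype pair along a chromosome: the TMRCA is piecewise
constant, recombinations arrive at rate $2T$ per Morgan, and at each
recombination the detached lineage re-coalesces under the piecewise-constant
size history (binary-searched cumulative hazards make each redraw O(log
pieces)). Maximal spans of constant TMRCA are the ground-truth IBD segments;
before any length threshold they tile the chromosome exactly. Migration is
ignored here: the generator follows a single deme through its split chain,
which is the regime the Ne-from-IBD stage assumes anyway.

# Quality control

`apply_qc()` applies, in a fixed documented order: site call rate (>= 98%),
sample call rate (>= 98%), the Levene-Haldane exact Hardy-Weinberg test
(p > 1e-6; probability-mass two-sidedness, computed by the standard
recurrence and exact to numerical precision), minor-allele frequency
(strictly positive), and greedy relatedness pruning of pairs with
$\hat\pi > 0.25$ (method-of-moments IBD from IBS counts, PLINK-style),
keeping the member with the higher call rate. The order is not dictated by
the underlying study; it is fixed here for reproducibility, and re-running
the chain on its own output is a no-op. Allele frequencies for $\hat\pi$
are estimated from the post-MAF panel.

# Statistics

**Hudson's F_ST** uses the ratio-of-averages estimator with per-locus
numerator $(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$ and
denominator $p_1(1-p_2)+p_2(1-p_1)$; it is robust to the strongly unequal
sample sizes typical of island cohorts. The published study does not name
its estimator; Weir-Cockerham is provided as an alternative flag and agrees
closely on balanced designs. Standard errors come from a weighted
delete-one-block jackknife (Busing's formula) over contiguous 5 cM blocks
when a genetic map is available, otherwise 200 equal-count blocks.

**Patterson's D** follows the frequency form
$D = \sum (p_1-p_2)(p_3-p_4) / \sum (p_1+p_2-2p_1p_2)(p_3+p_4-2p_3p_4)$
with the convention that positive values indicate excess sharing between P2
and P4 (or P1 and P3); with the quartet ordered (outgroup, source; X, Y),
positive D means source-Y sharing. The Z score uses the same weighted block
jackknife. `dstat_from_sfs()` computes the identical statistic from a joint
SFS (an algebraic identity, tested to 1e-12).

**ROH** detection is a PLINK-style sliding-window scan (50-site windows,
at most 1 heterozygote and 5 missing calls per window; runs kept at >= 50
sites and >= 1 Mb). The underlying study defers its ROH settings to a
supplement; these defaults are declared, not reconstructed, and are all
exposed.

**PCA** standardizes genotypes by $\sqrt{2p(1-p)}$ after mean imputation
and returns SVD scores.

# IBD detection, merging and sharing

One bespoke seed-and-extend detector replaces the three external tools used
in the underlying study (the study's own robustness argument — consistent
results across detectors — becomes a truth-versus-detected consistency test
here). Exact-match words of 64 consecutive sites seed candidate haplotype
pairs; each candidate pair's XOR mismatch profile is scanned for
breakpoints, defined as more than `max_mismatch = 2` discordances within a
`break_window` of 16 sites; spans between breakpoints that contain a seeded
word and reach `min_cM = 6` are reported. The break window is deliberately
tighter than the seed so that an isolated discordance (a genotyping error
inside a true segment) near a boundary is not absorbed into the boundary's
mismatch cluster, which would clip the reported end — with the window at
16 sites the endpoint error stays below 0.5 cM at typical array densities.
`merge_segments()` closes artificial breaks (gap <= 0.6 cM with at most one
discordant site in the gap), mirroring the published pipeline's merge step
whose exact thresholds are not printed.

The haplotype-sharing index between populations I and J is the mean total
shared cM per cross-population individual pair, times 100; within one
population the mean runs over the $n(n-1)/2$ unordered pairs (the published
equation is stated for two populations only).

# Ne from IBD length spectra ("IBDNe-lite")

For a haplotype pair, the probability of coalescing exactly $g$ generations
ago under a diploid trajectory $N_1, \dots, N_G$ is
$P(g) = \frac{1}{2N_g}\prod_{k<g}\left(1-\frac{1}{2N_k}\right)$, and given
TMRCA $g$ the expected number of maximal IBD spans with length in $[a, b)$
Morgans on a genome of $L$ Morgans is $L \cdot 2g\,(e^{-2ga}-e^{-2gb})$
(edge effects ignored). `fit_ne()` maximizes the Poisson composite
log-likelihood of binned counts of detected segments (>= 6 cM; the last bin
right-censored) over per-generation log sizes with a squared
second-difference penalty on $\log N$, bounded L-BFGS with an analytic
gradient, initialized at the constant-size moment estimate. The penalty
weight scales with the total observed count, which makes the estimator
invariant to replicating the data; the default weight (1 per observed
segment) was chosen by recovery experiments — it reproduces a constant
N = 5,000 within a few percent (harmonic mean over generations 4-50) while
still localizing a five-fold, 10-generation-old bottleneck. This is
deliberately "IBDNe-lite": no detection-error deconvolution and no
chromosome-edge corrections, validated by parameter recovery rather than
against the external tool. As with the published method, a strong bottleneck
leaves little information about sizes older than the bottleneck; estimates
there are smoothness-driven.

Diploid sample pairs contribute four haplotype pairs to `n_pairs`.

# SFS composite-likelihood fitting

`fit_parameters()` follows the fastsimcoal2 strategy: entry probabilities of
the observed SFS are estimated by Monte-Carlo simulation under candidate
parameters, and the multinomial composite log-likelihood
$\sum_e m_e \log \hat p_e$ is maximized. Design choices that matter:

* **Pairwise objective.** For three or more populations the default
  objective is the sum of all 2D pairwise marginal composite
  log-likelihoods (a standard fastsimcoal2 mode). The full five-way joint
  tensor has $41^5$ cells at 20 diploids per population; with Monte-Carlo
  probabilities almost every observed cell would sit on the pseudo-count
  floor. 2D marginals are dense and well estimated.
* **Marginal zero cells are data.** When a spectrum is marginalized, sites
  segregating only in other populations land in the all-zero cell; those
  cells carry much of the split-time information and are retained in the
  objective. (Entries monomorphic across the *full* sample are excluded,
  consistent with a segregating-sites generator; `exclude_monomorphic`
  controls this.)
* **Matched ascertainment.** When the objective is restricted to a subset
  of populations (`fit_demes`), the per-evaluation simulation still uses the
  full sampling design, because segregating-site ascertainment and length
  weighting depend on every sampled lineage, including the outgroup.
* **Common random numbers.** Every likelihood evaluation reuses one seed,
  making the objective a deterministic function of the parameters.
* **Pseudo-counts.** Where the tensor is small enough to enumerate, empty
  cells receive 0.5 simulated-site equivalents and the tensor is
  renormalized; for larger sparse tensors the same quantity is an
  unrenormalized probability floor for observed-but-unsimulated entries.
* **Noise-robust refinement.** After a coarse grid, integer parameters
  (split times) are swept at step 1 with a larger per-evaluation simulation
  size, and the point estimate is the peak of a quadratic fit to the noisy
  profile rather than the raw argmax, whose position is dominated by
  Monte-Carlo wiggle between adjacent generations. Continuous parameters
  are refined by Nelder-Mead.

Confidence intervals are parametric-bootstrap percentiles (simulate under
the fitted model, refit, take quantiles); the published analysis also
reports simulation-based 95% CIs, with details in a supplement that does
not print the construction, so the bootstrap is declared here. One
parameter (or a small subset) at a time is the supported desk-scale regime;
a full 18-parameter joint fit is possible in principle but takes hours, not
minutes.

# What the synthetic data do and do not establish

The real biobank genotypes are not public, so every quantitative check runs
on data simulated under the published fitted model. A green test therefore
establishes (a) that the implementations are internally correct against
analytic results, enumeration oracles, hand-computed examples and msprime,
and (b) that the published parameter set is internally consistent — e.g. it
reproduces the published MYNE-IKM F_ST, yields strongly positive
D(CHB, OKI; IKM, MYNE), and the split times are recoverable from data of
the published kind. It does not re-establish the published estimates from
real data, and the generator deliberately omits array ascertainment bias,
genotyping error, phasing error and linkage between sites (except in the
SMC engine), all of which affect real-data analyses.

# Numerical and degenerate-input choices

* Simulation is exact discrete-generation Wright-Fisher-style when event
  intensities are high and switches to at-most-one-event geometric jumps
  below intensity 0.1 per generation (second-order error below
  $\lambda^2/2 \approx 0.005$ per generation there).
* The SMC redraw sampler requires a strictly positive hazard in the final
  (open-ended) piece; trajectories are extended as constant beyond their
  horizon.
* `fit_ne` bounds $\log N$ in $[\log 10, \log 10^8]$ and flags
  non-convergence on the result instead of failing.
* Relatedness pruning breaks call-rate ties towards the lexicographically
  larger sample id; QC on an empty matrix returns an explicit empty result.
* `hwe_exact_test` sums probabilities no more probable than the observed
  configuration with a relative tolerance of 1e-12 to absorb rounding.
* Jackknife blocks with zero usable loci are dropped; ratio estimators
  error out when fewer than two blocks or two usable loci remain.

# Known limitations

* Independent-sites simulation cannot produce linkage-dependent statistics
  (LD, haplotype clustering); ROH and IBD validation therefore lean on the
  SMC engine.
* The IBD detector assumes phased haplotypes without switch errors.
* The Ne estimator ignores detection error below and near the 6 cM
  threshold; its oldest-generation estimates are penalty-smoothed.
* Migration during one-parameter refits is held at the generating values;
  joint confounding between migration and split times is not explored at
  desk scale.
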