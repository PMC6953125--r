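---
title: "Quantifying periportalization: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying periportalization: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Hepatocyte gene expression is zonated along the porto-central axis of the
liver lobule: pericentral programs (e.g. glutamine synthesis, many
cytochrome P450s) sit near the central vein, periportal programs (e.g. urea
cycle, gluconeogenesis) near the portal triad. Chronic fibrotic damage
remodels this organization: pericentral programs are lost while periportal
programs persist or extend — "periportalization". zonepipe operationalizes
that claim as a measurable quantity: opposite-signed enrichment of
pericentral and periportal gene sets in a ranked fibrosis
differential-expression signature.

The pipeline has four analysis stages plus a simulator:

1. **Zonation screen** (`call_zonation()`): from layered single-cell UMI
   counts, call genes whose expression changes monotonically from the most
   pericentral layer (1) to the most periportal layer (9).
2. **Consensus sets** (`build_consensus()`): integrate per-study pericentral
   and periportal sets; a gene qualifies when at least two studies agree.
3. **Differential expression** (`run_diffexp()`): per-month CCl4-versus-oil
   contrasts on bulk counts, with empirical-Bayes moderated t-statistics.
4. **Enrichment** (`periportalization_report()`, `ora_test()`,
   `footprint_scores()`, `regulon_activity()`): quantify the zonation shift
   in each month's signature.

# The zonation screen

## Filtering, normalization, layer assignment

Genes expressed (count ≥ 1) in fewer than 15 of the cells are removed; the
threshold mirrors the screen's origin on a 1415-hepatocyte matrix and is
exposed as `min_cells`. "Expressed" means a nonzero count — the simplest
reading, stated here because other conventions (count ≥ 2, CPM thresholds)
exist.

Counts are normalized by per-cell size factors before testing. We use
median-of-ratios factors: the factor of a cell is the median over reference
genes of the ratio of its count to the gene's geometric mean across cells,
rescaled so factors have geometric mean 1. Reference genes are those
expressed in every cell, which makes the estimator exactly equivariant under
rescaling a cell; on sparse UMI matrices where no such gene exists, geometric
means and medians are taken over nonzero entries only. This is a deliberate,
deterministic substitution for pooling/deconvolution normalization: the
downstream trend test is rank-based within genes, so only cross-cell scaling
matters, and a closed-form estimator keeps the stage exactly reproducible
and testable against a longhand oracle.

Each cell is assigned to the layer with the highest membership probability;
exact ties go to the lowest (most pericentral) layer index so results are
deterministic. The probability matrix is an input — the package does not
re-derive spatial positions from landmark genes.

## The Jonckheere–Terpstra trend test

For a gene with expression $x$ across ordered layers $1 \le \dots \le L$,
the JT statistic is

$$U = \sum_{a < b} \Big( \#\{x_a < x_b\} + \tfrac12\,\#\{x_a = x_b\} \Big),$$

the number of concordant between-layer pairs. Under the null of exchangeable
labels, $E[U] = (N^2 - \sum n_i^2)/4$ and the variance has the standard
tie-corrected form; `jt_test()` reports the standardized $z$ and a two-sided
p-value. Both increasing and decreasing monotone profiles are of interest
(periportal and pericentral calls respectively), hence a two-sided screen
with direction read off the sign of $z$; this is stated explicitly because a
one-sided convention would halve the p-values.

The *exact* null is available for tie-free data: $U$ decomposes into
successive-merge Mann–Whitney statistics that are mutually independent under
the null, so the exact distribution is a convolution of Mann–Whitney nulls
(computed from `stats::dwilcox`). `mode = "auto"` uses the exact null up to
`exact_cap = 20` observations and falls back to the tie-corrected normal
approximation otherwise — real layered data (hundreds of cells per layer,
discrete counts full of ties) always take the asymptotic branch; the exact
branch exists because it can be verified against brute-force enumeration,
which anchors the whole screen. Exact two-sided p-values are
$\min(1,\,2\min(P(U \le u),\,P(U \ge u)))$; the tie-free null is symmetric,
so this equals the $|U - E[U]|$ tail.

P-values are BH-adjusted over all genes surviving the expression filter, and
genes with $q \le 0.001$ are called pericentral ($z < 0$) or periportal
($z > 0$).

## Consensus construction

Study gene sets are first passed through an alias table
(`map_aliases()`) so symbols from different decades agree. A gene enters the
consensus for a direction when at least `min_studies = 2` studies report it
with that direction. A gene qualifying in *both* directions across studies
is contradictory evidence; such genes are excluded from both sets and
reported (`$conflicts`) — the underlying convention is not fixed anywhere
authoritative, so the package takes the conservative option and logs it.
Where a source study provides stratified lists (e.g. sex-specific sublists),
merging them into one per-study set is the caller's preprocessing decision;
the constructor takes one pericentral and one periportal set per study.

# Differential expression

## Normalization

Bulk counts are TMM-normalized: scale factors from the trimmed (30% on
M-values, 5% on A-values), precision-weighted mean of log count-fraction
ratios against a reference sample (the one whose upper-quartile count
fraction is closest to the mean), rescaled to geometric mean 1. The
implementation is cross-checked against edgeR's to machine precision in the
test suite. Expression is reported as $\log_2(\mathrm{CPM} + 0.5)$ on
effective library sizes; putting the pseudocount on the CPM scale makes the
transform exactly invariant to rescaling a sample's counts. Note that TMM
factors themselves are *not* exactly invariant under such rescaling — the
precision weights genuinely change — so invariance holds to about 0.03 log2
units, a property shared by the reference implementation.

## Contrasts and the month-6 imputation

The design has untreated month 0, oil months 2 and 12, and CCl4 months 2, 6
and 12 (six replicates each). Month 6 lacks oil controls; the oil effect is
nearly constant over time, so the month-6 oil group mean is imputed as the
arithmetic mean of the month-2 and month-12 oil means, *on the log2-CPM
scale* (the alternative — imputing raw counts — is a defensible reading; the
log-scale choice is flagged here as an interpretation). The imputed group
contributes to the contrast mean only: in
$\mathrm{ccl4}_6 - \mathrm{oil}_6$, the oil term is expanded as
$\tfrac12(\mathrm{oil}_2 + \mathrm{oil}_{12})$, the standard error follows
from the real groups' coefficients, and the residual degrees of freedom are
$n - \#\text{real groups}$ — imputation adds no information to the variance
pool.

## Moderated statistics

Per-gene residual variances $s^2$ (pooled across groups, $d$ df) are shrunk
toward an empirical-Bayes prior $(d_0, s_0^2)$ fitted by method-of-moments
on $\log s^2$: the excess of the log-variance dispersion over the
$\psi'(d/2)$ sampling term determines $d_0$ through the monotone inverse of
the trigamma function, and the mean determines $s_0^2$. Zero or negative
excess yields $d_0 = \infty$ with $s_0^2$ the mean observed variance. The
moderated statistic is

$$\tilde s^2 = \frac{d_0 s_0^2 + d\,s^2}{d_0 + d}, \qquad
  t = \frac{\widehat{\mathrm{logFC}}}{u\,\tilde s}, \qquad
  t \sim t_{d_0 + d},$$

with $u$ the contrast's unit standard error. At $d_0 = 0$ this is the
ordinary t-statistic; at $d_0 = \infty$ a z-test at the pooled variance.
The test suite pins exact agreement with limma's empirical-Bayes path on
shared fixtures. Robust or trended priors and count-level (voom-style)
precision weights are intentionally out of scope: moderation is applied to
log2-CPM directly, and the validation surface is recovery on synthetic data,
not numerical identity with any particular historical run.

DE calls use $|\mathrm{logFC}| \ge 1.5$ and $q \le 0.05$ (boundaries
inclusive); the overlap analysis relaxes this to $0.8 / 0.2$ and takes the
union of per-month intersections with a zonation set.

# Enrichment

## GSEA

Signatures are genes ranked by moderated t, descending, ties broken by gene
id. The enrichment score is the classic weighted Kolmogorov–Smirnov running
sum: hits advance by $|t|^w$ (normalized over the set's hits; $w = 1$ by
default), misses retreat by $1/(n-k)$, and ES is the extremum of maximal
absolute deviation. Genes in a set but absent from the signature are dropped
and counted. The leading edge is the set members at or before (positive ES)
/ at or after (negative ES) the peak.

Significance comes from a gene-set permutation null — random same-size sets
drawn from the signature — since sample permutation is impossible on a
single contrast. With $b$ of the $m$ sign-matched null scores at least as
extreme as the observed ES, $p = (1+b)/(1+m)$, one-tailed on the observed
sign. Dividing by the sign-matched count (rather than the total permutation
count) is what makes the p-value uniform under the null, a property the test
suite checks by KS test; the attainable minimum is $1/(1+m) \approx
2/n_{\mathrm{perm}}$. NES is ES divided by the mean $|$null ES$|$ of
matching sign — NES conventions differ between implementations, so ours is
stated here. The two consensus sets per signature are reported without
multiplicity adjustment, deliberately. No adaptive tail approximation is
used; p-values are floored at the permutation resolution.

## ORA, footprint and regulon scores

Over-representation of a query list in a set against a fixed background of
20,000 genes (a typical quantified mouse transcriptome) uses the one-sided
Fisher exact test, i.e. the hypergeometric upper tail; the odds ratio is
computed from the 2×2 table with a 0.5 continuity correction only when a
cell is zero (and flagged).

Footprint pathway activity is the weight–statistic inner product over a
pathway's most-responsive genes, standardized against a permutation null
that reassigns statistics to genes; the weight matrix is an input file, not
a constant, because footprint models are version-dependent. Regulon (TF)
activity rank-transforms the signature to standard-normal quantiles and
scores $\sum_t \mathrm{mode}_t\,q_t / \sqrt{\#\text{targets}}$ — a
deliberately simplified rank-based analogue of analytic regulon enrichment,
without interaction-likelihood weights, multi-tail blending, or pleiotropy
correction. Both scores are exactly antisymmetric under negation of the
signature, which the tests exploit.

# The simulator

`simulate_layered_cells()` emulates the layered single-cell study: 1415
cells over 9 layers (uniform true layers), a Dirichlet layer-probability
row per cell with extra concentration (default 10, on a base of 0.3) on the
true layer — the source data provide such probabilities but no generative
recipe, so sharpness is an exposed placeholder. Planted profiles are
geometric (constant log2 step per layer, total range `profile_amplitude`,
default 2), which guarantees the strict monotonicity the screen targets;
unplanted genes are flat. Counts are negative-binomial with
$\mathrm{Var} = \mu + \phi\mu^2$ and a single global $\phi$ (default 0.1,
Poisson at 0), scaled by log-normal per-cell size factors (sdlog 0.3) to
exercise normalization. Baseline per-gene depth is log-normal (median 0.2
UMI/cell, sdlog 1.2 — sparse whole-transcriptome scale; exposed as
`depth_meanlog`/`depth_sdlog`).

`simulate_bulk_timecourse()` generates the six-group fibrosis design (six
replicates each). CCl4 group means are shifted by planted log2 fold changes;
the defaults encode the biology the pipeline is meant to detect:
pericentral genes progressively down (−1.5, −2, −3 at months 2, 6, 12) and
periportal genes transiently up (+1.5, +1.5, 0) — the transient profile
matches the observation that periportal enrichment is significant at months
2 and 6 but not 12. `simulate_study_sets()` produces noisy per-study set
pairs (sensitivity/false-positive-rate model) for exercising the consensus
rule. All randomness flows from the single config seed; identical configs
give byte-identical outputs.

What the simulator does **not** emulate: doublets, ambient RNA, batch
effects, gene–gene correlation, non-monotone ("porto-central peaking")
zonation profiles, or library-size dependence on biology. Passing tests
therefore show that the statistical machinery recovers planted structure
under clean assumptions — not that real data meet those assumptions.

# Power, depth, and what the recovery experiments mean

Detection power of the trend screen is set jointly by amplitude, cell
number, dispersion, *and expression depth*. At 1415 cells and amplitude 2, a
gene with mean expression below roughly 0.1 UMI/cell is undetectable by any
trend test — most of its per-cell observations are zero ties. At the sparse
default depth about a quarter of planted genes sit below that floor, so
whole-panel sensitivity measures the depth distribution more than the
screen. The recovery experiments (tests and the acceptance script) therefore
plant genes at quantifiable depth (`depth_meanlog = 0`, median 1 UMI/cell),
where sensitivity ≥ 0.9 at empirical FDP ≤ 0.05 is the meaningful statement
about the screen itself; the sparser default remains in force everywhere
else.

Similarly, the bulk DE stage with six replicates and $\phi = 0.1$ has a
delta-method standard error of about $\sqrt{2\phi/6}/\ln 2 \approx 0.27$
log2 units per contrast, so individual logFC estimates scatter accordingly;
the tests check unbiasedness and coverage at that precision (and a bias
bound away from the detection floor, where the CPM pseudocount attenuates
estimates toward zero), and FDR control at $q \le 0.05$.

# Problem sizes and numerical choices

The shipped experiments use 200–2,000 genes, up to 1,415 cells, 500–10,000
GSEA permutations, and enumeration oracles up to $n = 8$; these sizes were
chosen so the full suite reruns quickly on one CPU while keeping every
Monte-Carlo margin (3 SE bands, KS calibration at α = 0.01) meaningful.
Other numerical conventions, collected: probability rows must sum to 1
within 1e-9; layer-assignment ties break low; signature ties break
lexicographically; BH is applied per screened matrix; the trigamma inverse
uses the monotone Newton iteration; the exact JT branch refuses ties rather
than approximating them silently; zero-total cells or samples are reported
by name rather than silently dropped.

# Known limitations

- Normalization substitutions (median-of-ratios for cells, no voom weights
  for bulk) are documented choices, adequate for rank-based and
  moderated-mean inference here, but they are not the historical tools'
  outputs gene-for-gene.
- The regulon score is a simplified rank-based analogue, suitable for
  direction and relative magnitude, not for reproducing a specific tool's
  activity values.
- The consensus stage takes per-study sets as given; it does not model
  study-specific sensitivity or resolve symbol ambiguity beyond the alias
  table.
- GSEA p-values are floored at the permutation resolution
  ($\approx 2/n_{\mathrm{perm}}$); reporting deep tails requires raising
  `n_perm`.
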