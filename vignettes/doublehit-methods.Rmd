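---
title: "Methods: secondary-drug ranking and the single-cell double-hit screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secondary-drug ranking and the single-cell double-hit screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doublehit)
```

This vignette documents the models, conventions and design choices behind
each stage of the pipeline, what the synthetic-data generators do and do not
emulate, and the package's known limitations.

## 1. Resistance classification and secDrug ranking

The input is a drug × cell-line matrix of IC50 values
R~ki~ (nM), with the primary drug's row S~bi~. A cell line is
**resistant** to the primary drug iff its IC50 is *strictly greater* than
the empirical q-quantile of the primary drug's non-missing IC50s. Two
conventions matter and are fixed deliberately:

* **Quantile definition** — linear interpolation between order statistics
  (`stats::quantile` type 7). With values {1, 2, 3, 4} and q = 0.5 the
  threshold is 2.5.
* **Strict inequality** — if every line has the same IC50, *no* line is
  resistant; a degenerate distribution should not manufacture a resistant
  class.

The classification quantile defaults to **q = 0.75**: the upper quartile is
a conservative resistant set that still leaves enough lines to rank
against. The literature that motivates this design states that *a* quantile
threshold is used without fixing it, so q is an exposed, documented
parameter rather than a constant.

A candidate drug k **kills** resistant line i when R~ki~ ≤ its kill
threshold. The default kill rule is *per-drug relative*: the threshold is
drug k's own median IC50 across **all** lines (q_kill = 0.5), so a line is
"killed" when it sits in the more-sensitive half of that drug's potency
range. An absolute concentration cutoff is available
(`kill_rule("absolute", cutoff_nM = …)`) for sensitivity analysis, but the
relative rule is the default because raw cross-drug comparisons of IC50
magnitudes conflate potency scale with differential sensitivity.

Ranking order: kill count (desc), then **mean log10 IC50 over the evaluable
resistant lines** (asc), then drug id (asc). The tie-break mean is taken on
the log scale so a single extreme line cannot dominate, and over the
resistant lines because that is the population the secondary drug is being
chosen for. The final id tie-break makes rankings byte-deterministic.
Missing R~ki~ removes line i from both the numerator and denominator for
drug k; drugs covering fewer than half of the resistant lines are flagged
`low_coverage`, not dropped.

No optimization or regularization machinery is attached to the ranking: the
procedure is exactly classification + counting + tie-breaks, which is the
part that is fully specified and testable.

## 2. Dose-response estimation

Survival readings are normalized so the untreated-control mean is 100%.
IC50s come from the variable-slope sigmoid (4PL)

$$S(D) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}{1 + (D/\mathrm{IC50})^{h}},$$

fitted by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with the
IC50 parameterized on log10 concentration — this makes the optimization
scale-equivariant (rescaling doses rescales the fitted IC50 exactly) and
well-conditioned across decades. Zero-dose points are excluded from the
sigmoid (they anchor normalization only); replicates are pooled, not
averaged, so the residual sum of squares reflects replicate scatter; no
weighting by default, optional 1/Y weighting. Initialization: top = max
observed, bottom = min observed, IC50 = dose nearest the half-range,
h = 1. A fitted IC50 outside [min dose / 10, max dose × 10] is an
extrapolation and is reported with `converged = FALSE`; a curve whose
dose-mean survival increases monotonically (no kill) is refused with a
"no response" error rather than fitted.

## 3. Median-effect synergy

Single agents are summarized by the median-effect equation
$f_a/f_u = (D/D_m)^m$, fitted by OLS on the linearized form
$\log(f_a/f_u) = m\log D - m \log D_m$. Points with $f_a$ outside
[ε, 1 − ε] are excluded (ε = 0.005 by default) because the logit explodes
at the extremes; at least three usable points are required and the plot's
linear correlation r is reported as a fit diagnostic.

For a combination pair (d₁, d₂) at *observed* combined effect $f_a$ (never
a predicted one), the two-term (mutually exclusive) combination index is

$$CI = \frac{d_1}{D_{x1}} + \frac{d_2}{D_{x2}}, \qquad
D_{xj} = D_{mj}\left(\frac{f_a}{1-f_a}\right)^{1/m_j}.$$

Band conventions: CI ≤ 0.3 strong synergism (the 0.1–0.3 and < 0.1
reporting ranges are merged), 0.3–0.9 synergism, 0.9–1.1 additive window,
\> 1.1 antagonism window; edges fall to the lower band. The two synergy
bands are standard; the outer windows are customary extensions and labelled
as such. The three-term mutually-nonexclusive CI variant is out of scope.

Two identities anchor the implementation and its tests: a drug combined
with itself at (D/2, D/2) has CI = 1 exactly, and a combination point's
normalized isobologram coordinate sum *is* its CI. The combination
generator inverts the CI equation by bisection on $f_a$ (the dose sum is
strictly decreasing in $f_a$, so the root is unique), which makes the
generator an independent oracle for `compute_ci()`.

## 4. Single-cell double-hit screen

Counts are normalized per cell to 10,000 and log(1 + x) transformed.
Clustering is an **input**: the package ships only a deterministic k-means
on top principal components (`cluster_baseline()`) for fixture generation,
and a nearest-centroid label transfer (`transfer_labels()`) to put post
cells into the pre label space; graph-based clustering and embeddings are
out of scope.

A marker program scores each cell by the mean signed log-normalized
expression of its genes (down-direction genes negated). The **positivity
rule** — a cell is positive iff more than half of the program's up-genes
have nonzero counts — is a documented choice: "high expression" of a
pathway is qualitative in the motivating analyses, and a
fraction-of-detected-genes rule is robust to dropout where a threshold on a
continuous score would need per-dataset tuning. The continuous mean score
is always reported alongside.

The double-hit score for drug d with rank r of K is
$(1 - (r-1)/K) \times \text{coverage}$, where coverage is the cell-weighted
mean positive fraction of d's target-pathway program over the flagged
clusters. Both factors live in [0, 1], so the product does too; rank 1 with
full coverage gives exactly 1 and zero coverage annihilates any rank. The
score is a transparent fusion heuristic for prioritization — the underlying
integration idea is qualitative, and we make it explicit rather than claim
statistical calibration for it.

**Cluster erosion** is tested per cluster with a two-sided Fisher exact
test on (in-cluster vs out) × (pre vs post), BH-adjusted across clusters;
*eroded* additionally requires the post proportion to be at most half the
pre proportion. The halving condition keeps statistically significant but
biologically trivial composition drift (large n makes tiny shifts
significant) from being reported as loss of a subclone.

## 5. Differential expression and reverse matching

Per gene, a two-sided Wilcoxon rank-sum test — exact (via
`stats::wilcox.test`) when both groups have ≤ 25 samples and the gene is
tie-free, otherwise the normal approximation with tie and continuity
corrections, vectorised; the two paths agree with `wilcox.test` row by
row. Fold change is $\log_2((\bar{x}_A + c)/(\bar{x}_B + c))$ with
pseudocount c = 1 on normalized (linear-scale) expression. Significance is
gated on **raw p < 0.05 and |log2FC| ≥ 1**; the BH-adjusted q is reported
but not gated on, matching the simple two-group screening convention this
pipeline reproduces — users wanting FDR control can gate on `p_adj`. A
"mean fold-change > |1|" criterion is read on the log2 scale, since a
linear fold-change > 1 is vacuous. The cohort comparison deliberately uses
the same Wilcoxon engine as the treatment comparison (not an empirical
Bayes linear model): one engine keeps the two signatures directly
comparable, at some cost in power for small cohorts.

Reverse matching intersects the two results and keeps genes significant in
both with opposite directions; genes **up in patients / down after
treatment** are the headline direction and are listed first. The operation
is symmetric: swapping the inputs swaps the direction columns over the same
gene set.

## 6. What the generators emulate — and what they do not

All generators take a `seed`, use an RNG stream local to the call (the
global stream is untouched), and return a ground-truth manifest; downstream
recovery tests read truth only from the manifest.

* `simulate_pgx_panel()` — log10 IC50 ~ Normal(μ~k~, 0.3) per drug, μ~k~
  uniform on [1, 3] (10 nM–1 µM medians); defaults: 100 lines, 30 drugs,
  resistant fraction 0.2, primary-drug shift +1.5 log10 in the resistant
  subgroup, planted secondary drug shifted −1.0 there, 5% missing at
  random. Not emulated: the correlated drug-target structure, tissue
  effects, and non-random missingness of real panels — so recovery rates
  here bound the idealized, not the real, problem.
* `simulate_combination()` — exact inversion of the CI equation plus
  Gaussian fa noise (default experiments use σ = 0.02), clipped to the
  usable fa range. Real combination assays add plate effects and
  heteroscedastic noise this does not model.
* `simulate_sc_counts()` — negative binomial (dispersion 0.5), depth
  LogNormal(log 5000, 0.3): typical droplet magnitudes. Four default
  subclones (bulk, EMT-high, stemness-high, PSAT1-high) with program genes
  elevated e² ≈ 7.4-fold in their own cluster and down-weighted at baseline
  so they sit near dropout elsewhere; the post condition erodes the
  PSAT1-high cluster from 20% to 1% of cells. No doublets (excluded
  upstream in the emulated workflow), no ambient RNA, no batch effects,
  no cell-cycle structure.
* `simulate_cohort()` — 100 patients, 49 recurrent / 51 not; 10 signature
  genes (led by LTB4R, IFITM3, TMEM120B) shifted +2 log2 in recurrent
  patients and −2 log2 after treatment in two 30-sample arms; per-sample
  log2 noise sd 0.4. Real cohorts have confounders, library-size artifacts
  and far weaker effects; the planted effect is sized so the pipeline's
  recovery guarantees are properties of the method, not of a marginal
  signal.

Passing the planted-truth tests therefore shows the *machinery* is correct
and calibrated under its stated assumptions; it does not certify
performance on real GDSC, droplet or cohort data.

## 7. Numerical conventions and degenerate inputs

* Quantiles: type 7 everywhere (classification and kill thresholds).
* IC50 must be > 0; non-positive or non-finite input values become missing
  with a warning (log transforms must be defined). Units are nM internally;
  µM input is converted on read.
* fa clipping ε = 0.005 for median-effect fits, generators and CI.
* Fisher tests use `stats::fisher.test` exactly; BH via `stats::p.adjust`.
* Constant genes: p = 1, log2FC = 0 by convention.
* All-equal IC50s ⇒ zero resistant lines ⇒ `rank_secdrugs()` errors with
  instructions to lower q, rather than ranking against an empty class.
* Problem sizes in the tests and acceptance computations (200-seed
  recovery sweeps, 10,000 null genes, 1,000 cells per condition, 500 null
  erosion simulations) were chosen as the smallest sizes at which the
  binomial noise on the measured rates is well inside the asserted margins.

## 8. Known limitations

* The kill rule and classification quantile that produced any particular
  published ranking are not identifiable from the ranking alone; defaults
  here are documented choices, and conclusions should be checked across q
  and q_kill.
* The double-hit score is a prioritization heuristic without a null model;
  use it to order candidates, not to test hypotheses.
* Erosion detection assumes a shared cluster label space; nearest-centroid
  transfer is crude when treatment shifts expression globally.
* The Wilcoxon engine reports, but does not gate on, multiple-testing
  correction by default; with ~10⁴ genes the raw-p gate implies ~500
  null positives, which the |log2FC| gate only partially removes.
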