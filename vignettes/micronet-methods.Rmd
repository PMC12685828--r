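---
title: "Models and methods behind micronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind micronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

micronet analyses amplicon count tables from a replicated two-factor field
design — cropping system (W, S, SW) × sampling location (bulk,
rhizosphere) × block — and ships a simulator of that design so every stage
can be tested against known truth. This vignette records the statistical
models, the defaults and why they were chosen, the numerical decisions, and
what the tests do and do not demonstrate.

## The study design and its six groups

Samples carry a treatment (W = wheat monoculture, S = soybean monoculture,
SW = wheat–soybean intercrop) and a location (bulk vs rhizosphere soil).
The derived six-level group label (W, SW, S, RW, RSW, RS — rhizosphere
groups prefixed R) is fixed in that display order everywhere so letter
displays and plots line up across outputs. Counts are stored as integers;
relative abundances are always derived on the fly, never stored, which
rules out double normalisation.

## Soil statistics

Each soil variable is analysed with a fixed-effects ANOVA
`y ~ block + location * treatment` on the complete balanced design; blocks
are additive and treated as fixed. Group comparisons use unprotected
Fisher's LSD: pairwise t statistics with the pooled residual mean square of
that ANOVA, no multiplicity correction within a variable — the convention
behind lowercase-letter columns in agronomy tables. Letters come from an
insertion algorithm over the non-significance matrix and are verified in
the tests against the display's defining property (two groups share a
letter iff their pairwise p ≥ α). Marginal means for a location (or
treatment) are unweighted means of its cell means, which for a balanced
design equals the plain mean but stays correct if cells are later
aggregated. Percent differences are 100·(a−b)/b on unrounded means;
reported contrasts are rounded to one decimal only at display time.

An essentially constant response (total SS at numerical-noise level,
relative tolerance 1e-12) has no variance to partition; F ratios are
returned as `NA` with a warning rather than the misleading ratios a raw
`anova()` would print.

## Diversity

Shannon entropy uses the natural log by default with a `base` argument
(base 2 gives bits); since published work rarely states the base, ratios of
same-base values are the only scale-free comparison. Simpson is the
Gini–Simpson index 1 − Σ pᵢ². Chao1 is the bias-corrected estimator
S_obs + F₁(F₁−1)/(2(F₂+1)). Rarefaction is **off** by default — the choice
is exposed (`rarefy_depth`, seeded subsampling without replacement) rather
than guessed.

Bray–Curtis distances are computed on per-sample relative abundances, so
library-size differences cannot masquerade as community differences; the
tests cover the equivalent invariance (scaling a sample's counts leaves
distances unchanged).

PCoA is the Gower double-centering of −d²/2 followed by a symmetric
eigendecomposition; coordinates are eigenvectors scaled by √λ for positive
eigenvalues; negative eigenvalues are reported but carry no coordinates,
and explained proportions are taken over the positive spectrum. On a
Euclidean distance matrix the embedding reproduces all pairwise distances
to 1e-8, which the tests assert.

PERMANOVA is the one-way permutation test: SS_total = Σ_{i<j} d²ᵢⱼ/n,
within-group SS from within-group pair sums divided by group size,
pseudo-F = (SS_B/(k−1))/(SS_W/(n−k)), and p estimated as
(1 + #{F* ≥ F})/(1 + n_permutations), which guarantees p > 0 and gives p a
resolution of 1/(n_permutations+1). Permutations are unrestricted (no
block strata), matching the common default of distance-based multivariate
ANOVA implementations; the observed F and R² agree with `vegan::adonis2`
to 1e-10 in the tests, while the permutation p is checked by null
calibration (rejection rate within the binomial band around α).

## LEfSe-style biomarker discovery

Features are analysed at a chosen taxonomic rank (counts summed within
rank labels; unannotated taxa pooled under an explicit `"unclassified"`
sentinel; conservation of sample totals is tested). The screen is the
Kruskal–Wallis rank-sum test per feature on relative abundances; a feature
constant across all samples has nothing to rank and is assigned p = 1.

The effect size follows the published LEfSe convention: abundances scaled
to one million; per bootstrap round (2/3 of each class, with replacement,
at least 2 per class, at most 10 redraws), a one-axis linear discriminant
is fitted over the screen-passing features; a feature's score for a class
pair is ½(|its contribution wᵢ·Δmᵢ to the discriminant-axis mean
difference| + |its raw mean difference Δmᵢ|), maximised over class pairs;
the effect is log₁₀(1 + mean bootstrap score) and the default threshold
is 2. The enriched class is the class with the highest mean abundance —
the one-vs-rest semantics used for multi-class comparisons. The original
subclass (within-class Wilcoxon) stage is omitted: this design has no
subclass factor inside a comparison. Classes are iterated in order of
first appearance, so renaming labels permutes the output without touching
the bootstrap stream; results are deterministic under a fixed seed, and
effect sizes are monotone in a planted fold change (tested over a fold
grid).

Two properties of this procedure are worth knowing. First, the screen is
exact under the null, so on a table of m features about α·m will pass it
by chance in any single run — a LEfSe scan of null data is *quiet*, not
*empty*. Second, when many strong differential taxa are planted, the
compositional closure (everything else must shrink where they grow) makes
some non-planted features genuinely differentially abundant in relative
terms; the recovery test's false-discovery proportion counts those against
the method even though they are real signals of the relative-abundance
scale.

## Co-occurrence networks and stability

Networks are built per cropping system (both locations pooled, 6 samples
at paper scale) on relative abundances. Spearman correlation is the
default — rank-based, hence insensitive to whether raw counts, relative
abundances or log transforms are correlated; Pearson is available and the
choice is recorded in the network's parameters. A prevalence filter
(present in ≥ 1/3 of the selected samples by default) is mandatory because
all-pairs correlation across tens of thousands of sparse taxa at n ≤ 6 is
statistically meaningless; constant taxa are excluded with a warning.
Two-sided p-values come from the t approximation
t = r√((n−2)/(1−r²)), are Benjamini–Hochberg adjusted across every tested
pair, and edges require |r| > 0.6 and q < 0.05. Vertices are taxa with at
least one retained edge; edge sign is the sign of r.

Stability has three faces, each pinned to an explicit formula because the
quantities appear under these names with unstated definitions in the
applied literature:

* **Complexity** — for a set of compared networks, each index (vertices,
  edges, positive edges, negative edges, average degree 2E/V, mean local
  clustering with degree < 2 contributing 0) is divided by its maximum
  across the set, and the composite is the mean of those ratios. The
  network maximal on every index scores exactly 1; the composite is
  invariant to a common rescaling of any index; an index uniformly zero is
  excluded with a warning. The index set is configurable.
* **Robustness** — remove ⌊pV⌋ vertices uniformly at random with their
  edges; remaining connectivity is the fraction of the *original* V
  vertices that survive and still hold an edge; report mean ± SD over
  seeded repetitions (default 100) on a fraction grid including the 0.5
  and 0.9 checkpoints. The definition keeps robustness ≤ 1 − p, matching
  how reported values sit below the removal complement. On K₁₀₀ at
  p = 0.5 every draw gives exactly 0.5; on a star it matches exhaustive
  enumeration over removal sets.
* **Vulnerability** — global efficiency E = mean of 1/d(i,j) over ordered
  pairs (unweighted shortest paths, 1/∞ = 0); vulnerability is
  max over vertices of (E − E₋ᵢ)/E. Complete graphs score 0; a path's
  middle vertex scores 1; stars dwarf cycles. All three graph metrics are
  tested against independent brute-force implementations, exhaustively on
  every graph with ≤ 5 vertices and on random 6–7-vertex graphs.

## dbRDA

The community distance matrix is embedded by PCoA keeping
positive-eigenvalue axes (no Lingoes/Cailliez correction; the dropped
negative inertia is reported). Environmental variables are standardized
internally, so results are invariant to affine rescaling; a condition
number above 1e8 on the design is refused naming the variables. The
constrained step is the least-squares projection of the sample coordinates
onto the environmental design and an SVD of the fitted values; axis
percentages are constrained eigenvalues over total positive inertia, and
constrained + unconstrained inertia add to that total exactly.

Per-variable "explanatory degree" is the envfit-style r²: the squared
multiple correlation of the (standardized) variable with the first two
ordination axes — per-variable percentages on this definition may sum to
more than the axis totals, which is the only consistent reading of such
tables. Because a multivariate r² has no sign, the signed correlation with
axis 1 is reported alongside. Permutation tests are marginal (one variable
at a time, permuting the variable across samples), at 999 permutations by
default; below 99 a coarse-resolution warning fires.

## The synthetic-data generator

`community_design()` defaults are *paper-scale*: 18 samples (3 systems × 2
locations × 3 blocks), 600 bacterial + 150 eukaryotic taxa, depth 30,000,
baseline log-abundance spread σ = 1.5, Dirichlet-multinomial
overdispersion θ = 0.02, per-sample latent noise σ = 1, 40 bacterial (10
eukaryotic) differential taxa at a latent log-fold of ln 4, per-treatment
correlation modules densest for S in bacteria and for SW in eukaryotes,
and soil variables TP and AP tied to latent gradient 1 and pH and EOC to
gradient 2 (the variables reported as community drivers; the rest are
noise controls). Where the study conditions are unstated (θ, depth,
σ values), the defaults are conventional amplicon figures, chosen once.

Mechanics, per sample: latent log-abundance = the group's baseline
log-composition + differential effects + gradient loadings +
copula-correlated noise; counts ~ Dirichlet-multinomial(p/θ, depth), so
column totals equal the depth exactly and θ → 0 recovers the multinomial
(verified against multinomial variance). Module correlation is planted on
the latent Gaussian scale as an exchangeable ±ρ factor structure, so truth
is well-defined: the implied count-scale rank correlation is the Gaussian
copula's (6/π)·asin(ρ/2), which the tests recover within ±0.05 at ~200
samples. Count-scale correlation is *attenuated* relative to ρ by
compositional closure, finite depth and especially θ — at the default
θ = 0.02 a planted ρ = 0.75 is largely invisible to an |r| > 0.6 filter.
This is a property of real overdispersed count data, not a bug; recovery
tests that target the network stage therefore run at near-multinomial
θ = 1e-6.

Diversity effects are planted as *Shannon offsets*: a group's limiting
composition is tilted (p ∝ p₀^γ, γ solved by root-finding) to hit a target
entropy H₀ + δ, so `planted_diversity_offset()` is analytic by
construction — δ = ln 2 doubles the effective richness exp(H). The default
plants δ = −2.15 nats on the bulk wheat group, putting the intercropped
bulk group roughly 69% above it in the infinite-depth limit; finite depth
and overdispersion attenuate the realised gap (the README example shows
~56% at the defaults), and the realised difference is verified within 10%
of the analytic offset at depth 30,000 under low noise.

What the generator does **not** emulate: sequencing error and chimeras,
taxonomy misannotation, phylogenetic signal, zero-inflation beyond what
the Dirichlet-multinomial induces, spatial or temporal autocorrelation
between blocks, and genuine ecological interaction dynamics (modules are
statistical, not mechanistic). Passing recovery tests therefore shows the
*estimators* work on data matching their assumptions, not that field data
meet those assumptions.

## Problem sizes used by the test suite

Recovery and calibration tests inflate the sample count where the
paper-scale n = 6 per system has no power for the property under test —
the generator documents these as *test-scale*: ~200 samples for the copula
oracle, 30 for network module recovery (ρ = 0.9), 150 (25 blocks) for
biomarker recovery, 60 (10 blocks) for the soil-link recovery, 28 per
system (14 blocks, θ = 1e-6) for the complexity-ranking recovery. Null
calibrations use 500 replicates (PERMANOVA, ANOVA, dbRDA) or 1000 features
(Kruskal–Wallis) at reduced sizes; permutation counts in tests are 99–199
with the binomial band widened accordingly.

## Orchestration and reproducibility

`run_all()` derives every stage's seed from the global seed and the stage
name via a polynomial hash (kept below 2³¹), so adding a stage never
shifts another stage's random stream; the manifest records the derived
seeds and parameters, and a rerun with the same configuration is
byte-identical. All floating-point output is serialized at full precision;
rounding happens only in human-readable displays.

## Known limitations

* The network p-values use the t approximation for Spearman, which is
  anti-conservative at very small n for near-perfect correlations; it is
  also what allows any edge at all to clear an FDR threshold at n = 6.
* Compositional effects are not modelled out of the correlations (no
  SparCC/CLR-style treatment) — by design, as the target analyses use
  plain correlation networks.
* LEfSe results are pinned to this package's bootstrap and attribution
  conventions; bit-compatibility with the original tool is a non-goal.
* dbRDA drops negative eigenvalues rather than correcting them; the
  discarded magnitude is reported so users can judge the distortion.
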