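---
title: "Methods: screening placental nutrient transporters in IUGR and PE"
author: "placentaScreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening placental nutrient transporters in IUGR and PE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentaScreen)
```

# The problem and the pipeline

Intrauterine growth restriction (IUGR) and pre-eclampsia (PE) are both
associated with impaired transfer of nutrients across the placenta, and
the membrane transporters of the SLC, ABC and TRP families are the
molecular machinery of that transfer. `placentaScreen` implements a
funnel-shaped prioritisation strategy for these genes: a broad
cross-study expression screen produces a candidate panel; the panel is
re-measured by qPCR on a clinically characterised five-group cohort
(term and preterm controls, IUGR, PE, PE+IUGR); nonparametric group
testing identifies significantly regulated genes; and a geometric
classification of the per-gene (IUGR, PE) fold-change pair decides
*which disease* drives each change. The final targets are the genes
that clear both the statistical and the specificity filter.

This vignette documents the models, the tunable parameters and their
defaults, the numerical conventions, and the design choices made where
the procedure was genuinely open — together with what the simulation
results do and do not demonstrate.

# Cross-study meta-screen

Each study enters as a log2-scale genes × samples matrix with clinical
group labels. Columns are quantile-normalised (every sample is forced
onto the common distribution of column-sorted row means; ties within a
column receive the mean of the normalised values they span — the
operation is idempotent and equalises all column means).

Differential expression per study and disease contrast uses a moderated
t statistic. With pooled two-group variance $s_g^2$ on $d_g$ degrees of
freedom, the shrunken variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

where the prior $(d_0, s_0^2)$ is estimated by the method of moments on
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$: the excess of
$\mathrm{var}(e)$ over $\psi'(d_g/2)$ identifies $d_0$ through the
trigamma function (inverted by Newton iteration) and the mean of $e$
then identifies $s_0^2$. When the moment estimate of $d_0$ is
non-positive or infinite — essentially identical gene variances — it is
capped at 50, which keeps the shrinkage strong but finite. The p value
uses a t distribution on $d_g + d_0$ degrees of freedom. This moderated
statistic captures the small-sample stabilisation behaviour of the
empirical-Bayes tools commonly used for microarray screens while
remaining self-contained; the unit tests cross-check the moment
estimator against `limma::squeezeVar` on shared input.

Candidate selection applies three criteria: (i) measured in **more than
3** (i.e. at least 4) distinct studies — the strict reading of the vote
count; (ii) listed in the top 12 up- or down-regulated genes of **at
least one** study contrast; (iii) a curated placental-relevance flag,
supplied as an input table because it encodes expert annotation, not a
computation. Criterion (ii) deliberately uses the at-least-one-study
reading: requiring top-12 membership in every study would empty the
candidate set under the heterogeneous arm designs of the emulated
studies (several lack an IUGR or a PE arm entirely). Ranking ties break
by smaller p, then gene id, so the lists are deterministic. Selection
is monotone: adding a study in which a gene appears can only help it.

# qPCR quantification

Samples must pass four strict RNA-quality criteria: RIN > 6,
A260/280 > 2.0, A260/230 > 1.8, and yield > 5 ng/µl. All four are
strict inequalities, so a sample sitting exactly at a boundary fails.

Relative expression uses the comparative-Ct method with two reference
genes (UBQ and YWHAZ, both stable across the clinical groups):

$$\Delta Ct = Ct_{target} - \tfrac12\left(Ct_{UBQ} + Ct_{YWHAZ}\right),
\qquad
\Delta\Delta Ct = \Delta Ct_{test} - \overline{\Delta Ct}_{term},
\qquad
FC = 2^{-\Delta\Delta Ct}.$$

The control aggregate is the **arithmetic mean** of the term-control
ΔCt values (the standard convention of the comparative-Ct method; a
median anchor would be equally defensible but is not offered, keeping
the centering identity exact: control-group log2 fold changes average
to zero by construction). Technical replicates sharing a sample id are
averaged per gene before ΔCt. Because ΔCt subtracts a per-sample
reference aggregate, any sample-level offset on all Ct values cancels
end to end — asserted as a property test.

The scatter coordinates are $x$ = mean log2 FC over the IUGR samples
and $y$ = mean log2 FC over the PE samples. PE+IUGR samples are
excluded from both axes — the scatter contrasts the *isolated*
diseases — but remain in the statistics as a fifth group, since the
combined phenotype is informative for significance even when it cannot
be attributed to either disease alone.

# Group statistics

The Kruskal–Wallis test is implemented from the rank formulas with
mid-ranks and tie correction:

$$H = \left[\frac{12}{N(N+1)}\sum_j \frac{R_j^2}{n_j} - 3(N+1)\right]
  \Big/ \left[1 - \frac{\sum_t (t^3-t)}{N^3-N}\right],$$

with p from $\chi^2_{g-1}$, the approximation used by mainstream
statistical software; an exact enumeration mode exists for ≤ 12 total
observations. When all observations are identical the statistic is
defined as 0 and p as 1. Because H depends only on ranks, testing
per-sample log2 fold changes, linear fold changes, or raw ΔCt gives
identical results — asserted as a test rather than assumed.

Dunn's post-hoc compares each disease group against the term control:

$$z_j = \frac{\bar R_{term} - \bar R_j}
 {\sqrt{\left[\frac{N(N+1)}{12} - \frac{\sum_t(t^3-t)}{12(N-1)}\right]
 \left(\frac{1}{n_{term}} + \frac{1}{n_j}\right)}}.$$

The family-wise adjustment multiplies the raw two-sided normal p by the
number of comparisons (four in the full design), capped at 1 — a
deliberately conservative Bonferroni-style choice, with the raw p always
reported alongside so other corrections can be applied downstream.
Genes are flagged significant iff the Kruskal–Wallis p is strictly
below α = 0.05.

The chi-square approximation deserves a caveat at these sample sizes:
at group sizes 13/7/8/5/10 its true type-I level is ≈ 0.041 (slightly
conservative), and for three groups of ten its tail probabilities can
differ from the exact permutation null by up to roughly 0.01 — more
than the Monte-Carlo error of a 20,000-draw permutation estimate. The
acceptance checks expose both facts rather than hiding them; users who
need exact calibration at small N should use the permutation/exact
modes.

# Hierarchical clustering and heatmap export

Similarity is centred Pearson correlation — subtract each vector's
mean, correlate, and take $d = 1 - r \in [0, 2]$ — the classic
clustering-software convention; an uncentred variant is available
behind a flag. Zero-variance vectors are rejected with the offending
id. Agglomeration is UPGMA: merge the pair of clusters with minimal
average inter-cluster distance; the merged cluster's distances are
size-weighted averages, exactly the mean over all cross pairs. Two
determinism conventions are fixed: ties in the minimal distance break
by the lexicographically smallest member labels, and at every internal
node the child containing the lexicographically smallest leaf comes
first in the leaf order. (Optimal leaf ordering is out of scope; the
lexicographic rule is about reproducibility, not aesthetics.) Both
axes are clustered by default; a genes-only mode orders samples by
clinical group, reproducing the usual presentation of such heatmaps.
Exports are newick trees (merge heights as ultrametric depths), the
reordered matrix and the two leaf-order files; per-gene values are
median-centred with the red = up / green = down convention recorded as
metadata rather than rendered.

# Interaction-graph clustering

The confidence-weighted edge list keeps edges with score **strictly**
greater than 0.4 (medium confidence); isolated nodes survive as
singletons. Markov clustering then alternates expansion (matrix
squaring) and inflation (elementwise power, column renormalisation)
on the column-stochastic transition matrix, pruning entries below
1e-5, until the matrix changes by less than 1e-8 or 200 iterations
(non-convergence returns the current partition, flagged). Inflation
defaults to 2.0, the de facto standard granularity. Self-loops are
weighted by each node's maximum incident edge weight — a common
stabilisation that keeps attractors well-defined — and are
configurable in principle through the transition-matrix construction.
Overlapping attractor systems (rare) resolve by assigning a node to
the cluster of its lexicographically smallest attractor. Column sums
are monitored at every inflation step; the largest deviation from 1 is
reported in the result object.

The packaged `synthetic_interaction_edges.tsv` fixture (46 transporter
gene symbols, generated by `simulateEdgeList` with seed 46) plants
three substrate-class communities — amino-acid, vitamin, and
microelement/ion transporters — plus a lipid/carbohydrate remainder:
dense high-confidence edges within communities, sparse sub-threshold
edges between them, and a few weak above-threshold bridges that MCL at
inflation 2.0 must split.

# Specificity classification

Genes whose linear fold change does not exceed 1.14 in magnitude
(above 114% or below 86% of the term-control level) in **at least one**
disease are left unclassified; requiring the filter in both diseases
would discard exactly the single-disease-dominant genes the analysis
is after. The retained genes are classified by fixed-order bands with
error threshold ε = 0.2 on the log2 scale (consistent with
log2(1.14) ≈ 0.19):

1. |y| ≤ ε and |x| > ε → **IUGR_dominant** (ratio r = y/x near 0);
2. |x| ≤ ε and |y| > ε → **PE_dominant** (r diverging);
3. |y − x| ≤ ε → **equal** (r near 1);
4. |y + x| ≤ ε → **equal_reversed** (r near −1);
5. otherwise **mixed**.

The fixed order guarantees exactly one class per gene. The directional
reading — points hugging the x axis are IUGR-dominated, points hugging
the y axis PE-dominated — follows the geometry of the axis definitions
(x is the IUGR effect, y the PE effect). The opposite reading of the
ratio limits (r → 0 meaning PE-dominated) is sometimes stated for this
kind of diagram but contradicts the axis definitions, so no mode
implementing it is offered. The dominance list for a disease ranks its dominant genes by
effect magnitude (|x| for IUGR, |y| for PE), back-filling from mixed
genes with the matching larger axis only when fewer than n = 3 dominant
genes exist; ties break by gene id. Final targets are the
KW-significant genes that are top-3 dominant for either disease or
classed equal/equal_reversed.

# The synthetic cohort: what it emulates and what it shows

The generator's defaults describe the emulated study conditions, fixed
once:

| parameter | default | units | rationale |
|---|---|---|---|
| group sizes | 13/7/8/5/10 | samples | term/preterm/IUGR/PE/PE+IUGR cohort sizes |
| `effectSize` | 1.0 | log2 | a two-fold planted change, the order of the largest screen effects |
| `noiseSd` | 0.3 | log2 / cycles | typical inter-individual plus technical spread for tissue qPCR |
| `ctBaseline` | 30 | cycles | mid-range threshold cycles for placental transcripts |
| panel | 200 genes: 3 IUGR-only, 3 PE-only, 4 equal, 2 equal-reversed, 188 null | — | mirrors the funnel: a top-3 per disease and a handful of equally affected genes among a mostly unchanged panel |
| `nStudies` | 7 | — | arm structure mirrors the heterogeneous meta-analysis designs (some studies lack an IUGR or PE arm) |

Expression values are gene baseline + planted effect + additive
Gaussian noise on the log2 scale; Ct values are `ctBaseline − log2
expression + noise` on the cycle scale, so a +1 log2 effect lowers Ct
by one cycle; PE+IUGR samples receive the sum of both disease effects
(the combined phenotype treated additively); reference genes carry no
group effect; planted effect signs alternate so the panel contains
both up- and down-regulation. All randomness flows from one master
seed through deterministic child seeds: identical configurations give
byte-identical fixture bundles. The generator does **not** model
probe-level intensities, batch effects, amplification-efficiency
differences, or count data.

A variance budget makes explicit what these conditions can and cannot
demonstrate. With per-measurement noise σ = 0.3 and two noisy
reference genes, sd(ΔCt) = σ√1.5 ≈ 0.37; the scatter coordinates then
carry sd(x) ≈ 0.17 and sd(y) ≈ 0.19, and the band half-width ε = 0.2
is only ≈ 1σ of the relevant contrasts. Consequently a planted
IUGR-only gene lands inside its band with probability ≈ 0.70 and a
planted equal gene ≈ 0.66 — *independent of effect size*, because the
band tests deviations orthogonal to the effect. The simulation results
bear this out: across 20 cohorts, essentially **all** planted non-null
genes are KW-significant (the five-group test has overwhelming power at
a two-fold effect), the class assigned to a planted gene matches in
≈ 70% of cases at σ = 0.3 but > 99% at σ = 0.1, and among genes
receiving a *definite* class (dominant/equal/reversed, i.e. excluding
mixed) the assignment is ≈ 99% correct even at σ = 0.3. Equally, with
188 null genes tested at raw α = 0.05, a handful of false positives per
cohort is expected and some land in the equality bands, so the final
report reproduces the planted target set only approximately at σ = 0.3
and exactly in the noise-free limit. Passing tests therefore certify
the *mechanics* (formulas, filters, determinism, recovery in the
low-noise regime) — they do not certify that ε = 0.2 bands are reliable
at single-cohort qPCR noise, which is a property of the procedure
itself, faithfully reproduced.

# Numerical conventions and degenerate inputs

* Results tables are written with 6 significant digits (stable diffs);
  matrices with full 17-digit precision (exact round trips). Readers
  reject rather than coerce: duplicate ids, non-numeric cells,
  negative counts, out-of-range scores and self-loops are errors. A
  blank study-arm count reads as 0 (absent arm).
* Gene and sample ids are case-sensitive throughout; all internal
  orderings use locale-independent radix sorting.
* All-identical observations: H = 0, p = 1. Zero fold change: t = 0,
  p = 1; zero shrunken variance with non-zero fold change: ±∞, p = 0.
* x = 0 in the specificity ratio: r recorded as signed infinity (the
  class comes from the bands, never from r itself).
* Single-column quantile normalisation returns the input with a
  warning; fewer than two vectors, zero-variance vectors, and
  asymmetric distance matrices are errors.
* Pipeline configs are flat key=value files; unknown keys are errors,
  so a misspelt threshold cannot silently fall back to a default.

# Problem sizes used by the test suite

The suite exercises: 100 random 6–10-leaf matrices against a
brute-force UPGMA oracle; 50 three-group datasets (n = 10 per group)
against a 20,000-draw permutation null; 10,000 simulated null genes for
the empirical type-I error at the cohort group sizes; 20 seeds × 200
genes for end-to-end recovery; and 20 seeds × 40 genes × 7 studies for
meta-screen recovery. These sizes keep the default run in the
low-minutes range on one core while leaving the Monte-Carlo error of
each estimate well below the margins being asserted.

# Known limitations

* The moderated-t screen is a self-contained reimplementation of
  empirical-Bayes variance shrinkage, not a byte-level reproduction of
  any specific published screen's software stack.
* Criterion (iii) of the candidate selection is an input flag; the
  package does not curate placental relevance.
* The chi-square Kruskal–Wallis p is an approximation whose small-N
  bias is documented above; Dunn's adjustment is Bonferroni-style, more
  conservative than stepwise alternatives.
* MCL granularity depends on the inflation parameter; 2.0 is a
  convention, not an estimate.
* Protein-level validation (western blotting, membrane fractionation)
  and retrieval of real interaction scores or GEO matrices are outside
  the package's scope; the interaction graph and expression matrices
  are inputs.
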