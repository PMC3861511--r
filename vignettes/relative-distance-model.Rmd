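---
title: "The relative-distance model: replicate-level selection of discriminating gene sets"
author: "rdarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The relative-distance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdarray)
```

## The problem

Biomonitoring of chemical exposure with gene-expression biomarkers fails
when single genes respond to many unrelated stressors. Given a qRT-PCR
array measured over several treatment groups with a handful of biological
replicates each, the practical questions are: which individual genes can
tell a *specific pair* of treatments apart, and what is the smallest gene
set whose joint expression fingerprint separates *all* treatments — at the
level of individual replicates, not group means?

Mean-difference statistics (t, ANOVA) answer a different question: they
compare group centres. With three biological replicates per group, a
treatment call for a *new* sample hinges on every replicate lying closer
to its own group's cloud than to any other. The relative-distance (RD)
model encodes precisely that, replicate by replicate.

## The model

All distances are Euclidean in log2 fold-change coordinates over the
active gene set of size $j$. For focal replicate $a_1$ of group A against
group B (triplicates), let $d_{a_1b_1}, d_{a_1b_2}, d_{a_1b_3}$ be its
distances to B's replicates and $d_{a_1a_2}, d_{a_1a_3}$ those to its own
siblings. With $md$ the means and $SD$ the standard deviations of the two
lists,

$$rd_{a_1b} \;=\; \bigl(md_{a_1b} - SD_{a_1b}\bigr) \;-\;
                 \bigl(md_{aa} + SD_{aa}\bigr).$$

The margin form demands that the between-group distance, *deflated* by its
spread, still exceed the within-group distance *inflated* by its spread —
every one of the four summary quantities affects the sign, which is what
makes the sign test below meaningful. A pair of groups is **discriminated**
by a gene set iff all six directed rd values (each replicate of each group
as focal) are strictly positive; $rd = 0$ fails. The **mean RD** — over the
six values of one pair, or pooled over all directed values of all pairs —
is the ranking score. For equal group sizes the pooled mean coincides with
the mean of per-pair means (asserted in the test suite).

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `sdMethod` | `"sample"` | SD denominator: $n-1$ (sample) or $n$ (population). Sample is the qPCR-statistics convention; with 2–3 distances per list the choice is material, so both are exposed. |
| `rdForm` | `"margin"` | `"margin"` as above; `"ratio"` gives the t-like $(md_{a_1b}-md_{aa})/(SD_{a_1b}+SD_{aa})$, whose *sign* ignores the SDs — kept as a sensitivity check, not the default. |
| `scale` | `"log2"` | coordinate scale of the fold-change matrix. log2 is the standard pre-analysis transform for expression ratios and symmetrizes up/down regulation; `"linear"` is available to probe scale sensitivity (the rd statistic is scale-equivariant, not scale-invariant). |

Group sizes other than 3 generalize naturally ($|B|$ between-group and
$|A|-1$ within-group distances, $|A|+|B|$ directed values, the all-positive
rule unchanged) with a minimum of 2 replicates per group; the 3+3 design is
the validated reference. The sample SD of a single distance (groups of 2)
is taken as 0.

## Normalization

Raw Ct tables are converted by the $2^{-\Delta\Delta Ct}$ method:
$\Delta Ct$ subtracts the *arithmetic mean* of the housekeeping Ct values
in the same replicate — numerically identical to dividing by the geometric
mean of housekeeping expression levels, since Ct is a log2 scale.
$\Delta\Delta Ct$ references each treatment replicate to the *mean* control
$\Delta Ct$: replicates are independent pools, so no treatment–control
pairing exists in the design. Two invariants pin the arithmetic down and
are enforced by tests: adding a constant to every Ct of one replicate
(targets and housekeeping alike) leaves all fold changes unchanged, and
control-group fold changes have geometric mean 1 per gene. Missing values
are rejected, not imputed — the distance geometry has no defined behaviour
under missingness.

## Searching gene sets

`searchGeneSets()` maximizes the pooled mean RD per set size. Subsets are
enumerated exhaustively while $C(G, s) \le$ `exhaustiveLimit` (default
$10^6$); beyond that the best exhaustively-found seed set grows by greedy
forward selection, one gene per step, optionally widened to a beam
(`beam` > 1). Exhausting all $2^{61}$ subsets of a 61-gene panel is not
feasible for any implementation, so the reported optimum is certified only
for exhaustible sizes; the per-size `strategy` column keeps the output
honest about which rows are global optima. All tie-breaking — between
equal-scoring subsets and between equal-scoring greedy extensions — is
lexicographic by gene id, so results are deterministic across platforms.
On random 12-gene panels the greedy curve tracks the exhaustive optimum to
within a fraction of a percent on average (recomputed by the acceptance
script), but no approximation guarantee exists; treat greedy rows as lower
bounds.

## Cluster validation

A selected set's discrimination claim is confirmed by an independent
route: UPGMA (average-linkage, Euclidean) clustering of the replicate
profiles restricted to the set, cut into $k$ = number-of-groups clusters.
A group is *pure* when its replicates occupy one cluster alone;
`purity = "clade"` offers the stricter complete-subtree criterion. The
agglomeration is implemented with the size-weighted average-linkage update
and a fixed tie-break (merge the pair whose smallest leaf labels sort
first) so that trees are reproducible; it is verified in the tests against
both `stats::hclust` and an $O(n^3)$ oracle that recomputes every
cluster-pair mean distance from the original leaves. When tied merge
heights straddle the cut the partition is not unique; such results are
flagged `indeterminate` and never reported as pure. No significance is
attached to dendrograms: none is defined for this procedure.

## The synthetic-data generator

`SyntheticDesign()` emulates the reference study structure — $G$ genes,
$K$ groups, 3 replicates, by default 61 × 5 × 3 — with per-replicate log2
fold changes drawn as group mean + Gaussian(0, `nullSigma`) noise and
exported as linear fold changes. Planted genes carry distinct group means;
null genes are identically distributed everywhere, so ground truth is
exact. Defaults were fixed once, on field-typical grounds: `nullSigma` =
0.25 log2 units, a realistic inter-replicate variability for pooled qPCR
samples; planted effects in the study-shaped panel
(`exampleStudyDesign()`) span 1–7 log2 units, the range qPCR arrays report
for strong responders. The alternative `lognormal_linear` noise model
applies multiplicative lognormal noise on the linear scale to stress-test
scale sensitivity. `generateCt()` maps the same draws into Ct space
(1 cycle = 1 log2 unit, noiseless control and housekeeping rows), making
the ddCt round-trip exact by construction and testable to $10^{-10}$.

What the generator does **not** emulate: between-gene correlation (real
pathway genes co-respond), amplification-efficiency variation,
heteroscedasticity across expression levels, and outlier replicates.
Passing tests on synthetic panels therefore demonstrate correctness of the
statistics and search machinery under the stated noise model — not
robustness of gene choices on any real dataset.

`exampleStudyDesign()` plants thirteen marker-like genes chosen so that,
by construction: every planted gene has at least one group pair with
identical means (hence no single gene separates all five groups); an
estrogen-marker-like gene (`vtg1`) responds equally to both doses of the
same compound; the pair `vtg1` + `hspa5` separates every group pair with a
minimum mean separation of 12 within-group SDs; and `vtg1` + `cyp1a1`
cannot split the two doses. This panel is synthetic — it reproduces the
qualitative structure of such a study, not measured data — and is labelled
as such wherever it appears.

## Numerical choices

- Sign comparisons against 0 use exact double-precision sign, no epsilon:
  $rd = 0$ arises only in degenerate constructed inputs and fails the
  strict rule by design.
- The ratio form defines $0/0 = 0$ and $x/0 = \pm\infty$ (sign of the md
  difference).
- Subset scoring decomposes squared distances over genes, so exhaustive
  enumeration reduces to one cross-product per group pair per chunk of
  20 000 subsets; exact ties between subset scores are resolved by
  enumerating in lexicographic gene order and keeping the first maximum.

## Validation design

The test suite and acceptance script recompute everything they assert at
these problem sizes, chosen to exercise every code path at desk-scale: the
study-shaped 61 × 5 × 3 panel (exhaustive search to size 4, ≈ 5 × 10⁵
subsets, greedy beyond); directed-rd agreement with a loop-based
brute-force oracle on 200 random 3+3 instances at 1, 2, 5 and 61 genes
(tolerance $10^{-12}$); UPGMA agreement with the $O(n^3)$ oracle on random
4–15-leaf instances; planted-pair recovery across 50 seeds at effect = 10
`nullSigma`; and greedy-vs-exhaustive comparison on 30 random 12-gene,
3-group panels.

## Known limitations

- No null distribution, p-values or multiple-testing control are defined
  for rd; the all-positive rule is a deterministic criterion, not a test.
- With triplicates the SDs entering rd are estimated from 2–3 values and
  are themselves noisy; the margin form inherits that variance.
- Selected sets are not cross-validated; mean RD measures separation on
  the data at hand, not generalization to new exposures.
- Greedy/beam results beyond the exhaustible sizes are lower bounds on the
  true optimum.
- Group labels are free text with no dose semantics; two concentrations of
  one compound are simply two groups.
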