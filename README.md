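# rdarray — relative-distance biomarker selection for multi-gene qPCR arrays

Classical single-gene biomarkers of chemical exposure are rarely specific:
estrogen-responsive genes answer to many xenoestrogens, dioxin-responsive
genes to several unrelated stressors. A multi-gene qRT-PCR array can carry a
chemical-specific fingerprint — but only if the right genes, and the right
*combinations* of genes, are selected. `rdarray` implements the **relative
distance (RD)** model for exactly that task: a replicate-level statistic
that asks, for every biological replicate, whether it sits unambiguously
closer to its own treatment group than to another, and search procedures
built on it that screen single genes and assemble gene sets able to
discriminate all treatment groups at once.

## The statistic

Work in log2 fold-change coordinates over a gene set of size *j*. For focal
replicate *a₁* of group A against group B (triplicate design), with
Euclidean distances *d(a₁,bᵢ)* to the three replicates of B and *d(a₁,aᵢ)*
to its two siblings:

- *md_a₁b* = mean of the three between-group distances, *SD_a₁b* their SD;
- *md_aa* = mean of the two within-group distances, *SD_aa* their SD;
- **rd_a₁b = (md_a₁b − SD_a₁b) − (md_aa + SD_aa)**.

rd > 0 means the focal replicate's distance to the other group exceeds its
within-group distance even after inflating the latter and deflating the
former by one standard deviation each. A gene set **discriminates** a pair
of groups iff all six directed rd values (three per direction) are strictly
positive; the **mean RD** (over the 6 values of a pair, or over all 60
directed values of the 10 pairs of 5 groups) ranks genes and gene sets.
Standard deviations use the sample (n−1) convention by default, and a
t-like ratio form is available (`sdMethod`, `rdForm` arguments).

The workflow: `ddctNormalize()` (2^−ΔΔCt against the geometric mean of
housekeeping genes) → `toLog2FoldChange()` → `screenGenes()` per group
pair → `searchGeneSets()` (exhaustive while C(G, s) is feasible, then
deterministic greedy forward selection) → `averageLinkageCluster()` to
confirm a selected set by UPGMA cluster purity. `SyntheticDesign()` /
`generateFoldChange()` / `generateCt()` simulate the whole design with
planted ground truth.

## Worked example

A synthetic study-shaped panel — 61 genes, 5 treatment groups (two being
doses of the same estrogenic compound), 3 replicates — with marker-like
planted structure:

```r
library(rdarray)
des <- exampleStudyDesign(seed = 1)
fcm <- toLog2FoldChange(generateFoldChange(des))

head(screenGenes(fcm)[, 1:5], 3)
#>          gene      groupA      groupB    meanRD discriminates
#> 1        vtg1        TCDD      E2_low   6.45626          TRUE
#> 2      cyp1a1        TCDD      E2_low   5.51610          TRUE
#> 3       hsp70        TCDD      E2_low   4.21863          TRUE

searchGeneSets(fcm, sizes = 1:4)
#>        size    meanRD discriminatesAll    strategy                  genes
#> 1         1   4.77023            FALSE  exhaustive                   vtg1
#> 2         2   6.14895             TRUE  exhaustive             hspa5;vtg1
#> 3         3   7.05677             TRUE  exhaustive      cyp1a1;hspa5;vtg1
#> 4         4   7.34935             TRUE  exhaustive cyp1a1;hsp70;hspa5;v..
```

No single gene separates all five groups (the best singleton, the
estrogen marker `vtg1`, cannot split the two doses of the same compound),
but the pair `vtg1` + `hspa5` does — and average-linkage clustering
confirms it, while the classical marker pair `vtg1` + `cyp1a1` leaves the
two doses entangled:

```r
averageLinkageCluster(fcm, c("vtg1", "hspa5"))
#> DendrogramResult: 15 leaves, cut at k = 5
#>   purity: TCDD=TRUE, E2_low=TRUE, E2_high=TRUE, Lindane=TRUE, Arsenic=TRUE
#>   all pure: TRUE
averageLinkageCluster(fcm, c("vtg1", "cyp1a1"))
#>   purity: TCDD=TRUE, E2_low=FALSE, E2_high=FALSE, Lindane=TRUE, Arsenic=TRUE
#>   all pure: FALSE
```

A command-line interface with `normalize`, `screen`, `search`, `cluster`
and `simulate` subcommands ships at
`system.file("scripts", "rdarray.R", package = "rdarray")`.

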