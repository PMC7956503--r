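# uEVstrat

Label-free spectral-count proteomics for subject stratification, marker
selection and phenotype linkage — built around the analysis of urinary
extracellular-vesicle (EV) proteomes in preschool children, where
unsupervised clustering of the EV proteome defines subject groups whose
respiratory impedance (measured by the forced oscillation technique, FOT)
differs.

The package is for proteomics/biostatistics practitioners who have
run-level protein identification lists (one spectral count, SpC, per
protein per LC-MS/MS run) and per-subject phenotype tables, and want a
tested, reproducible route from those lists to proteome-defined subject
groups, compact marker panels and group-phenotype statistics.

## What it computes

**Ingest.** Run-level protein lists are aligned over the union of
accessions into a proteins × runs matrix (absences are structural zeros),
total-count normalized (each column scaled to the grand mean column
total), quality-controlled across technical replicate pairs (Pearson *r*
and regression slope, expected near 1), filtered to proteins detected in
strictly more than 25% of runs, and replicate-averaged into per-subject
aSpC profiles.

**Stratification.** Subjects are clustered by Ward's minimum-variance
criterion on Euclidean distances (by default after a log2(x+1)
stabilization) and the tree is cut into *k* = 3 groups labeled A, B, C by
decreasing size.

**Differential expression.** For each pair of groups with mean aSpC
values X and Y per protein:

    DAve = 2 (X − Y) / (X + Y)        (bounded in [−2, 2])
    DCI  = (X + Y)(X − Y) / 2

A protein is a differentially expressed protein (DEP) when |DAve| > 0.2
and |DCI| > 5 in at least one comparison.

**Discriminant screen and LDA.** Per protein, the one-way ANOVA F ratio
across groups; proteins with F ≥ 5 and p ≤ 0.01 enter a linear
discriminant model with a common (pooled, shrinkage-regularized)
covariance Σ and Mahalanobis assignment
d²(x, μ_g) = (x − μ_g)ᵀ Σ⁻¹ (x − μ_g). The discriminant ∩ DEP
intersection is the marker pool; a compact panel (default 6 proteins,
balanced across groups) is drawn from it by differential strength.

**Alpha typing.** For subject *i* and panel protein *p*,
α_i(p) = aSpC_i(p) / Σ_q aSpC_i(q) over the panel; subjects are typed by
the nearest group α-centroid in Euclidean distance.

**Phenotype linkage.** Kruskal–Wallis tests of the seven FOT Z-scores
(Rrs6/8/10, Xrs6/8/10, AX) across proteome groups with Dunn–Holm post hoc
pairs, plus a "Table 1"-style cohort comparison (Yates-corrected
chi-squared for binary covariates, Kruskal–Wallis for quantitative ones).

**Synthetic data.** A seeded negative-binomial generator with a
long-tailed log-normal abundance baseline, planted group markers and
group-shifted FOT Z-scores exercises every stage against known truth.

## Worked example

```r
library(uEVstrat)

sim  <- simulateSpc(simConfig(seed = 42))     # 21 subjects, 42 runs
se   <- alignRuns(sim$runs)
se   <- normalizeTotalSpc(se)
se   <- filterByFrequency(se, minFrac = 0.25)
subj <- averageReplicates(se)
subj
#> SpcExperiment: 757 proteins x 21 subjects (normalized)
#> provenance:
#>    aligned 42 runs over the union of 1144 accessions (absent = 0)
#>   total-SpC normalization: each column scaled to the grand mean total 5734.43
#>   frequency filter: kept 757/1144 proteins detected in > 25% of 42 runs
#>   replicates averaged to aSpC over 21 subjects

groups <- cutTree(clusterSubjects(subj), k = 3)
table(groups)
#> A B C
#> 9 6 6

disc <- fRatioSelect(subj, groups)            # F >= 5, p <= 0.01
deps <- pairwiseDeps(subj, groups)
deps
#> DepSet: 124 DEPs over 3 comparisons (|DAve| > 0.2, |DCI| > 5)

panel <- selectMarkerPanel(
  intersectPanels(disc$accession[disc$selected], deps, subj, groups),
  deps, k = 6)
panel
#> MarkerPanel (intersection): 6 proteins
#>    P1046, P0024, P0813, P0961, P0539, P0761
#>   lda_only 9 | intersection 43 | dep_only 81

prof   <- alphaProfile(subj, panel)
assign <- assignByAlpha(prof, alphaCentroids(subj, panel, groups))
head(assign, 4)
#>   subject_id assigned    margin degenerate
#> 1        S01        A 0.4515682      FALSE
#> 2        S02        A 0.3882443      FALSE
#> 3        S03        A 0.2829601      FALSE
#> 4        S04        A 0.4498837      FALSE

fot <- simulateFot(sim$truth, seed = 43)
rep <- compareGroupsFot(fot, groups)
print(rep$summary[, c("variable", "H", "p", "median_A", "median_C")],
      digits = 3)
#>   variable     H       p median_A median_C
#> 1   z_rrs6  4.02 0.13369    0.723  -0.9782
#> 2   z_rrs8  3.31 0.19107    0.707  -0.0127
#> 3  z_rrs10 13.05 0.00147    1.034  -1.0235
#> 4   z_xrs6  8.05 0.01788   -0.455   0.6284
#> 5   z_xrs8  4.14 0.12610   -0.231   1.4372
#> 6  z_xrs10  8.76 0.01251   -0.772   0.7910
#> 7     z_ax 11.11 0.00387    1.434  -1.5968
```

Reading the output: 1144 proteins were identified across the 42 simulated
runs, 757 survive the >25% detection filter; clustering recovers the
planted 9/6/6 group structure exactly (`adjustedRand(groups,
sim$truth$groups[names(groups)])` is 1); 124 proteins pass the DAve/DCI
thresholds, 43 of them also pass the F screen, and the 6-protein panel
types every subject with a positive margin. In the phenotype table, the
resistance and AX Z-scores are higher — and reactance lower — in group A
than in group C, with the planted contrasts carrying the smallest
Kruskal–Wallis p-values.

The same chain runs as one configured command:

```r
runPipeline(list(simulate = TRUE, output_dir = "out", seed = 42))
# or, from a shell:  Rscript inst/scripts/run_pipeline.R config.yaml
```

writing TSV reports (QC, matrix, groups, discriminants, DEPs, alpha
typing, FOT tests), a Newick dendrogram and a `summary.json` with the
stage funnel.

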