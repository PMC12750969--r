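# vertecol

Ecological inference from vertebral shape in carnivorans — a tested,
reusable 3D geometric-morphometrics pipeline going from landmark
configurations of serially sampled presacral vertebrae to ecological
predictions (running speed, hunting mode) for extant species and for fossil
specimens projected into the extant morphospace.

## Who this is for

Palaeontologists and morphometricians who have digitized 3D landmarks on
vertebrae (or any serially homologous elements), ecological category
assignments for the extant species, and optionally a time-calibrated
phylogeny — and who want to know how much locomotor/behavioural signal the
elements carry and what they predict for a fossil.

## What it computes

For each vertebral position (CF/CM/CL, TF/TM/TD/TL, LF/LM/LL: the
first/middle/last sampled vertebra per presacral region plus the
diaphragmatic thoracic), and for named multi-element combinations:

1. **Generalized Procrustes analysis (GPA).** Iterative superimposition
   removing translation, scale and orientation. Each configuration ends
   centered with unit centroid size
   (`CS = sqrt(sum of squared landmark distances to the centroid)`);
   original sizes are kept as a covariate.
2. **Shape PCA.** Covariance-matrix PCA (divisor *n* − 1) of the vectorized
   aligned coordinates; species mean shapes are used so every later analysis
   sees one point per species.
3. **Multi-block combination.** Each element is superimposed separately,
   vectorized, centered, scaled to unit total variance, concatenated, and a
   single PCA is run on the concatenation — a consensus morphospace over
   several vertebrae.
4. **PERMANOVA.** Distance-based pseudo-F,
   `F = (SS_between/(g−1)) / (SS_within/(N−g))` with
   `SS_total = (1/N) Σ_{i<j} d²_ij`, global and for every pair of category
   levels, with seeded permutation p-values.
5. **Phylogenetic GLS.** Multivariate regression of shape on speed, hunting
   or log centroid size under a Brownian-motion covariance (`C[i,j]` =
   shared root-to-ancestor branch length); `R² = SS_effect/SS_total` in the
   `C^{-1/2}`-transformed space, significance by residual randomization
   (RRPP).
6. **CVA + Mahalanobis membership.** Canonical variate analysis on retained
   PC scores (between/within generalized eigenproblem, within-group
   whitened); leave-one-out classification accuracy; fossils are centered,
   scaled, rotated onto the extant consensus, projected onto the retained
   PCs and mapped into canonical space, where squared Euclidean distance to
   a group mean is the Mahalanobis distance `d²_g` and membership is the
   softmax posterior `p_g = exp(−d²_g/2) / Σ_h exp(−d²_h/2)` (chi-square
   typicality reported alongside).
7. **Synthetic data generator.** Pure-birth trees, Brownian shape evolution,
   category effect vectors orthogonal to translation/scale, digitizing
   noise, random rigid motions, and pseudo-fossils of known class — so the
   whole pipeline is testable without any downloads.

## Worked example

```r
library(vertecol)

truth <- simulation_truth(n_species = 12, positions = c("CF", "LF"), seed = 42)
sim   <- simulate_dataset(truth, seed = 43)

blk <- species_mean_shapes(
  generalized_procrustes(subset_position(sim$dataset, "LF")))
blk
#> aligned_block[LF]: 12 configurations x 30 landmarks; GPA 6 iterations (converged)

sp <- fit_pca(blk)
sp
#> shape_space[LF]: 12 specimens, 11 components
#>   leading variance fractions: 0.371 0.278 0.122 0.077 0.034

grp <- factor(sim$ecology$speed[match(blk$specimen_ids, sim$ecology$species)])
pairwise_permanova(blk, grp, n_perm = 999, seed = 42)
#>             comparison pseudo_f p_value p_adjusted n_permutations seed
#> 1 fast vs intermediate 1.086590   0.361      1.000            999   43
#> 2         fast vs slow 2.149256   0.088      0.264            999   44
#> 3 intermediate vs slow 1.428234   0.209      0.627            999   45

m  <- cva_from_space(sp, grp)
f  <- make_pseudofossil(truth, "fast", "LF", seed = 44)
membership_probabilities(m, project_external(m, f),
                         position = "LF", category_set = "speed")
#> fossil_prediction [LF speed]: fast (p = 1.000, strong support)
#>         group mahalanobis_d2 probability typicality
#>          fast        44.5147           1          0
#>  intermediate       676.3833           0          0
#>          slow      6371.0741           0          0
```

Reading: at 12 species the pairwise PERMANOVA has little power (no pair is
significant at the 0.005 reporting threshold), yet the CVA posterior
identifies the pseudo-fossil's true speed class decisively — its Mahalanobis
distance to the "fast" mean is hundreds of units smaller than to the
alternatives, and the softmax posterior saturates at 1. The non-zero `d²`
even to the true group is expected: the within-group covariance is
estimated from few species in a retained-PC space of non-trivial dimension.

The same analysis runs from files (Morphologika landmarks, ecology CSV,
Newick tree) through one configuration:

```r
run_pipeline(list(output_dir = "run1", positions = c("CF", "LF"),
                  combinations = list(all = c("CF", "LF")),
                  input = list(landmarks = "landmarks.txt",
                               ecology = "ecology.csv", tree = "tree.nwk")))
```

which writes per-position PCA variance, PERMANOVA, PGLS and CVA tables, a
fossil prediction table, and a `manifest.json` with seeds and file
checksums (reruns are byte-identical). A thin command-line wrapper with
`simulate | gpa | pca | permanova | pgls | cva | predict-fossil | run-all`
subcommands lives at `inst/scripts/vertecol`.

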