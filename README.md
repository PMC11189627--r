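# sdmblend

Tools for asking a practical question in species distribution modelling
(SDM): **does blending community-sourced occurrence records (smartphone-app
observations) into traditional survey data improve presence-only models, and
by how much per record?** The package implements the full pipeline needed to
answer it — quality filtering of community records driven by observer
statistics, audit-based estimation of record validity, effort-weighted
pseudo-absence selection, a MaxEnt-style penalized regression, spatial-block
evaluation with the continuous Boyce index, and a blending/downsampling
experiment with a mixed-model summary — together with a synthetic-data
generator (virtual species on simulated landscapes with configurable
observer error) so every stage is testable against known truth without any
external data.

Who it is for: quantitative ecologists and biodiversity-informatics
developers who want a transparent, fully scriptable reference implementation
of this kind of analysis, or a sandbox for studying how observation bias and
data quality propagate into presence-only SDMs.

## The core model and statistics

**Presence-background model.** Habitat suitability is modelled from
presence records and background (pseudo-absence) points by maximum entropy,
in its penalized-regression form: continuous predictors are expanded into
linear, quadratic and hinge features `max(0, (x−k)/(x_max−k))`, and
coefficients maximize an L1-penalized background-contrast likelihood with
per-feature penalties `reg_multiplier × class_weight(n_presence) ×
sd_j/√n_presence` (published MaxEnt defaults; multiplier 2.5). Background
cells are drawn with probability proportional to `log(n + 1.2)` of local
record counts — a target-group sampling-effort proxy — from two surfaces
(all-taxa community counts; specialist + survey counts for the focal
taxon), merged 5,000 + 5,000 into 10,000 points.

**Record validity.** An audited record is *valid* if it documents a wild,
correctly identified individual: `p_valid(taxon) = frac_wild ×
acc_species`. A community presence enters the test set only under
multi-observer consensus: `p_tp = 1 − (1 − p_valid)^n_users > 0.99`.

**Evaluation.** Models are scored by the continuous Boyce index: the
Spearman correlation between predicted-to-expected presence ratios (P/E) in
overlapping suitability windows and the window midpoints, on a spatially
held-out block, with at least 50 test presences required for validity. The
blending experiment fits both dataset types over a geometric grid of
training sizes (20–20,000) and summarizes Fisher-z-transformed Boyce
indices with `z ~ type × log10(n) + (1 | species)`.

## Worked example

```r
library(sdmblend)

world <- build_experiment_world(n_species = 6, seed = 42)
cat("certified observers:", length(world$certified), "of", nrow(world$profiles$users), "\n")
cat("records passing filter:", nrow(world$filtered), "of", nrow(world$community),
    sprintf("(%.1f%%)\n", 100 * nrow(world$filtered) / nrow(world$community)))
round(world$p_valid, 3)

runs <- run_experiment(world$assemblies, c(100, 400), replicates = 3,
                       world$cfg, seed = 43)
aggregate(bi ~ type + n_records, runs, mean, na.rm = TRUE)
fit_mixed_model(runs)$coefficients
```

Output (R 4.3.3, this repository):

```
certified observers: 25 of 30
records passing filter: 80332 of 98000 (82.0%)
 amphibian       bird     insect seed_plant
     0.959      0.964      0.966      0.946

         type n_records        bi
1     blended       100 0.7736591
2 traditional       100 0.9010179
3     blended       400 0.7698948
4 traditional       400 0.9060044

               term estimate std_error     t     p
1       (Intercept)     1.96      0.81  2.41 0.016
2       typeblended    -1.21      1.05 -1.16 0.247
3             log_n    -0.20      0.35 -0.59 0.558
4 typeblended:log_n     0.49      0.46  1.07 0.286
```

Reading it: 25 of 30 simulated observers meet the certification thresholds
(< 15% of public records suggested as misidentified, < 0.5% flagged, > 20
public records), 82% of raw community records survive the automatic filter,
and the audited per-taxon validity `p_valid` of the *filtered* records is
0.95–0.97 (filtering removes labelled non-wild individuals and corrects
identifications). The run table gives the mean Boyce index per dataset type
and training size; on this particular 6-species draw the survey-only models
score higher at both sizes, and the mixed model finds no significant type
or interaction effect (a 6-species, 2-size design has very little power;
the full 20-species experiment lives in
`tests/testthat/test-acceptance.R`, and the vignette discusses why the
matched-size ordering is close to even on this synthetic world).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sdmblend", package = "sdmblend"))')
Rscript $CLI simulate --out records.csv --n 1000 --effort community --seed 1
Rscript $CLI filter --records records.csv --out filtered.csv --report cert.json
Rscript $CLI audit --records filtered.csv --out metrics.csv
Rscript $CLI experiment --out runs.csv --species 20 --seed 1
```

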