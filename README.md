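# evodfnc

Multiframe evolving dynamic functional network connectivity motifs.

## The problem

Resting-state fMRI studies routinely summarize time-varying whole-brain
connectivity by clustering windowed correlation frames into a handful of
static "snapshot" states and treating the dynamics as transitions between
them. That view cannot see *how* connectivity reconfigures — the multi-window
paths through which the brain enters, holds, and leaves characteristic
configurations — which is exactly where group differences in clinical
cohorts (e.g. schizophrenia patients versus controls) may reside.

`evodfnc` is for researchers with network timecourses in hand (e.g. group-ICA
network timecourses) who want **movie-style connectivity motifs** instead of
static states, plus the statistics to test group and symptom effects on
their usage.

## The method

For `N` networks, each sliding window yields a dFNC frame
`Γ(t) ∈ [-1, 1]^D`, `D = N(N-1)/2` (1081 for N = 47), from a tapered 22-TR
window advanced 1 TR at a time. The pipeline then:

1. embeds all frames jointly into 2D with UMAP
   (`n_neighbors = 25`, `min_dist = 0.75`), averaging `R = 25` runs
   (Procrustes-aligned by default) so each subject's trajectory
   `γ̂(t) = (x̂(t), ŷ(t))` stays a continuous curve;
2. linearizes every length-`τ` trajectory sub-segment (`τ = 44`, twice the
   window) to a (midpoint, slope, length) triple, clips slopes at
   `max(|x|, |y|)`, and k-means-clusters the triples into `K = 10`
   **linear trajectory exemplars**;
3. **lifts** each exemplar back to connectivity space: each of `τ` evenly
   spaced points along the exemplar becomes the mean of the `n = 25`
   spatially nearest observed frames, giving a `τ × D` evolving motif
   (EVOdFNC);
4. scores each observed length-`τ` window against the motifs frame by frame:
   the **representational importance** (RI) weight of motif `k` is the
   fraction of the window's frames whose best frame-wise correlate is motif
   `k` (weights are multiples of `1/τ` and sum to 1); RI weight vectors are
   clustered into `M = 10` meta-states with per-subject occupancy rates;
5. fits per-feature OLS models — diagnosis + age + gender + head motion, and
   a patients-only model with six positive symptom scores entered jointly —
   with BH-FDR correction.

A time-blind 5-state k-means baseline (`cluster_snapshots()`) and a
synthetic-cohort generator with planted evolving motifs (`simulate_cohort()`)
are included, so every stage is testable without any restricted data.

## Worked example

```r
library(evodfnc)

# a synthetic cohort: 10 controls + 10 patients, 12 networks, 158 TRs,
# two planted evolving motifs with a 2:1 group usage ratio
cohort <- simulate_cohort(synth_config(seed = 1))
bundle <- run_pipeline(cohort, evo_config(seed = 1), out_dir = "run1")

bundle
#> <evo_bundle> 20 subjects | 10 motifs (tau = 44) | 10 meta-states | models: group

# how continuous are the embedded subject trajectories?
mean(sapply(cohort$manifest$subject_id,
            function(s) continuity_ratio(bundle$embedding, s)))
#> [1] 0.009786222

# does a lifted motif recover planted motif 1?
planted <- cohort$ground_truth$motif_frames[[1]]
best <- max(sapply(bundle$motifs$motifs, function(m) {
  mean(sapply(1:44, function(t) cor(m[t, ], planted[t, ])))
}))
best
#> [1] 0.8588899

# group model on subject-mean representational importance
tidy(bundle$effects$group)
#> # A tibble: 10 x 7
#>   feature predictor estimate statistic p.value q.value     n
#>   <chr>   <chr>        <dbl>     <dbl>   <dbl>   <dbl> <int>
#> 1 motif1  diagnosis  0.0414      0.988   0.339   0.565    20
#> 2 motif2  diagnosis -0.00541    -0.127   0.901   0.901    20
#> # ... one row per motif
```

The continuity ratio compares a subject's median consecutive-frame distance
in the embedding to the median distance of random frame pairs — 0.0098 means
trajectories are two orders of magnitude smoother than chance, the property
the embedding parameters are chosen for. The recovery correlation of 0.86 is
the mean frame-wise Pearson correlation between the best lifted motif and
the planted ground-truth motif at window resolution. At this deliberately
small cohort size (n = 20) the diagnosis effect on a single motif's RI is
directional but not individually significant; the replicated experiment in
`scripts/acceptance.R` runs ten 60-subject cohorts, where the planted effect
is detected in 8 of 10.

`autoplot()` methods are provided for embeddings, exemplar sets, motif sets
(frame-strip heatmaps with a symmetric color range at the 95th percentile of
motif magnitudes), and effect tables; `tidy()`/`glance()` methods cover the
fitted objects.

A command-line front end mirrors the pipeline:

```sh
Rscript inst/cli/evodfnc.R simulate --preset tiny --seed 1 --out cohort1
Rscript inst/cli/evodfnc.R run-all --manifest cohort1/manifest.csv --out bundle1
```

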