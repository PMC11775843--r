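# endotyper

Unsupervised endotyping of arterial hypotension from routine haemodynamic
monitoring data.

## The problem

Hypotension (mean arterial pressure, MAP, below 65 mmHg for at least one
minute) in surgical and critically ill patients is a final common pathway
of several distinct circulatory failures — loss of vascular tone, loss of
circulating volume, depressed contractility, or inappropriate bradycardia —
each calling for a different treatment. `endotyper` implements a pipeline
that sorts hypotensive 20-second data points into four mechanistic
*endotypes* from four clinically actionable variables: stroke volume index
(SVI), heart rate (HR), systemic vascular resistance index (SVRI) and
stroke volume variation (SVV).

The pipeline is, in order:

1. **Episode detection** — maximal runs of ≥3 consecutive 20-s points with
   MAP < 65 mmHg, each extended backward with its contiguous pre-episode
   window of points with MAP in [65, 72);
2. **Normalization** — per-variable z-scores (x − μ)/σ;
3. **Embedding** — an autoencoder 4 → 16 → 8 → 2 → 8 → 16 → 4 trained on
   mean-squared reconstruction error; the 2-D bottleneck is the latent
   space;
4. **Clustering** — a full-covariance Gaussian mixture
   p(z) = Σₖ πₖ N(z; μₖ, Σₖ) fitted by EM in the latent space; the number
   of components is chosen by the Calinski–Harabasz index (higher better)
   with the Davies–Bouldin index (lower better) as a cross-check;
5. **Labelling** — clusters are named vasodilation / hypovolaemia /
   myocardial depression / bradycardia by a deterministic rule on their
   original-unit means (lowest HR → bradycardia; then lowest SVRI →
   vasodilation; then lower HR → myocardial depression);
6. **Per-point probabilities** — each point receives the mixture posterior
   over the four endotypes, and a frozen model can be applied unchanged to
   new data;
7. **Cross-dataset similarity** — endotypes of two fits are compared by the
   closed-form Gaussian Kullback–Leibler divergence
   KL(P‖Q) = ½[tr(Σ_Q⁻¹Σ_P) + (μ_Q−μ_P)ᵀΣ_Q⁻¹(μ_Q−μ_P) − d + ln(det Σ_Q/det Σ_P)]
   in a shared normalized variable space, with a minimum-cost bijective
   matching.

Because no public dataset carries these variables, the package ships a
synthetic cohort generator (`generate_cohort()`) that plants the published
development-cohort endotype mixture (weights 34.9/32.1/22.4/10.6%, with
the published per-variable means and standard deviations) inside realistic
MAP trajectories, together with ground-truth labels — the basis of all
validation and parameter-recovery tests.

## Worked example

```r
library(endotyper)

cohort <- generate_cohort(cohort_config(n_patients = 100,
                                        points_per_patient = 400,
                                        mode = "direct", seed = 1))
run <- run_pipeline(cohort, pipeline_config(seed = 1))
run4 <- refit_at_k(run, 4)   # the four-endotype solution
print(run4)
```

```
Endotyping run
  100 patients, 2555 episodes, 13930 hypotensive + 7654 preceding points
  selected k = 3 (CH and DB agree)
  endotype shares:
    myocardial_depression   23.5%
    hypovolaemia            29.3%
    vasodilation            36.8%
    bradycardia             10.4%
```

The four-component shares recover the planted mixing weights
(34.9 / 32.1 / 22.4 / 10.6%). Note the index-based selection itself
settled on k = 3 on this synthetic cohort: with *independent* Gaussians at
the published marginal spreads the four endotypes overlap heavily, and
merging the nearest pair is genuinely optimal for the Calinski–Harabasz
criterion — see the methods vignette
(`vignettes/endotyping-methods.Rmd`) for the analysis. `refit_at_k(run, 4)`
exposes the four-component solution that the recovery targets are defined
on.

Per-point endotype probabilities for new data use the frozen model:

```r
new_points <- run4$points[1:2, ]
assign_endotypes(run4$model, new_points)[, c("p_vasodilation", "label")]
#>   p_vasodilation        label
#> 1      0.9275035 vasodilation
#> 2      0.9762690 vasodilation
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/endotyper.R` (`simulate`, `detect`, `fit`, `apply`, `compare`).

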