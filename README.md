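# stFingerprint

Explainable classification of groups from regional brain time series.

Resting-state fMRI studies of clinical heterogeneity — for example, how
the functional brain organisation of females and males differs within an
autism cohort — face three coupled problems: the discriminative signal
lives in regional *dynamics* rather than simple summary statistics; the
data come from many acquisition sites with different scanners and
recording lengths; and the groups are heavily imbalanced (autism is
diagnosed about four times more often in males). **stFingerprint**
implements a complete analysis cycle for this setting, aimed at
neuroimaging researchers who want a validated, end-to-end reference
implementation they can run on their own region-by-time matrices:

1. **Classification.** A spatiotemporal 1D-convolutional network
   (stDNN): brain regions are input channels, two convolution+ReLU
   blocks run over time, temporal averaging makes the representation
   length-invariant, a one-hot site vector absorbs multi-site
   heterogeneity, and an affine head yields two class logits. Training
   minimises the label-distribution-aware margin (LDAM) loss,

   Δ<sub>j</sub> = C·n<sub>j</sub><sup>−1/4</sup> (rescaled so
   max Δ = 0.5),  ℓ(z, y) = −log [ e^{s(z_y−Δ_y)} / (e^{s(z_y−Δ_y)} +
   e^{s z_{1−y}}) ],

   which gives the rare class a larger decision margin; with Δ = 0 and
   s = 1 it is exactly softmax cross-entropy.
2. **Validation.** Stratified fivefold cross-validation; zero-shot
   transfer of the five fold models to an independent cohort whose sites
   were never seen in training (unseen sites are encoded as zero
   vectors, so no retraining is needed); and a specificity check that
   applies the same models to a population that lacks the group signal.
3. **Explanation.** Integrated-gradients "fingerprints": each subject's
   (region × time) map of signed attributions of the target-class logit,
   computed by a midpoint path integral that satisfies the completeness
   axiom. Group-level features are the median across subjects, then the
   median across the five fold models, thresholded at the top 5% of all
   (region, time) cells.
4. **Brain–behaviour association.** Per-region fingerprint scores
   (temporal means, averaged over fold models) are Spearman-correlated
   with symptom-domain scores within each group, with Benjamini–Hochberg
   FDR correction over the regions × domains family.

Because the clinical cohorts this method targets are access-restricted,
the package ships a synthetic multi-site cohort generator that plants a
group-discriminative oscillatory signal in chosen regions and links a
symptom score to one region's signal amplitude — so every stage above is
testable, with known ground truth, on any machine.

## Worked example

```r
library(stFingerprint)

cohort <- zscoreNormalize(generateCohort(synthConfig()))
cohort
#> Cohort: 100 subjects, 30 regions, 3 sites
#>   class counts (0/1): 80/20
#>   timepoints Nt: 100-148

cv <- crossValidate(cohort)
cv
#> CVResult: 5 folds
#>   accuracy 0.970 (s.d. 0.045)
#>   precision 0.977 (s.d. 0.032)
#>   recall 0.970 (s.d. 0.045)
#>   F1 0.971 (s.d. 0.043)

transfer <- zscoreNormalize(generateTransferCohort(synthConfig(), c("extA", "extB")))
tr <- applyModels(cv, transfer)
round(tr$summary$mean[tr$summary$metric == "accuracy"], 3)
#> [1] 0.944
```

The default cohort has 100 subjects at a 4:1 class imbalance across 3
sites, 30 regions of which 5 carry a planted oscillation in class-1
subjects at effect size 2 (baseline-s.d. units). Fivefold
cross-validation reaches 97% mean accuracy, and the five models carry
over to a freshly generated cohort from two *unseen* sites at 94% —
the zero-shot transfer property. Applying the same models to a cohort
generated without the planted effect drops accuracy to the 80%
majority-class rate: the classifier is specific to the group signal, not
to site or noise structure.

Fingerprinting and symptom association continue from the fitted models:

```r
g1 <- which(classLabels(cohort) == 1L)
maps <- lapply(cv@models, function(m)
  lapply(g1, function(i) integratedGradients(m, cohort, i, nSteps = 50L)))
feats <- thresholdTopFeatures(aggregateGroupFeatures(maps), 5, regionNames(cohort))
feats@regionHits          # regions surviving the top-5% consensus mask

scores <- regionScoreMatrix(cv@models, cohort, nSteps = 50L)
associateSymptoms(cohort, scores, c("rrb", "social", "comm"), group = 1L)
```

On the default cohort the top-5% mask recovers all five planted regions
and nothing else. A one-command version of the whole flow — simulate,
train, transfer, specificity, attribute, associate, with TSV outputs and
a JSON run report — is `runPipeline("out/", seed = 42)`, also exposed as
a CLI in `inst/cli/stfingerprint.R`.

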