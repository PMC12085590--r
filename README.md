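# socialtouch

Trial-based analysis of how neurons and orofacial behavior discriminate
social touch (contact with another mouse) from non-social touch (contact
with an object), under voluntary versus forced presentation. The package is
aimed at labs running head-fixed touch assays with chronic extracellular
probes and videography: a motorized platform presents a stimulus in repeated
bouts (5 s touch, 5 s interstimulus interval), while single-unit spiking and
pose-label time series are recorded.

It implements the full analysis chain as composable functions:

- **Timeline** — bout schedules and platform kinematics that define every
  trial window (`build_bout_schedule`, `travel_time`,
  `platform_position_trace`).
- **Spikes** — unit quality control (ISI violation < 10 %, amplitude cutoff
  < 10 %, median amplitude > 50 µV), regular-spiking classification
  (peak-to-trough ≥ 400 µs), depth-based region assignment, 50 ms rate
  binning, 250 ms moving-average smoothing, trial alignment over [−2, +7] s,
  and z-scoring to the pre-touch ISI baseline.
- **Behavior** — pose-label motion energy (two-frame displacement), eye
  area (shoelace polygon), saccade detection along the temporal–nasal axis,
  aversive-facial-expression bout detection (orbital tightening, whisker
  protraction), and running-avoidance fractions, all honoring a per-frame
  exclusion mask.
- **Clustering** — PCA of the unit × time z-scored PSTH matrix (components
  to > 95 % variance), gap-statistic choice of K, consensus k-means over
  random restarts with a co-assignment stability matrix, and merging of
  clusters into excited / suppressed / weak response classes.
- **Modulation** — the modulation index
  `MI = (FR_stim − FR_ISI) / (FR_stim + FR_ISI)` in three window variants
  (full 5 s stimulus vs ISI; first 3 s vs prior 3 s; platform-movement
  [−1, 1] s vs [−3, −1] s), Δmodulation (MI_social − MI_object), and an
  aversion-epoch split.
- **Preference** — leave-one-out decision variables
  `DV_i = t_i · (loo-mean difference between contexts)`, tie-aware
  trapezoidal auROC, a label-permutation significance test (1000 draws,
  α = 0.05), and social/object/none classification that reverses for
  suppressed units.
- **Decoding** — RBF-kernel soft-margin classification of touch context
  (cost 1, 10-fold cross-validation, stratified 80/20 splits, 100
  iterations, 1–20-unit subsampling), time-resolved decoding in 50 ms bins,
  label/feature shuffle controls, a 1.5 SD baseline-drift exclusion rule,
  and locomotion-augmented feature spaces. Behavioral decoders use 23
  pose-label motion energies or the aversive-behavior set at 100 ms bins.
- **Encoding** — a 13-regressor × 80-trial ridge linear encoding model of
  per-trial firing (penalty by cross-validation), sign-preserving
  normalized β weights (L1 = 1), weight–weight correlations across units,
  and a group summary over the 10 non-binary regressors with negative-cvR²
  exclusion.
- **Synthetic sessions** — a seeded generator of Poisson units drawn from
  four temporal archetypes with context-dependent gain, plus correlated
  behavioral channels with planted aversive events, providing ground truth
  for every stage.

## Worked example

```r
library(socialtouch)

cfg <- synthetic_config(n_units = c(vS1 = 30), n_bouts = 20,
                        social_gain = 2.5, object_gain = 1, seed = 42)
session <- generate_session(cfg)
qc <- qc_filter_units(session$units)

voluntary <- session$trials[session$trials$choice == "voluntary", ]
psths <- session_psths(session, voluntary, qc$kept$unit_id, window = c(-3, 10))
m   <- build_psth_matrix(psths)
red <- pca_reduce(m)                                   # 2 components > 95 %
cm  <- kmeans_consensus(red$scores, 4, n_restarts = 100,
                        psth_matrix = m, seed = 42)
cls <- group_response_classes(cm)
table(planted = session$ground_truth$units$archetype,
      recovered = cls$unit_class)
#>                    recovered
#> planted             excited suppressed
#>   suppressed              0          7
#>   sustained_excited       8          0
#>   transient_excited       8          0
#>   unmodulated             7          0

u1 <- qc$kept$unit_id[1]
psth_modulation_index(psths[[as.character(u1)]]$aligned, "STIM")
#> [1] 0.4154...   # stimulus roughly 2.4x the ISI rate

fx <- make_feature_matrix(session, "neural", voluntary, unit_ids = u1)
rs <- fx$x[voluntary$context == "social", 1]
ro <- fx$x[voluntary$context == "object", 1]
pref <- bootstrap_preference_test(rs, ro, n_boot = 1000, seed = 42)
c(pref$auroc, pref$p_boot)
#> [1] 1.000 0.001    -> classify_preference(...) == "social"

fx_all <- make_feature_matrix(session, "neural", voluntary,
                              unit_ids = qc$kept$unit_id)
dec <- decode_context(fx_all, decoder_config(n_units_subsample = 10,
                                             n_iterations = 100, seed = 42))
dec$accuracy_mean
#> [1] 1         # planted 2.5x context gain is fully decodable
shuffle_controls(fx_all, decoder_config(n_units_subsample = 10,
                                        n_iterations = 100, seed = 42),
                 "test_labels")$accuracy_mean
#> [1] 0.5       # chance once test labels are shuffled
```

The table shows the four planted response archetypes collapsing into the
excited/suppressed classes (the "unmodulated" archetype has no temporal
shape change but still carries the session-wide context gain, so it sits in
the excited class here). The modulation index of ~0.42 corresponds to a
stimulus rate ~2.4× the ISI rate; the unit's auROC of 1.0 with p ≈ 0.001
marks it social-preferring; population decoding of context is perfect at
this planted separation while the shuffled-label control sits at chance.

`run_pipeline(cfg, out_dir)` chains all stages (simulate → QC → PSTH →
cluster → modulation → preference → decode → encode) and writes csv/json
tables plus a log to `out_dir`.

## Vignette

`vignettes/socialtouch-methods.Rmd` describes the models and procedures,
the defaults and their units, what the synthetic generator does and does not
emulate, and the numerical edge-case policies.
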