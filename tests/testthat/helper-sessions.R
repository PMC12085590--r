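# Shared small synthetic fixtures, built in code at test time.

# single-region session with unmodulated Poisson units and a context gain;
# frame rate kept low: these fixtures exercise spikes, not video
gain_session <- function(gain, n_units = 10, n_bouts = 40, seed = 1,
                         choices = "forced", baseline = c(4, 8)) {
  cfg <- synthetic_config(
    n_units = c(vS1 = n_units),
    archetype_props = c(transient_excited = 0, sustained_excited = 0,
                        suppressed = 0, unmodulated = 1),
    n_bouts = n_bouts, choices = choices, baseline_range = baseline,
    social_gain = gain, object_gain = 1, frame_rate = 30, seed = seed)
  trl <- generate_trials(cfg)
  u <- generate_units(cfg)
  sp <- generate_spike_trains(u, trl, cfg)
  structure(list(trials = trl, units = u, spikes = sp, behavior = NULL,
                 ground_truth = list(units = u),
                 meta = list(seed = seed)),
            class = "touch_session")
}

# archetype-mix session used for clustering / PSTH shape tests
archetype_session <- function(n_units = 40, n_bouts = 20, seed = 42) {
  cfg <- synthetic_config(n_units = c(vS1 = n_units), n_bouts = n_bouts,
                          choices = "voluntary", frame_rate = 30, seed = seed)
  trl <- generate_trials(cfg)
  u <- generate_units(cfg)
  sp <- generate_spike_trains(u, trl, cfg)
  structure(list(trials = trl, units = u, spikes = sp, behavior = NULL,
                 ground_truth = list(units = u), meta = list(seed = seed)),
            class = "touch_session")
}

# brute-force tie-aware auROC over all trial pairs (independent oracle)
pairwise_auroc <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}
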