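# Shared fixtures: reduced designs and hand-built epochs keep the suite
# fast while exercising the same code paths as the full-scale study.

# compact montage with midline + both sensorimotor sets
small_channels <- function() {
  unique(c("Fz", "Cz", "Pz", sensorimotor_channels("left"),
           sensorimotor_channels("right")))
}

small_design <- function(subjects = 2L, groups = "control",
                         schemes = c("FVS-1", "NMES-2"),
                         arms = "dominant", unions = "ECU-ED",
                         channels = small_channels(), rate = 250) {
  design_spec(groups = groups, subjects_per_group = subjects, arms = arms,
              muscle_unions = unions, schemes = schemes,
              analyzed_channels = channels, sampling_rate = rate)
}

# epoch with specified constant baseline/block values per channel
constant_epoch <- function(baseline = 0, block = 0, channels = c("Fz", "Cz", "Pz"),
                           rate = 100) {
  nb <- 5 * rate; nk <- 10 * rate
  vals <- t(vapply(seq_along(channels), function(i) {
    b <- if (length(baseline) > 1) baseline[i] else baseline
    k <- if (length(block) > 1) block[i] else block
    c(rep(b, nb), rep(k, nk))
  }, numeric(nb + nk)))
  rownames(vals) <- channels
  new_epoch(vals, rate, metadata = list())
}

# noise-free epoch carrying only a P300-like half-wave on the midline
p300_epoch <- function(amp, latency = 0.4, width = 0.3, rate = 250) {
  channels <- c("Fz", "Cz", "Pz")
  n <- 15 * rate
  tt <- seq(-5, by = 1 / rate, length.out = n)
  hw <- amp * ifelse(abs((tt - latency) / width) <= 0.5,
                     cos(pi * (tt - latency) / width), 0)
  vals <- rbind(Fz = hw, Cz = hw, Pz = hw)
  new_epoch(vals, rate)
}

first_trial_recording <- function(design, seed = 1L,
                                  effects_fn = default_effects) {
  man <- simulation_manifest(design, seed, effects_fn)
  simulate_trial(man$trials[1, ], man$effects[[1]], design,
                 man$block_onsets)
}
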