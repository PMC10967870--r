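#' Study design specification
#'
#' Describes the factorial layout of the stimulation study: two groups
#' (stroke, control) of 15 participants, stimulated on both arms and both
#' forearm muscle unions with eight schemes (five focal vibration
#' intensities FVS-1..5 and three electrical intensities NMES-1..3), six
#' 10-s stimulation blocks per trial, recorded from 62 analyzed 10-10
#' channels at 1000 Hz.
#'
#' @param groups Group labels.
#' @param subjects_per_group Participants per group.
#' @param arms Target arm labels.
#' @param muscle_unions Target muscle-union labels.
#' @param schemes Ordered stimulation scheme labels.
#' @param blocks_per_trial Stimulation blocks in one trial.
#' @param analyzed_channels Ordered channel labels (default 62-channel 10-10).
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_duration_s Acquisition duration of one trial in seconds.
#' @return A `design_spec` list.
#' @export
design_spec <- function(groups = c("stroke", "control"),
                        subjects_per_group = 15L,
                        arms = c("dominant", "nondominant"),
                        muscle_unions = c("ECU-ED", "FCR-FD"),
                        schemes = c(paste0("FVS-", 1:5), paste0("NMES-", 1:3)),
                        blocks_per_trial = 6L,
                        analyzed_channels = montage_1010()$label,
                        sampling_rate = 1000,
                        trial_duration_s = 240) {
  if (anyDuplicated(analyzed_channels))
    stop("configuration error: duplicate channel labels in 'analyzed_channels'")
  stopifnot(length(groups) >= 1L, subjects_per_group >= 1L,
            blocks_per_trial >= 1L, sampling_rate > 0, trial_duration_s > 0)
  structure(list(
    groups = groups,
    subjects_per_group = as.integer(subjects_per_group),
    arms = arms,
    muscle_unions = muscle_unions,
    schemes = schemes,
    blocks_per_trial = as.integer(blocks_per_trial),
    analyzed_channels = analyzed_channels,
    sampling_rate = sampling_rate,
    trial_duration_s = trial_duration_s
  ), class = "design_spec")
}

#' Stimulation scheme descriptions
#'
#' FVS schemes carry a nominal vibration amplitude in G, strictly
#' decreasing from 1.9 G (FVS-1) to 0.7 G (FVS-5). NMES schemes are ranked
#' by threshold role: motor threshold (NMES-1), the median of the
#' perceptual and motor thresholds (NMES-2), and the perceptual threshold
#' (NMES-3). `drive` is the normalized effective stimulus drive in (0, 1]
#' used by [default_effects()]: FVS amplitude relative to 1.9 G, and
#' 1 / 0.75 / 0.5 for the three NMES threshold roles.
#'
#' @return data.frame with `label`, `stim_type`, `intensity_level`,
#'   `nominal_intensity`, `drive`.
#' @export
scheme_table <- function() {
  g <- c(1.9, 1.6, 1.3, 1.0, 0.7)
  data.frame(
    label = c(paste0("FVS-", 1:5), paste0("NMES-", 1:3)),
    stim_type = rep(c("FVS", "NMES"), c(5L, 3L)),
    intensity_level = c(1:5, 1:3),
    nominal_intensity = c(g, NA, NA, NA),
    threshold_role = c(rep(NA_character_, 5L),
                       "motor", "median", "perceptual"),
    drive = c(g / 1.9, 1.0, 0.75, 0.5),
    stringsAsFactors = FALSE
  )
}

scheme_spec <- function(label) {
  tb <- scheme_table()
  i <- match(label, tb$label)
  if (is.na(i)) stop("unknown stimulation scheme: ", label)
  as.list(tb[i, ])
}

#' Enumerate the full factorial episode index
#'
#' One record per group x subject x arm x union x scheme x block x channel.
#' With the default design this yields 178,560 episode records in each
#' group (15 subjects x 2 arms x 2 unions x 8 schemes x 6 blocks x
#' 62 channels).
#'
#' @param config A [design_spec()].
#' @return data.frame episode index with stable, deterministic ordering.
#' @export
build_design <- function(config = design_spec()) {
  stopifnot(inherits(config, "design_spec"))
  if (anyDuplicated(config$analyzed_channels))
    stop("configuration error: duplicate channel labels")
  idx <- expand.grid(
    channel = config$analyzed_channels,
    block = seq_len(config$blocks_per_trial),
    scheme = config$schemes,
    union = config$muscle_unions,
    arm = config$arms,
    subject = seq_len(config$subjects_per_group),
    group = config$groups,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  idx <- idx[, c("group", "subject", "arm", "union", "scheme", "block", "channel")]
  idx$subject_id <- sprintf("%s%02d", substr(idx$group, 1, 1), idx$subject)
  idx
}

#' Ground-truth effect parameters for a group x scheme cell
#'
#' Encodes the qualitative effect structure the pipeline must recover:
#' higher stimulus drive gives a larger and earlier P300; FVS responses
#' are earlier than NMES responses at matched intensity rank; theta power
#' rises transiently at block onset (ERS) while alpha and beta power drop
#' (ERD) with an exponential return toward baseline (adaptation); the
#' stroke group shows attenuated amplitudes and a laterality shift toward
#' the contralesional hemisphere.
#'
#' @param group `"stroke"` or `"control"`.
#' @param scheme A scheme label (see [scheme_table()]) or a scheme list.
#' @param stroke_scale Multiplicative attenuation applied to stroke-group
#'   effect magnitudes.
#' @return An `effect_params` list.
#' @export
default_effects <- function(group, scheme, stroke_scale = 0.6) {
  if (!group %in% c("stroke", "control")) stop("unknown group: ", group)
  if (is.character(scheme)) scheme <- scheme_spec(scheme)
  d <- scheme$drive
  is_fvs <- scheme$stim_type == "FVS"
  p <- list(
    p300_amp = 6 * d,                                  # uV
    p300_latency = if (is_fvs) 0.34 + (1 - d) * 0.25
                   else 0.45 + (1 - d) * 0.30,          # s
    p300_width = 0.30,                                  # s
    theta_ers_gain = 1 + 1.0 * d,
    alpha_erd_depth = 0.45 * d,
    beta_erd_depth = 0.35 * d,
    erd_adaptation_tau = 4.0,                           # s
    laterality_weight = 0.80,
    noise_1f_scale = 8,                                 # uV RMS
    oscillator_base_amp = c(theta = 3, alpha = 5, beta = 3, gamma = 1.5) # uV RMS
  )
  if (group == "stroke") {
    p$p300_amp <- p$p300_amp * stroke_scale
    p$theta_ers_gain <- 1 + (p$theta_ers_gain - 1) * stroke_scale
    p$alpha_erd_depth <- p$alpha_erd_depth * stroke_scale
    p$beta_erd_depth <- p$beta_erd_depth * stroke_scale
    p$laterality_weight <- 0.65
  }
  stopifnot(p$alpha_erd_depth >= 0, p$alpha_erd_depth <= 1,
            p$beta_erd_depth >= 0, p$beta_erd_depth <= 1,
            p$p300_latency >= 0.25, p$p300_latency <= 0.8,
            p$p300_amp >= 0)
  structure(p, class = "effect_params")
}

#' Zero-effect parameters (background activity only)
#'
#' @return An `effect_params` list with all injected effects switched off.
#' @export
null_effects <- function() {
  p <- default_effects("control", "FVS-1")
  p$p300_amp <- 0
  p$theta_ers_gain <- 1
  p$alpha_erd_depth <- 0
  p$beta_erd_depth <- 0
  p
}

#' Build a simulation manifest for a synthetic study
#'
#' One record per stimulation trial (group x subject x arm x union x
#' scheme) with its ground-truth effect parameters, a reproducible trial
#' seed derived from the master seed by counter-based mixing, and the
#' block onset schedule. Lesioned hemisphere is assigned alternately
#' (left/right) across stroke subjects; controls carry `NA`.
#'
#' @param config A [design_spec()].
#' @param master_seed Integer master seed.
#' @param effects_fn Function `(group, scheme) -> effect_params`.
#' @return A `simulation_manifest` list: `$trials` (data.frame),
#'   `$effects` (list of `effect_params` per trial), `$master_seed`,
#'   `$config`.
#' @export
simulation_manifest <- function(config = design_spec(), master_seed = 1L,
                                effects_fn = default_effects) {
  trials <- expand.grid(
    scheme = config$schemes,
    union = config$muscle_unions,
    arm = config$arms,
    subject = seq_len(config$subjects_per_group),
    group = config$groups,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  trials <- trials[, c("group", "subject", "arm", "union", "scheme")]
  trials$subject_id <- sprintf("%s%02d", substr(trials$group, 1, 1), trials$subject)
  trials$lesioned_hemisphere <- ifelse(
    trials$group == "stroke",
    ifelse(trials$subject %% 2L == 1L, "left", "right"),
    NA_character_
  )
  trials$trial_seed <- vapply(seq_len(nrow(trials)),
                              function(i) mix_seed(master_seed, i), integer(1))
  onsets <- block_onsets(config)
  effects <- lapply(seq_len(nrow(trials)),
                    function(i) effects_fn(trials$group[i], trials$scheme[i]))
  structure(list(trials = trials, effects = effects,
                 block_onsets = onsets, master_seed = as.integer(master_seed),
                 config = config),
            class = "simulation_manifest")
}

# fixed block schedule: 10-s blocks every 35 s (>= 20 s quiet between blocks)
block_onsets <- function(config, first_onset = 20, spacing = 35,
                         block_dur = 10, min_gap = 20) {
  onsets <- first_onset + spacing * (seq_len(config$blocks_per_trial) - 1L)
  if (any(diff(onsets) - block_dur < min_gap))
    stop("block onset schedule violates the minimum quiet-gap invariant")
  if (utils::tail(onsets, 1L) + block_dur > config$trial_duration_s)
    stop("block onset schedule exceeds the trial duration")
  onsets
}

# stationary Gaussian noise synthesized in the frequency domain: complex
# Gaussian amplitudes on the positive-frequency bins weighted by `w`,
# Hermitian-mirrored, one inverse FFT. Scaled by the process's theoretical
# RMS (unit in expectation), not the realized RMS: normalizing each
# realization would equalize per-trial variance, making across-subject
# t statistics sub-Gaussian and deflating permutation error rates.
spectral_noise <- function(n, weights_pos) {
  act <- which(weights_pos > 0)
  if (length(act) == 0L) return(numeric(n))
  W <- complex(n)
  amp <- weights_pos[act] *
    complex(real = stats::rnorm(length(act)),
            imaginary = stats::rnorm(length(act)))
  W[act + 1L] <- amp                       # bin 1 is DC, kept at zero
  W[n - act + 1L] <- Conj(amp)             # Hermitian symmetry
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  rms_theory <- 2 * sqrt(sum(weights_pos[act]^2)) / n
  x / rms_theory
}

# positive-frequency grid (Hz) for bins 1..floor(n/2)
pos_freqs <- function(n, fs) (seq_len(n %/% 2L)) * fs / n

# band-limited Gaussian noise, unit RMS (brick-wall support [f1, f2))
band_noise <- function(n, fs, f1, f2) {
  f <- pos_freqs(n, fs)
  spectral_noise(n, as.numeric(f >= f1 & f < f2))
}

# 1/f (pink-like) Gaussian background, unit RMS; flat below 1 Hz
pink_noise <- function(n, fs) {
  f <- pos_freqs(n, fs)
  spectral_noise(n, 1 / sqrt(pmax(f, 1)))
}

#' Simulate one stimulation trial
#'
#' Generates a 4-min multichannel recording: per channel, 1/f background
#' noise plus theta/alpha/beta/gamma band-limited oscillators with
#' unit-mean envelopes. Within each 10-s stimulation block, the alpha and
#' beta envelopes on sensorimotor channels are multiplied by
#' `1 - depth * exp(-(t - onset) / tau)` (desynchronization with
#' adaptation), the theta envelope is multiplied by `theta_ers_gain` over
#' the first 0.5 s, and a positive half-wave of amplitude `p300_amp` is
#' added to the midline channels (Fz/Cz/Pz weighted 0.8/1.0/0.9).
#' Sensorimotor effects are split between hemispheres by
#' `laterality_weight` (fraction on the hemisphere contralateral to the
#' stimulated arm). Event markers carry the scheme label at each block
#' onset. Bit-reproducible given the trial seed.
#'
#' @param trial One-row data.frame (or list) with at least `arm`, `scheme`,
#'   `trial_seed`; typically a row of a [simulation_manifest()]'s `$trials`.
#' @param effects An `effect_params` list for this trial.
#' @param config A [design_spec()].
#' @param block_onsets Block onset times in seconds.
#' @return An `eeg_recording`.
#' @export
simulate_trial <- function(trial, effects, config = design_spec(),
                           block_onsets = NULL) {
  stopifnot(inherits(config, "design_spec"))
  if (is.null(block_onsets)) block_onsets <- block_onsets(config)
  if (any(diff(block_onsets) < 30))
    stop("block onset schedule violates the minimum quiet-gap invariant")
  fs <- config$sampling_rate
  n <- round(config$trial_duration_s * fs)
  chans <- config$analyzed_channels
  nch <- length(chans)
  tt <- seq(0, by = 1 / fs, length.out = n)
  set.seed(trial$trial_seed)

  bt <- band_table()
  base_amp <- effects$oscillator_base_amp

  # per-channel hemispheric weight of sensorimotor effects
  contra <- contralateral_hemisphere(trial$arm)
  sm_contra <- sensorimotor_channels(contra)
  sm_ipsi <- sensorimotor_channels(if (contra == "left") "right" else "left")
  w_ch <- numeric(nch)
  names(w_ch) <- chans
  w_ch[chans %in% sm_contra] <- effects$laterality_weight
  w_ch[chans %in% sm_ipsi] <- 1 - effects$laterality_weight

  # block-locked envelope factors shared by all channels (scaled by w_ch)
  erd_env <- function(depth, tau) {
    env <- rep(1, n)
    for (o in block_onsets) {
      i <- which(tt >= o & tt < o + 10)
      env[i] <- 1 - depth * exp(-(tt[i] - o) / tau)
    }
    env
  }
  theta_env_gain <- function(gain) {
    env <- rep(1, n)
    for (o in block_onsets) {
      i <- which(tt >= o & tt < o + 0.5)
      env[i] <- gain
    }
    env
  }

  # midline P300 half-waves
  p300 <- numeric(n)
  if (effects$p300_amp > 0) {
    for (o in block_onsets) {
      p300 <- p300 + half_wave(tt, effects$p300_amp,
                               o + effects$p300_latency, effects$p300_width)
    }
  }
  midline_w <- c(Fz = 0.8, Cz = 1.0, Pz = 0.9)

  samples <- matrix(0, nrow = nch, ncol = n, dimnames = list(chans, NULL))
  for (ci in seq_len(nch)) {
    x <- effects$noise_1f_scale * pink_noise(n, fs)
    for (bi in seq_len(nrow(bt))) {
      band <- bt$band[bi]
      osc <- base_amp[[band]] * band_noise(n, fs, bt$f1[bi], bt$f2[bi])
      w <- w_ch[ci]
      if (w > 0) {
        env <- switch(band,
          theta = theta_env_gain(1 + w * (effects$theta_ers_gain - 1)),
          alpha = erd_env(w * effects$alpha_erd_depth, effects$erd_adaptation_tau),
          beta  = erd_env(w * effects$beta_erd_depth, effects$erd_adaptation_tau),
          rep(1, n))
        osc <- osc * env
      }
      x <- x + osc
    }
    if (chans[ci] %in% names(midline_w))
      x <- x + midline_w[[chans[ci]]] * p300
    samples[ci, ] <- x
  }

  events <- data.frame(
    onset_sample = as.integer(round(block_onsets * fs)) + 1L,
    label = rep(trial$scheme, length(block_onsets)),
    stringsAsFactors = FALSE
  )
  new_recording(samples, fs, chans, events)
}
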