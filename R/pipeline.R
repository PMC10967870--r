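#' Run configuration for a synthetic study
#'
#' Bundles every tunable of the pipeline: the study design, band table,
#' period of interest, P300 search window, filter settings, artifact
#' threshold, permutation counts, representative schemes for the
#' time-frequency outputs, and the master seed. Serializable to JSON so a
#' copy can accompany every run's outputs.
#'
#' @param design A [design_spec()].
#' @param master_seed Integer master seed for every random draw.
#' @param effects_fn `(group, scheme) -> effect_params` ground truth.
#' @param period Period of interest for RSP, seconds after onset.
#' @param p300_window P300 peak search window, seconds after onset.
#' @param ptp_threshold Artifact rejection threshold, uV peak-to-peak.
#' @param n_perm Permutation count for all permutation tests.
#' @param alpha Significance level.
#' @param representative_schemes Schemes for ERSP maps and topographies.
#' @param ersp_channels Channels for the representative ERSP maps.
#' @param topo_bands Bands for ERD/ERS topographies.
#' @param topo_window ERD/ERS latency window, seconds.
#' @param tfr_decim Temporal decimation of time-frequency maps.
#' @param tfr_freqs Frequencies (Hz) of the time-frequency grid.
#' @param compute_timefreq Compute ERSP maps and topographies (the
#'   costliest stage)?
#' @param filter_settings List with `low`, `high`, `notch`, `order`.
#' @return A `run_config` list.
#' @export
run_config <- function(design = design_spec(), master_seed = 1L,
                       effects_fn = default_effects,
                       period = c(0.30, 0.75), p300_window = c(0.25, 0.80),
                       ptp_threshold = 200, n_perm = 2000, alpha = 0.05,
                       representative_schemes = c("FVS-1", "NMES-2"),
                       ersp_channels = c("C3", "C4"),
                       topo_bands = c("theta", "alpha", "beta"),
                       topo_window = c(0, 10), tfr_decim = 20L,
                       tfr_freqs = 2:45, compute_timefreq = TRUE,
                       filter_settings = list(low = 1, high = 100,
                                              notch = c(49, 51), order = 4)) {
  structure(as.list(environment()), class = "run_config")
}

#' Per-participant reading units
#'
#' Averages a feature across the repeated blocks of a stimulation trial,
#' yielding one value per (subject, arm, union, scheme) cell -- the
#' experimental reading unit consumed by the statistical batteries. The
#' number of contributing blocks (after artifact rejection) is logged per
#' cell.
#'
#' @param features Long data.frame containing the grouping keys present
#'   among `subject_id`, `group`, `arm`, `union`, `scheme`, `band`,
#'   `region`, plus a value column.
#' @param value Value column name.
#' @return data.frame of block means with an `n_blocks` column.
#' @export
summarize_reading_units <- function(features, value = "value") {
  keys <- intersect(c("subject_id", "group", "arm", "union", "scheme",
                      "band", "region"), names(features))
  agg <- stats::aggregate(features[[value]], features[keys], mean)
  names(agg)[ncol(agg)] <- value
  cnt <- stats::aggregate(features[[value]], features[keys], length)
  agg$n_blocks <- cnt$x
  agg
}

# features of one simulated / recorded trial after preprocessing
trial_features <- function(rec, trial, cfg) {
  fsets <- cfg$filter_settings
  rec <- bandpass_notch(rec, low = fsets$low, high = fsets$high,
                        notch = fsets$notch, order = fsets$order)
  rec <- flip_montage(rec, trial$lesioned_hemisphere)
  epochs <- segment_epochs(rec, metadata = as.list(trial))
  rej <- reject_artifacts(epochs, ptp_threshold = cfg$ptp_threshold)
  kept <- rej$kept
  if (length(kept) == 0L)
    return(list(p300 = NULL, rsp = NULL, epochs = kept, n_rejected = length(epochs)))

  erps <- lapply(kept, compute_erp)
  p300_wave <- midline_p300(average_erps(erps))
  pk <- extract_p300(p300_wave, window = cfg$p300_window)
  p300 <- data.frame(group = trial$group, subject_id = trial$subject_id,
                     arm = trial$arm, union = trial$union,
                     scheme = trial$scheme,
                     peak_amplitude = pk$peak_amplitude,
                     peak_latency = pk$peak_latency,
                     n_blocks = length(kept), stringsAsFactors = FALSE)

  rsp <- do.call(rbind, lapply(seq_along(kept), function(b) {
    v <- compute_rsp(kept[[b]], period = cfg$period)
    v$block <- b
    v
  }))
  agg <- rbind(aggregate_rsp(rsp, "whole-brain"),
               tryCatch(aggregate_rsp(rsp, "contralateral-sensorimotor",
                                      arm = trial$arm),
                        error = function(e) NULL))
  agg$group <- trial$group; agg$subject_id <- trial$subject_id
  agg$arm <- trial$arm; agg$union <- trial$union; agg$scheme <- trial$scheme

  list(p300 = p300, rsp = agg, epochs = kept,
       n_rejected = length(epochs) - length(kept))
}

# per-channel ERD/ERS topography values for one trial's kept epochs
trial_topo <- function(epochs, cfg) {
  chans <- rownames(epochs[[1]]$samples)
  out <- list()
  for (band in cfg$topo_bands) {
    fr <- band_edges(band)
    freqs <- cfg$tfr_freqs[cfg$tfr_freqs >= fr[1] & cfg$tfr_freqs < fr[2]]
    if (length(freqs) == 0L) next
    vals <- vapply(chans, function(ch) {
      per_block <- vapply(epochs, function(ep) {
        em <- compute_ersp(
          compute_tfr(ep$samples[ch, ], ep$rate, freqs = freqs,
                      decim = cfg$tfr_decim),
          ep$time, channel = ch)
        compute_erd_ers(em, fr, window = cfg$topo_window)$value
      }, numeric(1))
      mean(per_block)
    }, numeric(1))
    out[[band]] <- vals
  }
  out
}

#' Run the full synthetic study pipeline
#'
#' Generates every trial of the configured design, preprocesses it
#' (filter, montage flip, segmentation, artifact rejection), extracts the
#' P300 and relative-spectral-power reading units, computes representative
#' ERSP maps with their baseline-permutation masks and ERD/ERS
#' topographies, and runs the statistical batteries. Every random draw is
#' derived from the master seed, so a rerun with the same configuration
#' reproduces the bundle exactly.
#'
#' @param cfg A [run_config()].
#' @param progress Print per-stage progress lines?
#' @return A `report_bundle` list: `episode_counts`, `p300`, `rsp`,
#'   `ersp`, `topo`, `topo_tests`, `stats`, `rejections`, `manifest`,
#'   `config`, `log`.
#' @export
run_synthetic_study <- function(cfg = run_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  t_start <- Sys.time()
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- list(stage = stage, info = sprintf(...),
                                     elapsed_s = as.numeric(Sys.time() - t_start,
                                                            units = "secs"))
    if (progress) message(stage, ": ", sprintf(...))
  }

  design <- cfg$design
  idx <- build_design(design)
  episode_counts <- table(idx$group)
  note("design", "%d episode records per group", episode_counts[[1]])

  manifest <- simulation_manifest(design, cfg$master_seed, cfg$effects_fn)
  trials <- manifest$trials
  p300_rows <- list(); rsp_rows <- list(); n_rej <- 0L
  topo_acc <- list()      # topo_acc[[scheme]][[band]]: subject x channel rows
  ersp_acc <- list()      # ersp_acc[[scheme]][[channel]][[group]]: list of maps

  for (i in seq_len(nrow(trials))) {
    trial <- trials[i, ]
    rec <- simulate_trial(trial, manifest$effects[[i]], design,
                          manifest$block_onsets)
    fx <- trial_features(rec, trial, cfg)
    p300_rows[[i]] <- fx$p300
    rsp_rows[[i]] <- fx$rsp
    n_rej <- n_rej + fx$n_rejected
    if (cfg$compute_timefreq && trial$scheme %in% cfg$representative_schemes &&
        length(fx$epochs) > 0) {
      topo <- trial_topo(fx$epochs, cfg)
      for (band in names(topo)) {
        key <- paste(trial$scheme, band, sep = "|")
        topo_acc[[key]] <- rbind(
          topo_acc[[key]],
          data.frame(group = trial$group, subject_id = trial$subject_id,
                     arm = trial$arm, union = trial$union,
                     t(topo[[band]]), check.names = FALSE))
      }
      for (ch in intersect(cfg$ersp_channels, rownames(fx$epochs[[1]]$samples))) {
        maps <- lapply(fx$epochs, ersp_for_epoch, channel = ch,
                       freqs = cfg$tfr_freqs, decim = cfg$tfr_decim)
        key <- paste(trial$scheme, ch, trial$group, sep = "|")
        ersp_acc[[key]] <- c(ersp_acc[[key]], maps)
      }
    }
  }
  note("features", "%d trials processed, %d epochs rejected",
       nrow(trials), n_rej)

  p300 <- do.call(rbind, p300_rows)
  rsp <- do.call(rbind, rsp_rows)

  # group-level ERSP per (scheme, channel, group): all blocks of all
  # subjects pooled as observations for the baseline-permutation mask
  ersp_out <- list()
  for (k in seq_along(ersp_acc)) {
    masked <- baseline_permutation_mask(
      ersp_acc[[k]], n_perm = cfg$n_perm, alpha = cfg$alpha,
      seed = mix_seed(cfg$master_seed, 10000L + k))
    masked$n_blocks <- length(ersp_acc[[k]])
    masked$mask_fraction <- mean(masked$mask)
    ersp_out[[names(ersp_acc)[k]]] <- masked
  }

  # topographic group comparisons on the representative schemes
  graph <- NULL
  topo_tests <- list()
  if (length(topo_acc) > 0) {
    mont <- montage_1010()
    mont <- mont[mont$label %in% design$analyzed_channels, , drop = FALSE]
    graph <- neighbor_graph(mont)
    for (key in names(topo_acc)) {
      df <- topo_acc[[key]]
      chans <- setdiff(names(df), c("group", "subject_id", "arm", "union"))
      # reading unit: mean over arms/unions per subject
      groups <- unique(df$group)
      if (length(groups) != 2L) next
      mats <- lapply(groups, function(g) {
        sub <- df[df$group == g, ]
        m <- stats::aggregate(sub[chans], by = list(sub$subject_id), mean)
        as.matrix(m[, -1, drop = FALSE])
      })
      colnames(mats[[1]]) <- colnames(mats[[2]]) <- chans
      if (nrow(mats[[1]]) < 2 || nrow(mats[[2]]) < 2) next
      topo_tests[[key]] <- topo_compare(
        mats[[1]], mats[[2]], adjacency = graph, n_perm = cfg$n_perm,
        alpha = cfg$alpha,
        seed = mix_seed(cfg$master_seed, 20000L + match(key, names(topo_acc))))
    }
    note("topography", "%d topographic comparisons", length(topo_tests))
  }

  stats_out <- list()
  if (!is.null(p300) && length(unique(p300$scheme)) >= 2) {
    for (dv in c("peak_amplitude", "peak_latency")) {
      stats_out[[paste0("p300_", dv)]] <-
        tryCatch(parametric_battery(p300, dv = dv), error = function(e) NULL)
    }
  }
  if (!is.null(rsp)) {
    for (b in unique(rsp$band)) {
      sub <- rsp[rsp$band == b & rsp$region == "whole-brain", ]
      if (nrow(sub) > 0 && length(unique(sub$scheme)) >= 2) {
        stats_out[[paste0("rsp_", b)]] <-
          tryCatch(parametric_battery(sub, dv = "rsp"),
                   error = function(e) NULL)
      }
    }
  }
  note("stats", "%d statistical tables", length(stats_out))

  structure(list(episode_counts = episode_counts, p300 = p300, rsp = rsp,
                 ersp = ersp_out, topo = topo_acc, topo_tests = topo_tests,
                 stats = stats_out,
                 rejections = n_rej, manifest = manifest, config = cfg,
                 log = log),
            class = "report_bundle")
}

#' Write a run's feature tables to CSV
#'
#' @param bundle A `report_bundle` from [run_synthetic_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_feature_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("p300", "rsp")) {
    if (is.null(bundle[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (length(bundle$topo) > 0) {
    topo_long <- do.call(rbind, lapply(names(bundle$topo), function(key) {
      df <- bundle$topo[[key]]
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      keys <- c("group", "subject_id", "arm", "union")
      chans <- setdiff(names(df), keys)
      long <- utils::stack(df[chans])
      names(long) <- c("value", "channel")
      cbind(df[rep(seq_len(nrow(df)), length(chans)), keys, drop = FALSE],
            scheme = parts[1], band = parts[2], long)
    }))
    p <- file.path(dir, "topo.csv")
    utils::write.csv(topo_long, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (length(bundle$topo_tests) > 0) {
    cl <- lapply(bundle$topo_tests, function(res) {
      lapply(res$clusters, function(c)
        list(channels = c$channels, mass = c$mass, p = c$p))
    })
    p <- file.path(dir, "topo_clusters.json")
    jsonlite::write_json(cl, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  cfg_path <- file.path(dir, "config.json")
  cfg <- bundle$config
  cfg$effects_fn <- NULL
  cfg$design <- unclass(cfg$design)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, cfg_path))
}
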