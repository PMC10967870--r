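#' Band-pass and notch filter a recording
#'
#' Applies a fourth-order Butterworth band-pass (1-100 Hz) followed by a
#' fourth-order Butterworth band-stop (49-51 Hz), both forward-backward
#' (zero-phase) so that component latencies are preserved; the effective
#' magnitude attenuation of each stage is therefore doubled relative to a
#' single pass.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band-pass edges in Hz.
#' @param notch Band-stop edges in Hz.
#' @param order Butterworth order of each stage.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_notch <- function(rec, low = 1, high = 100, notch = c(49, 51),
                           order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate <= 2 * high)
    stop("sampling rate ", rec$rate, " Hz too low for a ", high,
         " Hz band edge")
  nyq <- rec$rate / 2
  bp <- signal::butter(order, c(low, high) / nyq, type = "pass")
  bs <- signal::butter(order, notch / nyq, type = "stop")
  out <- rec
  for (i in seq_len(nrow(rec$samples))) {
    y <- signal::filtfilt(bp, rec$samples[i, ])
    out$samples[i, ] <- signal::filtfilt(bs, y)
  }
  out
}

#' Mirror the montage for left-lesion participants
#'
#' Swaps the data of every mirrored 10-10 label pair (C3/C4, FC1/FC2, ...)
#' when `lesioned_hemisphere` is `"left"`, so that the affected hemisphere
#' lies on the right side for all participants; midline (`z`) channels
#' and right-lesion or control data are untouched.
#'
#' @param x An `eeg_recording` or `eeg_epoch`.
#' @param lesioned_hemisphere `"left"`, `"right"`, or `NA` (controls).
#' @return Same type as `x`.
#' @export
flip_montage <- function(x, lesioned_hemisphere) {
  if (is.na(lesioned_hemisphere) || lesioned_hemisphere == "right") return(x)
  if (lesioned_hemisphere != "left")
    stop("lesioned_hemisphere must be 'left', 'right', or NA")
  labels <- rownames(x$samples)
  mirrored <- mirror_label(labels)
  lateral <- mirrored != labels
  missing <- setdiff(mirrored[lateral], labels)
  if (length(missing) > 0)
    stop("unpaired lateral channel(s): montage lacks ",
         paste(missing, collapse = ", "))
  perm <- match(mirrored, labels)
  x$samples <- x$samples[perm, , drop = FALSE]
  rownames(x$samples) <- labels
  x
}

#' Segment a recording into baseline + stimulation epochs
#'
#' One 15-s epoch per event marker: 5 s baseline `[-5, 0)` and 10 s
#' stimulation block `[0, 10)` (half-open; the onset sample belongs to the
#' stimulation span). Events with less than 5 s of history or 10 s of
#' future within the record are skipped with a warning and logged.
#'
#' @param rec An `eeg_recording` with event markers.
#' @param metadata Named list (or one-row data.frame) of trial metadata
#'   joined onto every epoch (subject, group, arm, union, ...); may be NULL.
#' @param baseline_s,block_s Baseline and stimulation span durations (s).
#' @return List of `eeg_epoch` objects; attribute `"skipped"` holds a
#'   data.frame of skipped events.
#' @export
segment_epochs <- function(rec, metadata = NULL, baseline_s = 5,
                           block_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$rate
  nb <- round(baseline_s * fs)
  nk <- round(block_s * fs)
  n <- ncol(rec$samples)
  epochs <- list()
  skipped <- data.frame(onset_sample = integer(0), label = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (is.data.frame(metadata)) metadata <- as.list(metadata[1, , drop = FALSE])
  for (e in seq_len(nrow(rec$events))) {
    on_s <- rec$events$onset_sample[e]
    if (on_s - nb < 1L || on_s + nk - 1L > n) {
      warning("event at sample ", on_s, " too close to the record edge; skipped")
      skipped <- rbind(skipped, data.frame(
        onset_sample = on_s, label = rec$events$label[e],
        reason = "record edge", stringsAsFactors = FALSE))
      next
    }
    idx <- (on_s - nb):(on_s + nk - 1L)
    md <- metadata %||% list()
    md$scheme <- md$scheme %||% rec$events$label[e]
    md$block <- length(epochs) + 1L
    md$onset_sample <- on_s
    epochs[[length(epochs) + 1L]] <- new_epoch(
      rec$samples[, idx, drop = FALSE], fs,
      baseline_s = baseline_s, block_s = block_s, metadata = md)
  }
  attr(epochs, "skipped") <- skipped
  epochs
}

#' Construct an epoch
#'
#' @param samples channels x time matrix spanning `[-baseline_s, block_s)`.
#' @param rate Sampling rate in Hz.
#' @param baseline_s,block_s Span durations in seconds.
#' @param metadata Named list of factorial metadata.
#' @return An `eeg_epoch`.
#' @export
new_epoch <- function(samples, rate, baseline_s = 5, block_s = 10,
                      metadata = list()) {
  stopifnot(is.matrix(samples))
  nexp <- round((baseline_s + block_s) * rate)
  if (ncol(samples) != nexp)
    stop("epoch must have ", nexp, " samples, got ", ncol(samples))
  time <- seq(-baseline_s, by = 1 / rate, length.out = nexp)
  structure(list(samples = samples, time = time, rate = rate,
                 baseline_s = baseline_s, block_s = block_s,
                 metadata = metadata),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels, [%g, %g) s @ %g Hz\n",
              nrow(x$samples), -x$baseline_s, x$block_s, x$rate))
  invisible(x)
}

# index helpers: half-open spans
baseline_idx <- function(epoch) which(epoch$time < 0)
block_idx <- function(epoch) which(epoch$time >= 0)

#' Threshold-based epoch rejection
#'
#' Deterministic stand-in for operator artifact screening: an epoch is
#' dropped iff any channel's peak-to-peak amplitude exceeds `ptp_threshold`
#' or any sample is non-finite. The rejection log records one reason per
#' dropped epoch.
#'
#' @param epochs List of `eeg_epoch`.
#' @param ptp_threshold Peak-to-peak threshold in microvolts.
#' @return List with `$kept` (epochs) and `$log` (data.frame of drops).
#' @export
reject_artifacts <- function(epochs, ptp_threshold = 200) {
  keep <- logical(length(epochs))
  log <- data.frame(epoch = integer(0), reason = character(0),
                    channel = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(epochs)) {
    s <- epochs[[i]]$samples
    if (!all(is.finite(s))) {
      bad <- rownames(s)[which(!apply(is.finite(s), 1, all))[1]]
      log <- rbind(log, data.frame(epoch = i, reason = "non-finite",
                                   channel = bad, stringsAsFactors = FALSE))
      next
    }
    ptp <- apply(s, 1, function(v) diff(range(v)))
    if (any(ptp > ptp_threshold)) {
      bad <- rownames(s)[which.max(ptp)]
      log <- rbind(log, data.frame(epoch = i, reason = "peak-to-peak",
                                   channel = bad %||% NA_character_,
                                   stringsAsFactors = FALSE))
      next
    }
    keep[i] <- TRUE
  }
  list(kept = epochs[keep], log = log)
}
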