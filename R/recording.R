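#' Construct a continuous EEG recording
#'
#' @param samples channels x time numeric matrix, in microvolts.
#' @param rate Sampling rate in Hz.
#' @param channel_labels Unique channel labels, one per row of `samples`.
#' @param events data.frame with `onset_sample` (1-based, strictly
#'   increasing, within the record) and `label`; may have zero rows.
#' @return An `eeg_recording` list.
#' @export
new_recording <- function(samples, rate, channel_labels,
                          events = data.frame(onset_sample = integer(0),
                                              label = character(0))) {
  stopifnot(is.matrix(samples), nrow(samples) == length(channel_labels),
            rate > 0)
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  if (nrow(events) > 0) {
    if (is.unsorted(events$onset_sample, strictly = TRUE))
      stop("event onsets must be strictly increasing")
    if (any(events$onset_sample < 1L) ||
        any(events$onset_sample > ncol(samples)))
      stop("event onset outside the record")
  }
  rownames(samples) <- channel_labels
  structure(list(samples = samples, rate = rate,
                 channel_labels = channel_labels, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$samples), ncol(x$samples), x$rate, nrow(x$events)))
  invisible(x)
}

#' Read a continuous recording from disk
#'
#' @param path Path to the header file (`.vhdr` for BrainVision, `.edf`
#'   for EDF+).
#' @param format `"brainvision"` or `"edf+"`; inferred from the file
#'   extension when missing.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "brainvision", "edf+")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     vhdr = "brainvision", edf = "edf+",
                     stop("cannot infer recording format from '", path, "'"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "brainvision" = read_brainvision(path),
         "edf+" = read_edf(path))
}

#' Write a continuous recording to disk
#'
#' BrainVision output is a `.vhdr`/`.vmrk`/`.eeg` triplet (IEEE float 32
#' by default, so the round trip is exact to single precision); EDF+
#' output is a single 16-bit `.edf` file with an annotation channel
#' carrying the event markers (round trip exact to the amplitude
#' quantization step).
#'
#' @param rec An `eeg_recording`.
#' @param path Output path without extension (BrainVision) or with `.edf`.
#' @param format `"brainvision"` or `"edf+"`.
#' @param binary_format BrainVision sample encoding, `"IEEE_FLOAT_32"` or
#'   `"INT_16"`.
#' @return Invisibly, the path of the written header file.
#' @export
write_recording <- function(rec, path, format = c("brainvision", "edf+"),
                            binary_format = c("IEEE_FLOAT_32", "INT_16")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  switch(format,
         "brainvision" = write_brainvision(rec, path, match.arg(binary_format)),
         "edf+" = write_edf(rec, path))
}
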