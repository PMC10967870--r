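#' Power spectral density per channel
#'
#' Two estimators: a Hann-tapered periodogram, zero-padded so the grid
#' resolution is at most 1 Hz (used for the short period of interest),
#' and Welch's method (Hann, 2-s segments, 50 % overlap, used for the 5-s
#' baseline). Densities are one-sided, in uV^2/Hz, and Parseval-
#' consistent: the grid integral approximates the signal variance.
#'
#' @param segment channels x time matrix (uV) or a numeric vector.
#' @param rate Sampling rate in Hz.
#' @param method `"periodogram"` or `"welch"`.
#' @param welch_seg_s Welch segment length in seconds.
#' @return List with `freq` (Hz) and `psd` (channels x freq matrix).
#' @export
compute_psd <- function(segment, rate, method = c("periodogram", "welch"),
                        welch_seg_s = 2) {
  method <- match.arg(method)
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  n <- ncol(segment)
  if (n < 0.25 * rate)
    stop("segment too short for spectral estimation (< 0.25 s)")
  if (method == "welch" && n >= 1.5 * welch_seg_s * rate) {
    seg_n <- round(welch_seg_s * rate)
    step <- seg_n %/% 2L
    starts <- seq(1L, n - seg_n + 1L, by = step)
    pieces <- lapply(starts, function(s)
      hann_periodogram(segment[, s:(s + seg_n - 1L), drop = FALSE], rate))
    psd <- Reduce(`+`, lapply(pieces, `[[`, "psd")) / length(pieces)
    return(list(freq = pieces[[1]]$freq, psd = psd))
  }
  hann_periodogram(segment, rate)
}

hann_periodogram <- function(segment, rate) {
  n <- ncol(segment)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))   # Hann taper
  nfft <- max(n, ceiling(rate))                         # grid <= 1 Hz
  nf <- nfft %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * rate / nfft
  psd <- matrix(0, nrow(segment), nf,
                dimnames = list(rownames(segment), NULL))
  denom <- rate * sum(w^2)
  for (i in seq_len(nrow(segment))) {
    x <- segment[i, ] * w
    X <- stats::fft(c(x, numeric(nfft - n)))[seq_len(nf)]
    p <- Mod(X)^2 / denom
    p[c(-1, -nf)] <- 2 * p[c(-1, -nf)]                  # one-sided
    psd[i, ] <- p
  }
  list(freq = freq, psd = psd)
}

# fraction of total 1-100 Hz power inside [f1, f2)
band_fraction <- function(freq, psd_row, f1, f2, total_range = c(1, 100)) {
  tot <- freq >= total_range[1] & freq < total_range[2]
  inb <- freq >= f1 & freq < f2
  denom <- sum(psd_row[tot])
  if (denom <= 0) stop("zero total power in the 1-100 Hz range")
  sum(psd_row[tot & inb]) / denom
}

#' Relative spectral power of an epoch
#'
#' For each channel, `RSP = (band fraction of the block-period spectrum)
#' - (band fraction of the baseline spectrum)`, fractions taken relative
#' to the total 1-100 Hz power. The block period defaults to the period
#' of interest 0.30-0.75 s after stimulation onset; the baseline spectrum
#' is estimated over the full 5-s baseline by Welch's method (set
#' `matched_baseline = TRUE` for a duration-matched baseline slice ending
#' at onset instead).
#'
#' @param epoch An `eeg_epoch`.
#' @param band Band name from [band_table()], or a numeric `c(f1, f2)`.
#' @param period Period of interest in seconds after onset.
#' @param matched_baseline Use a baseline slice of the same duration as
#'   `period` instead of the full baseline.
#' @return data.frame with `channel`, `band`, `rsp` (each value in
#'   `[-1, 1]`).
#' @export
compute_rsp <- function(epoch, band = band_table()$band,
                        period = c(0.30, 0.75), matched_baseline = FALSE) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (period[1] < 0 || period[2] > epoch$block_s)
    stop("period of interest must lie inside the stimulation span")
  sel_blk <- epoch$time >= period[1] & epoch$time < period[2]
  if (matched_baseline) {
    dur <- period[2] - period[1]
    sel_bas <- epoch$time >= -dur & epoch$time < 0
  } else {
    sel_bas <- epoch$time < 0
  }
  blk <- compute_psd(epoch$samples[, sel_blk, drop = FALSE], epoch$rate,
                     method = "periodogram")
  bas <- compute_psd(epoch$samples[, sel_bas, drop = FALSE], epoch$rate,
                     method = "welch")
  bands <- if (is.numeric(band)) {
    data.frame(band = sprintf("%g-%g", band[1], band[2]),
               f1 = band[1], f2 = band[2])
  } else {
    tb <- band_table()
    tb[match(band, tb$band), ]
  }
  out <- expand.grid(channel = rownames(epoch$samples), band = bands$band,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rsp <- NA_real_
  for (r in seq_len(nrow(out))) {
    bi <- match(out$band[r], bands$band)
    ci <- match(out$channel[r], rownames(epoch$samples))
    fb <- band_fraction(blk$freq, blk$psd[ci, ], bands$f1[bi], bands$f2[bi])
    fa <- band_fraction(bas$freq, bas$psd[ci, ], bands$f1[bi], bands$f2[bi])
    out$rsp[r] <- fb - fa
  }
  out
}

#' Aggregate relative spectral power over a channel region
#'
#' Unweighted mean over the region's channels, then over blocks when a
#' `block` column is present. The contralateral sensorimotor region is
#' resolved from the stimulated arm in the post-flip frame (left-arm
#' stimulation maps to the right-hemisphere sensorimotor set).
#'
#' @param values data.frame from [compute_rsp()] (optionally with a
#'   `block` column and several bands).
#' @param region `"whole-brain"` or `"contralateral-sensorimotor"`.
#' @param arm Stimulated arm (`"dominant"`/`"nondominant"`), required for
#'   the sensorimotor region.
#' @return data.frame with `band`, `region`, `rsp`.
#' @export
aggregate_rsp <- function(values, region = c("whole-brain",
                                             "contralateral-sensorimotor"),
                          arm = NULL) {
  region <- match.arg(region)
  chans <- unique(values$channel)
  if (region == "contralateral-sensorimotor") {
    if (is.null(arm)) stop("arm is required for the sensorimotor region")
    set <- sensorimotor_channels(contralateral_hemisphere(arm))
    set <- intersect(set, chans)
    if (length(set) == 0L)
      stop("contralateral sensorimotor set is empty for this montage")
    values <- values[values$channel %in% set, , drop = FALSE]
  }
  has_block <- "block" %in% names(values)
  out <- lapply(split(values, values$band), function(df) {
    m <- if (has_block) {
      mean(tapply(df$rsp, df$block, mean))   # channels first, then blocks
    } else mean(df$rsp)
    data.frame(band = df$band[1], region = region, rsp = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
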