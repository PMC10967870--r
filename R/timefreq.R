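#' Morlet wavelet time-frequency decomposition
#'
#' Complex Morlet power, default frequencies 2-100 Hz in 1-Hz steps with
#' `max(3, f/2)` cycles per wavelet. Kernels are normalized so that a
#' sinusoid of amplitude A at the wavelet's frequency yields power A^2/2
#' (uV^2). Bins whose wavelet support (3 temporal SDs) crosses the series
#' boundary are flagged as edge-contaminated.
#'
#' @param x Numeric vector, one channel's samples (uV).
#' @param rate Sampling rate in Hz (must exceed twice the top frequency).
#' @param freqs Analysis frequencies in Hz.
#' @param n_cycles Cycle rule, a function of frequency.
#' @param decim Keep every `decim`-th output sample.
#' @return List: `power` (freq x time, uV^2), `freq`, `sample_idx`
#'   (1-based indices into `x` of the kept time bins), `edge`
#'   (freq x time logical).
#' @export
compute_tfr <- function(x, rate, freqs = 2:100,
                        n_cycles = function(f) pmax(3, f / 2), decim = 1L) {
  stopifnot(is.numeric(x), length(x) > 0)
  if (rate <= 2 * max(freqs))
    stop("sampling rate ", rate, " Hz too low for ", max(freqs), " Hz")
  n <- length(x)
  keep <- seq(1L, n, by = as.integer(decim))
  nt <- length(keep)
  nf <- length(freqs)
  cyc <- n_cycles(freqs)
  power <- matrix(NA_real_, nf, nt)
  edge <- matrix(FALSE, nf, nt)
  nfft <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  for (k in seq_len(nf)) {
    f <- freqs[k]
    sigma_t <- cyc[k] / (2 * pi * f)
    half <- min(ceiling(3 * sigma_t * rate), n - 1L)
    tt <- (-half:half) / rate
    g <- exp(-tt^2 / (2 * sigma_t^2))
    kern <- g * exp(2i * pi * f * tt) * sqrt(2) / sum(g)
    K <- stats::fft(c(kern, complex(real = numeric(nfft - length(kern)))))
    conv <- stats::fft(X * K, inverse = TRUE) / nfft
    centered <- conv[(half + 1L):(half + n)]    # align kernel center
    p <- Mod(centered)^2
    power[k, ] <- p[keep]
    edge[k, ] <- keep <= half | keep > n - half
  }
  list(power = power, freq = freqs, sample_idx = keep, edge = edge)
}

#' Event-related spectral perturbation of one epoch channel
#'
#' Per frequency f, `ERSP(f, t) = (S(f, t) - mu_baseline(f)) /
#' sigma_baseline(f)` with mu and sigma the mean and SD of the
#' time-frequency power over the epoch's baseline time bins
#' (edge-contaminated bins excluded from the estimate).
#'
#' @param tfr Output of [compute_tfr()] computed on a full epoch channel.
#' @param time Time axis (s) of the *undecimated* epoch samples.
#' @param channel Channel label carried through for bookkeeping.
#' @param min_baseline_bins Minimum uncontaminated baseline bins per
#'   frequency.
#' @return An `ersp_map`: `values` (freq x time, z units), `freq`, `time`
#'   (decimated), `edge`, `channel`, `mask` (NULL until
#'   [baseline_permutation_mask()] is applied).
#' @export
compute_ersp <- function(tfr, time, channel = NA_character_,
                         min_baseline_bins = 10L) {
  tt <- time[tfr$sample_idx]
  bas <- tt < 0
  values <- matrix(NA_real_, nrow(tfr$power), ncol(tfr$power))
  for (k in seq_len(nrow(tfr$power))) {
    ok <- bas & !tfr$edge[k, ]
    if (sum(ok) < min_baseline_bins)
      stop("fewer than ", min_baseline_bins,
           " clean baseline bins at ", tfr$freq[k], " Hz")
    mu <- mean(tfr$power[k, ok])
    sg <- stats::sd(tfr$power[k, ok])
    if (sg == 0)
      stop("zero baseline variance at ", tfr$freq[k], " Hz")
    values[k, ] <- (tfr$power[k, ] - mu) / sg
  }
  structure(list(values = values, freq = tfr$freq, time = tt,
                 edge = tfr$edge, channel = channel, mask = NULL),
            class = "ersp_map")
}

#' Baseline-permutation significance mask for block-averaged ERSP
#'
#' The observed statistic per (f, t) bin is the mean ERSP across blocks.
#' The null is built per frequency by pooling the z-scored baseline time
#' bins of all blocks and drawing `n_perm` surrogate block-sized means;
#' the two-sided empirical p is `(b + 1) / (n_perm + 1)`, followed by
#' Benjamini-Hochberg FDR across all uncontaminated bins. The mask is
#' `TRUE` where the corrected p is at most `alpha`.
#'
#' @param ersps List of `ersp_map` objects (one per block, same grid).
#' @param n_perm Number of surrogate draws.
#' @param alpha FDR level.
#' @param seed Optional RNG seed.
#' @return An `ersp_map` holding the block-mean `values`, plus `mask`
#'   (logical) and `p` (BH-adjusted p values; NA at edge bins).
#' @export
baseline_permutation_mask <- function(ersps, n_perm = 2000, alpha = 0.05,
                                      seed = NULL) {
  if (length(ersps) < 2L)
    stop("need at least 2 blocks for the baseline permutation")
  if (n_perm < 10) stop("n_perm < 10 is not a usable permutation count")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse empirical p")
  if (!is.null(seed)) set.seed(seed)
  tmpl <- ersps[[1]]
  nb <- length(ersps)
  nf <- nrow(tmpl$values); nt <- ncol(tmpl$values)
  obs <- Reduce(`+`, lapply(ersps, `[[`, "values")) / nb
  edge_any <- Reduce(`|`, lapply(ersps, `[[`, "edge"))
  bas <- tmpl$time < 0
  p <- matrix(NA_real_, nf, nt)
  for (k in seq_len(nf)) {
    pool <- unlist(lapply(ersps, function(e) {
      ok <- bas & !e$edge[k, ]
      e$values[k, ok]
    }))
    draws <- matrix(sample(pool, n_perm * nb, replace = TRUE), n_perm, nb)
    null_means <- abs(rowMeans(draws))
    valid <- which(!edge_any[k, ])
    for (j in valid) {
      b <- sum(null_means >= abs(obs[k, j]))
      p[k, j] <- (b + 1) / (n_perm + 1)
    }
  }
  ok <- !is.na(p)
  p_adj <- p
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  mask <- !is.na(p_adj) & p_adj <= alpha
  out <- tmpl
  out$values <- obs
  out$edge <- edge_any
  out$mask <- mask
  out$p <- p_adj
  out
}

#' ERD/ERS summary of an ERSP map
#'
#' The per-channel ERD/ERS value is the plain mean of ERSP over the band
#' F times latency-window T rectangle: `(1/K) * sum_{f in F} sum_{t in T}
#' ERSP(f, t)` with K the number of bins in the window. With
#' `stat = "peak"` the signed extremum (largest absolute value) over the
#' window is returned instead of the mean.
#'
#' @param ersp An `ersp_map`.
#' @param band Band name or numeric `c(f1, f2)` (half-open).
#' @param window Latency window `c(t1, t2)` in seconds (default the full
#'   stimulation block).
#' @param stat `"mean"` or `"peak"`.
#' @return List with `value` (z units), `K`, `band`, `window`.
#' @export
compute_erd_ers <- function(ersp, band, window = c(0, 10),
                            stat = c("mean", "peak")) {
  stat <- match.arg(stat)
  stopifnot(inherits(ersp, "ersp_map"))
  fr <- if (is.numeric(band)) band else band_edges(band)
  fi <- which(ersp$freq >= fr[1] & ersp$freq < fr[2])
  ti <- which(ersp$time >= window[1] & ersp$time < window[2])
  if (length(fi) == 0L || length(ti) == 0L)
    stop("empty frequency x time window for ERD/ERS")
  vals <- ersp$values[fi, ti, drop = FALSE]
  K <- length(vals)
  value <- if (stat == "mean") sum(vals) / K else vals[which.max(abs(vals))]
  list(value = value, K = K,
       band = if (is.numeric(band)) sprintf("%g-%g", fr[1], fr[2]) else band,
       window = window, stat = stat)
}

#' ERSP map of one epoch channel
#'
#' Convenience wrapper: Morlet decomposition of a single epoch channel
#' followed by baseline z-normalization.
#'
#' @param epoch An `eeg_epoch`.
#' @param channel Channel label.
#' @param freqs Analysis frequencies (Hz).
#' @param decim Temporal decimation factor.
#' @return An `ersp_map`.
#' @export
ersp_for_epoch <- function(epoch, channel, freqs = 2:100, decim = 10L) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  ci <- match(channel, rownames(epoch$samples))
  if (is.na(ci)) stop("channel not in epoch: ", channel)
  tfr <- compute_tfr(epoch$samples[ci, ], epoch$rate, freqs = freqs,
                     decim = decim)
  compute_ersp(tfr, epoch$time, channel = channel)
}
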