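#' Baseline-corrected event-related potential
#'
#' Per channel, `ERP(t) = p_block(t) - mean(p_baseline)`: the stimulation-
#' span waveform minus the channel's mean over the 5-s pre-stimulus
#' baseline. The result covers the stimulation span only.
#'
#' @param epoch An `eeg_epoch` with a nonempty baseline span.
#' @return An `erp_waveform`: `$values` (channels x time, uV), `$time`
#'   (s, stimulation span), `$metadata`.
#' @export
compute_erp <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  bi <- baseline_idx(epoch)
  if (length(bi) == 0L) stop("epoch has a zero-length baseline span")
  ki <- block_idx(epoch)
  base_mean <- rowMeans(epoch$samples[, bi, drop = FALSE])
  values <- epoch$samples[, ki, drop = FALSE] - base_mean
  structure(list(values = values, time = epoch$time[ki], rate = epoch$rate,
                 metadata = epoch$metadata),
            class = "erp_waveform")
}

#' Midline P300 waveform
#'
#' Unweighted average of the Fz, Cz and Pz ERP channels.
#'
#' @param erp An `erp_waveform` containing Fz, Cz, Pz.
#' @return An `erp_waveform` with a single row labelled `"P300"`.
#' @export
midline_p300 <- function(erp) {
  stopifnot(inherits(erp, "erp_waveform"))
  need <- c("Fz", "Cz", "Pz")
  missing <- setdiff(need, rownames(erp$values))
  if (length(missing) > 0)
    stop("missing midline channel(s): ", paste(missing, collapse = ", "))
  v <- colMeans(erp$values[need, , drop = FALSE])
  out <- erp
  out$values <- matrix(v, nrow = 1, dimnames = list("P300", NULL))
  out
}

#' P300 peak amplitude and latency
#'
#' The peak is the maximum of the waveform inside the search window
#' (default 0.25-0.80 s after stimulation onset, the conventional P300
#' onset range); latency is the time of that maximum, ties broken by the
#' earliest time.
#'
#' @param p300 A single-channel `erp_waveform` (see [midline_p300()]).
#' @param window Search window in seconds, `c(lo, hi)`.
#' @return List with `peak_amplitude` (uV) and `peak_latency` (s).
#' @export
extract_p300 <- function(p300, window = c(0.25, 0.80)) {
  stopifnot(inherits(p300, "erp_waveform"), nrow(p300$values) == 1L)
  sel <- which(p300$time >= window[1] & p300$time <= window[2])
  if (length(sel) == 0L) stop("P300 search window is empty after clipping")
  v <- p300$values[1, sel]
  i <- which.max(v)                       # which.max returns the first max
  list(peak_amplitude = unname(v[i]), peak_latency = unname(p300$time[sel][i]))
}

#' Average ERP waveforms
#'
#' Pointwise mean across waveforms sharing a time axis (e.g. the six
#' blocks of a trial, averaged before peak extraction).
#'
#' @param erps List of `erp_waveform` with identical shapes.
#' @return An `erp_waveform`.
#' @export
average_erps <- function(erps) {
  stopifnot(length(erps) >= 1L)
  tmpl <- erps[[1]]
  for (e in erps[-1]) {
    if (!isTRUE(all.equal(e$time, tmpl$time)))
      stop("ERP waveforms have mismatched time axes")
  }
  vals <- Reduce(`+`, lapply(erps, `[[`, "values")) / length(erps)
  tmpl$values <- vals
  tmpl
}

#' Cluster-based permutation comparison of ERP amplitudes over time
#'
#' Delegates to [cluster_permutation()] over the 1-D time dimension and
#' reports significant time spans.
#'
#' @param erps_a,erps_b Lists of single-channel `erp_waveform` objects
#'   (one per subject/observation).
#' @param paired Paired observations across conditions?
#' @param n_perm,cluster_alpha,alpha,seed See [cluster_permutation()].
#' @return data.frame with `start_s`, `end_s`, `mass`, `p` for every
#'   cluster (possibly zero rows); attribute `"result"` holds the full
#'   `cluster_test_result`.
#' @export
erp_cluster_compare <- function(erps_a, erps_b, paired = FALSE,
                                n_perm = 2000, cluster_alpha = 0.05,
                                alpha = 0.05, seed = NULL) {
  stopifnot(length(erps_a) >= 2L, length(erps_b) >= 2L)
  tax <- erps_a[[1]]$time
  for (e in c(erps_a, erps_b)) {
    if (!isTRUE(all.equal(e$time, tax)))
      stop("ERP waveforms have mismatched time axes")
    if (nrow(e$values) != 1L)
      stop("erp_cluster_compare expects single-channel waveforms")
  }
  A <- do.call(rbind, lapply(erps_a, function(e) e$values[1, ]))
  B <- do.call(rbind, lapply(erps_b, function(e) e$values[1, ]))
  res <- cluster_permutation(A, B, dimension = "time", paired = paired,
                             n_perm = n_perm, cluster_alpha = cluster_alpha,
                             alpha = alpha, seed = seed)
  spans <- do.call(rbind, lapply(res$clusters, function(cl) {
    data.frame(start_s = tax[min(cl$members)], end_s = tax[max(cl$members)],
               mass = cl$mass, p = cl$p, significant = cl$p <= alpha)
  })) %||% data.frame(start_s = numeric(0), end_s = numeric(0),
                      mass = numeric(0), p = numeric(0),
                      significant = logical(0))
  attr(spans, "result") <- res
  spans
}
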