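#' EEG frequency band table
#'
#' Band edges follow the conventional clinical definitions used throughout
#' the pipeline: theta 4-8 Hz, alpha 8-12 Hz, beta 13-30 Hz, gamma
#' 30-100 Hz. Intervals are half-open `[f1, f2)`; the 12-13 Hz gap between
#' alpha and beta is intentional. All bands lie inside the 1-100 Hz
#' analysis range of the band-pass filter.
#'
#' @return A data.frame with columns `band`, `f1`, `f2`.
#' @export
band_table <- function() {
  out <- data.frame(
    band = c("theta", "alpha", "beta", "gamma"),
    f1 = c(4, 8, 13, 30),
    f2 = c(8, 12, 30, 100),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$f1 < out$f2), all(out$f1 >= 1), all(out$f2 <= 100))
  out
}

band_edges <- function(band) {
  tb <- band_table()
  i <- match(band, tb$band)
  if (is.na(i)) stop("unknown band: ", band)
  c(tb$f1[i], tb$f2[i])
}
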