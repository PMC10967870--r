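# Minimal EDF+C writer/reader: 16-bit signals in 1-s data records plus an
# "EDF Annotations" channel carrying the event markers as time-stamped
# annotation lists (TALs). Physical range is set per channel from the
# data, so the round-trip error is bounded by one quantization step,
# (physmax - physmin) / 65535.

# format a number into at most 8 ASCII chars without losing the value's
# leading digits (required for the physical min/max header fields)
edf_num8 <- function(v) {
  for (d in 6:1) {
    s <- formatC(v, digits = d, format = "g", width = 0)
    if (nchar(s) <= 8) return(s)
  }
  substr(formatC(v, format = "g"), 1, 8)
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)               # left-justified, space-padded
}

write_edf <- function(rec, path) {
  if (!grepl("\\.edf$", path)) path <- paste0(path, ".edf")
  fs <- rec$rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF+ writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(rec$samples)
  n <- ncol(rec$samples)
  nrec <- ceiling(n / fs)
  npad <- nrec * fs - n
  x <- rec$samples
  if (npad > 0) x <- cbind(x, matrix(0, nch, npad))

  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  same <- pmax - pmin < 1e-12
  pmax[same] <- pmin[same] + 1
  # widen slightly, then snap to the 8-char header representation so the
  # quantization uses exactly the bounds a reader will parse back
  span <- pmax - pmin
  pmin <- vapply(pmin - 1e-3 * span, function(v) as.numeric(edf_num8(v)),
                 numeric(1))
  pmax <- vapply(pmax + 1e-3 * span, function(v) as.numeric(edf_num8(v)),
                 numeric(1))
  dmin <- -32768; dmax <- 32767
  dig <- round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  storage.mode(dig) <- "integer"

  anno_samples <- 64L                      # 128 bytes per record for TALs
  ns <- nch + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeBin(charToRaw(edf_pad(s, width)), con)

  wr("0", 8)                               # version
  wr("X X X X", 80)                        # patient id (EDF+ anonymous)
  wr("Startdate 01-JAN-2025 X X X", 80)    # recording id
  wr("01.01.25", 8)
  wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8)    # header bytes
  wr("EDF+C", 44)
  wr(as.character(nrec), 8)
  wr("1", 8)                               # record duration, s
  wr(as.character(ns), 4)

  labs <- c(rec$channel_labels, "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                         # transducer
  for (i in seq_len(ns)) wr(if (i <= nch) "uV" else "", 8)  # dimension
  for (i in seq_len(ns)) wr(if (i <= nch) edf_num8(pmin[i]) else "-1", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) edf_num8(pmax[i]) else "1", 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)                         # prefilter
  for (i in seq_len(ns)) wr(as.character(if (i <= nch) fs else anno_samples), 8)
  for (i in seq_len(ns)) wr("", 32)                         # reserved

  ev_onsets <- (rec$events$onset_sample - 1L) / fs
  ev_labels <- rec$events$label
  for (r in seq_len(nrec)) {
    t0 <- r - 1L
    idx <- (t0 * fs + 1L):(t0 * fs + fs)
    # each signal's samples are contiguous within a record
    for (i in seq_len(nch))
      writeBin(dig[i, idx], con, size = 2, endian = "little")
    pieces <- paste0("+", t0, "\x14\x14")  # record timestamp TAL
    in_rec <- which(ev_onsets >= t0 & ev_onsets < t0 + 1)
    for (j in in_rec) {
      pieces <- c(pieces, paste0(sprintf("+%.7g", ev_onsets[j]),
                                 "\x14", ev_labels[j], "\x14"))
    }
    # TALs are separated by nul bytes, which R strings cannot hold
    raw_tal <- do.call(c, lapply(pieces, function(p) c(charToRaw(p), as.raw(0))))
    raw_tal <- raw_tal[-length(raw_tal)]
    if (length(raw_tal) > 2L * anno_samples)
      stop("too many events in one EDF record for the annotation buffer")
    writeBin(c(raw_tal, raw(2L * anno_samples - length(raw_tal))), con)
  }
  invisible(path)
}

read_edf <- function(path) {
  fsz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(rawToChar(readBin(con, "raw", width)))

  version <- rd(8)
  if (version != "0") stop("malformed EDF header in ", path)
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path)

  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  anno_idx <- which(labels == "EDF Annotations")
  sig_idx <- setdiff(seq_len(ns), anno_idx)
  nch <- length(sig_idx)
  rec_bytes <- sum(spr) * 2L
  expected <- hdr_bytes + as.double(nrec) * rec_bytes
  if (!is.na(fsz) && fsz < expected)
    stop("truncated EDF file '", path, "': expected ", expected,
         " bytes, found ", fsz, " (ends at byte offset ", fsz, ")")

  fs <- spr[sig_idx[1]] / rec_dur
  chunks <- vector("list", nrec)
  tal_raw <- vector("list", nrec)
  for (r in seq_len(nrec)) {
    recmat <- matrix(NA_real_, nch, spr[sig_idx[1]])
    k <- 0L
    for (i in seq_len(ns)) {
      if (i %in% anno_idx) {
        tal_raw[[r]] <- readBin(con, "raw", spr[i] * 2L)
      } else {
        k <- k + 1L
        d <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
        recmat[k, ] <- (d - dmin[i]) / (dmax[i] - dmin[i]) *
          (pmax[i] - pmin[i]) + pmin[i]
      }
    }
    chunks[[r]] <- recmat
  }
  samples <- do.call(cbind, chunks)
  rownames(samples) <- labels[sig_idx]

  onsets <- numeric(0); evlab <- character(0)
  for (r in seq_len(nrec)) {
    if (is.null(tal_raw[[r]])) next
    txt <- rawToChar(tal_raw[[r]][tal_raw[[r]] != as.raw(0)])
    tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
    # events live after the record-timestamp TAL, separated by \x14
    for (tal in tals[-1]) {
      parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      parts <- parts[nzchar(parts)]
      j <- 1L
      while (j + 1L <= length(parts)) {     # (onset, label) pairs
        if (grepl("^[+-][0-9.]+$", parts[j])) {
          onsets <- c(onsets, as.numeric(parts[j]))
          evlab <- c(evlab, parts[j + 1L])
        }
        j <- j + 2L
      }
    }
  }
  events <- data.frame(onset_sample = as.integer(round(onsets * fs)) + 1L,
                       label = evlab, stringsAsFactors = FALSE)
  if (nrow(events) > 0) {
    events <- events[order(events$onset_sample), , drop = FALSE]
    rownames(events) <- NULL
  }
  new_recording(samples, fs, labels[sig_idx], events)
}
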