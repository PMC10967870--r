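# BrainVision .vhdr/.vmrk/.eeg triplet, multiplexed binary layout.
# Samples are stored either as IEEE float 32 (lossless for single
# precision) or as INT_16 with a per-file resolution in uV per LSB.

write_brainvision <- function(rec, path, binary_format = "IEEE_FLOAT_32") {
  path <- sub("\\.vhdr$", "", path)
  base <- basename(path)
  vhdr <- paste0(path, ".vhdr")
  vmrk <- paste0(path, ".vmrk")
  eeg <- paste0(path, ".eeg")
  nch <- nrow(rec$samples)

  resolution <- 1
  if (binary_format == "INT_16") {
    m <- max(abs(rec$samples))
    resolution <- if (m > 0) m / 32000 else 1
  }

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$rate, scientific = FALSE)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(nch), rec$channel_labels,
            format(resolution, scientific = FALSE))
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  if (nrow(rec$events) > 0) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$events)) + 1L,
                        rec$events$label, rec$events$onset_sample))
  }
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  flat <- as.vector(rec$samples)           # multiplexed: channels fastest
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(flat, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(flat / resolution)), con, size = 2,
             endian = "little")
  }
  invisible(vhdr)
}

parse_bv_ini <- function(lines) {
  sect <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sect <- gsub("\\[|\\]", "", ln)
      out[[sect]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && sect != "") {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[sect]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE, encoding = "UTF-8")
  ini <- parse_bv_ini(lines)
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (is.null(ci) || is.null(ci$NumberOfChannels))
    stop("malformed BrainVision header: ", vhdr_path)
  if (!identical(ci$DataOrientation %||% "MULTIPLEXED", "MULTIPLEXED"))
    stop("only MULTIPLEXED BrainVision data is supported")
  nch <- as.integer(ci$NumberOfChannels)
  rate <- 1e6 / as.numeric(ci$SamplingInterval)
  fmt <- bi$BinaryFormat %||% "IEEE_FLOAT_32"

  chinfo <- ini[["Channel Infos"]]
  labels <- character(nch)
  resolution <- rep(1, nch)
  for (k in seq_len(nch)) {
    entry <- chinfo[[paste0("Ch", k)]]
    if (is.null(entry)) stop("missing Ch", k, " in BrainVision header")
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      resolution[k] <- as.numeric(parts[3])
  }

  dirn <- dirname(vhdr_path)
  eeg_path <- file.path(dirn, ci$DataFile)
  bytes_per <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  fsz <- file.info(eeg_path)$size
  frame <- bytes_per * nch
  if (is.na(fsz)) stop("missing data file: ", eeg_path)
  if (fsz %% frame != 0)
    stop("truncated BrainVision binary '", eeg_path, "': file ends at byte ",
         fsz, ", mid-frame (frame size ", frame, " bytes, ",
         fsz %% frame, " trailing bytes)")
  n <- fsz %/% frame
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  flat <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = n * nch, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = n * nch, size = 2, endian = "little")
  }
  samples <- matrix(flat, nrow = nch)
  samples <- samples * resolution
  rownames(samples) <- labels

  events <- data.frame(onset_sample = integer(0), label = character(0),
                       stringsAsFactors = FALSE)
  vmrk_path <- if (!is.null(ci$MarkerFile)) file.path(dirn, ci$MarkerFile) else ""
  if (nzchar(vmrk_path) && file.exists(vmrk_path)) {
    mki <- parse_bv_ini(readLines(vmrk_path, warn = FALSE, encoding = "UTF-8"))
    mk <- mki[["Marker Infos"]]
    if (!is.null(mk)) {
      rows <- lapply(mk, function(entry) {
        parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
        if (parts[1] != "Stimulus") return(NULL)
        data.frame(onset_sample = as.integer(parts[3]), label = parts[2],
                   stringsAsFactors = FALSE)
      })
      rows <- Filter(Negate(is.null), rows)
      if (length(rows) > 0) {
        events <- do.call(rbind, rows)
        events <- events[order(events$onset_sample), , drop = FALSE]
        rownames(events) <- NULL
      }
    }
  }
  new_recording(samples, rate, labels, events)
}
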