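#' Default 62-channel 10-10 montage
#'
#' The analysis montage is a standard 10-10 cap with the reference (FCz)
#' excluded, leaving 62 analyzed channels including the midline Fz/Cz/Pz
#' and the sensorimotor C3/C4.
#' Coordinates are 2-D projected scalp positions on a regular row/column
#' grid (front of the head at positive y, left hemisphere at negative x),
#' sufficient for mirror-pair lookup and spatial adjacency.
#'
#' @return A data.frame with columns `label`, `x`, `y`.
#' @export
montage_1010 <- function() {
  rows <- list(
    Fp = list(y = 4, labels = c("Fp1", "Fpz", "Fp2"),    x = c(-1, 0, 1)),
    AF = list(y = 3, labels = c("AF7", "AF3", "AFz", "AF4", "AF8"),
              x = c(-4, -2, 0, 2, 4)),
    F  = list(y = 2, labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
              x = -4:4),
    FC = list(y = 1, labels = c("FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8"),
              x = c(-4, -3, -2, -1, 1, 2, 3, 4)),
    FT = list(y = 0.5, labels = c("FT9", "FT10"), x = c(-5, 5)),
    C  = list(y = 0, labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
              x = -4:4),
    CP = list(y = -1, labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
              x = -4:4),
    P  = list(y = -2, labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
              x = -4:4),
    PO = list(y = -3, labels = c("PO7", "PO3", "POz", "PO4", "PO8"),
              x = c(-4, -2, 0, 2, 4)),
    O  = list(y = -4, labels = c("O1", "Oz", "O2"), x = c(-2, 0, 2))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(label = r$labels, x = r$x * 0.2, y = r$y * 0.2,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  stopifnot(nrow(out) == 62L, !anyDuplicated(out$label))
  out
}

#' Mirror a channel label across the mid-sagittal plane
#'
#' Odd-numbered 10-10 labels (left hemisphere) map to the matching even
#' label (right hemisphere) and vice versa; midline labels ending in `z`
#' map to themselves.
#'
#' @param labels Character vector of 10-10 channel labels.
#' @return Character vector of mirrored labels.
#' @export
mirror_label <- function(labels) {
  vapply(labels, function(lab) {
    m <- regmatches(lab, regexpr("[0-9]+$", lab))
    if (length(m) == 0L) {
      if (!grepl("z$", lab)) stop("label '", lab, "' has no digit and no 'z' suffix")
      return(lab)
    }
    n <- as.integer(m)
    stem <- sub("[0-9]+$", "", lab)
    paste0(stem, if (n %% 2L == 1L) n + 1L else n - 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Left and right sensorimotor channel sets
#'
#' Default sensorimotor region used for the contralateral relative spectral
#' power aggregate and for the injected ERD support in the generator.
#'
#' @param side `"left"` or `"right"`.
#' @return Character vector of 9 channel labels.
#' @export
sensorimotor_channels <- function(side = c("left", "right")) {
  side <- match.arg(side)
  left <- c("FC5", "FC3", "FC1", "C5", "C3", "C1", "CP5", "CP3", "CP1")
  if (side == "left") left else mirror_label(left)
}

#' Hemisphere contralateral to a stimulated arm
#'
#' The generator and the region aggregation assume the dominant arm is the
#' right arm, so dominant-arm stimulation drives the left hemisphere.
#'
#' @param arm `"dominant"` or `"nondominant"`.
#' @return `"left"` or `"right"`.
#' @export
contralateral_hemisphere <- function(arm = c("dominant", "nondominant")) {
  arm <- match.arg(arm)
  if (arm == "dominant") "left" else "right"
}

#' Build a channel neighborhood graph from 2-D montage coordinates
#'
#' Neighbors are channels closer than `radius_factor` times the montage's
#' median nearest-neighbour distance. The rule is deterministic and
#' montage-agnostic; the resulting graph is symmetric with no self-loops,
#' both asserted before returning.
#'
#' @param montage data.frame with `label`, `x`, `y` (default [montage_1010()]).
#' @param radius_factor Multiplier on the median nearest-neighbour distance.
#' @return Named list: for each channel, the character vector of its neighbors.
#' @export
neighbor_graph <- function(montage = montage_1010(), radius_factor = 1.5) {
  stopifnot(nrow(montage) >= 1L, !anyDuplicated(montage$label))
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  dimnames(d) <- list(montage$label, montage$label)
  if (nrow(montage) == 1L) {
    g <- stats::setNames(list(character(0)), montage$label)
    return(structure(g, class = "neighbor_graph"))
  }
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  radius <- radius_factor * stats::median(nn)
  g <- lapply(seq_len(nrow(d)), function(i) colnames(d)[d[i, ] <= radius])
  names(g) <- montage$label
  # invariants: symmetric, no self-neighbors
  for (ch in names(g)) {
    stopifnot(!(ch %in% g[[ch]]))
    for (nb in g[[ch]]) stopifnot(ch %in% g[[nb]])
  }
  structure(g, class = "neighbor_graph")
}
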