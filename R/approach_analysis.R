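# Approach events: a pair's distance dropping below the personal-space
# threshold, and the approaching angle sampled in look-back windows.

#' Detect approach-event onsets
#'
#' An onset is a downward crossing of the distance threshold: the first frame
#' at which `d < threshold` with `d >= threshold` at the previous frame. A
#' pair already below the threshold at the start of the session produces no
#' onset (nothing was crossed); successive crossings are separate events.
#'
#' @param distances a `pair_series` of kind `"distance"`.
#' @param threshold onset distance in cm (50 cm, the personal-space distance
#'   at which touch is possible).
#' @return data frame `i, j, onset_frame`, one row per crossing per unordered
#'   pair. Both members are later evaluated as candidate approachers.
#' @export
detect_events <- function(distances, threshold = 50) {
  stopifnot(inherits(distances, "pair_series"), distances$kind == "distance")
  N <- length(distances$ids)
  out <- list()
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      d <- distances$values[, i, j]
      cross <- which(d[-1] < threshold & d[-length(d)] >= threshold) + 1L
      if (length(cross)) {
        out[[length(out) + 1L]] <- data.frame(
          i = distances$ids[i], j = distances$ids[j], onset_frame = cross)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(i = character(), j = character(),
                      onset_frame = integer()))
  }
  do.call(rbind, out)
}

#' Sample approaching angles in a look-back window before each onset
#'
#' For each onset and each directed reading of its pair (i approaching j and
#' j approaching i), the heading angle of the candidate approacher toward the
#' other is sampled at every frame of the look-back window in which the pair
#' distance lies inside the band. Windows are half-open: "0 to 1 s before"
#' covers frames in `[t0 - 1 s, t0)`, excluding the onset frame itself. The
#' band gate (distance in `[100, 200)` cm by default) keeps only frames where
#' the candidate genuinely closed in from outside near range, which is what
#' makes the sampling directional. Windows that would precede the start of
#' the session are truncated.
#'
#' @param events data frame from [detect_events()].
#' @param angles a `pair_series` of kind `"angle"`.
#' @param distances the matching `pair_series` of kind `"distance"`.
#' @param window numeric `c(lo, hi)` seconds before onset, e.g. `c(0, 1)`,
#'   `c(1, 2)`, `c(2, 3)`.
#' @param band numeric `c(lo, hi)` cm; samples require `lo <= d < hi`.
#' @return data frame `approacher, target, onset_frame, frame, distance,
#'   theta` with one row per retained sample.
#' @export
approach_angles <- function(events, angles, distances,
                            window = c(0, 1), band = c(100, 200)) {
  stopifnot(inherits(angles, "pair_series"), angles$kind == "angle",
            inherits(distances, "pair_series"), distances$kind == "distance")
  dt <- angles$frame_interval
  k_lo <- round(window[1] / dt)
  k_hi <- round(window[2] / dt)
  T <- dim(angles$values)[1]
  out <- list()
  if (nrow(events)) {
    for (r in seq_len(nrow(events))) {
      t0 <- events$onset_frame[r]
      frames <- seq.int(max(1L, t0 - k_hi), t0 - k_lo - 1L)
      frames <- frames[frames >= 1L & frames <= T]
      if (length(frames) == 0L) next
      for (dir in 1:2) {
        a <- if (dir == 1) events$i[r] else events$j[r]
        b <- if (dir == 1) events$j[r] else events$i[r]
        d <- distances$values[frames, a, b]
        th <- angles$values[frames, a, b]
        keep <- !is.na(d) & d >= band[1] & d < band[2] & !is.na(th)
        if (any(keep)) {
          out[[length(out) + 1L]] <- data.frame(
            approacher = a, target = b, onset_frame = t0,
            frame = frames[keep], distance = d[keep], theta = th[keep])
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(approacher = character(), target = character(),
                      onset_frame = integer(), frame = integer(),
                      distance = numeric(), theta = numeric()))
  }
  do.call(rbind, out)
}

#' Directed-pair approach matrix
#'
#' For each directed pair (row approacher, column target), the fraction of the
#' approacher's approaching-angle samples that land both on that target and in
#' the selected angle bin. Rows are normalized by the approacher's total
#' sample count over all targets; an approacher with no samples has an
#' all-zero row. The diagonal is zero by construction.
#'
#' @param samples data frame from [approach_angles()] (typically the 0-1 s
#'   window).
#' @param ids individual identifiers fixing the matrix order.
#' @param bin numeric `c(lo, hi]` degrees; the default `(10, 20]` is the
#'   "20 degree" bin of the 10-degree-wide family.
#' @return an `ids` x `ids` matrix of normalized frequencies.
#' @export
approach_matrix <- function(samples, ids, bin = c(10, 20)) {
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(samples) == 0L) return(M)
  totals <- table(factor(samples$approacher, levels = ids))
  inbin <- samples$theta > bin[1] & samples$theta <= bin[2]
  if (bin[1] == 0) inbin <- inbin | samples$theta == 0  # first bin closed at 0
  hits <- samples[inbin, , drop = FALSE]
  if (nrow(hits)) {
    tab <- table(factor(hits$approacher, levels = ids),
                 factor(hits$target, levels = ids))
    denom <- as.numeric(totals)
    denom[denom == 0] <- 1
    M <- sweep(unclass(tab), 1, denom, "/")
    dimnames(M) <- list(ids, ids)
  }
  diag(M) <- 0
  M
}

#' Per-individual approaching-angle samples
#'
#' Convenience split of [approach_angles()] output into each approacher's
#' sample vector, the unit used by the histogram comparison. Individuals with
#' no samples get a zero-length vector (excluded downstream).
#'
#' @param samples data frame from [approach_angles()].
#' @param ids individual identifiers.
#' @return named list of numeric vectors of angles (degrees).
#' @export
approach_samples_by_child <- function(samples, ids) {
  out <- lapply(ids, function(id) samples$theta[samples$approacher == id])
  names(out) <- ids
  out
}
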