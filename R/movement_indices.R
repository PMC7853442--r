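# Movement indices: pairwise distance, heading angle toward a partner, and
# per-individual angular momentum about the static group centre.

#' Pairwise distance series
#'
#' Euclidean distance (cm) between every pair of individuals at every frame.
#'
#' @param traj a `trajectory_set`.
#' @return an object of class `pair_series` with `kind = "distance"`:
#'   `values` is a `[frame, i, j]` array, symmetric in `i`/`j`, `NA` on the
#'   diagonal.
#' @export
pair_distance <- function(traj) {
  p <- traj$pos
  T <- dim(p)[1]; N <- dim(p)[2]; ids <- traj$ids
  vals <- array(NA_real_, c(T, N, N), dimnames = list(NULL, ids, ids))
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      d <- sqrt((p[, i, 1] - p[, j, 1])^2 + (p[, i, 2] - p[, j, 2])^2)
      vals[, i, j] <- d
      vals[, j, i] <- d
    }
  }
  structure(list(kind = "distance", values = vals, ids = ids, time = traj$time,
                 frame_interval = traj$frame_interval),
            class = "pair_series")
}

#' Heading-angle series toward each partner
#'
#' For the ordered pair (i, j), the angle (degrees, in `[0, 180]`) between
#' individual i's velocity vector and the displacement vector from i to j at
#' the same frame. 0 degrees means i is moving straight at j. Frames where
#' either vector has zero length (or velocity is undefined) are `NA`.
#'
#' @param traj a `trajectory_set` with velocities (see [compute_velocity()]).
#' @return a `pair_series` with `kind = "angle"`; `values[t, i, j]` is the
#'   angle of i's motion relative to j (not symmetric).
#' @export
pair_angle <- function(traj) {
  if (is.null(traj$vel)) stop("velocities not computed; call compute_velocity()")
  p <- traj$pos; v <- traj$vel
  T <- dim(p)[1]; N <- dim(p)[2]; ids <- traj$ids
  vals <- array(NA_real_, c(T, N, N), dimnames = list(NULL, ids, ids))
  speed <- sqrt(v[, , 1]^2 + v[, , 2]^2)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      dx <- p[, j, 1] - p[, i, 1]
      dy <- p[, j, 2] - p[, i, 2]
      dn <- sqrt(dx^2 + dy^2)
      dot <- v[, i, 1] * dx + v[, i, 2] * dy
      den <- speed[, i] * dn
      ang <- acos(pmin(1, pmax(-1, dot / den))) * 180 / pi
      ang[!is.finite(den) | den == 0] <- NA_real_
      vals[, i, j] <- ang
    }
  }
  structure(list(kind = "angle", values = vals, ids = ids, time = traj$time,
                 frame_interval = traj$frame_interval),
            class = "pair_series")
}

#' @export
print.pair_series <- function(x, ...) {
  cat("<pair_series:", x$kind, "> ", length(x$ids), " individuals x ",
      dim(x$values)[1], " frames\n", sep = "")
  invisible(x)
}

#' Static centre of the group
#'
#' The mean over the whole session of the per-frame centroid of all
#' individuals; the fixed reference point about which rotation is measured.
#'
#' @param traj a `trajectory_set`.
#' @return length-2 numeric `(x, y)` in cm.
#' @export
static_group_center <- function(traj) {
  c(x = mean(apply(traj$pos[, , 1, drop = FALSE], 1, mean)),
    y = mean(apply(traj$pos[, , 2, drop = FALSE], 1, mean)))
}

#' Per-individual angular momentum about the static group centre
#'
#' For each individual and frame, the magnitude of the 2-D cross product of
#' the unit radial vector (position relative to the static group centre) and
#' the unit velocity vector: `|sin(phi)|` for `phi` the angle between them.
#' 1 indicates pure rotation about the centre, 0 pure radial motion. Frames
#' with zero speed or zero radius (or undefined velocity) are `NA`.
#'
#' @param traj a `trajectory_set` with velocities.
#' @param center the static group centre; computed from `traj` by default.
#' @return a `[frame, individual]` matrix of class `momentum_series` with the
#'   centre stored in `attr(, "center")`.
#' @export
angular_momentum <- function(traj, center = static_group_center(traj)) {
  if (is.null(traj$vel)) stop("velocities not computed; call compute_velocity()")
  p <- traj$pos; v <- traj$vel
  ax <- p[, , 1] - center[1]
  ay <- p[, , 2] - center[2]
  an <- sqrt(ax^2 + ay^2)
  vn <- sqrt(v[, , 1]^2 + v[, , 2]^2)
  m <- abs(ax * v[, , 2] - ay * v[, , 1]) / (an * vn)
  m[!is.finite(m)] <- NA_real_
  m <- pmin(m, 1)  # guard against round-off above 1
  dim(m) <- dim(p)[1:2]
  dimnames(m) <- list(NULL, traj$ids)
  structure(m, center = center, class = c("momentum_series", "matrix"))
}

#' Mean speed (activity amount) per individual
#'
#' @param traj a `trajectory_set` with velocities.
#' @return named vector of mean speeds over valid frames (cm/s).
#' @export
activity_amount <- function(traj) {
  if (is.null(traj$vel)) stop("velocities not computed; call compute_velocity()")
  speed <- sqrt(traj$vel[, , 1]^2 + traj$vel[, , 2]^2)
  dim(speed) <- dim(traj$vel)[1:2]
  out <- colMeans(speed, na.rm = TRUE)
  names(out) <- traj$ids
  out
}

#' Group-level angular momentum per frame
#'
#' The per-frame mean of the individual angular momenta over the individuals
#' valid at that frame; frames with no valid individual are `NA`.
#'
#' @param momentum a `momentum_series` from [angular_momentum()].
#' @return numeric vector, one value per frame, in `[0, 1]` or `NA`.
#' @export
group_angular_momentum <- function(momentum) {
  out <- rowMeans(momentum, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  unname(out)
}

#' Tidy long-format export of a pair series
#'
#' @param ps a `pair_series`.
#' @param symmetric_once for distance series, keep only `i < j` rows.
#' @return data frame `frame, time, i, j, value, valid`.
#' @export
pair_series_long <- function(ps, symmetric_once = ps$kind == "distance") {
  N <- length(ps$ids); T <- dim(ps$values)[1]
  rows <- list()
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      if (symmetric_once && i > j) next
      v <- ps$values[, i, j]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = seq_len(T), time = ps$time, i = ps$ids[i], j = ps$ids[j],
        value = v, valid = !is.na(v))
    }
  }
  do.call(rbind, rows)
}
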