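# Trajectory ingestion: raw digitized positions -> analysis-ready trajectory_set.

#' CSV layout descriptor for position files
#'
#' Position files are wide CSVs: one time column plus an x and a y column per
#' individual, named `<id><suffix_x>` and `<id><suffix_y>`. Empty cells are
#' missing samples (gaps), never zeros.
#'
#' @param time_col name of the time column (seconds).
#' @param suffix_x,suffix_y column-name suffixes identifying x and y columns.
#' @return an object of class `csv_dialect`.
#' @export
csv_dialect <- function(time_col = "time", suffix_x = "_x", suffix_y = "_y") {
  structure(list(time_col = time_col, suffix_x = suffix_x, suffix_y = suffix_y),
            class = "csv_dialect")
}

#' Read a raw digitized session
#'
#' Reads a wide position CSV into a `raw_digitization`: one `(time, x, y)`
#' series per individual, with missing cells kept as explicit `NA` gaps.
#'
#' @param path path to the CSV file.
#' @param dialect a [csv_dialect()] describing the column layout.
#' @param sample_interval nominal digitization interval in seconds. `NULL`
#'   infers it as the median time step.
#' @return an object of class `raw_digitization`: list with `sample_interval`
#'   and `series`, a named list of data frames with columns `time`, `x`, `y`.
#' @export
read_session <- function(path, dialect = csv_dialect(), sample_interval = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!dialect$time_col %in% names(df)) {
    stop("time column '", dialect$time_col, "' not found in ", path)
  }
  time <- df[[dialect$time_col]]
  if (anyNA(time)) stop("malformed CSV: missing time value at row ",
                        which(is.na(time))[1])
  if (any(diff(time) <= 0)) {
    stop("non-monotone time at row ", which(diff(time) <= 0)[1] + 1L)
  }
  xs <- names(df)[endsWith(names(df), dialect$suffix_x) &
                    names(df) != dialect$time_col]
  ids <- substring(xs, 1, nchar(xs) - nchar(dialect$suffix_x))
  if (length(ids) == 0L) stop("no '*", dialect$suffix_x, "' columns found in ", path)
  series <- lapply(ids, function(id) {
    xc <- paste0(id, dialect$suffix_x)
    yc <- paste0(id, dialect$suffix_y)
    if (!yc %in% names(df)) stop("missing y column for individual '", id, "'")
    data.frame(time = time, x = as.numeric(df[[xc]]), y = as.numeric(df[[yc]]))
  })
  names(series) <- ids
  if (is.null(sample_interval)) sample_interval <- stats::median(diff(time))
  structure(list(sample_interval = sample_interval, series = series),
            class = "raw_digitization")
}

#' Write a raw session or trajectory set as a wide CSV
#'
#' Inverse of [read_session()]; for a `trajectory_set`, velocity columns
#' (`<id>_vx`, `<id>_vy`) are appended when velocities are present.
#'
#' @param x a `raw_digitization` or `trajectory_set`.
#' @param path output CSV path.
#' @param dialect a [csv_dialect()].
#' @return `path`, invisibly.
#' @export
write_session <- function(x, path, dialect = csv_dialect()) {
  if (inherits(x, "raw_digitization")) {
    time <- x$series[[1]]$time
    out <- data.frame(time = time)
    for (id in names(x$series)) {
      out[[paste0(id, dialect$suffix_x)]] <- x$series[[id]]$x
      out[[paste0(id, dialect$suffix_y)]] <- x$series[[id]]$y
    }
  } else if (inherits(x, "trajectory_set")) {
    out <- data.frame(time = x$time)
    for (id in x$ids) {
      out[[paste0(id, dialect$suffix_x)]] <- x$pos[, id, 1]
      out[[paste0(id, dialect$suffix_y)]] <- x$pos[, id, 2]
    }
    if (!is.null(x$vel)) {
      for (id in x$ids) {
        out[[paste0(id, "_vx")]] <- x$vel[, id, 1]
        out[[paste0(id, "_vy")]] <- x$vel[, id, 2]
      }
    }
  } else stop("unsupported object of class ", paste(class(x), collapse = "/"))
  names(out)[1] <- dialect$time_col
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a trajectory set
#'
#' The central container: positions of all individuals on a shared uniform
#' frame grid, with optional velocities.
#'
#' @param pos numeric array `[frame, individual, coordinate]` with individual
#'   ids as the second dimnames and coordinates `c("x", "y")`.
#' @param frame_interval frame spacing in seconds.
#' @param time optional vector of frame times; defaults to `0, dt, 2*dt, ...`.
#' @param vel optional velocity array of the same shape as `pos` (cm/s).
#' @param meta list of session metadata; if it contains `arena = c(w, h)` the
#'   positions are checked against that bounding box (with `arena_tol` cm of
#'   slack for calibration error).
#' @param arena_tol tolerance in cm for the arena bounds check.
#' @return an object of class `trajectory_set` with fields `frame_interval`,
#'   `time`, `ids`, `pos`, `vel`, `meta`.
#' @export
trajectory_set <- function(pos, frame_interval = 0.05, time = NULL, vel = NULL,
                           meta = list(), arena_tol = 10) {
  stopifnot(length(dim(pos)) == 3, dim(pos)[3] == 2)
  if (dim(pos)[1] < 2L) stop("a trajectory set needs at least 2 frames")
  ids <- dimnames(pos)[[2]]
  if (is.null(ids)) {
    ids <- as.character(seq_len(dim(pos)[2]))
    dimnames(pos) <- list(NULL, ids, c("x", "y"))
  }
  if (is.null(time)) time <- (seq_len(dim(pos)[1]) - 1L) * frame_interval
  if (!is.null(meta$arena)) {
    a <- meta$arena
    ok <- pos[, , 1] >= -arena_tol & pos[, , 1] <= a[1] + arena_tol &
          pos[, , 2] >= -arena_tol & pos[, , 2] <= a[2] + arena_tol
    if (!all(ok, na.rm = TRUE)) {
      stop("positions fall outside the configured arena bounding box")
    }
  }
  structure(list(frame_interval = frame_interval, time = time, ids = ids,
                 pos = pos, vel = vel, meta = meta),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", length(x$ids), " individuals x ", dim(x$pos)[1],
      " frames @ ", x$frame_interval, " s (",
      round((dim(x$pos)[1] - 1) * x$frame_interval, 2), " s)\n", sep = "")
  if (is.null(x$vel)) cat("  velocities: not computed\n")
  invisible(x)
}

#' Number of frames in a trajectory set
#' @param traj a `trajectory_set`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$pos)[1]

#' Resample raw digitized positions onto a uniform frame grid
#'
#' Fits an interpolating cubic spline per individual and coordinate and
#' evaluates it on a uniform grid. The spline passes exactly through the raw
#' samples, so it bridges short gaps; individuals with fewer than 4 non-missing
#' samples, or missing more than `max_missing_frac` of their samples, are
#' excluded with a warning rather than silently interpolated.
#'
#' The shared grid spans the overlap of all retained individuals' time ranges
#' (no extrapolation).
#'
#' @param raw a `raw_digitization`.
#' @param frame_interval target frame spacing in seconds.
#' @param method spline end conditions, passed to [stats::splinefun()]. The
#'   default `"fmm"` reproduces polynomials up to cubic exactly.
#' @param max_missing_frac maximum tolerated fraction of missing samples.
#' @param meta metadata forwarded to [trajectory_set()].
#' @return a `trajectory_set` with positions only.
#' @export
resample_spline <- function(raw, frame_interval = 0.05, method = "fmm",
                            max_missing_frac = 0.1, meta = list()) {
  stopifnot(inherits(raw, "raw_digitization"))
  keep <- list()
  for (id in names(raw$series)) {
    s <- raw$series[[id]]
    ok <- !is.na(s$x) & !is.na(s$y)
    if (sum(ok) < 4L) {
      warning("individual '", id, "' has fewer than 4 usable samples; excluded")
      next
    }
    if (mean(!ok) > max_missing_frac) {
      warning("individual '", id, "' is missing ", round(100 * mean(!ok)),
              "% of samples (> ", round(100 * max_missing_frac),
              "%); excluded")
      next
    }
    keep[[id]] <- s[ok, ]
  }
  if (length(keep) == 0L) stop("no individual has enough samples to resample")
  t0 <- max(vapply(keep, function(s) s$time[1], 0))
  t1 <- min(vapply(keep, function(s) s$time[nrow(s)], 0))
  if (t1 - t0 < frame_interval) stop("individual time ranges do not overlap")
  grid <- seq(t0, t1, by = frame_interval)
  pos <- array(NA_real_, c(length(grid), length(keep), 2),
               dimnames = list(NULL, names(keep), c("x", "y")))
  for (id in names(keep)) {
    s <- keep[[id]]
    pos[, id, 1] <- splinefun(s$time, s$x, method = method)(grid)
    pos[, id, 2] <- splinefun(s$time, s$y, method = method)(grid)
  }
  trajectory_set(pos, frame_interval = frame_interval, time = grid, meta = meta)
}

#' Estimate per-frame velocities by finite differences
#'
#' Backward differences by default: `v(t) = (c(t) - c(t-1)) / dt`, so the
#' velocity at a frame describes the displacement arriving at it; the first
#' frame has no velocity (`NA`). `"central"` uses `(c(t+1) - c(t-1)) / (2 dt)`
#' and leaves both end frames `NA`.
#'
#' @param traj a `trajectory_set`.
#' @param scheme differencing scheme.
#' @return the `trajectory_set` with its `vel` field filled (cm/s).
#' @export
compute_velocity <- function(traj, scheme = c("backward", "central")) {
  scheme <- match.arg(scheme)
  p <- traj$pos
  dt <- traj$frame_interval
  v <- array(NA_real_, dim(p), dimnames = dimnames(p))
  T <- dim(p)[1]
  if (scheme == "backward") {
    v[2:T, , ] <- (p[2:T, , , drop = FALSE] - p[1:(T - 1), , , drop = FALSE]) / dt
  } else {
    if (T >= 3) {
      v[2:(T - 1), , ] <- (p[3:T, , , drop = FALSE] -
                             p[1:(T - 2), , , drop = FALSE]) / (2 * dt)
    }
  }
  traj$vel <- v
  traj$meta$velocity_scheme <- scheme
  traj
}
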