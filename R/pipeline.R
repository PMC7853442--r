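# End-to-end orchestration: sessions -> indices -> histograms -> comparisons.

#' Load a processed trajectory CSV
#'
#' Reads a wide trajectory CSV already on a uniform frame grid (the format
#' written by [write_session()]) straight into a `trajectory_set`.
#'
#' @param path CSV path.
#' @param dialect a [csv_dialect()].
#' @param meta metadata forwarded to [trajectory_set()].
#' @return a `trajectory_set` (positions only; call [compute_velocity()]).
#' @export
load_trajectory <- function(path, dialect = csv_dialect(), meta = list()) {
  raw <- read_session(path, dialect)
  time <- raw$series[[1]]$time
  dts <- diff(time)
  if (max(dts) - min(dts) > 1e-6) {
    stop("trajectory CSV is not on a uniform frame grid; use read_session() ",
         "and resample_spline()")
  }
  pos <- array(NA_real_, c(length(time), length(raw$series), 2),
               dimnames = list(NULL, names(raw$series), c("x", "y")))
  for (id in names(raw$series)) {
    pos[, id, 1] <- raw$series[[id]]$x
    pos[, id, 2] <- raw$series[[id]]$y
  }
  trajectory_set(pos, frame_interval = dts[1], time = time, meta = meta)
}

#' Analyse one session
#'
#' Computes every index and the approach analysis for a single session:
#' pairwise distances and heading angles, the static group centre, angular
#' momenta, approach events with approaching-angle samples per look-back
#' window, and the per-individual sample sets consumed by the histogram
#' comparison.
#'
#' @param traj a `trajectory_set` (velocities are computed if absent).
#' @param threshold approach-onset distance (cm).
#' @param band approaching-angle distance band (cm).
#' @param windows list of look-back windows in seconds before onset.
#' @return object of class `session_analysis`.
#' @export
analyze_session <- function(traj, threshold = 50, band = c(100, 200),
                            windows = list(`0-1` = c(0, 1), `1-2` = c(1, 2),
                                           `2-3` = c(2, 3))) {
  if (is.null(traj$vel)) traj <- compute_velocity(traj)
  dist_ps <- pair_distance(traj)
  angle_ps <- pair_angle(traj)
  center <- static_group_center(traj)
  momentum <- angular_momentum(traj, center)
  events <- detect_events(dist_ps, threshold = threshold)
  approach <- lapply(windows, function(w)
    approach_angles(events, angle_ps, dist_ps, window = w, band = band))
  structure(list(
    traj = traj, ids = traj$ids,
    distance = dist_ps, angle = angle_ps,
    center = center, momentum = momentum,
    group_momentum = group_angular_momentum(momentum),
    activity = activity_amount(traj),
    events = events, approach = approach,
    samples = list(
      distance = pair_samples_by_child(dist_ps),
      angle = pair_samples_by_child(angle_ps),
      momentum = momentum_samples_by_child(momentum),
      approach_angle = approach_samples_by_child(approach[[1]], traj$ids))),
    class = "session_analysis")
}

#' Pipeline configuration
#'
#' @param class_a,class_b named lists of sessions for the two classes; each
#'   element is a `trajectory_set` or a path to a processed trajectory CSV.
#'   Class A comes first in every comparison (sign convention).
#' @param class_labels display labels for the two classes.
#' @param out_dir output directory for tables (created if needed); `NULL`
#'   keeps everything in memory.
#' @param distance_max last regular distance-bin edge (cm).
#' @param threshold,band,windows see [analyze_session()].
#' @param approach_window which look-back window feeds the approaching-angle
#'   histograms and matrices (name in `windows`).
#' @param alpha significance level on Bonferroni-corrected p-values.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(class_a, class_b, class_labels = c("A", "B"),
                            out_dir = NULL, distance_max = 1350,
                            threshold = 50, band = c(100, 200),
                            windows = list(`0-1` = c(0, 1), `1-2` = c(1, 2),
                                           `2-3` = c(2, 3)),
                            approach_window = "0-1", alpha = 0.05) {
  if (length(class_a) && is.null(names(class_a))) {
    names(class_a) <- paste0("A", seq_along(class_a))
  }
  if (length(class_b) && is.null(names(class_b))) {
    names(class_b) <- paste0("B", seq_along(class_b))
  }
  structure(list(class_a = class_a, class_b = class_b,
                 class_labels = class_labels, out_dir = out_dir,
                 distance_max = distance_max, threshold = threshold,
                 band = band, windows = windows,
                 approach_window = approach_window, alpha = alpha),
            class = "pipeline_config")
}

.load_session <- function(x, name) {
  if (inherits(x, "trajectory_set")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("pipeline stage 'load': session '", name,
                              "': file not found: ", x)
    return(load_trajectory(x))
  }
  stop("pipeline stage 'load': session '", name,
       "' is neither a trajectory_set nor a file path")
}

# per-class child histogram lists for each index, children prefixed by session
.class_histograms <- function(analyses, specs, approach_window) {
  out <- list()
  for (kind in names(specs)) {
    hists <- list()
    for (sname in names(analyses)) {
      an <- analyses[[sname]]
      smp <- if (kind == "approach_angle")
        approach_samples_by_child(an$approach[[approach_window]], an$ids)
      else an$samples[[kind]]
      h <- session_histograms(smp, specs[[kind]],
                              drop_empty = kind == "approach_angle")
      if (length(h)) names(h) <- paste(sname, names(h), sep = ":")
      hists <- c(hists, h)
    }
    out[[kind]] <- hists
  }
  out
}

#' Run the full comparison pipeline
#'
#' Loads every session of both classes, analyses them, builds per-individual
#' histograms for the four indices (distance, heading angle, approaching
#' angle, angular momentum), compares the classes per bin, and (optionally)
#' writes all tables plus a machine-readable run log. Deterministic given
#' inputs and configuration.
#'
#' @param config a [pipeline_config()].
#' @return object of class `report_bundle`: list with `analyses` (per class),
#'   `comparisons` (one `group_comparison` per index), `class_means`,
#'   `matrices` (per-session directed-pair approach matrices), `config`, and
#'   `log` (every analysis setting used).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  specs <- list(
    distance = bin_spec("distance", distance_max = config$distance_max),
    angle = bin_spec("angle"),
    approach_angle = bin_spec("approach_angle"),
    momentum = bin_spec("momentum"))

  run_stage <- function(stage, sname, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed for session '", sname, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  analyses <- list()
  for (cls in c("class_a", "class_b")) {
    analyses[[cls]] <- list()
    for (sname in names(config[[cls]])) {
      traj <- .load_session(config[[cls]][[sname]], sname)
      analyses[[cls]][[sname]] <- run_stage("analyze", sname,
        analyze_session(traj, threshold = config$threshold,
                        band = config$band, windows = config$windows))
    }
  }

  hists_a <- .class_histograms(analyses$class_a, specs, config$approach_window)
  hists_b <- .class_histograms(analyses$class_b, specs, config$approach_window)

  comparisons <- list(); class_means <- list()
  for (kind in names(specs)) {
    comparisons[[kind]] <- compare_classes(hists_a[[kind]], hists_b[[kind]],
                                           specs[[kind]], alpha = config$alpha)
    class_means[[kind]] <- list(
      a = class_mean_histogram(hists_a[[kind]]),
      b = class_mean_histogram(hists_b[[kind]]))
  }

  matrices <- list()
  for (cls in c("class_a", "class_b")) {
    for (sname in names(analyses[[cls]])) {
      an <- analyses[[cls]][[sname]]
      matrices[[sname]] <- approach_matrix(
        an$approach[[config$approach_window]], an$ids)
    }
  }

  log <- list(
    class_labels = config$class_labels,
    sessions_a = names(config$class_a), sessions_b = names(config$class_b),
    threshold_cm = config$threshold, band_cm = config$band,
    windows_s = config$windows, approach_window = config$approach_window,
    distance_max_cm = config$distance_max, alpha = config$alpha,
    bonferroni_family = lapply(specs, function(s) s$n_bins),
    velocity_scheme = "backward")

  bundle <- structure(list(analyses = analyses, comparisons = comparisons,
                           class_means = class_means, matrices = matrices,
                           histograms = list(a = hists_a, b = hists_b),
                           config = config, log = log),
                      class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle's tables to disk
#'
#' Emits one comparison CSV and one class-means CSV per index, per-session
#' event and approaching-angle sample CSVs, per-session approach matrices,
#' and a JSON run log. All outputs are plain text and byte-reproducible.
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (kind in names(bundle$comparisons)) {
    write.csv(bundle$comparisons[[kind]],
              file.path(out_dir, paste0("comparison_", kind, ".csv")),
              row.names = FALSE)
    cm <- bundle$class_means[[kind]]
    cm$a$class <- rep(bundle$config$class_labels[1], nrow(cm$a))
    cm$b$class <- rep(bundle$config$class_labels[2], nrow(cm$b))
    write.csv(rbind(cm$a, cm$b),
              file.path(out_dir, paste0("class_means_", kind, ".csv")),
              row.names = FALSE)
  }
  for (cls in c("class_a", "class_b")) {
    for (sname in names(bundle$analyses[[cls]])) {
      an <- bundle$analyses[[cls]][[sname]]
      write.csv(an$events, file.path(out_dir, paste0("events_", sname, ".csv")),
                row.names = FALSE)
      aw <- bundle$config$approach_window
      write.csv(an$approach[[aw]],
                file.path(out_dir, paste0("approach_samples_", sname, ".csv")),
                row.names = FALSE)
      write.csv(bundle$matrices[[sname]],
                file.path(out_dir, paste0("approach_matrix_", sname, ".csv")))
    }
  }
  jsonlite::write_json(bundle$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Session shapes of the observed study design
#'
#' The participant counts and piano-playing durations of the five observed
#' sessions (four visits to the younger class, one to the older class), used
#' to size simulated sessions like the real ones.
#'
#' @return data frame `session, class, mean_age, n_children, duration_s`.
#' @export
study_session_shapes <- function() {
  data.frame(
    session = c("5.03", "5.28", "5.59", "5.71", "6.18"),
    class = c(rep("five-year", 4), "six-year"),
    mean_age = c(5.03, 5.28, 5.59, 5.71, 6.18),
    n_children = c(12L, 13L, 13L, 11L, 11L),
    duration_s = c(61.05, 36.68, 100.59, 42.18, 37.11))
}

#' Reproduce the deposited-data analysis
#'
#' Runs the full pipeline on the five deposited position CSVs (four
#' younger-class sessions vs the older-class session) and extracts the
#' headline per-bin statistics: the 50 cm distance bin, the 20 degree
#' approaching-angle bin (0-1 s window), and the 0.8 and 1 angular-momentum
#' bins. Each younger-class session is compared separately against the
#' older-class session, as in the original design.
#'
#' The deposited files must sit in `data_dir` as `S1*.csv` ... `S5*.csv`
#' (S1-S4 the younger class in chronological order, S5 the older class), in
#' the wide layout of [csv_dialect()]. Files on a coarse digitization grid
#' are spline-resampled to 0.05 s first.
#'
#' @param data_dir directory containing the deposited CSVs.
#' @param out_dir optional directory for the full table outputs.
#' @return data frame with one row per (comparison session, headline bin):
#'   `session, index, bin, t, df, p_raw, p_bonferroni, g`.
#' @export
reproduce_study <- function(data_dir, out_dir = NULL) {
  paths <- lapply(1:5, function(k) {
    hit <- list.files(data_dir, pattern = paste0("^S", k, ".*\\.csv$"),
                      full.names = TRUE)
    if (length(hit) == 0L) stop("deposited dataset S", k, " not found in ",
                                data_dir)
    hit[1]
  })
  load1 <- function(p) {
    raw <- read_session(p)
    resample_spline(raw, frame_interval = 0.05)
  }
  six <- load1(paths[[5]])
  shapes <- study_session_shapes()
  out <- list()
  for (k in 1:4) {
    five <- load1(paths[[k]])
    cfg <- pipeline_config(
      class_a = stats::setNames(list(five), shapes$session[k]),
      class_b = list(`6.18` = six),
      class_labels = c("five-year", "six-year"),
      out_dir = if (is.null(out_dir)) NULL else
        file.path(out_dir, shapes$session[k]))
    bundle <- run_pipeline(cfg)
    pick <- function(kind, bin) {
      r <- bundle$comparisons[[kind]]
      r[r$bin == bin, c("t", "df", "p_raw", "p_bonferroni", "g")]
    }
    head <- rbind(
      cbind(index = "distance", bin = "50", pick("distance", "50")),
      cbind(index = "approach_angle", bin = "20", pick("approach_angle", "20")),
      cbind(index = "momentum", bin = "0.8", pick("momentum", "0.8")),
      cbind(index = "momentum", bin = "1", pick("momentum", "1.0")))
    head <- cbind(session = shapes$session[k], head)
    out[[k]] <- head
  }
  do.call(rbind, out)
}
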