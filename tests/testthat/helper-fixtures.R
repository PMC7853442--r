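# Fixtures are built in code: small deterministic trajectories with known
# geometry, plus random-walk sets for oracle comparisons.

# trajectory_set from a list of per-individual T x 2 position matrices
traj_from_list <- function(pos_list, dt = 0.05, velocities = TRUE) {
  T <- nrow(pos_list[[1]])
  ids <- names(pos_list)
  if (is.null(ids)) ids <- paste0("c", seq_along(pos_list))
  pos <- array(NA_real_, c(T, length(pos_list), 2),
               dimnames = list(NULL, ids, c("x", "y")))
  for (k in seq_along(pos_list)) pos[, k, ] <- pos_list[[k]]
  tr <- trajectory_set(pos, frame_interval = dt)
  if (velocities) tr <- compute_velocity(tr)
  tr
}

# smooth-ish random walk trajectories for brute-force oracle checks
random_walk_traj <- function(n_agents, T, dt = 0.05, seed = 1, step_sd = 8) {
  set.seed(seed)
  pos_list <- lapply(seq_len(n_agents), function(k) {
    start <- runif(2, 100, 800)
    steps <- matrix(rnorm(2 * (T - 1), 0, step_sd), ncol = 2)
    rbind(start, start + apply(steps, 2, cumsum))
  })
  traj_from_list(pos_list, dt = dt)
}

# random raw digitization (possibly with gaps) for round-trip properties
random_raw_session <- function(n_agents, n_samples, seed = 1, gap_prob = 0) {
  set.seed(seed)
  time <- (seq_len(n_samples) - 1) * 0.2
  series <- lapply(seq_len(n_agents), function(k) {
    x <- cumsum(rnorm(n_samples, 0, 20)) + 500
    y <- cumsum(rnorm(n_samples, 0, 20)) + 400
    if (gap_prob > 0) {
      gap <- runif(n_samples) < gap_prob
      x[gap] <- NA; y[gap] <- NA
    }
    data.frame(time = time, x = x, y = y)
  })
  names(series) <- paste0("c", seq_len(n_agents))
  structure(list(sample_interval = 0.2, series = series),
            class = "raw_digitization")
}

# brute-force oracles: plain double loops, independent of the implementation
oracle_distance <- function(traj) {
  T <- dim(traj$pos)[1]; N <- dim(traj$pos)[2]
  out <- array(NA_real_, c(T, N, N))
  for (t in seq_len(T)) for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j) out[t, i, j] <- sqrt(sum((traj$pos[t, i, ] - traj$pos[t, j, ])^2))
  }
  out
}

oracle_angle <- function(traj) {
  T <- dim(traj$pos)[1]; N <- dim(traj$pos)[2]
  out <- array(NA_real_, c(T, N, N))
  for (t in seq_len(T)) for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    v <- traj$vel[t, i, ]; d <- traj$pos[t, j, ] - traj$pos[t, i, ]
    nv <- sqrt(sum(v^2)); nd <- sqrt(sum(d^2))
    if (is.na(nv) || nv == 0 || nd == 0) next
    out[t, i, j] <- acos(max(-1, min(1, sum(v * d) / (nv * nd)))) * 180 / pi
  }
  out
}

oracle_center <- function(traj) {
  T <- dim(traj$pos)[1]; N <- dim(traj$pos)[2]
  acc <- c(0, 0)
  for (t in seq_len(T)) {
    ct <- c(0, 0)
    for (i in seq_len(N)) ct <- ct + traj$pos[t, i, ]
    acc <- acc + ct / N
  }
  acc / T
}

oracle_momentum <- function(traj, center) {
  T <- dim(traj$pos)[1]; N <- dim(traj$pos)[2]
  out <- matrix(NA_real_, T, N)
  for (t in seq_len(T)) for (i in seq_len(N)) {
    a <- traj$pos[t, i, ] - center
    v <- traj$vel[t, i, ]
    na <- sqrt(sum(a^2)); nv <- sqrt(sum(v^2))
    if (is.na(nv) || nv == 0 || na == 0) next
    ua <- a / na; uv <- v / nv
    out[t, i] <- abs(ua[1] * uv[2] - ua[2] * uv[1])
  }
  out
}
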