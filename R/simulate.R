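# Agent-based generator of the two behavioural regimes the analysis targets:
# large-scale rotation about the group centre, and short-time-scale mutual
# pursuit ("tag") with contacts inside the personal-space radius.

#' Simulation configuration
#'
#' Discrete-time kinematic agents (heading + speed) in a rectangular hall.
#' Rotation-mode agents orbit the hall centre on phase-balanced rings; tag
#' agents wander until drawn into a pursuit, with one chaser steering toward a
#' target that flees once the chaser comes within `flee_radius`. On contact
#' (distance < `contact_radius`) the tagged agent becomes the chaser and picks
#' a new target. Walls reflect.
#'
#' @param n_agents number of agents.
#' @param duration session length in seconds.
#' @param frame_interval frame spacing in seconds.
#' @param arena hall width and height in cm.
#' @param speed_mean,speed_sd per-agent running speed distribution (cm/s),
#'   truncated at 0.
#' @param heading_noise SD (radians/step) of the heading jitter applied to
#'   rotation-mode agents.
#' @param wander_noise SD (radians/step) of the heading random walk of
#'   uninvolved tag-mode agents.
#' @param mode `"rotation"`, `"tag"`, or `"mixed"`.
#' @param p_social probability an agent plays tag in `"mixed"` mode.
#' @param contact_radius contact / role-switch distance in cm.
#' @param flee_radius distance at which a target starts fleeing (cm).
#' @param chase_gain,flee_gain per-step relaxation of the chaser's (target's)
#'   heading toward (away from) the line of sight, in `[0, 1]`.
#' @param chase_boost speed multiplier of the chaser (children sprint when
#'   "it").
#' @param cohesion_gain,cohesion_radius uninvolved tag players farther than
#'   `cohesion_radius` cm from the playing group's centroid steer back toward
#'   it with per-step gain `cohesion_gain`, keeping the game loosely
#'   clustered.
#' @param ring_range radial extent of the rotation rings as fractions of the
#'   shorter hall dimension.
#' @param seed integer RNG seed; identical seed and config give identical
#'   output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_agents = 12, duration = 40, frame_interval = 0.05,
                       arena = c(1000, 850), speed_mean = 200, speed_sd = 40,
                       heading_noise = 0.15, wander_noise = 0.35,
                       mode = c("mixed", "rotation", "tag"), p_social = 0.5,
                       contact_radius = 50, flee_radius = 200,
                       chase_gain = 0.5, flee_gain = 0.25, chase_boost = 1.4,
                       cohesion_gain = 0.1, cohesion_radius = 250,
                       ring_range = c(0.14, 0.45), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_agents >= 1, duration > 0, frame_interval > 0,
            speed_mean >= 0, speed_sd >= 0, heading_noise >= 0,
            p_social >= 0, p_social <= 1)
  structure(list(n_agents = n_agents, duration = duration,
                 frame_interval = frame_interval, arena = arena,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 heading_noise = heading_noise, wander_noise = wander_noise,
                 mode = mode, p_social = p_social,
                 contact_radius = contact_radius, flee_radius = flee_radius,
                 chase_gain = chase_gain, flee_gain = flee_gain,
                 chase_boost = chase_boost, cohesion_gain = cohesion_gain,
                 cohesion_radius = cohesion_radius, ring_range = ring_range,
                 seed = seed),
            class = "sim_config")
}

# sample one element from a vector (avoids sample()'s scalar expansion)
.pick <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

.wrap_angle <- function(a) atan2(sin(a), cos(a))

# Balanced ring assignment: agents are grouped into antipodal pairs (and one
# equilateral triple when the count is odd and >= 3), one ring per group, so
# the group centroid coincides with the ring centre exactly whenever speeds
# within a ring are equal (e.g. speed_sd = 0).
.ring_layout <- function(n, r_min, r_max) {
  sizes <- if (n == 1L) 1L
           else if (n %% 2L == 0L) rep(2L, n / 2L)
           else c(3L, rep(2L, (n - 3L) / 2L))
  n_rings <- length(sizes)
  radii <- if (n_rings == 1L) (r_min + r_max) / 2 else
    seq(r_min, r_max, length.out = n_rings)
  r <- numeric(n); phase <- numeric(n); k <- 1L
  for (g in seq_len(n_rings)) {
    off <- runif(1, 0, 2 * pi)
    ph <- off + 2 * pi * (seq_len(sizes[g]) - 1L) / sizes[g]
    idx <- k:(k + sizes[g] - 1L)
    r[idx] <- radii[g]
    phase[idx] <- ph
    k <- k + sizes[g]
  }
  list(r = r, phase = phase)
}

#' Simulate a mixed rotation/pursuit session
#'
#' Each agent is independently assigned to the pursuit ("tag") group with
#' probability `p_social`; the rest orbit the hall centre. `p_social = 0`
#' reproduces [simulate_rotation()] and `p_social = 1` reproduces
#' [simulate_tag()] exactly at the same seed.
#'
#' @param config a [sim_config()].
#' @return list with `trajectories` (a `trajectory_set` with velocities) and
#'   `truth`: `social` (logical per agent), `chaser`/`target` (per-frame ids,
#'   `NA` when no pursuit is active), and `contacts` (data frame
#'   `frame, chaser, target` of role-switch contacts).
#' @export
simulate_mixed <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_agents
  dt <- config$frame_interval
  T <- round(config$duration / dt) + 1L
  arena <- config$arena
  center <- arena / 2
  ids <- sprintf("a%02d", seq_len(n))

  social <- rbinom(n, 1, config$p_social) == 1
  speeds <- pmax(0, rnorm(n, config$speed_mean, config$speed_sd))

  pos <- array(NA_real_, c(T, n, 2), dimnames = list(NULL, ids, c("x", "y")))
  rot <- which(!social); soc <- which(social)

  # rotation agents: balanced rings about the hall centre
  r_min <- config$ring_range[1] * min(arena)
  r_max <- config$ring_range[2] * min(arena)
  if (length(rot)) {
    lay <- .ring_layout(length(rot), r_min, r_max)
    ring_r <- lay$r; ring_th <- lay$phase
    pos[1, rot, 1] <- center[1] + ring_r * cos(ring_th)
    pos[1, rot, 2] <- center[2] + ring_r * sin(ring_th)
  } else ring_r <- ring_th <- numeric(0)

  # tag agents: scattered over the central part of the hall
  if (length(soc)) {
    pos[1, soc, 1] <- runif(length(soc), 0.1 * arena[1], 0.9 * arena[1])
    pos[1, soc, 2] <- runif(length(soc), 0.1 * arena[2], 0.9 * arena[2])
  }
  phi <- runif(n, 0, 2 * pi)  # headings (used by tag agents)

  chaser <- NA_integer_; target <- NA_integer_
  if (length(soc) >= 2L) {
    chaser <- .pick(soc)
    target <- .pick(setdiff(soc, chaser))
  }
  chaser_log <- rep(NA_character_, T)
  target_log <- rep(NA_character_, T)
  contacts <- list()
  if (!is.na(chaser)) {
    chaser_log[1] <- ids[chaser]; target_log[1] <- ids[target]
  }

  cur <- pos[1, , , drop = TRUE]
  if (n == 1L) cur <- matrix(cur, 1, 2)

  for (t in 2:T) {
    # --- rotation agents: step toward the next point on the home circle,
    #     then jitter; aiming at the circle keeps each agent on its own ring
    if (length(rot)) {
      dth <- speeds[rot] * dt / pmax(ring_r, 1)
      ideal_x <- center[1] + ring_r * cos(ring_th + dth)
      ideal_y <- center[2] + ring_r * sin(ring_th + dth)
      sx <- ideal_x - cur[rot, 1]
      sy <- ideal_y - cur[rot, 2]
      eps <- rnorm(length(rot), 0, config$heading_noise)
      cur[rot, 1] <- cur[rot, 1] + cos(eps) * sx - sin(eps) * sy
      cur[rot, 2] <- cur[rot, 2] + sin(eps) * sx + cos(eps) * sy
    }
    # --- tag agents: wander / chase / flee
    if (length(soc)) {
      noise <- rnorm(length(soc), 0, 1)
      phi[soc] <- phi[soc] + config$wander_noise * noise
      sp <- speeds[soc]
      # cohesion: stragglers steer back toward the playing group
      if (length(soc) >= 2L && config$cohesion_gain > 0) {
        cx <- mean(cur[soc, 1]); cy <- mean(cur[soc, 2])
        gx <- cx - cur[soc, 1]; gy <- cy - cur[soc, 2]
        far <- which(sqrt(gx^2 + gy^2) > config$cohesion_radius &
                       soc != chaser)
        if (length(far)) {
          gi <- soc[far]
          phi[gi] <- phi[gi] + config$cohesion_gain *
            .wrap_angle(atan2(gy[far], gx[far]) - phi[gi])
        }
      }
      if (!is.na(chaser)) {
        ci <- match(chaser, soc)
        los <- atan2(cur[target, 2] - cur[chaser, 2],
                     cur[target, 1] - cur[chaser, 1])
        phi[chaser] <- phi[chaser] - config$wander_noise * noise[ci] +
          config$chase_gain * .wrap_angle(los - phi[chaser]) +
          0.1 * noise[ci]
        sp[ci] <- sp[ci] * config$chase_boost
        # every tag player near the chaser evades, heading away from it
        dx <- cur[soc, 1] - cur[chaser, 1]
        dy <- cur[soc, 2] - cur[chaser, 2]
        dd <- sqrt(dx^2 + dy^2)
        ev <- which(dd < config$flee_radius & soc != chaser)
        if (length(ev)) {
          away <- atan2(dy[ev], dx[ev])
          gi <- soc[ev]
          phi[gi] <- phi[gi] - config$wander_noise * noise[ev] +
            config$flee_gain * .wrap_angle(away - phi[gi]) +
            0.2 * noise[ev]
        }
      }
      cur[soc, 1] <- cur[soc, 1] + sp * dt * cos(phi[soc])
      cur[soc, 2] <- cur[soc, 2] + sp * dt * sin(phi[soc])
    }
    # --- walls: specular reflection
    for (k in 1:2) {
      low <- cur[, k] < 0
      high <- cur[, k] > arena[k]
      if (any(low)) cur[low, k] <- -cur[low, k]
      if (any(high)) cur[high, k] <- 2 * arena[k] - cur[high, k]
      bounced <- low | high
      if (any(bounced & social)) {
        b <- which(bounced & social)
        phi[b] <- if (k == 1) pi - phi[b] else -phi[b]
      }
    }
    # rotation agents keep their home radius; only the polar angle tracks
    # the realized position
    if (length(rot)) {
      ring_th <- atan2(cur[rot, 2] - center[2], cur[rot, 1] - center[1])
    }
    pos[t, , ] <- cur
    # --- contact: swap roles, draw a fresh target
    if (!is.na(chaser)) {
      chaser_log[t] <- ids[chaser]; target_log[t] <- ids[target]
      d_ct <- sqrt(sum((cur[chaser, ] - cur[target, ])^2))
      if (d_ct < config$contact_radius) {
        contacts[[length(contacts) + 1L]] <-
          data.frame(frame = t, chaser = ids[chaser], target = ids[target])
        new_chaser <- target
        target <- .pick(setdiff(soc, new_chaser))
        chaser <- new_chaser
      }
    }
  }

  traj <- trajectory_set(pos, frame_interval = dt,
                         meta = list(arena = arena, mode = config$mode,
                                     seed = config$seed))
  traj <- compute_velocity(traj)
  contacts <- if (length(contacts)) do.call(rbind, contacts) else
    data.frame(frame = integer(), chaser = character(), target = character())
  list(trajectories = traj,
       truth = list(social = stats::setNames(social, ids),
                    chaser = chaser_log, target = target_log,
                    contacts = contacts),
       config = config)
}

#' Simulate a rotation-dominated session
#'
#' All agents orbit the hall centre with a common angular direction; the
#' regime in which the per-individual angular momentum concentrates near 1.
#'
#' @param config a [sim_config()]; its `p_social` and `mode` are overridden.
#' @return see [simulate_mixed()].
#' @export
simulate_rotation <- function(config = sim_config(mode = "rotation")) {
  config$mode <- "rotation"; config$p_social <- 0
  simulate_mixed(config)
}

#' Simulate a pursuit ("tag") session
#'
#' All agents play tag: one chaser sprints at a fleeing target, roles switch
#' on contact; the regime producing sub-50 cm proximity and approach events
#' with small approaching angles within a second of onset.
#'
#' @param config a [sim_config()]; its `p_social` and `mode` are overridden.
#' @return see [simulate_mixed()].
#' @export
simulate_tag <- function(config = sim_config(mode = "tag")) {
  config$mode <- "tag"; config$p_social <- 1
  simulate_mixed(config)
}
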