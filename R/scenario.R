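#' Marked-step hallway walk scenario
#'
#' Describes the hallway protocol used for gait validation: the subject
#' walks a straight marked course of `path_length` metres, stepping on marks
#' spaced `step_length` apart, out and back `n_round_trips` times past a
#' wall-mounted radar.  The course is radial to the radar at a fixed azimuth
#' (`walk_azimuth`), so an oblique walk projects fully onto range with
#' constant geometry.
#'
#' Within each step the torso speed is modulated by a raised cosine with
#' exactly one speed maximum per step (the stance/swing "sawtooth"):
#' `v(tau) = v_avg * (1 - m * cos(2*pi*tau/T_step))`, which integrates to
#' exactly one `step_length` per step.  When `speed_modulation_depth > 0`
#' the first and last step of every pass use full depth 1 so that the
#' subject smoothly decelerates to standstill at each end of the course
#' before the turn dwell and re-accelerates after it.
#'
#' @param path_length Course length [m]; must be an integer multiple of
#'   `step_length`.  Default 4.2.
#' @param step_length Mark spacing [m]; default 0.7.
#' @param n_round_trips Number of out-and-back round trips; default 3.
#' @param avg_speed Mean walking speed within a pass [m/s]; default 0.87.
#' @param speed_modulation_depth Fractional depth `m` of the per-step speed
#'   modulation, in `[0, 1)`; default 0.5.
#' @param turn_duration Standstill dwell at each course end [s]; default 1.
#' @param start_range Range from the radar to the near end of the course
#'   [m]; default 0.8.
#' @param radar_height Radar mounting height [m]; default 1.2.  Elevation is
#'   collapsed in the simulation (the height motivates the torso-dominant
#'   amplitude weighting); stored as metadata.
#' @param walk_azimuth Azimuth of the (radial) course relative to boresight
#'   [degrees]; default 0.
#' @param sway_amplitude Amplitude of the slow postural/breathing sway of
#'   the torso [m]; default 0.006.  At millimetre wavelengths even a
#'   standing subject is never phase-static; this few-millimetre motion is
#'   what distinguishes a person from true static clutter (and is orders of
#'   magnitude below the range-bin spacing, so it does not affect gait
#'   geometry).
#' @param sway_frequency Sway frequency [Hz]; default 0.35.
#' @param rng_seed Integer seed forwarded to [synthesize_cube()] by
#'   [simulate_walk_cube()].
#' @return An object of class `walk_scenario`.
#' @export
walk_scenario <- function(path_length = 4.2,
                          step_length = 0.7,
                          n_round_trips = 3L,
                          avg_speed = 0.87,
                          speed_modulation_depth = 0.5,
                          turn_duration = 1.0,
                          start_range = 0.8,
                          radar_height = 1.2,
                          walk_azimuth = 0,
                          sway_amplitude = 0.006,
                          sway_frequency = 0.35,
                          rng_seed = 1L) {
  if (path_length <= 0 || step_length <= 0 || start_range <= 0)
    stop("walk_scenario: lengths must be > 0", call. = FALSE)
  n_steps <- path_length / step_length
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("walk_scenario: path_length must be an integer multiple of step_length",
         call. = FALSE)
  if (n_round_trips < 1L)
    stop("walk_scenario: n_round_trips must be >= 1", call. = FALSE)
  if (avg_speed <= 0)
    stop("walk_scenario: avg_speed must be > 0", call. = FALSE)
  if (speed_modulation_depth < 0 || speed_modulation_depth >= 1)
    stop("walk_scenario: speed_modulation_depth must be in [0, 1)", call. = FALSE)
  if (turn_duration < 0)
    stop("walk_scenario: turn_duration must be >= 0", call. = FALSE)
  scn <- list(
    path_length = path_length, step_length = step_length,
    n_round_trips = as.integer(n_round_trips), avg_speed = avg_speed,
    speed_modulation_depth = speed_modulation_depth,
    turn_duration = turn_duration, start_range = start_range,
    radar_height = radar_height, walk_azimuth = walk_azimuth,
    sway_amplitude = sway_amplitude, sway_frequency = sway_frequency,
    rng_seed = as.integer(rng_seed)
  )
  class(scn) <- "walk_scenario"
  scn
}

#' Torso trajectory and ground truth for a walk scenario
#'
#' Builds the closed-form torso trajectory implied by a [walk_scenario()]
#' and its ground-truth record.  The result carries vectorised functions
#' `range_fn(t)` (radial range [m]) and `speed_fn(t)` (signed radial
#' velocity [m/s], away-positive), valid for any `t >= 0` (the subject is
#' stationary before the first and after the last pass), plus the ground
#' truth:
#'
#' * `true_step_times` — instants of the per-step speed maxima (mid-step);
#' * `true_step_points` — radial range at those instants; within a pass the
#'   points are spaced exactly `step_length` apart;
#' * `true_step_count` — `n_round_trips * 2 * path_length / step_length`;
#' * `true_avg_speed` — total distance over elapsed time from the start of
#'   the first pass to the end of the last pass, turn dwells included (the
#'   stopwatch definition used for reference speeds);
#' * `turn_intervals`, `pass_intervals` — [start, end] times [s].
#'
#' @param scn A [walk_scenario()].
#' @return An object of class `torso_trajectory` with elements `range_fn`,
#'   `speed_fn`, `duration`, `ground_truth` and `scenario`.
#' @export
#' @examples
#' tr <- torso_trajectory(walk_scenario())
#' tr$ground_truth$true_step_count   # 36
torso_trajectory <- function(scn) {
  stopifnot(inherits(scn, "walk_scenario"))
  steps_per_pass <- as.integer(round(scn$path_length / scn$step_length))
  n_passes <- 2L * scn$n_round_trips
  t_step <- scn$step_length / scn$avg_speed
  m <- scn$speed_modulation_depth

  # segment table: one row per step or turn, in time order
  seg_t0 <- numeric(0); seg_dur <- numeric(0); seg_type <- character(0)
  seg_x0 <- numeric(0); seg_dir <- numeric(0); seg_depth <- numeric(0)
  t_cur <- 0; x_cur <- 0
  pass_intervals <- matrix(numeric(0), ncol = 2)
  turn_intervals <- matrix(numeric(0), ncol = 2)
  for (p in seq_len(n_passes)) {
    dir <- if (p %% 2L == 1L) 1 else -1    # odd passes walk away from radar
    pass_start <- t_cur
    for (k in seq_len(steps_per_pass)) {
      depth <- if (m > 0 && (k == 1L || k == steps_per_pass)) 1 else m
      seg_t0 <- c(seg_t0, t_cur); seg_dur <- c(seg_dur, t_step)
      seg_type <- c(seg_type, "step"); seg_x0 <- c(seg_x0, x_cur)
      seg_dir <- c(seg_dir, dir); seg_depth <- c(seg_depth, depth)
      t_cur <- t_cur + t_step
      x_cur <- x_cur + dir * scn$step_length
    }
    pass_intervals <- rbind(pass_intervals, c(pass_start, t_cur))
    if (p < n_passes && scn$turn_duration > 0) {
      seg_t0 <- c(seg_t0, t_cur); seg_dur <- c(seg_dur, scn$turn_duration)
      seg_type <- c(seg_type, "turn"); seg_x0 <- c(seg_x0, x_cur)
      seg_dir <- c(seg_dir, 0); seg_depth <- c(seg_depth, 0)
      turn_intervals <- rbind(turn_intervals, c(t_cur, t_cur + scn$turn_duration))
      t_cur <- t_cur + scn$turn_duration
    }
  }
  duration <- t_cur
  segs <- list(t0 = seg_t0, dur = seg_dur, type = seg_type, x0 = seg_x0,
               dir = seg_dir, depth = seg_depth)
  v_avg <- scn$avg_speed
  start_range <- scn$start_range

  position <- function(t) {
    idx <- findInterval(pmax(t, 0), segs$t0)
    idx[idx < 1L] <- 1L
    tau <- pmin(pmax(t - segs$t0[idx], 0), segs$dur[idx])
    is_step <- segs$type[idx] == "step"
    x <- segs$x0[idx]
    if (any(is_step)) {
      i <- which(is_step)
      Ts <- segs$dur[idx[i]]
      x[i] <- x[i] + segs$dir[idx[i]] * v_avg *
        (tau[i] - segs$depth[idx[i]] * Ts / (2 * pi) * sin(2 * pi * tau[i] / Ts))
    }
    x
  }
  # Millimetre-scale torso sway keeps the subject from ever being truly
  # phase-static at mm wavelengths (it decorrelates the static-clutter
  # filter during turn dwells); negligible against the 8.6 cm bin spacing.
  sway <- function(t) {
    if (scn$sway_amplitude <= 0) return(0)
    scn$sway_amplitude * sin(2 * pi * scn$sway_frequency * t + 1)
  }
  range_fn <- function(t) start_range + position(t) + sway(t)
  speed_fn <- function(t) {
    idx <- findInterval(pmax(t, 0), segs$t0)
    idx[idx < 1L] <- 1L
    tau <- t - segs$t0[idx]
    v <- numeric(length(t))
    inside <- tau >= 0 & tau <= segs$dur[idx] & segs$type[idx] == "step"
    if (any(inside)) {
      i <- which(inside)
      Ts <- segs$dur[idx[i]]
      v[i] <- segs$dir[idx[i]] * v_avg *
        (1 - segs$depth[idx[i]] * cos(2 * pi * tau[i] / Ts))
    }
    v
  }

  step_rows <- which(segs$type == "step")
  true_step_times <- segs$t0[step_rows] + segs$dur[step_rows] / 2
  true_step_points <- range_fn(true_step_times)
  walk_elapsed <- pass_intervals[nrow(pass_intervals), 2] - pass_intervals[1, 1]
  truth <- list(
    true_step_times = true_step_times,
    true_step_points = true_step_points,
    true_step_count = length(step_rows),
    true_avg_speed = (n_passes * scn$path_length) / walk_elapsed,
    turn_intervals = turn_intervals,
    pass_intervals = pass_intervals,
    pass_speed = v_avg
  )
  stopifnot(truth$true_step_count ==
              scn$n_round_trips * 2L * steps_per_pass)
  structure(list(range_fn = range_fn, speed_fn = speed_fn,
                 duration = duration, ground_truth = truth, scenario = scn),
            class = "torso_trajectory")
}

#' @export
print.walk_scenario <- function(x, ...) {
  cat("<walk_scenario>\n")
  cat(sprintf("  course: %.1f m, steps of %.2f m, %d round trips\n",
              x$path_length, x$step_length, x$n_round_trips))
  cat(sprintf("  speed %.2f m/s (modulation %.2f), turn dwell %.1f s\n",
              x$avg_speed, x$speed_modulation_depth, x$turn_duration))
  cat(sprintf("  start range %.2f m, azimuth %.0f deg, radar height %.2f m\n",
              x$start_range, x$walk_azimuth, x$radar_height))
  invisible(x)
}
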