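# Discrete-time task engine: cursor/effector kinematics in a bounded
# workspace, hover-dwell target selection with per-target dwell clocks,
# timeouts, the sequential reach-and-grasp and reach-and-release state
# machines, and target placement schedulers.

#' Task configuration
#'
#' Geometry and timing of the cursor/robot paradigms.  The fast shelf
#' variant shortens all phase durations to `fast_scale` of the normal
#' settings, halves the hover dwell to 1 s and raises the robot speed limit
#' to `robot_speed_max`.
#'
#' @param workspace side of the square workspace, cm (origin at the centre).
#' @param hover_radius hover-disc radius, cm.
#' @param hover_duration continuous dwell required for selection, s.
#' @param grasp_tolerance vertical capture tolerance for the 1-D grasp step,
#'   cm.
#' @param max_feedback feedback-phase timeout, s.
#' @param prefeedback,postfeedback,iti phase durations, s.
#' @param robot_speed nominal constant robot speed, cm/s.
#' @param robot_speed_max robot speed limit (fast variant), cm/s.
#' @param fast_scale phase-duration scale of the fast variant.
#' @param tick simulation step, s (the decoder update interval).
#' @param approach_height height above the block at which the planar reach
#'   takes place and from which the grasp descends, cm.
#' @param fast switch applying the fast-variant settings.
#' @return a `task_config` list.
#' @export
task_config <- function(workspace = 32, hover_radius = 3, hover_duration = 2,
                        grasp_tolerance = 2, max_feedback = 12,
                        prefeedback = 3, postfeedback = 1, iti = 2,
                        robot_speed = 8, robot_speed_max = 20,
                        fast_scale = 2 / 3, tick = 0.04,
                        approach_height = 17, fast = FALSE) {
  if (fast) {
    prefeedback <- prefeedback * fast_scale
    postfeedback <- postfeedback * fast_scale
    iti <- iti * fast_scale
    max_feedback <- max_feedback * fast_scale
    hover_duration <- 1
  }
  if (hover_radius >= workspace / 2)
    stop_config("hover_radius must be below half the workspace side")
  if (hover_duration >= max_feedback)
    stop_config("hover_duration must be below max_feedback")
  for (nm in c("max_feedback", "prefeedback", "postfeedback", "iti",
               "hover_duration"))
    check_scalar(get(nm), nm, lower = 0)
  check_scalar(tick, "tick", lower = 0, strict_lower = TRUE)
  structure(list(
    workspace = workspace, hover_radius = hover_radius,
    hover_duration = hover_duration, grasp_tolerance = grasp_tolerance,
    max_feedback = max_feedback, prefeedback = prefeedback,
    postfeedback = postfeedback, iti = iti, robot_speed = robot_speed,
    robot_speed_max = robot_speed_max, fast_scale = fast_scale, tick = tick,
    approach_height = approach_height, fast = fast),
    class = "task_config")
}

#' Fixed target layouts
#'
#' Two lateral targets for the 1-D left/right paradigm; four targets at
#' `+/-12` cm on each axis for the 2-D paradigm; the five-target layout adds
#' a centre target.
#'
#' @param half distance of the edge targets from the centre, cm.
#' @return data.frame with columns `x`, `y`.
#' @export
layout_lr <- function(half = 12) data.frame(x = c(-half, half), y = c(0, 0))

#' @rdname layout_lr
#' @export
layout_fixed4 <- function(half = 12)
  data.frame(x = c(-half, half, 0, 0), y = c(0, 0, half, -half))

#' @rdname layout_lr
#' @export
layout_fixed5 <- function(half = 12)
  rbind(layout_fixed4(half), data.frame(x = 0, y = 0))

validate_layout <- function(layout, config) {
  if (is.null(layout) || nrow(layout) == 0)
    stop_arg("target layout must be non-empty")
  if (nrow(layout) > 1L) {
    d <- as.matrix(stats::dist(layout[, c("x", "y")]))
    diag(d) <- Inf
    if (any(d <= 2 * config$hover_radius))
      stop_config("target layout has overlapping hover discs")
  }
  invisible(layout)
}

# Number of whole tick intervals required for the hover dwell (rounded
# up).  The dwell clock runs between samples: a target is selected at the
# first tick lying >= hover_duration after the entry tick, so the
# continuously-inside time never undercuts hover_duration.
hover_ticks <- function(config) {
  if (config$hover_duration <= 0) return(0L)
  as.integer(ceiling(config$hover_duration / config$tick - 1e-9))
}

#' Run one feedback-phase trial
#'
#' Integrates `pos <- pos + v * tick` (clipped to the workspace).  A target
#' is selected when the position stays continuously within `hover_radius` of
#' its centre for `hover_duration`; leaving the disc resets that target's
#' dwell clock.  With `hover_duration = 0` selection fires on the first disc
#' *entry* (a transition from outside to inside; a cursor starting inside a
#' disc must leave it first).  Outcome is `HIT` if the selected target is
#' the cued one, `MISS` for any other target, `ABORT` at `max_feedback`.
#'
#' @param control_source either `function(state) -> c(vx, vy)` called once
#'   per tick with `state = list(t, pos, tick_index, cued, layout)`, or a
#'   precomputed matrix of per-tick velocities (n x 2).
#' @param layout data.frame of target centres (`x`, `y`).
#' @param cued index of the cued target in `layout`.
#' @param config a [task_config()].
#' @param start starting position (workspace centre by default).
#' @param axis optionally restrict motion to `"x"` (1-D paradigms).
#' @param record_trajectory keep the per-tick trajectory.
#' @return a `trial_result` list: `outcome`, `time_to_hit`,
#'   `selected_target`, `trajectory` (or `NULL`).
#' @export
run_trial <- function(control_source, layout, cued, config = task_config(),
                      start = c(0, 0), axis = NULL,
                      record_trajectory = FALSE) {
  validate_layout(layout, config)
  if (cued < 1 || cued > nrow(layout)) stop_arg("invalid cued target index")
  tick <- config$tick
  n_max <- as.integer(round(config$max_feedback / tick))
  need <- hover_ticks(config)
  half <- config$workspace / 2
  tx <- layout$x; ty <- layout$y
  nt <- nrow(layout)
  pos <- start
  d0 <- sqrt((pos[1] - tx)^2 + (pos[2] - ty)^2)
  inside_prev <- d0 <= config$hover_radius
  # entry-based (no-hover) selection requires a transition from outside:
  # discs containing the start position must be exited first.  With a dwell
  # requirement, holding still inside the disc is itself the selection
  # gesture, so the dwell clock may start immediately.
  eligible <- if (need == 0L) !inside_prev else rep(TRUE, nt)
  dwell <- as.integer(inside_prev & eligible)
  is_fun <- is.function(control_source)
  traj <- if (record_trajectory) matrix(NA_real_, n_max, 3) else NULL

  for (k in seq_len(n_max)) {
    v <- if (is_fun)
      control_source(list(t = (k - 1) * tick, pos = pos, tick_index = k,
                          cued = cued, layout = layout))
    else control_source[k, ]
    if (identical(axis, "x")) v[2] <- 0
    pos <- pmin(pmax(pos + v * tick, -half), half)
    if (record_trajectory) traj[k, ] <- c(k * tick, pos)
    d <- sqrt((pos[1] - tx)^2 + (pos[2] - ty)^2)
    inside <- d <= config$hover_radius
    eligible <- eligible | !inside
    active <- inside & eligible
    dwell <- ifelse(active, dwell + 1L, 0L)
    entered <- active & !inside_prev
    inside_prev <- inside
    done <- if (need == 0L) entered else dwell >= need + 1L
    if (any(done)) {
      sel <- which(done)
      if (length(sel) > 1L) sel <- sel[which.min(d[sel])]  # nearer target
      return(structure(list(
        outcome = if (sel == cued) "HIT" else "MISS",
        time_to_hit = k * tick, selected_target = sel,
        trajectory = if (record_trajectory) traj[seq_len(k), , drop = FALSE]
                     else NULL),
        class = "trial_result"))
    }
  }
  structure(list(outcome = "ABORT", time_to_hit = config$max_feedback,
                 selected_target = NA_integer_,
                 trajectory = traj), class = "trial_result")
}

#' Run the 1-D vertical grasp/release step
#'
#' A two-outcome trial driven by the vertical control axis alone: the
#' effector starts `approach_height` cm above the block and must remain
#' within `grasp_tolerance` of the block centre for `hover_duration`
#' (`HIT`), or the step times out (`ABORT`).
#'
#' @param control_source as in [run_trial()]; only `vy` is used and negative
#'   `vy` descends.
#' @param config a [task_config()].
#' @param start_z starting height above the block centre, cm.
#' @return a `trial_result` with `selected_target = 1` on success.
#' @export
run_vertical_trial <- function(control_source, config = task_config(),
                               start_z = config$approach_height) {
  tick <- config$tick
  n_max <- as.integer(round(config$max_feedback / tick))
  need <- hover_ticks(config)
  z <- start_z
  dwell <- 0L
  was_out <- abs(z) > config$grasp_tolerance
  is_fun <- is.function(control_source)
  for (k in seq_len(n_max)) {
    v <- if (is_fun)
      control_source(list(t = (k - 1) * tick, pos = c(0, z), tick_index = k,
                          cued = 1L, layout = data.frame(x = 0, y = 0)))
    else control_source[k, ]
    z <- max(min(z + v[2] * tick, config$approach_height + 5), -5)
    inside <- abs(z) <= config$grasp_tolerance
    was_out <- was_out || !inside
    dwell <- if (inside && was_out) dwell + 1L else 0L
    done <- if (need == 0L) inside && was_out else dwell >= need + 1L
    if (done)
      return(structure(list(outcome = "HIT", time_to_hit = k * tick,
                            selected_target = 1L, trajectory = NULL),
                       class = "trial_result"))
  }
  structure(list(outcome = "ABORT", time_to_hit = config$max_feedback,
                 selected_target = NA_integer_, trajectory = NULL),
            class = "trial_result")
}

#' Reach-and-grasp sequence (planar reach, then vertical grasp)
#'
#' Step 1 is a 2-D [run_trial()]; on a `HIT`, step 2 is the 1-D vertical
#' grasp.  Any failure terminates the sequence.
#'
#' @param control_factory `function(step_kind, step_index)` returning a
#'   control source for each step (`step_kind` is `"reach"` or `"grasp"`).
#' @param layout,cued,config as in [run_trial()].
#' @param start starting position of the planar reach.
#' @return a `sequence_result`: `steps` (list of trial results),
#'   `completed`, `total_time`.
#' @export
run_grasp_sequence <- function(control_factory, layout, cued,
                               config = task_config(), start = c(0, 0)) {
  s1 <- run_trial(control_factory("reach", 1L), layout, cued, config,
                  start = start)
  steps <- list(s1)
  completed <- FALSE
  if (s1$outcome == "HIT") {
    s2 <- run_vertical_trial(control_factory("grasp", 2L), config)
    steps[[2]] <- s2
    completed <- s2$outcome == "HIT"
  }
  structure(list(steps = steps, completed = completed,
                 total_time = sum(vapply(steps, `[[`, numeric(1),
                                         "time_to_hit"))),
            class = "sequence_result")
}

#' Reach-and-release shelf sequence
#'
#' Four sequential steps: planar reach on the table plane (3 targets),
#' vertical grasp, planar reach on the shelf plane (6 positions), vertical
#' release.  The first failed step terminates the attempt; callers restart
#' the whole sequence.
#'
#' @param control_factory `function(step_kind, step_index)` with
#'   `step_kind` in `"reach"`, `"grasp"`, `"shelf_reach"`, `"release"`.
#' @param table_layout 3-target table layout.
#' @param shelf_layout 6-position shelf layout (x-z plane).
#' @param cued_pair `c(table_index, shelf_index)`.
#' @param config a [task_config()].
#' @return a `sequence_result` with up to 4 steps.
#' @export
run_shelf_sequence <- function(control_factory, table_layout, shelf_layout,
                               cued_pair, config = task_config()) {
  steps <- list()
  kinds <- c("reach", "grasp", "shelf_reach", "release")
  for (i in 1:4) {
    src <- control_factory(kinds[i], i)
    r <- switch(kinds[i],
                reach = run_trial(src, table_layout, cued_pair[1], config),
                grasp = run_vertical_trial(src, config),
                shelf_reach = run_trial(src, shelf_layout, cued_pair[2],
                                        config),
                release = run_vertical_trial(src, config))
    steps[[i]] <- r
    if (r$outcome != "HIT") break
  }
  structure(list(steps = steps,
                 completed = length(steps) == 4L &&
                   all(vapply(steps, `[[`, character(1), "outcome") == "HIT"),
                 total_time = sum(vapply(steps, `[[`, numeric(1),
                                         "time_to_hit"))),
            class = "sequence_result")
}

#' Default shelf layouts
#'
#' Three equally spaced table positions (set forward of the workspace
#' centre, where the effector parks between steps) and a 3 x 2 grid of
#' shelf positions on the vertical plane.
#' @param config a [task_config()].
#' @return data.frame with columns `x`, `y`.
#' @export
layout_shelf_table <- function(config = task_config())
  data.frame(x = c(-10, 0, 10), y = c(-8, -8, -8))

#' @rdname layout_shelf_table
#' @export
layout_shelf_shelf <- function(config = task_config())
  data.frame(x = rep(c(-10, 0, 10), 2), y = rep(c(6, -6), each = 3))

# --- random target placement -------------------------------------------

#' Default workspace exclusion zones
#'
#' Two corner triangles (top-left and bottom-right) standing in for the
#' regions a real arm cannot reach, each covering `area_frac` of the
#' workspace.
#'
#' @param workspace workspace side, cm.
#' @param area_frac fraction of the workspace area per triangle.
#' @return list of polygons (data.frames with `x`, `y`).
#' @export
default_exclusions <- function(workspace = 32, area_frac = 0.1) {
  h <- workspace / 2
  L <- sqrt(2 * area_frac * workspace^2)
  list(top_left = data.frame(x = c(-h, -h, -h + L), y = c(h, h - L, h)),
       bottom_right = data.frame(x = c(h, h, h - L), y = c(-h, -h + L, -h)))
}

point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly$x[i]; yi <- poly$y[i]
    xj <- poly$x[j]; yj <- poly$y[j]
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside <- !inside
    j <- i
  }
  inside
}

#' Quadrant-balanced random target scheduler
#'
#' Cycles the four workspace quadrants in a freshly shuffled order per block
#' of four placements; within the drawn quadrant the position is uniform
#' outside the configured exclusion polygons (corner regions unreachable by
#' the arm).
#'
#' @param config a [task_config()].
#' @param exclusions list of polygons (data.frames with `x`, `y`), or
#'   `NULL` for none.
#' @param seed integer seed.
#' @return a scheduler environment for [place_random_target()].
#' @export
target_scheduler <- function(config = task_config(),
                             exclusions = default_exclusions(config$workspace),
                             seed = 1L) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$exclusions <- exclusions
  st$queue <- integer(0)
  with_seed(seed, st$rng <- get(".Random.seed", envir = globalenv()))
  st
}

#' Draw the next random target position
#'
#' @param scheduler a [target_scheduler()] environment.
#' @return list with `position` (`c(x, y)`) and `quadrant`.
#' @export
place_random_target <- function(scheduler) {
  cfg <- scheduler$config
  h <- cfg$workspace / 2
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", scheduler$rng, envir = globalenv())
  on.exit({
    scheduler$rng <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  if (length(scheduler$queue) == 0)
    scheduler$queue <- sample(4L)
  q <- scheduler$queue[1]
  scheduler$queue <- scheduler$queue[-1]
  xr <- switch(q, c(0, h), c(-h, 0), c(-h, 0), c(0, h))
  yr <- switch(q, c(0, h), c(0, h), c(-h, 0), c(-h, 0))
  for (i in 1:10000) {
    px <- stats::runif(1, xr[1], xr[2])
    py <- stats::runif(1, yr[1], yr[2])
    blocked <- any(vapply(scheduler$exclusions, function(pg)
      point_in_polygon(px, py, pg), logical(1)))
    if (!blocked)
      return(list(position = c(px, py), quadrant = q))
  }
  stop_config(sprintf("exclusion zones cover quadrant %d", q))
}

#' Rate-limited robot tracking of a commanded position
#'
#' The effector chases the commanded (virtual-cursor) position at up to the
#' configured speed limit; when the command outruns the limit the effector
#' lags and catches up at the limit speed.
#'
#' @param effector_pos current effector position `c(x, y)`.
#' @param commanded_pos commanded position `c(x, y)`.
#' @param config a [task_config()]; the limit is `robot_speed_max` in the
#'   fast variant and `robot_speed` otherwise.
#' @return list with the new `position` and the remaining `lag` distance.
#' @export
robot_track <- function(effector_pos, commanded_pos,
                        config = task_config()) {
  limit <- if (config$fast) config$robot_speed_max else config$robot_speed
  err <- commanded_pos - effector_pos
  dist <- sqrt(sum(err^2))
  step <- min(dist, limit * config$tick)
  newp <- if (dist > 0) effector_pos + err / dist * step else effector_pos
  list(position = newp, lag = sqrt(sum((commanded_pos - newp)^2)))
}

# --- control policies ---------------------------------------------------

#' Ideal control policy
#'
#' Heads straight for the cued target at a constant speed and halts at its
#' centre (the last step is shortened to land exactly on the centre).
#'
#' @param speed cm/s.
#' @param config a [task_config()].
#' @return a control-source function for [run_trial()].
#' @export
policy_ideal <- function(speed = NULL, config = task_config()) {
  if (is.null(speed)) speed <- config$robot_speed
  tick <- config$tick
  function(state) {
    tgt <- c(state$layout$x[state$cued], state$layout$y[state$cued])
    err <- tgt - state$pos
    d <- sqrt(sum(err^2))
    if (d == 0) return(c(0, 0))
    err / d * min(speed, d / tick)
  }
}

#' Ideal vertical (grasp/release) policy
#'
#' Descends at constant speed and stops at the block centre.
#'
#' @inheritParams policy_ideal
#' @return a control-source function for [run_vertical_trial()].
#' @export
policy_ideal_vertical <- function(speed = NULL, config = task_config()) {
  if (is.null(speed)) speed <- config$robot_speed
  tick <- config$tick
  function(state) {
    z <- state$pos[2]
    c(0, -sign(z) * min(speed, abs(z) / tick))
  }
}

#' Unbiased random-walk control policy
#'
#' I.i.d. zero-mean Gaussian velocity per tick on each axis; the empirical
#' chance-level proxy for a resting subject.  Draws from the calling RNG
#' stream (seed with `set.seed()` or [with_seed()]).
#'
#' @param sigma per-axis velocity standard deviation, cm/s.
#' @return a control-source function.
#' @export
policy_random_walk <- function(sigma = 20) {
  function(state) stats::rnorm(2, 0, sigma)
}
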