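# Task engine: hover-dwell selection, timeouts, kinematic closed forms,
# sequences, placement scheduler, robot tracking.

test_that("ideal-policy trial time follows the kinematic closed form", {
  # entry after ceil((d - r)/(speed*tick)) ticks, then hover_duration of
  # whole tick intervals continuously inside
  cases <- list(list(d = 12, speed = 8, hover = 2),
                list(d = 12, speed = 4, hover = 2),
                list(d = 12, speed = 8, hover = 1))
  for (cs in cases) {
    cfg <- task_config(hover_duration = cs$hover)
    lay <- layout_lr(cs$d)
    r <- run_trial(policy_ideal(speed = cs$speed, config = cfg), lay, 2,
                   cfg, axis = "x")
    entry <- ceiling((cs$d - cfg$hover_radius) / (cs$speed * cfg$tick) - 1e-9)
    expected <- (entry + round(cs$hover / cfg$tick)) * cfg$tick
    expect_equal(r$outcome, "HIT")
    expect_equal(r$time_to_hit, expected, tolerance = 1e-9)
  }
  # vertical grasp: descent from approach height to grasp tolerance
  cfg <- task_config()
  rv <- run_vertical_trial(policy_ideal_vertical(config = cfg), cfg)
  entry <- ceiling((cfg$approach_height - cfg$grasp_tolerance) /
                     (cfg$robot_speed * cfg$tick) - 1e-9)
  expect_equal(rv$outcome, "HIT")
  expect_equal(rv$time_to_hit, (entry + round(2 / cfg$tick)) * cfg$tick)
})

test_that("zero velocity aborts at exactly max_feedback", {
  cfg <- task_config()
  r <- run_trial(const_velocity(0, 0, 300), layout_fixed4(), 1, cfg)
  expect_equal(r$outcome, "ABORT")
  expect_equal(r$time_to_hit, 12)
  expect_true(is.na(r$selected_target))
})

test_that("leaving the hover disc resets the dwell clock", {
  cfg <- task_config()  # tick 0.04, hover 2 s -> 50 intervals
  v <- 25               # 1 cm per tick
  # 9 ticks in (x = 9, on the disc edge of the (12,0) target), wait 47
  # ticks (1.88 s, not enough), duck out for 2 ticks, back in 2 ticks,
  # then wait out the full dwell
  vel <- rbind(const_velocity(v, 0, 9), const_velocity(0, 0, 47),
               const_velocity(-v, 0, 2), const_velocity(v, 0, 2),
               const_velocity(0, 0, 60))
  r <- run_trial(vel, layout_lr(), 2, cfg, axis = "x")
  expect_equal(r$outcome, "HIT")
  # re-entry at tick 60; selection 50 intervals later
  expect_equal(r$time_to_hit, (60 + 50) * cfg$tick)
})

test_that("selection always takes at least hover_duration inside the disc", {
  cfg <- task_config()
  lay <- layout_fixed4()
  n_selected <- 0
  for (s in 1:30) {
    # noisy goal-directed controller: drifts into the disc, jitters around
    # its boundary, occasionally falls back out (adversarial grazing)
    vel <- with_seed(600 + s, matrix(rnorm(600, 0, 10), 300, 2))
    r <- run_trial(function(state) {
      tgt <- c(lay$x[1], lay$y[1])
      err <- tgt - state$pos
      err * 0.6 + vel[state$tick_index, ]
    }, lay, 1, cfg, record_trajectory = TRUE)
    if (r$outcome %in% c("HIT", "MISS")) {
      n_selected <- n_selected + 1
      sel <- r$selected_target
      tgt <- c(layout_fixed4()$x[sel], layout_fixed4()$y[sel])
      tr <- r$trajectory
      need <- round(cfg$hover_duration / cfg$tick) + 1   # samples inside
      last <- tr[(nrow(tr) - need + 1):nrow(tr), , drop = FALSE]
      d <- sqrt((last[, 2] - tgt[1])^2 + (last[, 3] - tgt[2])^2)
      expect_true(all(d <= cfg$hover_radius + 1e-9))
      expect_gte(r$time_to_hit, cfg$hover_duration)
    }
  }
  expect_gt(n_selected, 10)
})

test_that("position is always clipped to the workspace", {
  cfg <- task_config()
  vel <- with_seed(77, matrix(rnorm(600, 0, 200), 300, 2))
  r <- run_trial(vel, layout_fixed4(), 1, cfg, record_trajectory = TRUE)
  expect_true(all(abs(r$trajectory[, 2:3]) <= cfg$workspace / 2 + 1e-9))
})

test_that("start-inside discs: entry required without hover, dwell with", {
  cfg <- task_config()
  cfg$hover_duration <- 0
  # no-hover selection is entry-based: a motionless cursor sitting on the
  # centre target never *enters* it, so the trial times out
  r <- run_trial(const_velocity(0, 0, 300), layout_fixed5(), 5, cfg)
  expect_equal(r$outcome, "ABORT")
  # with a dwell requirement, holding still inside the cued disc is the
  # selection gesture itself
  cfg2 <- task_config()
  r2 <- run_trial(const_velocity(0, 0, 300), layout_fixed5(), 5, cfg2)
  expect_equal(r2$outcome, "HIT")
  expect_gte(r2$time_to_hit, cfg2$hover_duration)
  expect_lte(r2$time_to_hit, cfg2$hover_duration + 2 * cfg2$tick)
})

test_that("layout validation rejects overlap and empty layouts", {
  cfg <- task_config()
  expect_error(run_trial(const_velocity(0, 0, 10),
                         data.frame(x = c(0, 4), y = c(0, 0)), 1, cfg),
               class = "mubci_config_error")
  expect_error(run_trial(const_velocity(0, 0, 10),
                         data.frame(x = numeric(0), y = numeric(0)), 1, cfg),
               class = "mubci_argument_error")
})

test_that("robot tracking obeys the speed limit with closed-form catch-up", {
  cfg <- task_config()
  # slow command: zero lag
  tr <- robot_track(c(0, 0), c(0.2, 0), cfg)
  expect_equal(tr$lag, 0)
  expect_equal(tr$position, c(0.2, 0))
  # 10 cm step at 8 cm/s: catch-up in ceil(10/8/tick) ticks
  chase <- function(cfg, step) {
    pos <- c(0, 0); k <- 0
    repeat {
      k <- k + 1
      t <- robot_track(pos, c(step, 0), cfg)
      pos <- t$position
      if (t$lag == 0) return(k)
    }
  }
  expect_equal(chase(cfg, 10), ceiling(10 / 8 / cfg$tick))
  fast <- task_config(fast = TRUE)
  expect_equal(chase(fast, 10), ceiling(10 / 20 / fast$tick))
})

test_that("random-walk control selects symmetric targets uniformly", {
  cfg <- task_config()
  cfg$hover_duration <- 0
  lay <- layout_fixed4()
  sel <- integer(0)
  with_seed(2024, {
    for (i in 1:2000) {
      vel <- matrix(rnorm(600, 0, 20), 300, 2)
      r <- run_trial(vel, lay, 1, cfg)
      expect_true(r$outcome %in% c("HIT", "MISS", "ABORT"))
      if (!is.na(r$selected_target)) sel <- c(sel, r$selected_target)
    }
  })
  expect_gt(length(sel), 1000)
  p <- stats::chisq.test(table(factor(sel, levels = 1:4)))$p.value
  expect_gt(p, 0.001)
})

test_that("random target scheduler balances quadrants and honours exclusions", {
  cfg <- task_config()
  sched <- target_scheduler(cfg, seed = 5)
  qs <- integer(400); pts <- matrix(0, 400, 2)
  for (i in 1:400) {
    p <- place_random_target(sched)
    qs[i] <- p$quadrant; pts[i, ] <- p$position
  }
  expect_equal(as.numeric(table(qs)), rep(100, 4))
  for (pg in default_exclusions()) {
    inside <- vapply(seq_len(400), function(i)
      mubci:::point_in_polygon(pts[i, 1], pts[i, 2], pg), logical(1))
    expect_false(any(inside))
  }
  # without exclusions the placement is uniform on the square
  ps <- vapply(1:10, function(s) {
    sc <- target_scheduler(cfg, exclusions = list(), seed = 100 + s)
    xy <- t(vapply(1:1600, function(i) place_random_target(sc)$position,
                   numeric(2)))
    gx <- cut(xy[, 1], seq(-16, 16, length.out = 5))
    gy <- cut(xy[, 2], seq(-16, 16, length.out = 5))
    suppressWarnings(stats::chisq.test(table(gx, gy))$p.value)
  }, numeric(1))
  expect_gt(median(ps), 0.01)
  # a quadrant fully covered by exclusions is a configuration error
  full_q1 <- data.frame(x = c(0, 16, 16, 0), y = c(0, 0, 16, 16))
  sc <- target_scheduler(cfg, exclusions = list(full_q1), seed = 1)
  got_error <- FALSE
  for (i in 1:4) {
    got_error <- tryCatch({ place_random_target(sc); FALSE },
                          mubci_config_error = function(e) TRUE)
    if (got_error) break
  }
  expect_true(got_error)
})

test_that("grasp sequence composes reach and vertical steps", {
  cfg <- task_config()
  ideal <- function(kind, idx)
    if (kind == "grasp") policy_ideal_vertical(config = cfg)
    else policy_ideal(config = cfg)
  s <- run_grasp_sequence(ideal, layout_fixed4(), 3, cfg)
  expect_true(s$completed)
  expect_equal(vapply(s$steps, `[[`, "", "outcome"), c("HIT", "HIT"))
  # a wrong first selection terminates the sequence after one step
  wrong <- function(kind, idx) {
    force(kind)
    function(state) {
      tgt <- c(state$layout$x[1], state$layout$y[1])   # heads to target 1
      err <- tgt - state$pos
      d <- sqrt(sum(err^2))
      if (d == 0) c(0, 0) else err / d * min(8, d / cfg$tick)
    }
  }
  s2 <- run_grasp_sequence(wrong, layout_fixed4(), 3, cfg)
  expect_false(s2$completed)
  expect_length(s2$steps, 1)
  expect_equal(s2$steps[[1]]$outcome, "MISS")
})

test_that("shelf sequence runs four steps and stops at the first failure", {
  cfg <- task_config()
  tl <- layout_shelf_table(cfg); sl <- layout_shelf_shelf(cfg)
  ideal <- function(kind, idx)
    if (kind %in% c("grasp", "release")) policy_ideal_vertical(config = cfg)
    else policy_ideal(config = cfg)
  s <- run_shelf_sequence(ideal, tl, sl, c(2, 5), cfg)
  expect_true(s$completed)
  expect_length(s$steps, 4)
  # failure at step 3 (zero velocity on the shelf reach)
  fail3 <- function(kind, idx)
    if (kind == "shelf_reach") const_velocity(0, 0, 300)
    else ideal(kind, idx)
  s3 <- run_shelf_sequence(fail3, tl, sl, c(2, 5), cfg)
  expect_false(s3$completed)
  expect_length(s3$steps, 3)
  expect_equal(s3$steps[[3]]$outcome, "ABORT")
  # fast variant: shorter ideal completion
  fastc <- task_config(fast = TRUE)
  idealf <- function(kind, idx)
    if (kind %in% c("grasp", "release"))
      policy_ideal_vertical(speed = fastc$robot_speed_max, config = fastc)
    else policy_ideal(speed = fastc$robot_speed_max, config = fastc)
  sf <- run_shelf_sequence(idealf, tl, sl, c(2, 5), fastc)
  expect_true(sf$completed)
  expect_lt(sf$total_time, s$total_time)
  expect_equal(fastc$hover_duration, 1)
  expect_equal(fastc$max_feedback, 8)
})
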