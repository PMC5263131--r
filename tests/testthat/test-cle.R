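test_that("the lifecycle transition table is exactly the declared one", {
  tab <- lifecycle_table()
  states <- c("created", "initialized", "started", "paused", "stopped", "halted")
  expected <- rbind(
    data.frame(from = c("created", "stopped", "halted"), action = "initialize", to = "initialized"),
    data.frame(from = c("initialized", "paused"), action = "start", to = "started"),
    data.frame(from = "started", action = "pause", to = "paused"),
    data.frame(from = c("initialized", "started", "paused"), action = "stop", to = "stopped"),
    data.frame(from = states, action = "fail", to = "halted")
  )
  key <- function(d) sort(paste(d$from, d$action, d$to))
  expect_identical(key(as.data.frame(tab)), key(expected))
  # fail is legal from every state
  expect_setequal(tab$from[tab$action == "fail"], states)
})

test_that("illegal transitions are rejected explicitly, state unchanged", {
  sim <- simulation(probe_experiment())
  expect_error(sim_start(sim), class = "neuroloop_lifecycle_error") # created --start-->
  expect_equal(sim$state, "created")
  sim <- sim_initialize(sim)
  expect_equal(sim$state, "initialized")
  expect_equal(sim$time, 0)
  expect_error(sim_transition(sim, "initialize"), class = "neuroloop_lifecycle_error")
  sim <- sim_start(sim)
  sim <- sim_pause(sim)
  sim <- sim_start(sim)
  sim <- sim_stop(sim)
  expect_error(sim_step(sim), class = "neuroloop_lifecycle_error")
  expect_equal(sim_transition(sim, "fail")$state, "halted")
})

test_that("an invalid config halts at initialize with a diagnostic", {
  cfg <- probe_experiment(tfs = list(
    transfer_function("bad", "robot2neuron", function(ctx) list(),
                      subscriptions = "bot/camera",
                      devices = list(g = list(kind = "poisson_generator", target = "no_such_pop")))
  ))
  sim <- sim_initialize(simulation(cfg))
  expect_equal(sim$state, "halted")
  expect_match(sim$diagnostics, "no_such_pop")
})

test_that("device input written by a TF at step n acts on the brain at step n+1", {
  # impulse TF: huge DC at the first evaluation, then zero
  tf <- transfer_function(
    "impulse", "robot2neuron", subscriptions = "bot/camera",
    devices = list(d = list(kind = "dc_generator", target = "p", amplitude = 0)),
    state = list(fired = FALSE),
    body = function(ctx) {
      amp <- if (ctx$state$fired) 0 else 100
      list(devices = list(d = list(amplitude = amp)), state = list(fired = TRUE))
    }
  )
  sim <- started_sim(probe_experiment(tfs = list(tf)))
  sim <- sim_step(sim) # step 1: TF evaluated at its end, output buffered
  expect_equal(nrow(spike_records(sim$net)), 0)
  sim <- sim_step(sim) # step 2: impulse applied, neuron spikes in (20, 40]
  sp <- spike_records(sim$net)
  expect_gt(nrow(sp), 0)
  expect_gt(min(sp$time_ms), 20)
  expect_lte(min(sp$time_ms), 40)
})

test_that("motor command published by a TF at step n moves the robot at step n+1", {
  tf <- transfer_function(
    "drive", "robot2robot", subscriptions = "bot/pose",
    publications = "bot/wheel_cmd",
    body = function(ctx) {
      list(publish = list("bot/wheel_cmd" = list(left = 1, right = 1)))
    }
  )
  sim <- started_sim(probe_experiment(tfs = list(tf)))
  sim <- sim_step(sim) # command produced at the end of step 1
  expect_equal(sim$world$robots$bot$pose$x, 0) # not yet
  sim <- sim_step(sim)
  expect_equal(sim$world$robots$bot$pose$x, 0.02, tolerance = 1e-12) # 1 m/s for 20 ms
})

test_that("both clocks agree exactly after every step", {
  sim <- started_sim(probe_experiment())
  sim <- run_steps(sim, 7)
  expect_identical(sim$time, 7 * 20)
  expect_identical(sim$world$time, 7 * 20)
  expect_identical(sim$net$time, 7 * 20)
})

test_that("pause/resume is trajectory-neutral under a fixed seed", {
  mk_cfg <- function() {
    cfg <- load_experiment("braitenberg", seed = 5)
    cfg$events <- list()
    cfg$world$screens$screen_right$color <- c(255, 0, 0)
    cfg
  }
  fingerprint <- function(sim) {
    list(spike_records(sim$net), sim$world$robots$husky$pose, sim$net$v)
  }
  a <- run_steps(started_sim(mk_cfg()), 100)
  b <- started_sim(mk_cfg())
  b <- run_steps(b, 40)
  b <- sim_pause(b)
  b <- sim_start(b)
  b <- run_steps(b, 60)
  expect_identical(fingerprint(a), fingerprint(b))
})

test_that("parametrized reset restores only the selected parts", {
  cfg <- load_experiment("braitenberg", seed = 2)
  sim <- run_steps(started_sim(cfg), 120) # past the timed event
  expect_error(sim_reset(sim, character(0)), "non-empty")
  expect_error(sim_reset(sim, "time"), "unknown reset")

  moved <- sim$world$robots$husky$pose
  expect_false(isTRUE(all.equal(moved$theta, 0)))
  red <- sim$world$screens$screen_right$color

  s1 <- sim_reset(sim, "robot_pose")
  expect_equal(unlist(s1$world$robots$husky$pose), c(x = 0, y = 0, theta = 0))
  expect_identical(s1$net$v, sim$net$v) # brain untouched
  expect_identical(s1$world$screens$screen_right$color, red) # environment untouched
  expect_identical(s1$time, sim$time) # simulated time preserved
  expect_identical(s1$monitor, sim$monitor) # logs preserved

  s2 <- sim_reset(sim, "brain")
  expect_identical(s2$world$robots$husky$pose, moved)
  expect_equal(unique(s2$net$v), -70)
  expect_equal(sum(s2$net$queue), 0)

  s3 <- sim_reset(sim, c("robot_pose", "brain", "environment"))
  fresh <- sim_initialize(simulation(load_experiment("braitenberg", seed = 2)))
  expect_equal(s3$net$v, fresh$net$v)
  expect_equal(s3$world$robots$husky$pose, fresh$world$robots$husky$pose)
  expect_equal(s3$world$screens$screen_right$color, fresh$world$screens$screen_right$color)
  expect_gt(s3$time, 0) # but time and logs survive
})

test_that("runtime edits swap at the next step boundary and fail atomically", {
  tf_slow <- transfer_function(
    "drive", "robot2robot", subscriptions = "bot/pose", publications = "bot/wheel_cmd",
    body = function(ctx) list(publish = list("bot/wheel_cmd" = list(left = 0.1, right = 0.1)))
  )
  tf_fast <- transfer_function(
    "drive", "robot2robot", subscriptions = "bot/pose", publications = "bot/wheel_cmd",
    body = function(ctx) list(publish = list("bot/wheel_cmd" = list(left = 1, right = 1)))
  )
  sim <- started_sim(probe_experiment(tfs = list(tf_slow)))
  sim <- run_steps(sim, 3)
  x3 <- sim$world$robots$bot$pose$x
  sim <- sim_set_tf(sim, tf_fast)
  sim <- sim_step(sim) # swap at boundary; buffered slow command still applies
  expect_equal(sim$world$robots$bot$pose$x - x3, 0.1 * 0.02, tolerance = 1e-12)
  sim <- sim_step(sim)
  sim <- sim_step(sim)
  expect_equal(sim$world$robots$bot$pose$x - x3, 0.002 + 2 * 0.02, tolerance = 1e-12)

  # invalid brain is rejected and the simulation continues untouched
  expect_error(
    sim_set_brain(sim, list(populations = list(q = list(size = 0)))),
    "size"
  )
  expect_equal(sim$state, "started")
  sim <- sim_step(sim)
  expect_equal(sim$state, "started")

  # removing the only motor TF: the robot coasts on its last command
  sim <- sim_remove_tf(sim, "drive")
  x_before <- sim$world$robots$bot$pose$x
  sim <- run_steps(sim, 2)
  expect_equal(sim$world$robots$bot$pose$x - x_before, 2 * 0.02, tolerance = 1e-12)
})

test_that("a TF fault halts the simulation through the lifecycle", {
  tf_boom <- transfer_function(
    "boom", "robot2robot", subscriptions = "bot/pose",
    state = list(n = 0),
    body = function(ctx) {
      if (ctx$state$n >= 2) stop("deliberate fault")
      list(state = list(n = ctx$state$n + 1))
    }
  )
  sim <- started_sim(probe_experiment(tfs = list(tf_boom)))
  sim <- run_steps(sim, 2)
  expect_equal(sim$state, "started")
  sim <- sim_step(sim)
  expect_equal(sim$state, "halted")
  expect_match(sim$diagnostics, "deliberate fault")
})

test_that("whole-loop runs are deterministic: same seed, byte-identical CSVs", {
  dump <- function(seed, dir) {
    run <- run_braitenberg(duration_ms = 2000, seed = seed)
    export_run(run, dir)
  }
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  dump(9, d1)
  dump(9, d2)
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})
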