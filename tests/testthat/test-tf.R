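noop_body <- function(ctx) list()

test_that("TF kind discipline is enforced at declaration and registration", {
  expect_error(
    transfer_function("bad", "robot2robot", noop_body,
                      devices = list(d = list(kind = "dc_generator", target = "p"))),
    "must not touch devices"
  )
  expect_error(
    transfer_function("bad", "robot2neuron", noop_body, subscriptions = "t"),
    "input-side device"
  )
  expect_error(
    transfer_function("bad", "neuron2robot", noop_body,
                      devices = list(d = list(kind = "leaky_integrator", target = "p"))),
    "publication"
  )
  expect_error(
    transfer_function("bad", "neuron2monitor", noop_body,
                      publications = "x/wheel_cmd", monitors = "m"),
    "monitor sink"
  )
  expect_error(transfer_function("bad", "teleport", noop_body), "unknown TF kind")

  net <- build_network(list(populations = list(p = list(size = 2))))
  world <- simple_world()
  tf_bad_topic <- transfer_function(
    "t", "robot2neuron", noop_body, subscriptions = "ghost/topic",
    devices = list(g = list(kind = "poisson_generator", target = "p"))
  )
  expect_error(register_tf(tf_registry(), tf_bad_topic, net, world), "unknown topic")

  tf_bad_pop <- transfer_function(
    "t", "robot2neuron", noop_body, subscriptions = "bot/camera",
    devices = list(g = list(kind = "poisson_generator", target = "ghost_pop"))
  )
  expect_error(register_tf(tf_registry(), tf_bad_pop, net, world), "ghost_pop")
})

test_that("a Listing-1-style camera-to-Poisson TF binds, and names replace in place", {
  net <- build_network(list(
    populations = list(sensors = list(size = 3)),
    views = list(
      sensor_left = list(pop = "sensors", idx = 1),
      sensor_right = list(pop = "sensors", idx = 2),
      sensor_go = list(pop = "sensors", idx = 3)
    )
  ))
  world <- simple_world()
  tf1 <- tf_braitenberg_eye(list(robot = "bot"))
  res <- register_tf(tf_registry(), tf1, net, world)
  expect_equal(length(res$registry$tfs), 1)
  expect_true("eye_sensor.gen_left" %in% names(res$net$devices))

  tf1b <- tf_braitenberg_eye(list(robot = "bot", r_max = 500))
  res2 <- register_tf(res$registry, tf1b, res$net, world)
  expect_equal(length(res2$registry$tfs), 1) # replaced, not appended
})

test_that("detect_red counts the declared red predicate per image half", {
  blue <- array(0L, c(4, 6, 3)); blue[, , 3] <- 255L
  expect_equal(unname(detect_red(blue)), c(0, 0))

  half <- array(0L, c(4, 6, 3))
  half[, 1:3, 1] <- 255L # left half pure red
  half[, 4:6, 3] <- 255L
  expect_equal(unname(detect_red(half)), c(1, 0))

  img <- array(0L, c(64, 64, 3))
  img[, 1:16, 1] <- 255L # 16 x 64 red block in the left half
  expect_equal(unname(detect_red(img)), c(0.5, 0))

  # dark red (R = 50) fails the brightness floor
  dim_red <- array(0L, c(2, 2, 3)); dim_red[, , 1] <- 50L
  expect_equal(unname(detect_red(dim_red)), c(0, 0))
})

test_that("ratio-to-rate mapping and wheel command obey their contracts", {
  expect_equal(unname(rates_from_ratios(0, 0)), c(0, 0, 2000))
  expect_equal(unname(rates_from_ratios(1, 1)), c(2000, 2000, 0))
  expect_equal(unname(rates_from_ratios(0.25, 0.75)), c(500, 1500, 500))

  # equal deflections: equal positive speeds, straight motion
  cmd <- wheel_cmd_from_voltages(2, 2, scale = 4, k = 1, beta = 0.5)
  expect_equal(unname(cmd), rep(1 * (1 - 0.5) * 0.5, 2))
  # uR >> uL: right wheel forward, left backward -> counterclockwise
  cmd <- wheel_cmd_from_voltages(0, 4, scale = 4, k = 1, beta = 0.5)
  expect_gt(cmd[["right"]], 0)
  expect_lt(cmd[["left"]], 0)
  expect_gt(cmd[["right"]] - cmd[["left"]], 0) # omega > 0
  expect_equal(unname(wheel_cmd_from_voltages(0, 0)), c(0, 0))
})

test_that("evaluation isolates same-step outputs and flags device conflicts", {
  out0 <- evaluate_tfs(tf_registry(), simple_world(), build_network(list()), 0)
  expect_equal(length(out0$devices), 0)
  expect_equal(nrow(out0$monitor), 0)

  # two TFs: the first publishes, the second must not see it this step
  world <- simple_world()
  net <- build_network(list(populations = list(p = list(size = 1))))
  seen <- NULL
  tf_a <- transfer_function("a", "robot2robot", function(ctx) {
    list(publish = list("bot/wheel_cmd" = list(left = 1, right = 1)))
  }, subscriptions = "bot/pose", publications = "bot/wheel_cmd")
  tf_b <- transfer_function("b", "robot2monitor", function(ctx) {
    list(monitor = list(seen = if (is.null(ctx$topics[["bot/wheel_cmd"]])) 0 else 1))
  }, subscriptions = "bot/wheel_cmd", monitors = "seen")
  reg <- tf_registry()
  for (tf in list(tf_a, tf_b)) {
    res <- register_tf(reg, tf, net, world)
    reg <- res$registry
    net <- res$net
  }
  out <- evaluate_tfs(reg, world, net, 20)
  expect_equal(out$monitor$value[[1]], 0) # snapshot isolation
  expect_equal(out$publish[["bot/wheel_cmd"]]$left, 1)

  # two TFs writing one shared device: later registration wins, warning logged
  mk_writer <- function(name, rate) {
    transfer_function(name, "robot2neuron", function(ctx) {
      list(devices = list(g = list(rate = rate)))
    }, subscriptions = "bot/pose",
    devices = list(g = list(kind = "poisson_generator", target = "p", shared = "shared_gen")))
  }
  reg2 <- tf_registry()
  net2 <- build_network(list(populations = list(p = list(size = 1))))
  r <- register_tf(reg2, mk_writer("w1", 10), net2, world)
  r2 <- register_tf(r$registry, mk_writer("w2", 99), r$net, world)
  out <- evaluate_tfs(r2$registry, world, r2$net, 20)
  expect_equal(out$devices[["shared_gen"]]$rate, 99)
  expect_match(out$warnings, "written twice")

  # a TF body exception is a simulation fault
  tf_boom <- transfer_function("boom", "robot2robot", function(ctx) stop("kaput"),
                               subscriptions = "bot/pose")
  r3 <- register_tf(tf_registry(), tf_boom, net2, world)
  expect_error(evaluate_tfs(r3$registry, world, r3$net, 20),
               class = "neuroloop_fault")
})

test_that("evaluation order of non-conflicting TFs does not change outputs", {
  world <- simple_world()
  net <- build_network(list(populations = list(p = list(size = 2))))
  mk <- function(name, target, rate) {
    transfer_function(name, "robot2neuron", function(ctx) {
      list(devices = list(g = list(rate = rate)))
    }, subscriptions = "bot/pose",
    devices = list(g = list(kind = "poisson_generator", target = target)))
  }
  eval_perm <- function(order) {
    reg <- tf_registry(); n <- net
    for (tf in list(mk("t1", 1, 10), mk("t2", 2, 20))[order]) {
      res <- register_tf(reg, tf, n, world)
      reg <- res$registry; n <- res$net
    }
    out <- evaluate_tfs(reg, world, n, 0)
    out$devices[order(names(out$devices))]
  }
  expect_identical(eval_perm(1:2), eval_perm(2:1))
})

test_that("monitor sink validates channels and round-trips through CSV", {
  sink <- monitor_sink(c("joint", "spike"))
  expect_error(record_monitor(sink, 0, "ghost", 1), "undeclared")
  expect_equal(nrow(monitor_records(sink)), 0)

  for (t in c(20, 40, 60)) sink <- record_monitor(sink, t, "joint", t / 100)
  rec <- monitor_records(sink)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$channel, rep("joint", 3))

  f <- tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(time_ms = rec$time_ms, channel = rec$channel, value = unlist(rec$value)),
    f, row.names = FALSE
  )
  back <- utils::read.csv(f)
  expect_equal(back$time_ms, c(20, 40, 60))
  expect_equal(back$value, c(0.2, 0.4, 0.6))
})
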