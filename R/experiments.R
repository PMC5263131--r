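# ---------------------------------------------------------------------------
# packaged transfer-function library
#
# Each constructor takes (params, cfg) where params comes from the config
# file's tfs: entry and cfg is the full experiment config; it returns an
# nl_tf. Stateful TFs derive their private RNG stream from the master seed.

tf_braitenberg_eye <- function(params = list(), cfg = NULL) {
  robot <- params$robot %||% "husky"
  r_max <- params$r_max %||% 2000
  w_in <- params$w_in %||% 0.6
  w_go_in <- params$w_go_in %||% 0.15 # weaker so the search drive cannot saturate
  transfer_function(
    name = params$name %||% "eye_sensor",
    kind = "robot2neuron",
    subscriptions = paste0(robot, "/camera"),
    devices = list(
      gen_left = list(kind = "poisson_generator", target = "sensor_left", rate = 0, weight = w_in),
      gen_right = list(kind = "poisson_generator", target = "sensor_right", rate = 0, weight = w_in),
      gen_go = list(kind = "poisson_generator", target = "sensor_go", rate = 0, weight = w_go_in)
    ),
    monitors = c("red_left", "red_right"),
    body = function(ctx) {
      img <- ctx$topics[[1]]
      ratios <- detect_red(img)
      rates <- rates_from_ratios(ratios[["left"]], ratios[["right"]], r_max = r_max)
      list(
        devices = list(
          gen_left = list(rate = rates[["left"]]),
          gen_right = list(rate = rates[["right"]]),
          gen_go = list(rate = rates[["go"]])
        ),
        monitor = list(red_left = ratios[["left"]], red_right = ratios[["right"]])
      )
    }
  )
}

tf_braitenberg_wheels <- function(params = list(), cfg = NULL) {
  robot <- params$robot %||% "husky"
  scale <- params$scale %||% 4
  k <- params$k %||% 1.0
  beta <- params$beta %||% 0.5
  li_tau <- params$li_tau %||% 20
  li_w <- params$li_weight %||% 1.0
  transfer_function(
    name = params$name %||% "wheel_motor",
    kind = "neuron2robot",
    publications = paste0(robot, "/wheel_cmd"),
    devices = list(
      li_left = list(kind = "leaky_integrator", target = "actor_left", tau = li_tau, weight = li_w),
      li_right = list(kind = "leaky_integrator", target = "actor_right", tau = li_tau, weight = li_w)
    ),
    monitors = c("wheel_left", "wheel_right"),
    body = function(ctx) {
      cmd <- wheel_cmd_from_voltages(
        ctx$devices$li_left, ctx$devices$li_right,
        v_rest = 0, scale = scale, k = k, beta = beta
      )
      list(
        publish = setNames(list(list(left = cmd[["left"]], right = cmd[["right"]])),
                           paste0(robot, "/wheel_cmd")),
        monitor = list(wheel_left = cmd[["left"]], wheel_right = cmd[["right"]])
      )
    }
  )
}

tf_actor_rates <- function(params = list(), cfg = NULL) {
  window <- params$window %||% 200
  transfer_function(
    name = params$name %||% "actor_rates",
    kind = "neuron2monitor",
    devices = list(
      rate_left = list(kind = "population_rate", target = "actor_left", window = window),
      rate_right = list(kind = "population_rate", target = "actor_right", window = window)
    ),
    monitors = c("actor_rate_left", "actor_rate_right"),
    body = function(ctx) {
      list(monitor = list(
        actor_rate_left = ctx$devices$rate_left,
        actor_rate_right = ctx$devices$rate_right
      ))
    }
  )
}

tf_pose_monitor <- function(params = list(), cfg = NULL) {
  robot <- params$robot %||% "husky"
  transfer_function(
    name = params$name %||% "pose_monitor",
    kind = "robot2monitor",
    subscriptions = paste0(robot, "/pose"),
    monitors = c("pose_x", "pose_y", "pose_theta"),
    body = function(ctx) {
      p <- ctx$topics[[1]]
      list(monitor = list(pose_x = p$x, pose_y = p$y, pose_theta = p$theta))
    }
  )
}

tf_babble <- function(params = list(), cfg = NULL) {
  arm <- params$arm %||% "arm"
  n_joints <- params$n_joints %||% 3
  lo <- rep_len(as.numeric(params$lo %||% -pi / 2), n_joints)
  hi <- rep_len(as.numeric(params$hi %||% pi / 2), n_joints)
  seed <- derive_seed(cfg$cle$seed %||% 0, "tf:babble")
  transfer_function(
    name = params$name %||% "babble_controller",
    kind = "robot2robot",
    subscriptions = paste0(arm, c("/joints", "/tcp")),
    publications = paste0(arm, "/set_joints"),
    monitors = c("tcp_error", "iteration"),
    state = list(
      mode = "start", iter = 0L,
      model = forward_model(n_joints),
      rng = rng_state_new(seed)
    ),
    body = function(ctx) {
      st <- ctx$state
      angles <- ctx$topics[[paste0(arm, "/joints")]]$angles
      tcp <- ctx$topics[[paste0(arm, "/tcp")]]$xy
      draw_pose <- function(st) {
        res <- rng_eval(st$rng, function() runif(n_joints, lo, hi))
        st$rng <- res$state
        st$draw <- res$value
        st
      }
      out <- list()
      if (st$mode == "start") {
        # first held-out evaluation probes the untrained (zero) model
        st <- draw_pose(st)
        out$publish <- setNames(list(list(angles = st$draw)), paste0(arm, "/set_joints"))
        st$mode <- "observe_eval"
      } else if (st$mode == "observe_eval") {
        err <- sqrt(sum((predict_tcp(st$model, angles) - tcp)^2))
        out$monitor <- list(tcp_error = err, iteration = st$iter)
        st$iter <- st$iter + 1L
        st <- draw_pose(st)
        out$publish <- setNames(list(list(angles = st$draw)), paste0(arm, "/set_joints"))
        st$mode <- "observe_babble"
      } else { # observe_babble
        st$model <- train_forward_model_step(st$model, angles, tcp)
        st <- draw_pose(st)
        out$publish <- setNames(list(list(angles = st$draw)), paste0(arm, "/set_joints"))
        st$mode <- "observe_eval"
      }
      out$state <- st
      out
    }
  )
}

tf_retina <- function(params = list(), cfg = NULL) {
  robot <- params$robot %||% "icub"
  row <- params$row %||% 9
  gain <- params$gain %||% 6
  rc_args <- params$retina %||% list()
  ret <- retina_init(do.call(retina_config, rc_args))
  dt <- cfg$cle$cle_dt %||% 20
  transfer_function(
    name = params$name %||% "retina",
    kind = "robot2neuron",
    subscriptions = paste0(robot, "/camera"),
    devices = list(
      input = list(kind = "dc_generator", target = "layer1", amplitude = 0)
    ),
    state = list(ret = ret),
    body = function(ctx) {
      out <- red_green_opponency(ctx$state$ret, ctx$topics[[1]], dt)
      stripe <- extract_stripe(out$p1, out$p2, row)
      list(
        devices = list(input = list(amplitude = gain * stripe)),
        state = list(ret = out$ret)
      )
    }
  )
}

tf_centroid <- function(params = list(), cfg = NULL) {
  robot <- params$robot %||% "icub"
  width <- params$width %||% 320
  window <- params$window %||% 100
  floor <- params$floor %||% 3
  fov <- params$fov %||% (pi / 2)
  k_p <- params$k_p %||% 3
  max_vel <- params$max_vel %||% 1.5
  fixed_eye <- isTRUE(params$fixed_eye)
  transfer_function(
    name = params$name %||% "centroid_decoder",
    kind = "neuron2robot",
    subscriptions = paste0(robot, "/pose"),
    publications = paste0(robot, "/pan_cmd"),
    devices = list(
      spikes = list(kind = "spike_recorder", target = "layer2", window = window)
    ),
    monitors = "decoded_px",
    state = list(b_est = NA_real_),
    body = function(ctx) {
      sp <- ctx$devices$spikes
      ids <- sp$neuron_id - 2L * width # layer2 global ids follow layer1
      counts <- tabulate(ids[ids >= 1L & ids <= 2L * width], nbins = 2L * width)
      cen <- centroid_from_spikes(counts, width, floor = floor)
      pan <- ctx$topics[[1]]$pan
      st <- ctx$state
      if (!is.na(cen)) {
        # remember the target bearing in the base frame: the retina responds
        # to change, so the servo must outlive the transient that drove it
        st$b_est <- pan + ((cen - 0.5) / width - 0.5) * fov
      }
      vel <- if (fixed_eye || is.na(st$b_est)) 0 else clamp(k_p * (st$b_est - pan), -max_vel, max_vel)
      list(
        publish = setNames(list(list(vel = vel)), paste0(robot, "/pan_cmd")),
        monitor = list(decoded_px = cen),
        state = st
      )
    }
  )
}

tf_target_driver <- function(params = list(), cfg = NULL) {
  screen <- params$screen %||% "screen"
  mode <- params$mode %||% "sine"
  amp <- params$amp %||% 0.08
  period <- params$period %||% 3000 # ms
  offset <- params$offset %||% 0.08
  t_step <- params$t_step %||% 500 # ms; step mode jumps here
  rate <- params$rate %||% 2e-5 # width fractions per ms
  transfer_function(
    name = params$name %||% "target_driver",
    kind = "robot2robot",
    subscriptions = paste0(screen, "/target_pos"),
    publications = paste0(screen, "/set_target"),
    monitors = "target_cx",
    body = function(ctx) {
      cx <- switch(mode,
        sine = 0.5 + amp * sin(2 * pi * ctx$t / period),
        step = if (ctx$t < t_step) 0.5 else 0.5 + offset,
        linear = clamp(0.5 - amp + rate * ctx$t, 0.5 - 2 * amp, 0.5 + 2 * amp),
        abort(paste0("unknown target mode '", mode, "'"))
      )
      list(
        publish = setNames(list(list(cx = cx)), paste0(screen, "/set_target")),
        monitor = list(target_cx = cx)
      )
    }
  )
}

tf_truth_monitor <- function(params = list(), cfg = NULL) {
  robot <- params$robot %||% "icub"
  screen <- params$screen %||% "screen"
  width <- params$width %||% 320
  fov <- params$fov %||% (pi / 2)
  transfer_function(
    name = params$name %||% "truth_monitor",
    kind = "robot2monitor",
    subscriptions = c(paste0(robot, "/pose"), paste0(screen, "/target_pos")),
    monitors = c("true_px", "pan", "target_bearing"),
    body = function(ctx) {
      p <- ctx$topics[[paste0(robot, "/pose")]]
      tp <- ctx$topics[[paste0(screen, "/target_pos")]]$xy
      world_bearing <- atan2(tp[2] - p$y, tp[1] - p$x)
      rel <- wrap_angle(world_bearing - (p$theta - p$pan)) # positive = left
      px <- width * (0.5 - rel / fov) + 0.5
      bearing_base <- -wrap_angle(world_bearing - p$theta) # image convention
      list(monitor = list(true_px = px, pan = p$pan, target_bearing = bearing_base))
    }
  )
}

BUILTIN_TFS <- list(
  braitenberg_eye = tf_braitenberg_eye,
  braitenberg_wheels = tf_braitenberg_wheels,
  actor_rates = tf_actor_rates,
  pose_monitor = tf_pose_monitor,
  babble = tf_babble,
  retina = tf_retina,
  centroid = tf_centroid,
  target_driver = tf_target_driver,
  truth_monitor = tf_truth_monitor
)

# ---------------------------------------------------------------------------
# monitor helpers

#' Scalar monitor channels in wide form
#'
#' @param sim an `nl_sim` (or anything with a monitor sink).
#' @param channels channels to spread into columns (default: all scalar).
#' @return a tibble with `time_ms` and one column per channel.
#' @export
monitor_wide <- function(sim, channels = NULL) {
  rec <- monitor_records(sim$monitor)
  scalar <- vapply(rec$value, function(v) is.numeric(v) && length(v) == 1, logical(1))
  rec <- rec[scalar, ]
  channels <- channels %||% unique(rec$channel)
  out <- tibble::tibble(time_ms = sort(unique(rec$time_ms)))
  for (ch in channels) {
    sub <- rec[rec$channel == ch, ]
    out[[ch]] <- unlist(sub$value)[match(out$time_ms, sub$time_ms)]
  }
  out
}

run_trajectory <- function(sim) {
  tr <- monitor_wide(sim, c("pose_x", "pose_y", "pose_theta"))
  tibble::tibble(
    time_ms = tr$time_ms, x = tr$pose_x, y = tr$pose_y, theta = tr$pose_theta
  )
}

# ---------------------------------------------------------------------------
# packaged experiments

#' Run the Braitenberg vehicle experiment
#'
#' A differential-drive robot with a camera searches counterclockwise until
#' red pixels appear, then drives toward the screen displaying red. The
#' packaged 8-neuron brain has 3 sensor neurons (left red ratio, right red
#' ratio, and a "go" channel active without red), 3 relay neurons and 2
#' actor neurons whose leaky-integrator potentials become wheel commands.
#'
#' @param duration_ms run length in simulated ms.
#' @param seed master seed.
#' @param scenario `"event"` (both screens blue; a timed event turns the
#'   right screen red mid-run), `"red_from_start"`, or `"no_red"`.
#' @param config experiment config (default: the packaged one).
#' @return an `nl_run` list: `sim`, `trajectory` (tibble: time_ms, x, y,
#'   theta), `monitor` (tibble of all records), `channels` (wide tibble of
#'   scalar channels).
#' @export
run_braitenberg <- function(duration_ms = 24000, seed = 1,
                            scenario = c("event", "red_from_start", "no_red"),
                            config = NULL) {
  scenario <- match.arg(scenario)
  cfg <- config %||% load_experiment("braitenberg", seed = seed)
  if (scenario == "red_from_start") {
    cfg$events <- list()
    cfg$world$screens$screen_right$color <- c(255, 0, 0)
  } else if (scenario == "no_red") {
    cfg$events <- list()
  }
  finish_run(run_sim_config(cfg, duration_ms), cfg)
}

#' Run the motor-babbling sensorimotor learning experiment
#'
#' No brain network is involved: a stateful robot-to-robot controller
#' alternates between babbling (move to a random pose, observe joints and
#' TCP, one incremental least-squares update) and evaluation (move to a
#' held-out random pose, compare predicted and true TCP). The per-iteration
#' Euclidean TCP error goes to the monitor log.
#'
#' @param iterations number of babble/evaluate iterations.
#' @param seed master seed (babbling poses derive from it).
#' @param config experiment config (default: the packaged one).
#' @return an `nl_run` with an extra `errors` tibble: `iteration`,
#'   `error_m`. Iteration 0 is the untrained baseline.
#' @export
run_sensorimotor <- function(iterations = 40, seed = 1, config = NULL) {
  cfg <- config %||% load_experiment("sensorimotor", seed = seed)
  duration <- (2 * (iterations + 1) + 2) * cfg$cle$cle_dt
  run <- finish_run(run_sim_config(cfg, duration), cfg)
  ch <- monitor_wide(run$sim, c("tcp_error", "iteration"))
  ch <- ch[!is.na(ch$tcp_error), ]
  run$errors <- tibble::tibble(iteration = ch$iteration, error_m = ch$tcp_error)
  run$errors <- run$errors[run$errors$iteration <= iterations, ]
  class(run) <- c("nl_sensorimotor_run", class(run))
  run
}

#' Run the retina-based visual tracking experiment
#'
#' A fixed robot looks at a screen showing a green circle on a red
#' background. Camera frames pass through the red-green opponency chain;
#' one horizontal stripe of retinal current drives layer 1 of the 1,280
#' neuron readout; layer-2 spike counts are decoded to a target centroid
#' which (except in `fixed_eye` mode) steers the camera pan joint.
#'
#' @param mode `"fixed_eye"` (decode only, sinusoidal target), `"step"`
#'   (stationary off-center target, eye moves to capture it), or
#'   `"pursuit"` (linearly moving target, eye follows).
#' @param duration_ms run length (ms).
#' @param seed master seed.
#' @param config experiment config (default: the packaged one).
#' @return an `nl_run` with an extra `traces` tibble: per step `time_ms`,
#'   `decoded_px`, `true_px`, `target_cx`, `pan`, `target_bearing`.
#' @export
run_retina_tracking <- function(mode = c("fixed_eye", "step", "pursuit"),
                                duration_ms = 7000, seed = 1, config = NULL) {
  mode <- match.arg(mode)
  cfg <- config %||% load_experiment("retina_tracking", seed = seed)
  for (i in seq_along(cfg$tfs)) {
    b <- cfg$tfs[[i]]$builtin
    if (identical(b, "target_driver")) {
      cfg$tfs[[i]]$params$mode <- if (mode == "fixed_eye") "sine" else if (mode == "step") "step" else "linear"
    }
    if (identical(b, "centroid")) {
      cfg$tfs[[i]]$params$fixed_eye <- (mode == "fixed_eye")
    }
  }
  run <- finish_run(run_sim_config(cfg, duration_ms), cfg)
  run$traces <- monitor_wide(
    run$sim, c("decoded_px", "true_px", "target_cx", "pan", "target_bearing")
  )
  class(run) <- c("nl_tracking_run", class(run))
  run
}

run_sim_config <- function(cfg, duration_ms) {
  sim <- sim_initialize(simulation(cfg))
  if (sim$state == "halted") {
    abort(paste0("initialization failed: ", paste(sim$diagnostics, collapse = "; ")))
  }
  sim <- sim_start(sim)
  sim <- sim_run(sim, duration_ms)
  if (sim$state == "halted") {
    abort(paste0("simulation halted: ", paste(sim$diagnostics, collapse = "; ")))
  }
  sim
}

finish_run <- function(sim, cfg) {
  has_pose <- any(vapply(
    sim$registry$tfs, function(tf) "pose_x" %in% tf$monitors, logical(1)
  ))
  structure(
    list(
      sim = sim,
      trajectory = if (has_pose) run_trajectory(sim),
      monitor = monitor_records(sim$monitor),
      channels = monitor_wide(sim),
      config = cfg
    ),
    class = "nl_run"
  )
}

#' @export
print.nl_run <- function(x, ...) {
  cat(sprintf(
    "<nl_run> '%s': %d steps (%g ms), %d monitor records, state %s\n",
    x$config$name, x$sim$n_steps, x$sim$time, nrow(x$monitor), x$sim$state
  ))
  invisible(x)
}

#' Export a completed run to CSV
#'
#' Writes one CSV per monitor channel (`time_ms,value...`), the spike train
#' (`spikes.csv`: `time_ms,neuron_id`) and a JSON manifest (config name and
#' hash, master seed, duration, step count). Re-running with the same seed
#' reproduces every CSV byte for byte; only the manifest timestamp differs.
#'
#' @param run an `nl_run` (or an `nl_sim`).
#' @param directory output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_run <- function(run, directory) {
  sim <- if (inherits(run, "nl_sim")) run else run$sim
  cfg <- if (inherits(run, "nl_sim")) run$config else run$config
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) abort(paste0("cannot create directory '", directory, "'"))
  paths <- character(0)

  rec <- monitor_records(sim$monitor)
  for (ch in sim$monitor$channels) {
    sub <- rec[rec$channel == ch, ]
    vals <- sub$value
    k <- if (nrow(sub)) max(vapply(vals, length, integer(1))) else 1L
    df <- as.data.frame(matrix(NA_real_, nrow(sub), k))
    names(df) <- if (k == 1) "value" else paste0("value", seq_len(k))
    for (i in seq_len(nrow(sub))) df[i, seq_along(vals[[i]])] <- vals[[i]]
    df <- cbind(time_ms = sub$time_ms, df)
    p <- file.path(directory, paste0(ch, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  sp <- spike_records(sim$net)
  p <- file.path(directory, "spikes.csv")
  utils::write.csv(as.data.frame(sp), p, row.names = FALSE)
  paths <- c(paths, p)

  manifest <- list(
    experiment = cfg$name,
    config_hash = config_hash(cfg[c("world", "brain", "events", "monitors")]),
    seed = cfg$cle$seed,
    cle_dt_ms = cfg$cle$cle_dt,
    duration_ms = sim$time,
    n_steps = sim$n_steps,
    state = sim$state,
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mp <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mp))
}
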