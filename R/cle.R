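#' Closed-loop engine configuration
#'
#' @param cle_dt closed-loop timestep (ms); one camera/TF cycle. Must be an
#'   integer multiple of `neural_dt`.
#' @param neural_dt inner neural timestep (ms).
#' @param seed master seed; per-component streams (brain, each TF) are
#'   derived from it by stable hashing of the component name.
#' @param max_duration optional run cap (ms).
#' @return a validated config list.
#' @export
cle_config <- function(cle_dt = 20, neural_dt = 1, seed = 0, max_duration = NULL) {
  if (cle_dt <= 0 || neural_dt <= 0) abort("timesteps must be > 0")
  ratio <- cle_dt / neural_dt
  if (abs(ratio - round(ratio)) > 1e-9) abort("cle_dt must be an integer multiple of neural_dt")
  list(
    cle_dt = cle_dt, neural_dt = neural_dt,
    seed = as.integer(seed), max_duration = max_duration
  )
}

LIFECYCLE_STATES <- c("created", "initialized", "started", "paused", "stopped", "halted")

# legal transitions: action -> (from -> to)
LIFECYCLE_TABLE <- list(
  initialize = list(created = "initialized", stopped = "initialized", halted = "initialized"),
  start = list(initialized = "started", paused = "started"),
  pause = list(started = "paused"),
  stop = list(initialized = "stopped", started = "stopped", paused = "stopped"),
  fail = setNames(as.list(rep("halted", length(LIFECYCLE_STATES))), LIFECYCLE_STATES)
)

#' The simulation lifecycle transition table
#'
#' One row per legal `(state, action) -> state` edge. A normal run goes
#' created -> initialized -> started -> stopped, with started <-> paused
#' excursions; any error sends the simulation to `halted` from every state;
#' `stopped` and `halted` can only be left by re-initialization.
#'
#' @return a tibble with columns `from`, `action`, `to`.
#' @export
lifecycle_table <- function() {
  rows <- list()
  for (action in names(LIFECYCLE_TABLE)) {
    for (from in names(LIFECYCLE_TABLE[[action]])) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(from = from, action = action, to = LIFECYCLE_TABLE[[action]][[from]])
    }
  }
  dplyr::bind_rows(rows)
}

#' Create a simulation from an experiment configuration
#'
#' The simulation starts in lifecycle state `created`; call
#' [sim_initialize()] to build and validate all components.
#'
#' @param config an [experiment_config()].
#' @return an `nl_sim`.
#' @export
simulation <- function(config) {
  stopifnot(inherits(config, "nl_experiment"))
  structure(
    list(
      config = config, state = "created", time = 0, n_steps = 0L,
      net = NULL, world = NULL, registry = NULL, events = NULL,
      monitor = NULL, buffered = list(devices = list(), publish = list()),
      pending_edits = list(), diagnostics = character(0),
      transitions = tibble::tibble(
        time_ms = numeric(0), from = character(0),
        action = character(0), to = character(0)
      )
    ),
    class = "nl_sim"
  )
}

#' @export
print.nl_sim <- function(x, ...) {
  cat(sprintf(
    "<nl_sim> '%s', state %s, t = %g ms (%d steps)\n",
    x$config$name, x$state, x$time, x$n_steps
  ))
  invisible(x)
}

#' Apply a lifecycle action
#'
#' Legal transitions follow [lifecycle_table()] exactly; an illegal action
#' is rejected with an error and the state is unchanged, never silently
#' ignored. `fail` is legal from every state and leads to `halted`.
#'
#' @param sim an `nl_sim`.
#' @param action one of `initialize`, `start`, `pause`, `stop`, `fail`.
#' @return the updated simulation.
#' @export
sim_transition <- function(sim, action) {
  if (!action %in% names(LIFECYCLE_TABLE)) abort(paste0("unknown lifecycle action '", action, "'"))
  to <- LIFECYCLE_TABLE[[action]][[sim$state]]
  if (is.null(to)) {
    abort(paste0("illegal lifecycle transition: ", sim$state, " --", action, "-->"),
          class = "neuroloop_lifecycle_error")
  }
  sim$transitions <- dplyr::bind_rows(
    sim$transitions,
    tibble::tibble(time_ms = sim$time, from = sim$state, action = action, to = to)
  )
  sim$state <- to
  sim
}

#' Initialize a simulation
#'
#' Builds the world, the network (with its private RNG stream derived from
#' the master seed), binds and validates every transfer function and timed
#' event, and records the initial poses, brain state and screen contents as
#' reset targets. Any validation failure sends the simulation to `halted`
#' with a diagnostic instead of raising.
#'
#' @param sim an `nl_sim` in state `created` (or `stopped`/`halted` for
#'   re-initialization).
#' @return the updated simulation, in state `initialized` (or `halted`).
#' @export
sim_initialize <- function(sim) {
  sim <- sim_transition(sim, "initialize")
  cfg <- sim$config
  built <- tryCatch(
    {
      world <- build_world_from_spec(cfg$world)
      net <- build_network(cfg$brain, seed = derive_seed(cfg$cle$seed, "brain"))
      registry <- tf_registry()
      for (entry in cfg$tfs) {
        tf <- resolve_tf(entry, cfg)
        res <- register_tf(registry, tf, net, world)
        registry <- res$registry
        net <- res$net
      }
      events <- workflow_machine(cfg$events)
      validate_events(events, world)
      channels <- union(registry$channels, cfg$monitors %||% character(0))
      list(
        world = world, net = net, registry = registry, events = events,
        monitor = monitor_sink(channels)
      )
    },
    error = function(e) e
  )
  if (inherits(built, "error")) {
    sim$diagnostics <- c(sim$diagnostics, conditionMessage(built))
    return(sim_transition(sim, "fail"))
  }
  sim[names(built)] <- built
  sim$time <- 0
  sim$n_steps <- 0L
  sim$buffered <- list(devices = list(), publish = list())
  sim
}

#' @rdname sim_transition
#' @export
sim_start <- function(sim) sim_transition(sim, "start")

#' @rdname sim_transition
#' @export
sim_pause <- function(sim) sim_transition(sim, "pause")

#' @rdname sim_transition
#' @export
sim_stop <- function(sim) sim_transition(sim, "stop")

#' Advance the closed loop by one timestep
#'
#' One synchronization cycle: (1) apply any runtime edits queued for this
#' step boundary, then the TF outputs buffered at the end of the previous
#' step (device settings to the network, actuator commands to the world);
#' (2) advance the world by `cle_dt` and the network by `cle_dt/neural_dt`
#' inner steps — logically in parallel: neither sees the other's in-step
#' output; (3) evaluate all TFs on the two completed snapshots and buffer
#' their outputs for the next step; (4) fire due timed events. Data written
#' by a TF at step n is therefore first observable during step n+1 (the
#' one-step-delay contract). A fault in either simulator or any TF halts
#' the simulation.
#'
#' @param sim an `nl_sim` in state `started`.
#' @return the updated simulation.
#' @export
sim_step <- function(sim) {
  if (sim$state != "started") {
    abort(paste0("cannot step a simulation in state '", sim$state, "'"),
          class = "neuroloop_lifecycle_error")
  }
  res <- tryCatch(sim_step_inner(sim), error = function(e) e)
  if (inherits(res, "error")) {
    sim$diagnostics <- c(sim$diagnostics, conditionMessage(res))
    return(sim_transition(sim, "fail"))
  }
  res
}

sim_step_inner <- function(sim) {
  cfg <- sim$config$cle
  sim <- apply_pending_edits(sim)

  # (1) buffered outputs from the previous step's TF evaluation
  for (gname in names(sim$buffered$devices)) {
    setting <- sim$buffered$devices[[gname]]
    sim$net <- do.call(set_device, c(list(sim$net, gname), setting))
  }
  for (topic in names(sim$buffered$publish)) {
    sim$world <- apply_command(sim$world, topic, sim$buffered$publish[[topic]])
  }
  sim$buffered <- list(devices = list(), publish = list())

  # (2) both simulations, same timestep
  sim$world <- step_world(sim$world, cfg$cle_dt)
  sim$net <- step_network(sim$net, cfg$neural_dt, n_steps = as.integer(round(cfg$cle_dt / cfg$neural_dt)))

  t_new <- sim$time + cfg$cle_dt

  # (3) transfer functions on the frozen snapshots
  out <- evaluate_tfs(sim$registry, sim$world, sim$net, t_new)
  sim$registry <- out$registry
  sim$buffered <- list(devices = out$devices, publish = out$publish)
  for (w in out$warnings) warn(w)
  if (nrow(out$monitor)) {
    for (i in seq_len(nrow(out$monitor))) {
      sim$monitor <- record_monitor(
        sim$monitor, out$monitor$time_ms[i], out$monitor$channel[i],
        out$monitor$value[[i]], out$monitor$tf[i]
      )
    }
  }

  # (4) timed events
  ev <- events_tick(sim$events, sim$world, t_new)
  sim$events <- ev$machine
  sim$world <- ev$world

  sim$time <- t_new
  sim$n_steps <- sim$n_steps + 1L
  sim
}

#' Run a started simulation for a duration
#'
#' @param sim an `nl_sim` in state `started`.
#' @param duration_ms how long to run (simulated ms).
#' @return the updated simulation (state `started`, or `halted` on fault).
#' @export
sim_run <- function(sim, duration_ms) {
  end <- sim$time + duration_ms
  while (sim$state == "started" && sim$time < end) {
    if (!is.null(sim$config$cle$max_duration) && sim$time >= sim$config$cle$max_duration) break
    sim <- sim_step(sim)
  }
  sim
}

#' Parametrized reset
#'
#' Restores the selected parts of a running or paused simulation to their
#' initial values, leaving everything unselected untouched. Simulated time,
#' monitor logs and the lifecycle state are preserved.
#'
#' @param sim an `nl_sim` in state `started` or `paused`.
#' @param parts non-empty subset of `"robot_pose"`, `"brain"`,
#'   `"environment"`.
#' @return the updated simulation.
#' @export
sim_reset <- function(sim, parts) {
  if (!length(parts)) abort("reset selector must be a non-empty subset")
  bad <- setdiff(parts, c("robot_pose", "brain", "environment"))
  if (length(bad)) abort(paste0("unknown reset target(s): ", paste(bad, collapse = ", ")))
  if (!sim$state %in% c("started", "paused")) {
    abort(paste0("cannot reset a simulation in state '", sim$state, "'"),
          class = "neuroloop_lifecycle_error")
  }
  if ("robot_pose" %in% parts) {
    sim$world <- reset_robot_pose(sim$world)
    sim$buffered$publish <- list()
  }
  if ("brain" %in% parts) {
    sim$net <- reset_network_state(sim$net)
    sim$buffered$devices <- list()
  }
  if ("environment" %in% parts) {
    sim$world <- reset_environment(sim$world)
  }
  sim
}

# ---------------------------------------------------------------------------
# runtime editing: swaps occur at the next step boundary; validation failure
# leaves the old definition active and raises immediately.

#' Edit a running simulation
#'
#' `sim_set_tf()` adds or replaces a transfer function, `sim_remove_tf()`
#' removes one, `sim_set_brain()` swaps the brain description. The new
#' definition is validated immediately (on failure the old one stays active
#' and an error is raised); the swap itself happens at the next step
#' boundary, never mid-step.
#'
#' @param sim an `nl_sim` in state `started` or `paused`.
#' @param tf an `nl_tf`.
#' @return the updated simulation.
#' @export
sim_set_tf <- function(sim, tf) {
  check_editable(sim)
  # dry-run validation against copies
  invisible(register_tf(sim$registry, tf, sim$net, sim$world))
  sim$pending_edits <- c(sim$pending_edits, list(list(kind = "set_tf", tf = tf)))
  sim
}

#' @rdname sim_set_tf
#' @param name TF name to remove.
#' @export
sim_remove_tf <- function(sim, name) {
  check_editable(sim)
  sim$pending_edits <- c(sim$pending_edits, list(list(kind = "remove_tf", name = name)))
  sim
}

#' @rdname sim_set_tf
#' @param brain a brain description list (see [build_network()]).
#' @export
sim_set_brain <- function(sim, brain) {
  check_editable(sim)
  net <- build_network(brain, seed = derive_seed(sim$config$cle$seed, "brain")) # validates
  for (tf in sim$registry$tfs) { # devices must rebind
    invisible(register_tf(tf_registry(), tf, net, sim$world))
  }
  sim$pending_edits <- c(sim$pending_edits, list(list(kind = "set_brain", brain = brain)))
  sim
}

check_editable <- function(sim) {
  if (!sim$state %in% c("started", "paused")) {
    abort(paste0("cannot edit a simulation in state '", sim$state, "'"),
          class = "neuroloop_lifecycle_error")
  }
}

apply_pending_edits <- function(sim) {
  for (edit in sim$pending_edits) {
    if (edit$kind == "set_tf") {
      res <- register_tf(sim$registry, edit$tf, sim$net, sim$world)
      sim$registry <- res$registry
      sim$net <- res$net
      sim$monitor$channels <- union(sim$monitor$channels, edit$tf$monitors)
    } else if (edit$kind == "remove_tf") {
      sim$registry <- unregister_tf(sim$registry, edit$name)
      # robot coasts on its last command: buffered publishes are kept
    } else if (edit$kind == "set_brain") {
      net <- build_network(edit$brain, seed = derive_seed(sim$config$cle$seed, "brain"))
      registry <- tf_registry()
      for (tf in sim$registry$tfs) {
        res <- register_tf(registry, tf, net, sim$world)
        registry <- res$registry
        net <- res$net
      }
      sim$net <- net
      sim$registry <- registry
      sim$buffered$devices <- list()
    }
  }
  sim$pending_edits <- list()
  sim
}
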