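#' Declare an experiment
#'
#' The full declarative description of one closed-loop experiment: world
#' layout, brain description, transfer-function set, timed events, monitor
#' channels and engine timing. All cross-references are validated at
#' [sim_initialize()].
#'
#' @param name experiment name.
#' @param cle a [cle_config()].
#' @param world world spec list: `background`, and named lists `robots`,
#'   `arms`, `screens` whose entries are argument lists for [world_robot()],
#'   [world_arm()], [world_screen()].
#' @param brain brain description for [build_network()], or
#'   `list(builder = "retina", ...)` to use a packaged brain builder.
#' @param tfs list of `nl_tf` objects and/or `list(builtin = <name>,
#'   params = list(...))` references to the packaged TF library.
#' @param events list of timed events (see [workflow_machine()]).
#' @param monitors extra monitor channels beyond those declared by TFs.
#' @return an `nl_experiment`.
#' @export
experiment_config <- function(name, cle = cle_config(), world = list(),
                              brain = list(), tfs = list(), events = list(),
                              monitors = character(0)) {
  structure(
    list(
      name = name, cle = cle, world = world, brain = resolve_brain(brain, cle),
      tfs = tfs, events = events, monitors = monitors
    ),
    class = "nl_experiment"
  )
}

resolve_brain <- function(brain, cle) {
  if (!is.null(brain$builder)) {
    args <- brain[setdiff(names(brain), "builder")]
    brain <- switch(brain$builder,
      retina = do.call(retina_brain_description, args),
      abort(paste0("unknown brain builder '", brain$builder, "'"))
    )
  }
  brain$dt <- brain$dt %||% cle$neural_dt
  brain
}

#' Load an experiment configuration from a YAML file
#'
#' The file mirrors [experiment_config()]: top-level keys `name`, `cle`,
#' `world`, `brain`, `tfs` (builtin references), `events`, `monitors`.
#' See the three packaged experiments under
#' `system.file("extdata", package = "neuroloop")`.
#'
#' @param path path to a YAML file, or the bare name of a packaged
#'   experiment (`"braitenberg"`, `"sensorimotor"`, `"retina_tracking"`).
#' @param seed optional master-seed override.
#' @param overrides named list merged over the `cle` block.
#' @return an `nl_experiment`.
#' @export
load_experiment <- function(path, seed = NULL, overrides = list()) {
  if (!file.exists(path)) {
    pkg_path <- system.file("extdata", paste0(path, ".yaml"), package = "neuroloop")
    if (!nzchar(pkg_path)) abort(paste0("no such experiment config: '", path, "'"))
    path <- pkg_path
  }
  y <- yaml::read_yaml(path)
  cle_args <- y$cle %||% list()
  cle_args <- modifyList(cle_args, overrides)
  if (!is.null(seed)) cle_args$seed <- seed
  cle <- do.call(cle_config, cle_args)
  tfs <- lapply(y$tfs %||% list(), function(tf) {
    if (!is.null(tf$builtin)) tf else abort("YAML configs reference TFs by 'builtin' name")
  })
  experiment_config(
    name = y$name %||% tools::file_path_sans_ext(basename(path)),
    cle = cle,
    world = y$world %||% list(),
    brain = normalize_brain_yaml(y$brain %||% list()),
    tfs = tfs,
    events = y$events %||% list(),
    monitors = as.character(y$monitors %||% character(0))
  )
}

# YAML gives projections' weight matrices as list-of-rows; views as lists
normalize_brain_yaml <- function(brain) {
  if (!is.null(brain$builder)) return(brain)
  brain$projections <- lapply(brain$projections %||% list(), function(p) {
    if (is.list(p$weights)) p$weights <- do.call(rbind, lapply(p$weights, as.numeric))
    p
  })
  brain
}

build_world_from_spec <- function(spec) {
  robots <- lapply(spec$robots %||% list(), function(r) {
    world_robot(
      pose = pose2d(r$x %||% 0, r$y %||% 0, r$theta %||% 0),
      track = r$track %||% 0.4, fov = r$fov %||% (pi / 2),
      res_x = r$res_x %||% 64, res_y = r$res_y %||% 64, pan = r$pan %||% 0
    )
  })
  arms <- lapply(spec$arms %||% list(), function(a) {
    limits <- if (!is.null(a$limits_lo)) cbind(as.numeric(a$limits_lo), as.numeric(a$limits_hi))
    world_arm(
      lengths = as.numeric(a$lengths %||% c(0.4, 0.3, 0.2)),
      angles = if (!is.null(a$angles)) as.numeric(a$angles),
      limits = limits
    )
  })
  screens <- lapply(spec$screens %||% list(), function(s) {
    center <- as.numeric(s$center)
    angle <- if (!is.null(s$face)) {
      # orient the segment perpendicular to the line toward a point (so the
      # screen faces it, e.g. the robot start pose)
      face <- as.numeric(s$face)
      atan2(center[2] - face[2], center[1] - face[1]) + pi / 2
    } else {
      s$angle %||% (pi / 2)
    }
    world_screen(
      center = center, width = s$width %||% 1, height = s$height,
      color = as.numeric(s$color %||% c(0, 0, 255)),
      angle = angle, pattern = s$pattern
    )
  })
  build_world(
    robots = robots, arms = arms, screens = screens,
    background = as.numeric(spec$background %||% c(128, 128, 128))
  )
}

# declarative description of the two-layer retina readout brain, matching
# build_retina_brain()
retina_brain_description <- function(width = 320, window = 7, weight = 1.2, dt = 1) {
  n1 <- 2L * as.integer(width)
  half <- (as.integer(window) - 1L) %/% 2L
  W <- matrix(0, n1, n1)
  for (p in 0:1) {
    off <- p * width
    for (i in seq_len(width)) {
      src <- max(1L, i - half):min(width, i + half)
      W[off + src, off + i] <- weight
    }
  }
  list(
    dt = dt,
    populations = list(
      layer1 = list(size = n1),
      # local integrators: a 5 mV threshold lets a few active window inputs
      # (a moving edge) drive the readout
      layer2 = list(size = n1, params = list(v_thresh = -65))
    ),
    projections = list(list(pre = "layer1", post = "layer2", weights = W, delay = dt))
  )
}

# resolve a TF entry (nl_tf or builtin reference) at initialize time, when
# the master seed is known
resolve_tf <- function(entry, cfg) {
  if (inherits(entry, "nl_tf")) return(entry)
  if (!is.null(entry$builtin)) {
    ctor <- BUILTIN_TFS[[entry$builtin]]
    if (is.null(ctor)) abort(paste0("unknown builtin TF '", entry$builtin, "'"))
    params <- entry$params %||% list()
    return(ctor(params, cfg))
  }
  abort("TF entry must be an nl_tf or a list(builtin = ...)")
}
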