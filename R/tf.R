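TF_KINDS <- c("robot2neuron", "neuron2robot", "robot2robot", "robot2monitor", "neuron2monitor")
INPUT_DEVICE_KINDS <- c("poisson_generator", "dc_generator")
OUTPUT_DEVICE_KINDS <- c("spike_recorder", "population_rate", "leaky_integrator")

#' Declare a transfer function
#'
#' A transfer function (TF) couples the two simulations: it reads frozen
#' snapshots of topics and neural devices at the end of a closed-loop step
#' and produces device settings, topic publications and monitor records that
#' are applied at the *next* step. The body is a function of a single
#' context argument with elements `t` (ms), `topics` (latest message per
#' subscribed topic), `devices` (readout per bound output device), and
#' `state` (this TF's private state). It returns a list with any of
#' `devices` (named settings, e.g. `list(gen = list(rate = 100))`),
#' `publish` (named topic messages), `monitor` (named channel values),
#' and `state` (the updated private state).
#'
#' @param name TF name; registering a second TF with the same name replaces
#'   the first (runtime editing).
#' @param kind one of `r paste(TF_KINDS, collapse = ", ")`.
#' @param body the TF body function (pure in its bound inputs; all
#'   statefulness goes through `state`).
#' @param subscriptions character vector of topics read.
#' @param publications character vector of topics written.
#' @param devices named list of device declarations: each is
#'   `list(kind =, target =, ...)` as in [add_device()]; the name is the
#'   local name used in the body's `ctx$devices` / returned `devices`.
#' @param monitors character vector of declared monitor channels.
#' @param state initial private state.
#' @return a `nl_tf` spec.
#' @export
transfer_function <- function(name, kind, body, subscriptions = character(0),
                              publications = character(0), devices = list(),
                              monitors = character(0), state = NULL) {
  if (!kind %in% TF_KINDS) abort(paste0("unknown TF kind '", kind, "'"))
  if (!is.function(body)) abort("TF body must be a function")
  dev_kinds <- vapply(devices, function(d) d$kind %||% "", character(1))
  if (kind == "robot2neuron") {
    if (!length(subscriptions)) abort("robot2neuron TF needs at least one subscription")
    if (!any(dev_kinds %in% INPUT_DEVICE_KINDS)) abort("robot2neuron TF needs an input-side device")
  }
  if (kind == "neuron2robot") {
    if (!any(dev_kinds %in% OUTPUT_DEVICE_KINDS)) abort("neuron2robot TF needs an output-side device")
    if (!length(publications)) abort("neuron2robot TF needs at least one publication")
  }
  if (kind == "robot2robot" && length(devices)) abort("robot2robot TF must not touch devices")
  if (kind %in% c("robot2monitor", "neuron2monitor")) {
    if (length(publications)) abort("monitor TFs publish only to the monitor sink")
    if (!length(monitors)) abort("monitor TF needs at least one monitor channel")
  }
  structure(
    list(
      name = name, kind = kind, body = body,
      subscriptions = subscriptions, publications = publications,
      devices = devices, monitors = monitors, state = state
    ),
    class = "nl_tf"
  )
}

#' Create an empty TF registry
#' @return an `nl_registry`.
#' @export
tf_registry <- function() {
  structure(list(tfs = list(), channels = character(0)), class = "nl_registry")
}

#' Register a transfer function
#'
#' Validates the spec against the loaded network and world (unknown topics,
#' device kinds illegal for the TF kind, unresolvable populations are
#' rejected before the simulation starts) and binds its devices into the
#' network. TFs evaluate in registration order; re-registering a name
#' replaces the old TF in place.
#'
#' @param registry an `nl_registry`.
#' @param tf an `nl_tf` from [transfer_function()].
#' @param net the loaded `nl_network` (devices are bound into it).
#' @param world the `nl_world` (topics validated against it).
#' @return `list(registry, net)` with the TF bound.
#' @export
register_tf <- function(registry, tf, net, world) {
  stopifnot(inherits(tf, "nl_tf"))
  for (topic in tf$subscriptions) {
    if (is.null(world$bus$topics[[topic]]) && is.null(command_schema(world, topic))) {
      abort(paste0("TF '", tf$name, "' subscribes to unknown topic '", topic, "'"))
    }
  }
  for (topic in tf$publications) {
    if (is.null(command_schema(world, topic))) {
      abort(paste0("TF '", tf$name, "' publishes to unknown command topic '", topic, "'"))
    }
  }
  for (dn in names(tf$devices)) {
    d <- tf$devices[[dn]]
    gname <- tf_device_name(tf, dn)
    net <- tryCatch(
      do.call(add_device, c(list(net, gname, d$kind, d$target),
                            d[setdiff(names(d), c("kind", "target", "shared"))])),
      error = function(e) abort(paste0("TF '", tf$name, "', device '", dn, "': ", conditionMessage(e)))
    )
  }
  existing <- which(vapply(registry$tfs, function(x) x$name, character(1)) == tf$name)
  if (length(existing)) {
    registry$tfs[[existing]] <- tf
  } else {
    registry$tfs[[length(registry$tfs) + 1L]] <- tf
  }
  registry$channels <- union(registry$channels, tf$monitors)
  list(registry = registry, net = net)
}

#' Remove a transfer function from a registry
#' @param registry an `nl_registry`.
#' @param name TF name.
#' @return the updated registry.
#' @export
unregister_tf <- function(registry, name) {
  keep <- vapply(registry$tfs, function(x) x$name, character(1)) != name
  registry$tfs <- registry$tfs[keep]
  registry
}

# global device name for a TF-local binding; a `shared` field lets several
# TFs address one device (the declared conflict rule then applies)
tf_device_name <- function(tf, dn) {
  tf$devices[[dn]]$shared %||% paste0(tf$name, ".", dn)
}

# read one output device for the TF context
device_readout <- function(net, gname, kind) {
  switch(kind,
    leaky_integrator = leaky_integrator_read(net, gname),
    population_rate = population_rate(net, gname),
    spike_recorder = read_spikes(net, gname),
    NULL
  )
}

#' Evaluate all transfer functions on frozen snapshots
#'
#' Runs every TF body, in registration order, against the topic and device
#' state produced by the step just completed. Outputs are *buffered*: the
#' caller applies them at the start of the next closed-loop step, so no TF
#' can observe another TF's same-step output (snapshot isolation). If two
#' TFs set the same device, the later registration wins and a warning is
#' logged. A TF body that throws is reported as a simulation fault.
#'
#' @param registry an `nl_registry`.
#' @param world the `nl_world` snapshot.
#' @param net the `nl_network` snapshot.
#' @param t simulated time (ms) of the completed step.
#' @return a list with `devices` (named device settings), `publish` (named
#'   topic messages), `monitor` (tibble of records), `registry` (updated TF
#'   states), `warnings` (character).
#' @export
evaluate_tfs <- function(registry, world, net, t) {
  device_out <- list()
  device_writer <- character(0)
  publish_out <- list()
  warnings <- character(0)
  mon_time <- numeric(0)
  mon_tf <- character(0)
  mon_chan <- character(0)
  mon_val <- list()

  for (i in seq_along(registry$tfs)) {
    tf <- registry$tfs[[i]]
    ctx <- list(t = t, topics = list(), devices = list(), state = tf$state)
    for (topic in tf$subscriptions) ctx$topics[[topic]] <- bus_read(world, topic)
    for (dn in names(tf$devices)) {
      d <- tf$devices[[dn]]
      if (d$kind %in% OUTPUT_DEVICE_KINDS) {
        ctx$devices[[dn]] <- device_readout(net, tf_device_name(tf, dn), d$kind)
      }
    }
    out <- tryCatch(tf$body(ctx), error = function(e) {
      abort(paste0("transfer function '", tf$name, "' failed: ", conditionMessage(e)),
            class = "neuroloop_fault")
    })
    out <- out %||% list()
    if (!is.null(out$state)) registry$tfs[[i]]$state <- out$state

    for (dn in names(out$devices %||% list())) {
      if (!dn %in% names(tf$devices)) {
        abort(paste0("TF '", tf$name, "' writes undeclared device '", dn, "'"),
              class = "neuroloop_fault")
      }
      gname <- tf_device_name(tf, dn)
      if (!is.null(device_out[[gname]])) {
        warnings <- c(warnings, paste0("device '", gname, "' written twice; later TF wins"))
      }
      device_out[[gname]] <- out$devices[[dn]]
    }
    for (topic in names(out$publish %||% list())) {
      if (!topic %in% tf$publications) {
        abort(paste0("TF '", tf$name, "' publishes to undeclared topic '", topic, "'"),
              class = "neuroloop_fault")
      }
      if (!is.null(publish_out[[topic]])) {
        warnings <- c(warnings, paste0("topic '", topic, "' written twice; later TF wins"))
      }
      publish_out[[topic]] <- out$publish[[topic]]
    }
    for (chan in names(out$monitor %||% list())) {
      if (!chan %in% tf$monitors) {
        abort(paste0("TF '", tf$name, "' records to undeclared channel '", chan, "'"),
              class = "neuroloop_fault")
      }
      mon_time <- c(mon_time, t)
      mon_tf <- c(mon_tf, tf$name)
      mon_chan <- c(mon_chan, chan)
      mon_val <- c(mon_val, list(out$monitor[[chan]]))
    }
  }

  list(
    devices = device_out, publish = publish_out,
    monitor = tibble::tibble(time_ms = mon_time, tf = mon_tf, channel = mon_chan, value = mon_val),
    registry = registry, warnings = warnings
  )
}

# ---------------------------------------------------------------------------
# reusable TF library

#' Fraction of red pixels in each image half
#'
#' A pixel counts as red iff R >= 2 G, R >= 2 B and R >= 64 (8-bit scale).
#' For odd widths the center column belongs to the left half.
#'
#' @param image an `nl_image` (H x W x 3, 0-255).
#' @return named numeric `c(left, right)`, each in \[0, 1\].
#' @export
detect_red <- function(image) {
  r <- image[, , 1]
  g <- image[, , 2]
  b <- image[, , 3]
  red <- r >= 2 * g & r >= 2 * b & r >= 64
  w <- ncol(red)
  left_cols <- seq_len(ceiling(w / 2))
  left <- mean(red[, left_cols])
  right <- if (w > length(left_cols)) mean(red[, -left_cols]) else 0
  c(left = left, right = right)
}

#' Map red ratios to the three sensor-channel Poisson rates
#'
#' `rate_left = r_max * left`, `rate_right = r_max * right`, and a "go"
#' channel active in the absence of red: `rate_go = r_max * (1 - max(left,
#' right))`.
#'
#' @param left,right red-pixel ratios in \[0, 1\].
#' @param r_max maximum generator rate (Hz), default 2000.
#' @return named numeric `c(left, right, go)` in Hz.
#' @export
rates_from_ratios <- function(left, right, r_max = 2000) {
  stopifnot(left >= 0, left <= 1, right >= 0, right <= 1)
  c(left = r_max * left, right = r_max * right, go = r_max * (1 - max(left, right)))
}

#' Wheel speeds from the actor leaky-integrator potentials
#'
#' Deflections above the device resting potential are normalized by `scale`
#' and clamped to \[0, 1\]; each wheel is driven by its own side's
#' deflection with cross-inhibition from the other: `left = k (uL - beta
#' uR)`, `right = k (uR - beta uL)`. Equal deflections give equal positive
#' speeds (straight motion); `uR >> uL` turns the robot counterclockwise.
#'
#' @param vL,vR leaky-integrator potentials (mV).
#' @param v_rest device resting potential (mV).
#' @param scale deflection giving full drive (mV).
#' @param k speed gain (m/s).
#' @param beta cross-inhibition, 0 < beta < 1.
#' @return named numeric `c(left, right)` wheel speeds (m/s).
#' @export
wheel_cmd_from_voltages <- function(vL, vR, v_rest = 0, scale = 5, k = 1.0, beta = 0.5) {
  stopifnot(is.finite(vL), is.finite(vR))
  uL <- clamp((vL - v_rest) / scale, 0, 1)
  uR <- clamp((vR - v_rest) / scale, 0, 1)
  c(left = k * (uL - beta * uR), right = k * (uR - beta * uL))
}

# ---------------------------------------------------------------------------
# monitor sink

#' Create a monitor sink
#' @param channels declared channel names.
#' @return an `nl_monitor`.
#' @export
monitor_sink <- function(channels = character(0)) {
  structure(list(channels = channels, records = list()), class = "nl_monitor")
}

#' Append a record to a monitor sink
#'
#' @param sink an `nl_monitor`.
#' @param time_ms simulated time.
#' @param channel declared channel name.
#' @param value scalar or numeric vector.
#' @param tf source TF name.
#' @return the updated sink.
#' @export
record_monitor <- function(sink, time_ms, channel, value, tf = NA_character_) {
  if (!channel %in% sink$channels) {
    abort(paste0("undeclared monitor channel '", channel, "'"))
  }
  sink$records[[length(sink$records) + 1L]] <-
    list(time_ms = time_ms, tf = tf, channel = channel, value = value)
  sink
}

#' Monitor records as a tibble
#'
#' @param sink an `nl_monitor`.
#' @return tibble with columns `time_ms`, `tf`, `channel`, `value`
#'   (list-column; scalars for simple channels).
#' @export
monitor_records <- function(sink) {
  if (!length(sink$records)) {
    return(tibble::tibble(
      time_ms = numeric(0), tf = character(0),
      channel = character(0), value = list()
    ))
  }
  tibble::tibble(
    time_ms = vapply(sink$records, `[[`, numeric(1), "time_ms"),
    tf = vapply(sink$records, `[[`, character(1), "tf"),
    channel = vapply(sink$records, `[[`, character(1), "channel"),
    value = lapply(sink$records, `[[`, "value")
  )
}
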