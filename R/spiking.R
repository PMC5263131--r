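#' Default leaky integrate-and-fire parameters
#'
#' Typical cortical point-neuron values used throughout the packaged
#' experiments: membrane time constant 20 ms, resting and reset potential
#' -70 mV, threshold -55 mV, absolute refractory period 2 ms, exponential
#' current synapse with 5 ms decay, membrane resistance 10 MOhm.
#'
#' @param ... named overrides of any field (`tau_m`, `v_rest`, `v_reset`,
#'   `v_thresh`, `tau_refrac`, `tau_syn`, `r_m`).
#' @return a named list of LIF parameters.
#' @export
#' @examples
#' lif_params(tau_m = 10)
lif_params <- function(...) {
  p <- list(
    tau_m = 20, v_rest = -70, v_reset = -70, v_thresh = -55,
    tau_refrac = 2, tau_syn = 5, r_m = 10
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) abort(paste0("unknown LIF parameter(s): ", paste(bad, collapse = ", ")))
    p[names(ov)] <- ov
  }
  with(p, {
    if (any(c(tau_m, tau_refrac, tau_syn) <= 0)) abort("LIF time constants must be > 0")
    if (v_thresh <= v_reset) abort("v_thresh must exceed v_reset")
    if (v_thresh <= v_rest) abort("v_thresh must exceed v_rest")
  })
  p
}

#' Build a spiking network from a declarative brain description
#'
#' The description is a plain list (usually read from the `brain:` block of
#' an experiment config) with `populations`, optional `views` (named index
#' sets over populations; overlapping sets alias the same neurons), and
#' optional `projections`:
#'
#' ```
#' list(
#'   dt = 1,
#'   populations = list(sensors = list(size = 3), actors = list(size = 2)),
#'   views = list(left_sensor = list(pop = "sensors", idx = 1)),
#'   projections = list(
#'     list(pre = "sensors", post = "actors", weights = 0.5, delay = 1)
#'   )
#' )
#' ```
#'
#' Projection `weights` may be a scalar (dense all-to-all), a |pre| x |post|
#' matrix in nA per presynaptic spike, or `"one_to_one"` with a `weight`
#' scalar. Delays are in ms and are rounded up to the nearest neural step.
#'
#' @param description brain description list.
#' @param seed optional integer seed for the network's private RNG stream
#'   (Poisson generator devices).
#' @return an object of class `nl_network`.
#' @export
build_network <- function(description = list(), seed = NULL) {
  dt <- description$dt %||% 1
  stopifnot(dt > 0)
  pops <- description$populations %||% list()
  if (length(pops) && is.null(names(pops))) abort("populations must be named")

  offset <- 0L
  pop_tbl <- list()
  par_vec <- lapply(names(lif_params()), function(x) numeric(0))
  names(par_vec) <- names(lif_params())
  for (nm in names(pops)) {
    p <- pops[[nm]]
    size <- as.integer(p$size %||% abort(paste0("population '", nm, "' has no size")))
    if (size < 1L) abort(paste0("population '", nm, "' must have size >= 1"))
    params <- do.call(lif_params, as.list(p$params %||% list()))
    pop_tbl[[nm]] <- list(offset = offset, size = size, params = params)
    for (f in names(par_vec)) par_vec[[f]] <- c(par_vec[[f]], rep(params[[f]], size))
    offset <- offset + size
  }
  n <- offset

  views <- lapply(pop_tbl, function(p) p$offset + seq_len(p$size))
  for (nm in names(description$views %||% list())) {
    v <- description$views[[nm]]
    if (is.numeric(v)) {
      idx <- as.integer(v)
    } else {
      base <- views[[v$pop %||% ""]]
      if (is.null(base)) abort(paste0("view '", nm, "' references unknown population '", v$pop, "'"))
      idx <- base[as.integer(v$idx %||% seq_along(base))]
    }
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > n)) {
      abort(paste0("view '", nm, "' has out-of-range indices"))
    }
    views[[nm]] <- idx
  }

  projections <- list()
  max_delay <- 1L
  for (pr in description$projections %||% list()) {
    pre <- resolve_indices(views, pr$pre, n)
    post <- resolve_indices(views, pr$post, n)
    delay_ms <- pr$delay %||% dt
    if (delay_ms < dt) abort("projection delay must be >= neural dt")
    delay_steps <- as.integer(ceiling(delay_ms / dt))
    w <- pr$weights %||% pr$weight %||% abort("projection has no weights")
    if (identical(w, "one_to_one")) {
      if (length(pre) != length(post)) abort("one_to_one projection needs |pre| == |post|")
      W <- diag(pr$weight %||% 1, length(pre))
    } else if (is.matrix(w)) {
      W <- w
    } else if (is.list(w)) { # rows from YAML
      W <- do.call(rbind, lapply(w, as.numeric))
    } else {
      W <- matrix(as.numeric(w), length(pre), length(post))
    }
    if (!all(dim(W) == c(length(pre), length(post)))) {
      abort(sprintf(
        "projection weight matrix is %dx%d, expected %dx%d",
        nrow(W), ncol(W), length(pre), length(post)
      ))
    }
    projections[[length(projections) + 1L]] <-
      list(pre = pre, post = post, W = W, delay_steps = delay_steps)
    max_delay <- max(max_delay, delay_steps)
  }

  net <- structure(
    list(
      dt = dt, time = 0, step = 0L, n = n,
      pops = pop_tbl, views = views, projections = projections,
      tau_m = par_vec$tau_m, v_rest = par_vec$v_rest, v_reset = par_vec$v_reset,
      v_thresh = par_vec$v_thresh, tau_refrac = par_vec$tau_refrac,
      tau_syn = par_vec$tau_syn, r_m = par_vec$r_m,
      dec_m = exp(-dt / par_vec$tau_m), dec_syn = exp(-dt / par_vec$tau_syn),
      v = par_vec$v_rest, i_syn = numeric(n), refrac = numeric(n),
      max_delay = max_delay,
      queue = matrix(0, nrow = max_delay, ncol = max(n, 1L)),
      devices = list(),
      rng = if (!is.null(seed)) rng_state_new(seed),
      spike_times = list(), spike_ids = list(), n_spikes = 0L
    ),
    class = "nl_network"
  )
  net
}

resolve_indices <- function(views, ref, n) {
  if (is.null(ref)) abort("projection endpoint missing")
  if (is.numeric(ref)) {
    idx <- as.integer(ref)
  } else {
    idx <- views[[ref]]
    if (is.null(idx)) abort(paste0("unknown population or view '", ref, "'"))
  }
  if (any(idx < 1L) || any(idx > n)) abort("neuron index out of range")
  idx
}

#' @export
print.nl_network <- function(x, ...) {
  cat(sprintf(
    "<nl_network> %d neurons, %d populations, %d projections, %d devices, t = %g ms\n",
    x$n, length(x$pops), length(x$projections), length(x$devices), x$time
  ))
  invisible(x)
}

#' Number of neurons in a network
#' @param net an `nl_network`.
#' @return integer neuron count.
#' @export
neuron_count <- function(net) net$n

#' Synaptic fan-in of one neuron
#'
#' Counts distinct presynaptic neurons with a nonzero weight onto the given
#' (global, 1-based) neuron index across all projections.
#'
#' @param net an `nl_network`.
#' @param neuron global neuron index.
#' @return integer fan-in.
#' @export
fan_in <- function(net, neuron) {
  total <- integer(0)
  for (p in net$projections) {
    j <- which(p$post == neuron)
    if (length(j)) {
      total <- c(total, p$pre[rowSums(abs(p$W[, j, drop = FALSE])) > 0])
    }
  }
  length(unique(total))
}

# ---------------------------------------------------------------------------
# devices

DEVICE_KINDS <- c(
  "poisson_generator", "dc_generator", "spike_recorder",
  "population_rate", "leaky_integrator"
)

#' Attach a device to a network
#'
#' Devices are the abstract stimulus/readout entities through which transfer
#' functions talk to the network: `poisson_generator` and `dc_generator` on
#' the input side; `spike_recorder`, `population_rate` and `leaky_integrator`
#' on the output side.
#'
#' @param net an `nl_network`.
#' @param name device name (unique; re-adding replaces).
#' @param kind one of `r paste(DEVICE_KINDS, collapse = ", ")`.
#' @param target population/view name or global neuron indices.
#' @param ... kind-specific parameters: `rate` (Hz) and `weight` (nA/spike)
#'   for Poisson generators; `amplitude` (nA, scalar or per-neuron) for DC
#'   generators; `window` (ms) for recorders; `tau` (ms), `weight` (mV per
#'   source spike) for leaky integrators.
#' @return the updated network.
#' @export
add_device <- function(net, name, kind, target, ...) {
  if (!kind %in% DEVICE_KINDS) {
    abort(paste0("unknown device kind '", kind, "' (must be one of ",
                 paste(DEVICE_KINDS, collapse = ", "), ")"))
  }
  idx <- resolve_indices(net$views, target, net$n)
  if (!length(idx)) abort("device target must be non-empty")
  p <- list(...)
  dev <- switch(kind,
    poisson_generator = {
      rate <- p$rate %||% 0
      if (any(rate < 0)) abort("Poisson rate must be >= 0")
      list(rate = rate, weight = p$weight %||% 0.1)
    },
    dc_generator = {
      amp <- p$amplitude %||% 0
      if (any(!is.finite(amp))) abort("DC amplitude must be finite")
      list(amplitude = amp)
    },
    spike_recorder = list(window = p$window %||% 100, hist_t = numeric(0), hist_id = integer(0)),
    population_rate = {
      win <- p$window %||% 100
      if (win < net$dt) abort("population_rate window must be >= neural dt")
      steps <- as.integer(round(win / net$dt))
      list(window = win, counts = numeric(steps), ptr = 0L)
    },
    leaky_integrator = {
      list(
        tau = p$tau %||% 10, weight = p$weight %||% 1,
        v_rest = p$v_rest %||% 0, v = p$v_rest %||% 0
      )
    }
  )
  dev$kind <- kind
  dev$target <- idx
  net$devices[[name]] <- dev
  net
}

get_device <- function(net, name) {
  dev <- net$devices[[name]]
  if (is.null(dev)) abort(paste0("no device named '", name, "'"))
  dev
}

#' Update device control parameters
#'
#' Sets the controllable parameter of an input device: `rate` (Hz) of a
#' Poisson generator or `amplitude` (nA) of a DC generator. Used by transfer
#' functions; the new setting applies from the next neural step.
#'
#' @param net an `nl_network`.
#' @param name device name.
#' @param rate,amplitude new value (scalar, or one value per target neuron).
#' @return the updated network.
#' @export
set_device <- function(net, name, rate = NULL, amplitude = NULL) {
  dev <- get_device(net, name)
  if (!is.null(rate)) {
    if (dev$kind != "poisson_generator") abort("only poisson_generator devices take a rate")
    if (any(!is.finite(rate)) || any(rate < 0)) abort("Poisson rate must be finite and >= 0")
    dev$rate <- rate
  }
  if (!is.null(amplitude)) {
    if (dev$kind != "dc_generator") abort("only dc_generator devices take an amplitude")
    if (any(!is.finite(amplitude))) abort("DC amplitude must be finite")
    dev$amplitude <- amplitude
  }
  net$devices[[name]] <- dev
  net
}

#' Set the amplitude of a DC current generator
#'
#' @param net an `nl_network`.
#' @param name name of a `dc_generator` device.
#' @param amplitude current in nA, applied additively to each target neuron
#'   every step until changed.
#' @return the updated network.
#' @export
inject_current <- function(net, name, amplitude) {
  set_device(net, name, amplitude = amplitude)
}

#' Read the membrane potential of a leaky integrator device
#'
#' The device is itself a non-spiking leaky membrane (threshold disabled)
#' kicked by `weight` mV per source spike and decaying with its own `tau`.
#'
#' @param net an `nl_network`.
#' @param name name of a `leaky_integrator` device.
#' @return potential (mV).
#' @export
leaky_integrator_read <- function(net, name) {
  dev <- get_device(net, name)
  if (dev$kind != "leaky_integrator") abort(paste0("'", name, "' is not a leaky_integrator"))
  dev$v
}

#' Trailing-window population firing rate
#'
#' Mean single-neuron rate over the device's trailing window:
#' spikes / (window * population size), reported in Hz.
#'
#' @param net an `nl_network`.
#' @param name name of a `population_rate` device.
#' @return firing rate in Hz.
#' @export
population_rate <- function(net, name) {
  dev <- get_device(net, name)
  if (dev$kind != "population_rate") abort(paste0("'", name, "' is not a population_rate device"))
  sum(dev$counts) / (dev$window / 1000) / length(dev$target)
}

#' Spikes recorded by a spike recorder within its trailing window
#'
#' @param net an `nl_network`.
#' @param name name of a `spike_recorder` device.
#' @return a tibble with columns `time_ms`, `neuron_id` (global indices).
#' @export
read_spikes <- function(net, name) {
  dev <- get_device(net, name)
  if (dev$kind != "spike_recorder") abort(paste0("'", name, "' is not a spike_recorder"))
  keep <- dev$hist_t > net$time - dev$window
  tibble::tibble(time_ms = dev$hist_t[keep], neuron_id = dev$hist_id[keep])
}

#' Poisson spike count for one timestep
#'
#' Draws the number of spikes a Poisson generator emits in a step of `dt`
#' ms at the given rate: `count ~ Poisson(rate * dt / 1000)`. Uses the
#' session RNG, so it is reproducible under [set.seed()].
#'
#' @param rate rate in Hz (scalar or vector; one draw per element).
#' @param dt timestep in ms.
#' @return integer spike count(s).
#' @export
poisson_generate <- function(rate, dt) {
  if (any(!is.finite(rate)) || any(rate < 0)) abort("Poisson rate must be finite and >= 0")
  if (dt <= 0) abort("dt must be > 0")
  rpois(length(rate), rate * dt / 1000)
}

# ---------------------------------------------------------------------------
# integration

#' Advance the network by one or more neural timesteps
#'
#' Exponential-Euler integration of the LIF membrane and synaptic current,
#' holding each input constant across the step (exact for step-constant
#' drive). Neurons crossing threshold emit a spike, reset, and enter their
#' refractory period; projection spikes are queued with their transmission
#' delay; devices are updated in the same pass.
#'
#' @param net an `nl_network`.
#' @param dt timestep (ms); must equal the network's configured `dt`.
#' @param n_steps number of consecutive steps to take.
#' @return the updated network. Spikes emitted so far are available via
#'   [spike_records()].
#' @export
step_network <- function(net, dt = net$dt, n_steps = 1L) {
  if (!isTRUE(all.equal(dt, net$dt))) abort("dt must equal the configured neural timestep")
  if (net$n == 0L) {
    net$step <- net$step + as.integer(n_steps)
    net$time <- net$step * dt
    return(net)
  }

  poisson_names <- names(net$devices)[vapply(net$devices, function(d) d$kind == "poisson_generator", logical(1))]
  dc_names <- names(net$devices)[vapply(net$devices, function(d) d$kind == "dc_generator", logical(1))]

  i_ext <- numeric(net$n)
  for (nm in dc_names) {
    d <- net$devices[[nm]]
    i_ext[d$target] <- i_ext[d$target] + d$amplitude
  }

  for (k in seq_len(n_steps)) {
    s <- net$step + 1L
    row <- ((s - 1L) %% net$max_delay) + 1L
    delivered <- net$queue[row, ]
    net$queue[row, ] <- 0

    i_in <- numeric(net$n)
    if (length(poisson_names)) {
      draw <- function() {
        lapply(poisson_names, function(nm) {
          d <- net$devices[[nm]]
          rpois(length(d$target), rep_len(d$rate, length(d$target)) * net$dt / 1000)
        })
      }
      if (!is.null(net$rng)) {
        res <- rng_eval(net$rng, draw)
        net$rng <- res$state
        counts <- res$value
      } else {
        counts <- draw()
      }
      for (i in seq_along(poisson_names)) {
        d <- net$devices[[poisson_names[i]]]
        i_in[d$target] <- i_in[d$target] + counts[[i]] * d$weight
      }
    }

    net$i_syn <- net$i_syn * net$dec_syn + delivered + i_in
    v_inf <- net$v_rest + net$r_m * (net$i_syn + i_ext)
    net$v <- v_inf + (net$v - v_inf) * net$dec_m

    in_refrac <- net$refrac > 0
    if (any(in_refrac)) {
      net$v[in_refrac] <- net$v_reset[in_refrac]
      net$refrac[in_refrac] <- net$refrac[in_refrac] - net$dt
    }

    spiked <- which(!in_refrac & net$v >= net$v_thresh)
    net$step <- s
    net$time <- s * net$dt

    if (any(!is.finite(net$v))) {
      abort("non-finite membrane state", class = "neuroloop_fault")
    }

    if (length(spiked)) {
      net$v[spiked] <- net$v_reset[spiked]
      net$refrac[spiked] <- net$tau_refrac[spiked]
      sp <- logical(net$n)
      sp[spiked] <- TRUE
      for (p in net$projections) {
        fired <- sp[p$pre]
        if (any(fired)) {
          contrib <- colSums(p$W[fired, , drop = FALSE])
          drow <- ((s + p$delay_steps - 1L) %% net$max_delay) + 1L
          net$queue[drow, p$post] <- net$queue[drow, p$post] + contrib
        }
      }
      net$n_spikes <- net$n_spikes + 1L
      net$spike_times[[net$n_spikes]] <- rep(net$time, length(spiked))
      net$spike_ids[[net$n_spikes]] <- spiked
    }

    # device updates
    for (nm in names(net$devices)) {
      d <- net$devices[[nm]]
      if (d$kind == "leaky_integrator") {
        d$v <- d$v_rest + (d$v - d$v_rest) * exp(-net$dt / d$tau)
        if (length(spiked)) {
          nsp <- sum(match(spiked, d$target, nomatch = 0L) > 0L)
          if (nsp) d$v <- d$v + d$weight * nsp
        }
        net$devices[[nm]] <- d
      } else if (d$kind == "population_rate") {
        d$ptr <- (d$ptr %% length(d$counts)) + 1L
        d$counts[d$ptr] <- if (length(spiked)) sum(match(spiked, d$target, nomatch = 0L) > 0L) else 0
        net$devices[[nm]] <- d
      } else if (d$kind == "spike_recorder" && length(spiked)) {
        hit <- spiked[match(spiked, d$target, nomatch = 0L) > 0L]
        if (length(hit)) {
          keep <- d$hist_t > net$time - d$window
          d$hist_t <- c(d$hist_t[keep], rep(net$time, length(hit)))
          d$hist_id <- c(d$hist_id[keep], hit)
          net$devices[[nm]] <- d
        }
      }
    }
  }
  net
}

#' All spikes emitted so far
#'
#' @param net an `nl_network`.
#' @return a tibble with columns `time_ms` and `neuron_id` (global 1-based
#'   indices), ordered by time then neuron.
#' @export
spike_records <- function(net) {
  tibble::tibble(
    time_ms = unlist(net$spike_times) %||% numeric(0),
    neuron_id = unlist(net$spike_ids) %||% integer(0)
  )
}

# reset all dynamic state (membrane, synapses, queues, devices, logs);
# structure, parameters and the RNG stream position are preserved unless
# reseed is given.
reset_network_state <- function(net, seed = NULL) {
  net$v <- net$v_rest
  net$i_syn <- numeric(net$n)
  net$refrac <- numeric(net$n)
  net$queue[] <- 0
  net$time <- 0
  net$step <- 0L
  net$spike_times <- list()
  net$spike_ids <- list()
  net$n_spikes <- 0L
  for (nm in names(net$devices)) {
    d <- net$devices[[nm]]
    if (d$kind == "leaky_integrator") d$v <- d$v_rest
    if (d$kind == "population_rate") { d$counts[] <- 0; d$ptr <- 0L }
    if (d$kind == "spike_recorder") { d$hist_t <- numeric(0); d$hist_id <- integer(0) }
    net$devices[[nm]] <- d
  }
  if (!is.null(seed)) net$rng <- rng_state_new(seed)
  net
}
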