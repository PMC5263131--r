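#' Timed-event workflow machine
#'
#' Timed events mutate the world during a run: they fire at the first
#' closed-loop step boundary whose simulated time reaches their `at_ms`,
#' in time order with declaration order breaking ties, and once-events fire
#' at most once across pause/resume cycles. Supported actions:
#' `set_screen_color` (args: `id`, `color`), `set_screen_pattern` (args:
#' `id`, `pattern`), `set_target` (args: `id`, `cx`, optional `cy`).
#'
#' @param events list of event records `list(at_ms =, action =, args =,
#'   once = TRUE)`.
#' @return an `nl_events` machine.
#' @export
workflow_machine <- function(events = list()) {
  events <- lapply(events, function(e) {
    if (is.null(e$at_ms) || e$at_ms < 0) abort("event needs at_ms >= 0")
    if (is.null(e$action)) abort("event needs an action")
    e$once <- e$once %||% TRUE
    e
  })
  ord <- order(vapply(events, `[[`, numeric(1), "at_ms")) # stable: ties keep declaration order
  structure(
    list(events = events[ord], fired = logical(length(events))),
    class = "nl_events"
  )
}

EVENT_ACTIONS <- c("set_screen_color", "set_screen_pattern", "set_target")

# initialize-time validation: every event must reference existing entities
validate_events <- function(machine, world) {
  for (e in machine$events) {
    if (!e$action %in% EVENT_ACTIONS) {
      abort(paste0("unknown event action '", e$action, "'"))
    }
    id <- e$args$id
    if (is.null(id) || !id %in% names(world$screens)) {
      abort(paste0("event action '", e$action, "' references unknown screen '", id %||% "<missing>", "'"))
    }
  }
  invisible(machine)
}

fire_event <- function(world, e) {
  switch(e$action,
    set_screen_color = set_screen_color(world, e$args$id, e$args$color),
    set_screen_pattern = set_screen_pattern(world, e$args$id, e$args$pattern),
    set_target = {
      s <- world$screens[[e$args$id]]
      if (is.null(s$pattern)) abort(paste0("screen '", e$args$id, "' has no pattern"))
      s$pattern$cx <- e$args$cx
      if (!is.null(e$args$cy)) s$pattern$cy <- e$args$cy
      world$screens[[e$args$id]] <- s
      world
    },
    abort(paste0("unknown event action '", e$action, "'"), class = "neuroloop_fault")
  )
}

#' Fire all due events
#'
#' Called once per closed-loop step, after TF evaluation, with the step's
#' end time. All unfired events with `at_ms <= t` fire in order; an action
#' referencing a missing entity is a simulation fault.
#'
#' @param machine an `nl_events` machine.
#' @param world the `nl_world` to mutate.
#' @param t simulated time (ms).
#' @return `list(machine, world)`.
#' @export
events_tick <- function(machine, world, t) {
  for (i in seq_along(machine$events)) {
    e <- machine$events[[i]]
    if (!machine$fired[i] && e$at_ms <= t) {
      world <- tryCatch(fire_event(world, e), error = function(err) {
        abort(paste0("timed event at ", e$at_ms, " ms failed: ", conditionMessage(err)),
              class = "neuroloop_fault")
      })
      if (e$once) machine$fired[i] <- TRUE
    }
  }
  list(machine = machine, world = world)
}
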