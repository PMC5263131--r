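#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_point geom_line
#'   geom_step labs coord_equal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a closed-loop run
#'
#' For runs with a robot trajectory: the path in the plane with screens
#' overlaid. Otherwise all scalar monitor channels over time.
#'
#' @param object an `nl_run`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nl_run <- function(object, ...) {
  if (!is.null(object$trajectory)) {
    p <- ggplot(object$trajectory, aes(x = .data$x, y = .data$y)) +
      geom_path() +
      geom_point(data = object$trajectory[1, ], shape = 1, size = 3) +
      coord_equal() +
      labs(x = "x (m)", y = "y (m)", title = paste0("Trajectory: ", object$config$name))
    scr <- object$sim$world$screens
    if (length(scr)) {
      sd <- dplyr::bind_rows(lapply(names(scr), function(nm) {
        s <- scr[[nm]]
        tibble::tibble(x = s$center[1], y = s$center[2], screen = nm)
      }))
      p <- p + geom_point(data = sd, aes(x = .data$x, y = .data$y), shape = 15, size = 4)
    }
    return(p)
  }
  plot_channels(object)
}

#' Plot all scalar monitor channels of a run
#'
#' @param run an `nl_run`.
#' @param channels optional channel subset.
#' @return a ggplot, one facet per channel.
#' @export
plot_channels <- function(run, channels = NULL) {
  ch <- run$channels
  keep <- setdiff(names(ch), "time_ms")
  if (!is.null(channels)) keep <- intersect(keep, channels)
  long <- dplyr::bind_rows(lapply(keep, function(nm) {
    tibble::tibble(time_ms = ch$time_ms, channel = nm, value = ch[[nm]])
  }))
  ggplot(long, aes(x = .data$time_ms, y = .data$value)) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~channel, scales = "free_y") +
    labs(x = "time (ms)", y = NULL)
}

#' @rdname autoplot.nl_run
#' @export
autoplot.nl_sensorimotor_run <- function(object, ...) {
  ggplot(object$errors, aes(x = .data$iteration, y = .data$error_m)) +
    geom_line() +
    geom_point() +
    labs(x = "iteration", y = "TCP prediction error (m)")
}

#' @rdname autoplot.nl_run
#' @export
autoplot.nl_tracking_run <- function(object, ...) {
  tr <- object$traces
  long <- dplyr::bind_rows(
    tibble::tibble(time_ms = tr$time_ms, trace = "decoded", px = tr$decoded_px),
    tibble::tibble(time_ms = tr$time_ms, trace = "true", px = tr$true_px)
  )
  ggplot(long, aes(x = .data$time_ms, y = .data$px, linetype = .data$trace)) +
    geom_line(na.rm = TRUE) +
    labs(x = "time (ms)", y = "target pixel")
}

#' Raster plot of a network's spike records
#'
#' @param net an `nl_network` (or a tibble from [spike_records()]).
#' @return a ggplot raster of spike times by neuron.
#' @export
plot_spikes <- function(net) {
  sp <- if (inherits(net, "nl_network")) spike_records(net) else net
  ggplot(sp, aes(x = .data$time_ms, y = .data$neuron_id)) +
    geom_point(shape = ".", size = 2) +
    labs(x = "time (ms)", y = "neuron")
}

#' @importFrom rlang .data
NULL
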