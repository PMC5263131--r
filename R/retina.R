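#' Retina chain configuration
#'
#' Parameters of the red-green opponency processing chain. Each pathway is
#' the composition center-lowpass -> opponent subtraction in a leaky single
#' compartment -> static nonlinearity -> short-term plasticity:
#' `out = STP(NL(SC(lowpass(G_center(own)) , G_surround(other))))`.
#'
#' @param sigma_center,sigma_surround Gaussian widths in pixels; the center
#'   is narrow (1 px), the antagonistic surround broad (4 px). Either may be
#'   a per-pixel matrix (space-variant filtering).
#' @param tau_lowpass temporal low-pass time constant (ms) on the center.
#' @param tau_compartment leak time constant (ms) of the single compartment.
#' @param g_e,g_i excitatory (center) and inhibitory (surround) gains. The
#'   default imbalance (g_i < g_e) makes a neutral gray drive each pathway
#'   weakly, so STP adapts to it; a color step after the *opposite* color
#'   then meets a recovered synapse and responds harder — the opponency
#'   sensitization.
#' @param nonlinearity a list `list(kind =, gain =, offset =)`; kinds are
#'   `identity`, `rectifier`, `sigmoid`.
#' @param stp_depression depletion per unit output per ms.
#' @param stp_tau_rec resource recovery time constant (ms).
#' @return a config list.
#' @export
retina_config <- function(sigma_center = 1, sigma_surround = 4,
                          tau_lowpass = 50, tau_compartment = 20,
                          g_e = 1.0, g_i = 0.6,
                          nonlinearity = list(kind = "rectifier", gain = 1, offset = 0),
                          stp_depression = 0.02, stp_tau_rec = 500) {
  stopifnot(
    all(sigma_center > 0), all(sigma_surround > 0),
    tau_lowpass > 0, tau_compartment > 0, stp_tau_rec > 0, stp_depression >= 0
  )
  list(
    sigma_center = sigma_center, sigma_surround = sigma_surround,
    tau_lowpass = tau_lowpass, tau_compartment = tau_compartment,
    g_e = g_e, g_i = g_i, nonlinearity = nonlinearity,
    stp_depression = stp_depression, stp_tau_rec = stp_tau_rec
  )
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution along one margin with edge renormalization (a constant
# map stays constant even at the borders)
conv_margin <- function(m, k, margin) {
  r <- (length(k) - 1L) %/% 2L
  n <- if (margin == 1) nrow(m) else ncol(m)
  out <- m * 0
  wsum <- numeric(n)
  acc <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) {
    shift <- j - r - 1L
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    if (margin == 1) {
      acc[which(ok), ] <- acc[which(ok), ] + k[j] * m[src[ok], , drop = FALSE]
    } else {
      acc[, which(ok)] <- acc[, which(ok)] + k[j] * m[, src[ok], drop = FALSE]
    }
    wsum[ok] <- wsum[ok] + k[j]
  }
  if (margin == 1) acc / wsum else sweep(acc, 2, wsum, "/")
}

#' Gaussian spatial filter (space-variant capable)
#'
#' Normalized Gaussian blur: a constant map is preserved exactly (kernels
#' are renormalized at the borders). A scalar `sigma` uses fast separable
#' convolution; a per-pixel sigma matrix computes each output pixel with
#' its own local kernel.
#'
#' @param m numeric matrix.
#' @param sigma Gaussian width in pixels: scalar, or matrix of `dim(m)`.
#' @return filtered matrix.
#' @export
gaussian_filter <- function(m, sigma) {
  if (length(sigma) == 1L) {
    if (sigma <= 0) abort("sigma must be > 0")
    k <- gauss_kernel(sigma)
    return(conv_margin(conv_margin(m, k, 1), k, 2))
  }
  stopifnot(all(dim(sigma) == dim(m)), all(sigma > 0))
  out <- m * 0
  nr <- nrow(m)
  nc <- ncol(m)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      s <- sigma[i, j]
      r <- max(1L, ceiling(3 * s))
      ri <- max(1L, i - r):min(nr, i + r)
      rj <- max(1L, j - r):min(nc, j + r)
      w <- exp(-(outer((ri - i)^2, (rj - j)^2, "+")) / (2 * s^2))
      out[i, j] <- sum(w * m[ri, rj]) / sum(w)
    }
  }
  out
}

#' One step of the temporal low-pass microcircuit
#'
#' Per-pixel forward-Euler relaxation `y <- y + (dt/tau) (x - y)`.
#'
#' @param state list with `tau` (ms) and `y` (output memory matrix, or NULL
#'   to start at zero).
#' @param x input map.
#' @param dt step (ms).
#' @return the updated state; the output map is `state$y`.
#' @export
lowpass_step <- function(state, x, dt) {
  stopifnot(dt > 0, state$tau > 0)
  y <- state$y %||% (x * 0)
  state$y <- y + (dt / state$tau) * (x - y)
  state
}

#' One step of the single-compartment microcircuit
#'
#' Leaky accumulation of opponent drive:
#' `v <- v + (dt/tau) (-v + g_e E - g_i I)` per pixel.
#'
#' @param state list with `tau` (ms), gains `g_e`, `g_i`, and potential `v`
#'   (or NULL to start at zero).
#' @param E,I excitatory and inhibitory input maps.
#' @param dt step (ms).
#' @return the updated state; the potential map is `state$v`.
#' @export
single_compartment_step <- function(state, E, I, dt) {
  stopifnot(dt > 0, state$tau > 0)
  v <- state$v %||% (E * 0)
  state$v <- v + (dt / state$tau) * (-v + state$g_e * E - state$g_i * I)
  state
}

#' Static nonlinearity
#'
#' Elementwise monotone non-decreasing map: `identity`
#' (`gain * x + offset`), `rectifier` (`gain * max(x - offset, 0)`), or
#' `sigmoid` (`1 / (1 + exp(-gain (x - offset)))`).
#'
#' @param m input map.
#' @param config list with `kind`, `gain`, `offset`.
#' @return mapped matrix.
#' @export
nonlinearity <- function(m, config) {
  gain <- config$gain %||% 1
  offset <- config$offset %||% 0
  if (gain < 0) abort("nonlinearity gain must be >= 0 (monotone non-decreasing)")
  switch(config$kind %||% "identity",
    identity = gain * m + offset,
    rectifier = gain * pmax(m - offset, 0),
    sigmoid = 1 / (1 + exp(-gain * (m - offset))),
    abort(paste0("unknown nonlinearity kind '", config$kind, "'"))
  )
}

#' One step of the short-term plasticity microcircuit
#'
#' Depressing synapse with a per-pixel resource `x` in \[0, 1\]:
#' `out = x * input`; the resource is depleted proportionally to the output
#' and recovers toward 1 with `tau_rec`:
#' `x <- x + dt ((1 - x)/tau_rec - depression * out)`, clamped to \[0, 1\].
#'
#' @param state list with `depression`, `tau_rec` (ms) and resource `x`
#'   (or NULL to start fully recovered).
#' @param input input map (non-negative after the rectifier).
#' @param dt step (ms).
#' @return the updated state; the output map is `state$out`.
#' @export
stp_step <- function(state, input, dt) {
  stopifnot(dt > 0, state$tau_rec > 0)
  x <- state$x %||% (input * 0 + 1)
  out <- x * input
  x <- x + dt * ((1 - x) / state$tau_rec - state$depression * out)
  state$x <- clamp(x, 0, 1)
  state$out <- out
  state
}

#' Create the stateful red-green opponency chain
#'
#' @param config a [retina_config()].
#' @return an `nl_retina` carrying the per-pixel state of both pathways.
#' @export
retina_init <- function(config = retina_config()) {
  structure(list(config = config, p1 = NULL, p2 = NULL), class = "nl_retina")
}

pathway_init <- function(cfg) {
  list(
    lp = list(tau = cfg$tau_lowpass, y = NULL),
    sc = list(tau = cfg$tau_compartment, g_e = cfg$g_e, g_i = cfg$g_i, v = NULL),
    stp = list(depression = cfg$stp_depression, tau_rec = cfg$stp_tau_rec, x = NULL)
  )
}

pathway_step <- function(pw, center_raw, surround_raw, cfg, dt) {
  center <- gaussian_filter(center_raw, cfg$sigma_center)
  surround <- gaussian_filter(surround_raw, cfg$sigma_surround)
  pw$lp <- lowpass_step(pw$lp, center, dt)
  pw$sc <- single_compartment_step(pw$sc, pw$lp$y, surround, dt)
  nl <- nonlinearity(pw$sc$v, cfg$nonlinearity)
  pw$stp <- stp_step(pw$stp, nl, dt)
  pw
}

#' Process one RGB frame through the opponency chain
#'
#' Pathway 1 is R+G- (red center, green surround), pathway 2 the exact
#' mirror, so swapping the input's R and G channels swaps the two outputs.
#' Outputs are per-pixel presynaptic-current maps (nA scale), not spikes.
#'
#' @param ret an `nl_retina`.
#' @param frame an `nl_image` (H x W x 3, 0-255) or numeric array in
#'   \[0, 1\].
#' @param dt frame interval (ms), normally the closed-loop timestep.
#' @return `list(ret, p1, p2)`: the updated chain and the two pathway maps.
#' @export
red_green_opponency <- function(ret, frame, dt) {
  cfg <- ret$config
  scale <- if (max(frame) > 1) 255 else 1
  R <- frame[, , 1] / scale
  G <- frame[, , 2] / scale
  if (is.null(ret$p1)) ret$p1 <- pathway_init(cfg)
  if (is.null(ret$p2)) ret$p2 <- pathway_init(cfg)
  ret$p1 <- pathway_step(ret$p1, R, G, cfg, dt)
  ret$p2 <- pathway_step(ret$p2, G, R, cfg, dt)
  list(ret = ret, p1 = ret$p1$stp$out, p2 = ret$p2$stp$out)
}

#' Extract the horizontal stripe intersecting the target
#'
#' Returns the per-pixel currents of both pathways at one image row,
#' stacked: first the full row of pathway 1, then the full row of pathway 2
#' (length `2 * width`).
#'
#' @param p1,p2 pathway output maps from [red_green_opponency()].
#' @param row 1-based row index.
#' @return numeric vector of length `2 * ncol`.
#' @export
extract_stripe <- function(p1, p2, row) {
  if (row < 1 || row > nrow(p1)) abort("stripe row out of range")
  c(p1[row, ], p2[row, ])
}

#' Build the two-layer spiking readout for the retina stripe
#'
#' Layer 1 (`2 * width` neurons, one per pathway pixel) converts the
#' stripe's presynaptic currents to spikes via a DC generator device;
#' layer 2 (same size) integrates locally: each neuron receives from a
#' 7-neuron window (stride 1, truncated at the edges) of its own pathway's
#' layer-1 block, so its spike count encodes local stripe activity — the
#' target's edges. With the default width 320 the network totals 1,280
#' integrate-and-fire neurons.
#'
#' @param width stripe width in pixels.
#' @param window fan-in window on layer 1 (odd).
#' @param weight layer-1 to layer-2 synaptic weight (nA per spike).
#' @param neural_dt neural timestep (ms).
#' @param seed RNG seed for the network stream.
#' @return an `nl_network` with populations `layer1` and `layer2` and a
#'   `dc_generator` device `"retina_input"` on layer 1 plus a
#'   `spike_recorder` `"layer2_spikes"` on layer 2.
#' @export
build_retina_brain <- function(width = 320, window = 7, weight = 3,
                               neural_dt = 1, seed = NULL) {
  n1 <- 2L * width
  half <- (window - 1L) %/% 2L
  pre <- integer(0)
  post <- integer(0)
  for (p in 0:1) {
    off <- p * width
    for (i in seq_len(width)) {
      src <- max(1L, i - half):min(width, i + half)
      pre <- c(pre, off + src)
      post <- c(post, rep(n1 + off + i, length(src)))
    }
  }
  W <- matrix(0, n1, n1)
  W[cbind(pre, post - n1)] <- weight
  description <- list(
    dt = neural_dt,
    populations = list(
      layer1 = list(size = n1),
      layer2 = list(size = n1, params = list(v_thresh = -65))
    ),
    projections = list(
      list(pre = "layer1", post = "layer2", weights = W, delay = neural_dt)
    )
  )
  net <- build_network(description, seed = seed)
  net <- add_device(net, "retina_input", "dc_generator", "layer1", amplitude = 0)
  net <- add_device(net, "layer2_spikes", "spike_recorder", "layer2", window = 100)
  net
}

#' Decode the target centroid from layer-2 spike counts
#'
#' Spike-count-weighted mean pixel position across the two pathway blocks;
#' absent (NA) when the total count is below `floor`.
#'
#' @param counts spike counts, length `2 * width` (layer-2 order).
#' @param width stripe width in pixels.
#' @param floor minimum total count for a valid decode.
#' @return centroid pixel (1-based, fractional) or `NA`.
#' @export
centroid_from_spikes <- function(counts, width = length(counts) %/% 2L, floor = 3) {
  if (length(counts) != 2L * width) abort("counts must cover both pathway blocks")
  total <- sum(counts)
  if (total < floor) return(NA_real_)
  pos <- rep(seq_len(width), 2L)
  sum(pos * counts) / total
}

#' Proportional eye command toward a decoded centroid
#'
#' Pixel-to-bearing geometry in image convention (bearing positive toward
#' the right edge): `bearing = ((px - 0.5)/width - 0.5) * fov`; the command
#' is `k_p * bearing`, clipped at `max_vel`. An absent centroid returns a
#' zero command (hold).
#'
#' @param centroid_px centroid pixel (1-based) or NA.
#' @param width image width in pixels.
#' @param fov horizontal field of view (rad).
#' @param k_p proportional gain (1/s).
#' @param max_vel saturation (rad/s).
#' @return pan velocity command (rad/s).
#' @export
eye_command <- function(centroid_px, width, fov, k_p = 3, max_vel = 1.5) {
  if (is.na(centroid_px)) return(0)
  bearing <- ((centroid_px - 0.5) / width - 0.5) * fov
  clamp(k_p * bearing, -max_vel, max_vel)
}
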