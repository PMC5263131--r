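# shared fixtures, all built in code

# one LIF neuron, optionally with a DC generator
one_neuron_net <- function(amplitude = NULL, seed = NULL, dt = 1, params = list()) {
  net <- build_network(
    list(dt = dt, populations = list(p = list(size = 1, params = params))),
    seed = seed
  )
  if (!is.null(amplitude)) {
    net <- add_device(net, "dc", "dc_generator", "p", amplitude = amplitude)
  }
  net
}

# 3-neuron feedforward chain 1 -> 2 -> 3 driven by DC on neuron 1
chain_net <- function(dt = 1, w = 8, drive = 3) {
  net <- build_network(list(
    dt = dt,
    populations = list(chain = list(size = 3)),
    projections = list(
      list(pre = 1, post = 2, weights = matrix(w), delay = 1),
      list(pre = 2, post = 3, weights = matrix(w), delay = 1)
    )
  ))
  add_device(net, "dc", "dc_generator", 1, amplitude = drive)
}

# minimal world: one robot facing +x, optional screens
simple_world <- function(screens = list(), res = 64, fov = pi / 2) {
  build_world(
    robots = list(bot = world_robot(pose2d(0, 0, 0), res_x = res, res_y = res, fov = fov)),
    screens = screens
  )
}

# a screen at distance d straight ahead subtending exactly `frac` of the fov
front_screen <- function(d = 2, frac = 0.5, fov = pi / 2, color = c(255, 0, 0)) {
  w <- 2 * d * tan(frac * fov / 2)
  world_screen(center = c(d, 0), width = w, height = 10 * w, color = color, angle = pi / 2)
}

# tiny closed-loop experiment: 1-neuron brain, impulse TFs for probing the
# synchronization contract
probe_experiment <- function(tfs = list(), cle = cle_config(cle_dt = 20, neural_dt = 1, seed = 7),
                             events = list()) {
  experiment_config(
    name = "probe",
    cle = cle,
    world = list(
      robots = list(bot = list(x = 0, y = 0, theta = 0, res_x = 8, res_y = 8))
    ),
    brain = list(populations = list(p = list(size = 1))),
    tfs = tfs,
    events = events
  )
}

started_sim <- function(cfg) {
  sim <- sim_initialize(simulation(cfg))
  stopifnot(sim$state == "initialized")
  sim_start(sim)
}

run_steps <- function(sim, n) {
  for (i in seq_len(n)) sim <- sim_step(sim)
  sim
}
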