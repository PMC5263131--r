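test_that("gaussian filter is normalized, local, and space-variant capable", {
  m <- matrix(0, 21, 21)
  m[11, 11] <- 1
  out <- gaussian_filter(m, 1.5) # kernel radius 5 clears the border zone
  expect_equal(sum(out), 1, tolerance = 1e-6) # kernel mass preserved
  expect_equal(which.max(out), which.max(m))

  const <- matrix(3.7, 9, 13)
  expect_equal(gaussian_filter(const, 4), const, tolerance = 1e-12) # borders renormalized

  tiny <- gaussian_filter(m, 0.05) # sigma -> 0: approaches identity
  expect_gt(tiny[11, 11], 0.999)

  m2 <- matrix(0, 15, 15)
  m2[8, 4] <- 1 # impulse inside the narrow-sigma zone
  sig <- matrix(1, 15, 15)
  sig[, 9:15] <- 3 # wider blur on the right half
  sv <- gaussian_filter(m2, sig)
  expect_equal(which.max(sv), which.max(m2))
  expect_error(gaussian_filter(m, 0), "sigma")
})

test_that("temporal low-pass matches 1 - exp(-t/tau) for a unit step", {
  tau <- 50
  st <- list(tau = tau, y = NULL)
  x <- matrix(1, 2, 2)
  dt <- tau / 100
  ts <- seq(dt, 10 * tau, by = dt)
  err <- 0
  for (t in ts) {
    st <- lowpass_step(st, x, dt)
    err <- max(err, abs(st$y[1, 1] - (1 - exp(-t / tau))))
  }
  expect_lt(err, 0.01) # forward-Euler tolerance at dt = tau/100
  expect_equal(st$y[1, 1], 1, tolerance = 1e-3) # converged after 10 tau

  slow <- list(tau = 1e7, y = NULL)
  for (i in 1:50) slow <- lowpass_step(slow, x, 1)
  expect_lt(max(slow$y), 1e-5) # tau >> run length: output ~ 0
})

test_that("single compartment finds its fixed point and cancels balanced drive", {
  st <- list(tau = 20, g_e = 1.5, g_i = 0.5, v = matrix(5, 1, 1))
  zero <- matrix(0, 1, 1)
  for (i in 1:2000) st <- single_compartment_step(st, zero, zero, 1)
  expect_equal(st$v[1, 1], 0, tolerance = 1e-8) # decays to zero

  st <- list(tau = 20, g_e = 1.5, g_i = 0.5, v = NULL)
  E <- matrix(2, 1, 1)
  for (i in 1:2000) st <- single_compartment_step(st, E, zero, 1)
  expect_equal(st$v[1, 1], 1.5 * 2, tolerance = 1e-6) # v* = g_e E

  st <- list(tau = 20, g_e = 1, g_i = 2, v = matrix(1, 1, 1))
  for (i in 1:2000) st <- single_compartment_step(st, matrix(4, 1, 1), matrix(2, 1, 1), 1)
  expect_equal(st$v[1, 1], 0, tolerance = 1e-6) # g_e E == g_i I cancels
})

test_that("nonlinearities are monotone and behave per kind", {
  m <- matrix(seq(-2, 2, length.out = 9), 3)
  expect_identical(nonlinearity(m, list(kind = "identity")), m)
  expect_true(all(nonlinearity(-abs(m), list(kind = "rectifier")) == 0))
  sig <- nonlinearity(m, list(kind = "sigmoid", gain = 50))
  expect_true(all(diff(as.vector(sig)[order(as.vector(m))]) >= 0))
  expect_lt(sig[1, 1], 1e-6) # large gain approaches a step function
  expect_gt(sig[3, 3], 1 - 1e-6)
  expect_error(nonlinearity(m, list(kind = "bogus")), "unknown nonlinearity")
})

test_that("short-term plasticity depresses under drive and recovers in silence", {
  st <- list(depression = 0.02, tau_rec = 500, x = NULL)
  one <- matrix(1, 1, 1)
  st <- stp_step(st, one, 20)
  early <- st$out[1, 1]
  for (i in 1:200) st <- stp_step(st, one, 20)
  late <- st$out[1, 1]
  expect_lt(late / early, 1) # depression
  expect_gte(min(st$x), 0)

  for (i in 1:500) st <- stp_step(st, matrix(0, 1, 1), 20) # long silence
  expect_equal(st$out[1, 1], 0)
  expect_gt(st$x[1, 1], 0.99) # resource recovered
  st2 <- stp_step(st, one, 20)
  expect_equal(st2$out[1, 1], early, tolerance = 0.01) # full-strength response
})

test_that("opponency is sensitized by the opposite color and channel-symmetric", {
  frame <- function(r, g, b = 0) {
    f <- array(0, c(5, 20, 3))
    f[, , 1] <- r; f[, , 2] <- g; f[, , 3] <- b
    f
  }
  run_seq <- function(frames) {
    ret <- retina_init()
    outs <- NULL
    for (f in frames) {
      outs <- red_green_opponency(ret, f, 20)
      ret <- outs$ret
    }
    outs
  }
  gray <- frame(0.5, 0.5, 0.5)
  red <- frame(1, 0)
  green <- frame(0, 1)

  # static gray: both pathway outputs settle near zero drive
  g_end <- run_seq(rep(list(gray), 100))
  expect_lt(max(g_end$p2), 0.2)

  # green after 500 ms of red responds harder than green after gray
  after_red <- run_seq(c(rep(list(red), 25), list(green)))
  after_gray <- run_seq(c(rep(list(gray), 25), list(green)))
  expect_gt(mean(after_red$p2), mean(after_gray$p2))

  # swapping R and G swaps the two pathway outputs exactly
  a <- run_seq(list(red, green, red))
  b <- run_seq(list(green, red, green))
  expect_equal(a$p1, b$p2, tolerance = 1e-12)
  expect_equal(a$p2, b$p1, tolerance = 1e-12)
})

test_that("with identity nonlinearity and no STP the chain is linear", {
  cfg <- retina_config(nonlinearity = list(kind = "identity"), stp_depression = 0)
  respond <- function(scale) {
    ret <- retina_init(cfg)
    f <- array(0, c(5, 12, 3))
    f[3, 6, 1] <- scale
    out <- NULL
    for (i in 1:10) {
      out <- red_green_opponency(ret, f, 20)
      ret <- out$ret
    }
    out$p1
  }
  expect_equal(respond(0.2) + respond(0.3), respond(0.5), tolerance = 1e-9)
})

test_that("stripe extraction stacks both pathways at the requested row", {
  p1 <- matrix(0, 17, 320)
  p2 <- matrix(0, 17, 320)
  expect_equal(length(extract_stripe(p1, p2, 9)), 640)
  expect_true(all(extract_stripe(p1, p2, 9) == 0))
  p1[9, 42] <- 1
  s <- extract_stripe(p1, p2, 9)
  expect_equal(which(s != 0), 42) # locality: only the hot pixel's slot
  expect_error(extract_stripe(p1, p2, 18), "out of range")
})

test_that("the retina readout brain has 1280 neurons in two layers, fan-in 7", {
  net <- build_retina_brain(width = 320, window = 7)
  expect_equal(neuron_count(net), 1280)
  expect_equal(length(net$views$layer1), 640)
  expect_equal(length(net$views$layer2), 640)
  l2 <- net$views$layer2
  expect_equal(fan_in(net, l2[160]), 7) # interior window
  expect_equal(fan_in(net, l2[1]), 4) # truncated at the edge
  expect_lte(fan_in(net, l2[320]), 7)
  # windows never cross the pathway boundary
  expect_equal(fan_in(net, l2[321]), 4)
})

test_that("centroid decoding is a spike-count-weighted mean with a floor", {
  expect_true(is.na(centroid_from_spikes(numeric(640), 320)))
  counts <- numeric(640)
  counts[c(150, 170)] <- 5 # symmetric around 160
  expect_equal(centroid_from_spikes(counts, 320), 160)
  counts <- numeric(640)
  counts[100:104] <- 2 # uniform cluster at 100..104
  expect_equal(centroid_from_spikes(counts, 320), 102)
  expect_true(is.na(centroid_from_spikes(c(rep(0, 639), 1), 320, floor = 3)))
})

test_that("eye command follows pixel-to-bearing geometry with saturation", {
  expect_equal(eye_command(160.5, 320, pi / 2), 0)
  cmd <- eye_command(320, 320, pi / 2, k_p = 1, max_vel = 10)
  expect_gt(cmd, 0) # right edge: positive bearing, positive command
  expect_equal(cmd, ((320 - 0.5) / 320 - 0.5) * pi / 2, tolerance = 1e-12)
  expect_equal(eye_command(320, 320, pi / 2, k_p = 100, max_vel = 1.5), 1.5) # clamp
  expect_equal(eye_command(NA, 320, pi / 2), 0) # absent centroid: hold
})
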