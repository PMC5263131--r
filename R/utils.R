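#' @importFrom rlang abort warn %||%
#' @importFrom stats rpois runif setNames
#' @importFrom utils modifyList
NULL

# wrap an angle to (-pi, pi]
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-component RNG seed from a master seed
#'
#' Stable FNV-1a style hash of the component name folded into the master
#' seed, kept inside the positive 32-bit integer range so it is always a
#' valid argument to [set.seed()].
#'
#' @param master integer master seed.
#' @param name component name (e.g. `"brain"`, `"tf:babble"`).
#' @return an integer seed.
#' @export
derive_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 2166136261
  for (b in utf8ToInt(name)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer((as.numeric(master) + h) %% 2147483647)
}

# --- private RNG streams ------------------------------------------------
# Components that draw random numbers (the network's Poisson generators,
# stateful TFs) carry their own saved .Random.seed so that the closed loop
# is deterministic regardless of what the calling session does with the
# global RNG.

rng_state_new <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_global_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  get(".Random.seed", envir = globalenv())
}

restore_global_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Evaluate fun() under the stream `state`; returns list(value, state).
rng_eval <- function(state, fun) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_global_rng(old), add = TRUE)
  assign(".Random.seed", state, envir = globalenv())
  value <- fun()
  list(value = value, state = get(".Random.seed", envir = globalenv()))
}

# short stable hash of an arbitrary R object (config manifests)
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2)[-(1:14)] # drop header
  h <- 5381
  for (b in as.integer(bytes)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
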