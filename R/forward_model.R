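#' Incremental forward-kinematics model on a trigonometric tensor basis
#'
#' Linear least squares from joint angles to TCP position on the basis of
#' all tensor products of (1, cos(theta_j), sin(theta_j)) over the joints
#' (3^n features). Planar revolute-chain forward kinematics lies exactly in
#' the span of this basis (angle-addition expansion of cos/sin of cumulative
#' sums), so with noiseless observations the fit becomes exact once the
#' samples span the basis. Sufficient statistics (Gram matrix and
#' cross-moments) are accumulated incrementally; the solve uses a tiny
#' ridge for numerical definiteness before the basis is covered.
#'
#' @param n_joints number of revolute joints.
#' @param ridge regularizer added to the Gram diagonal.
#' @return an untrained `nl_forward_model` (predicts the zero map).
#' @export
forward_model <- function(n_joints = 3, ridge = 1e-9) {
  d <- 3^n_joints
  structure(
    list(
      n_joints = n_joints, d = d, ridge = ridge,
      A = matrix(0, d, d), b = matrix(0, d, 2), n_samples = 0L,
      weights = NULL
    ),
    class = "nl_forward_model"
  )
}

fm_features <- function(angles) {
  Reduce(kronecker, lapply(angles, function(a) c(1, cos(a), sin(a))))
}

#' One motor-babbling training update
#'
#' Adds a single (joint configuration, observed TCP) pair to the sufficient
#' statistics. Repeating a sample the model already fits exactly leaves the
#' fit unchanged (least-squares consistency).
#'
#' @param model an `nl_forward_model`.
#' @param angles joint angles (rad).
#' @param tcp observed TCP position, length 2 (m).
#' @return the updated model.
#' @export
train_forward_model_step <- function(model, angles, tcp) {
  stopifnot(length(angles) == model$n_joints, length(tcp) == 2)
  phi <- fm_features(angles)
  model$A <- model$A + tcrossprod(phi)
  model$b <- model$b + phi %*% t(tcp)
  model$n_samples <- model$n_samples + 1L
  model$weights <- NULL # refit lazily
  model
}

fm_weights <- function(model) {
  if (is.null(model$weights)) {
    solve(model$A + diag(model$ridge, model$d), model$b)
  } else {
    model$weights
  }
}

#' Predict the TCP position for a joint configuration
#'
#' @param model an `nl_forward_model`.
#' @param angles joint angles (rad).
#' @return length-2 predicted TCP (m); the zero map before any training.
#' @export
predict_tcp <- function(model, angles) {
  if (model$n_samples == 0L) return(c(0, 0))
  as.numeric(crossprod(fm_weights(model), fm_features(angles)))
}

#' @export
print.nl_forward_model <- function(x, ...) {
  cat(sprintf(
    "<nl_forward_model> %d joints, %d basis functions, %d samples\n",
    x$n_joints, x$d, x$n_samples
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted forward-model coefficients
#'
#' @param x an `nl_forward_model`.
#' @param ... unused.
#' @return a tibble with one row per basis function and columns `term`,
#'   `estimate_x`, `estimate_y`.
#' @export
tidy.nl_forward_model <- function(x, ...) {
  labs <- Reduce(
    function(a, b) as.vector(outer(b, a, paste, sep = ":")),
    lapply(seq_len(x$n_joints), function(j) c("1", paste0("cos", j), paste0("sin", j)))
  )
  w <- if (x$n_samples) fm_weights(x) else matrix(0, x$d, 2)
  tibble::tibble(term = labs, estimate_x = w[, 1], estimate_y = w[, 2])
}

#' One-line summary of a forward model
#'
#' @param x an `nl_forward_model`.
#' @param ... unused.
#' @return a one-row tibble with `n_samples`, `n_basis`, `gram_rank`.
#' @export
glance.nl_forward_model <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples, n_basis = x$d,
    gram_rank = qr(x$A)$rank
  )
}
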