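# Core relaxation dynamics.
#
# The state update is the synchronous map
#   s^n <- sigma( bottomup_n(s^{n-1}) + topdown_n(s^{n+1}) [+ nudge] )
# with sigma the hard-sigmoid clamp to [0,1],
#   bottomup_n = P_n(w_n * s^{n-1} + b_n)          (conv, P = max pool)
#              = w_n . s^{n-1} + b_n               (fc)
#   topdown_n  = wtd_{n+1} *^T P_{n+1}^{-1}(s^{n+1})  (conv above)
#              = wtd_{n+1}^T . s^{n+1}             (fc above)
# where wtd is the forward weight (bidirectional) or the independent
# backward weight (unidirectional), P^{-1} scatters to the argmax positions
# recorded by P at the same time step, and the topmost layer has no
# top-down term.

clamp01 <- function(a) {
  a[a < 0] <- 0
  a[a > 1] <- 1
  a
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# input as seen by layer 1: raw 4-d array for a conv first layer,
# flattened matrix for an fc first layer
input_for_layer1 <- function(x, arch) {
  if (arch$layers[[1]]$type == "conv") x else flat(x)
}

# One full evaluation of the pre-activation structure at state s.
# Returns bu (bottom-up incl. bias, pooled), idx (argmax maps), td
# (top-down, NULL for top layer), pre (= bu + td).
ep_pass <- function(x, s, params, arch) {
  N <- arch$n_tot
  bu <- vector("list", N); idx <- vector("list", N); td <- vector("list", N)
  prev <- input_for_layer1(x, arch)
  for (n in seq_len(N)) {
    l <- arch$layers[[n]]
    if (l$type == "conv") {
      z <- cpp_conv2d_fwd(prev, params$w[[n]], params$b[[n]],
                          l$stride, l$pad)
      if (!is.null(l$pool)) {
        pr <- cpp_maxpool(z, l$pool$window, l$pool$stride)
        bu[[n]] <- pr$values
        idx[[n]] <- pr$idx
      } else bu[[n]] <- z
    } else {
      z <- tcrossprod(flat(prev), params$w[[n]])
      if (!is.null(params$b[[n]]))
        z <- z + rep(params$b[[n]], each = nrow(z))
      bu[[n]] <- z
    }
    prev <- s[[n]]
  }
  for (n in seq_len(N - 1L)) {
    lu <- arch$layers[[n + 1L]]
    wt <- topdown_weight(params, arch, n + 1L)
    if (lu$type == "conv") {
      u <- if (!is.null(lu$pool))
        cpp_unpool(s[[n + 1L]], idx[[n + 1L]], lu$conv_shape[2], lu$conv_shape[3])
      else s[[n + 1L]]
      td[[n]] <- cpp_conv2d_bwd_data(u, wt, lu$stride, lu$pad,
                                     lu$in_shape[2], lu$in_shape[3])
    } else {
      tdf <- s[[n + 1L]] %*% wt
      td[[n]] <- unflat(tdf, arch$layers[[n]]$state_shape)
    }
  }
  pre <- vector("list", N)
  for (n in seq_len(N))
    pre[[n]] <- if (is.null(td[[n]])) bu[[n]] else bu[[n]] + td[[n]]
  list(bu = bu, idx = idx, td = td, pre = pre)
}

# subgradient mask of the hard sigmoid: 1 strictly inside (0,1), 0 at
# saturation
pass_mask <- function(pass) {
  lapply(pass$pre, function(p) (p > 0 & p < 1) * 1)
}

#' Scalar primitive function of the network
#'
#' The energy-like primitive whose state-gradient generates the dynamics:
#' the sum over adjacent layer pairs of the generalized scalar product
#' between the upper state and the (pooled) bottom-up drive it receives.
#' It is bilinear in the states of adjacent layers and linear in each
#' parameter, and exists only for shared (bidirectional) weights.
#'
#' @param x input batch array \code{(n, C, H, W)}.
#' @param s network state.
#' @param params,arch parameters and architecture.
#' @return numeric vector, one primitive value per batch element.
#' @export
primitive_value <- function(x, s, params, arch) {
  if (arch$coupling != "bidirectional")
    stop("no primitive exists for unidirectional coupling")
  validate_shapes(x, s, arch)
  pass <- ep_pass(x, s, params, arch)
  phi <- numeric(dim(x)[1])
  for (n in seq_len(arch$n_tot))
    phi <- phi + rowSums(flat(s[[n]]) * flat(pass$bu[[n]]))
  phi
}

validate_shapes <- function(x, s, arch) {
  if (!identical(as.integer(dim(x)[-1]), arch$input_shape))
    stop("input shape (", paste(dim(x)[-1], collapse = ","),
         ") does not match architecture input (",
         paste(arch$input_shape, collapse = ","), ")")
  n <- dim(x)[1]
  dims <- state_dims(arch, n)
  for (k in seq_along(s)) {
    dk <- dim_or_len(s[[k]])
    if (!identical(as.integer(dk), as.integer(dims[[k]])))
      stop("layer ", k, ": state shape (", paste(dk, collapse = ","),
           ") does not match expected (", paste(dims[[k]], collapse = ","), ")")
  }
  invisible(TRUE)
}

#' One synchronous step of the free dynamics
#'
#' All layers are updated simultaneously from the current state; outputs are
#' clamped to [0, 1] by the hard sigmoid.
#'
#' @inheritParams primitive_value
#' @param masks optional per-layer multiplicative dropout masks (see
#'   \code{\link{dropout_mask}}).
#' @return list with \code{state} (the next state) and \code{idx} (per-layer
#'   pooling argmax maps recorded at this step).
#' @export
free_step <- function(x, s, params, arch, masks = NULL) {
  pass <- ep_pass(x, s, params, arch)
  finish_step(pass, masks)
}

finish_step <- function(pass, masks = NULL) {
  snew <- lapply(pass$pre, clamp01)
  if (!is.null(masks)) {
    for (n in seq_along(snew))
      if (!is.null(masks[[n]])) snew[[n]] <- snew[[n]] * masks[[n]]
  }
  for (n in seq_along(snew))
    if (any(!is.finite(snew[[n]])))
      stop("non-finite values in state at layer ", n)
  class(snew) <- "ep_state"
  list(state = snew, idx = pass$idx)
}

#' One synchronous step of the nudged dynamics
#'
#' Identical to \code{\link{free_step}} except that the output error, scaled
#' by the signed nudging strength \code{beta}, is added to the pre-activation
#' of the nudged layer: the output layer receives \code{beta * (y - yhat)} in
#' \code{mse_output_layer} mode, and the top layer receives
#' \code{beta * w_out^T (y - softmax(w_out s_top))} in \code{ce_readout}
#' mode. \code{beta = 0} reproduces the free step bit for bit.
#'
#' @inheritParams free_step
#' @param y integer labels in \code{0 .. C-1}.
#' @param beta signed nudging strength.
#' @return as \code{\link{free_step}}.
#' @export
nudged_step <- function(x, s, params, arch, y, beta, masks = NULL) {
  pass <- ep_pass(x, s, params, arch)
  if (beta != 0) {
    N <- arch$n_tot
    y1 <- one_hot(y, arch$n_classes)
    if (arch$loss == "mse_output_layer") {
      pass$pre[[N]] <- pass$pre[[N]] + beta * (y1 - s[[N]])
    } else {
      if (is.null(params$w_out))
        stop("ce_readout nudging requested but params$w_out is missing")
      yhat <- softmax_rows(tcrossprod(flat(s[[N]]), params$w_out))
      fb <- (y1 - yhat) %*% params$w_out
      pass$pre[[N]] <- pass$pre[[N]] +
        beta * unflat(fb, arch$layers[[N]]$state_shape)
    }
  }
  finish_step(pass, masks)
}

#' Relax the network for a fixed number of steps
#'
#' Iterates \code{\link{nudged_step}} (or the free step when
#' \code{beta = 0}) from \code{s0}. By convention the free phase starts from
#' the all-zero state while nudged phases start from the free steady state
#' supplied as \code{s0}. Residuals
#' \code{||s_{t+1} - s_t|| / (||s_t|| + 1e-12)} are recorded at every step.
#'
#' @inheritParams nudged_step
#' @param s0 starting state.
#' @param steps number of synchronous update steps (\code{>= 0}).
#' @param record if \code{TRUE}, keep the full state trajectory.
#' @return an object of class \code{ep_phase}: \code{final_state},
#'   \code{trajectory} (list of states or \code{NULL}), \code{pool_idx}
#'   (per-step argmax maps), \code{residuals}, \code{beta_used},
#'   \code{steps}.
#' @export
relax <- function(x, s0, params, arch, steps, y = NULL, beta = 0,
                  record = FALSE, masks = NULL) {
  stopifnot(steps >= 0)
  if (beta != 0 && is.null(y))
    stop("nudged relaxation (beta != 0) requires labels y")
  s <- s0
  residuals <- numeric(steps)
  pool_idx <- vector("list", steps)
  traj <- if (record) vector("list", steps) else NULL
  for (t in seq_len(steps)) {
    st <- tryCatch(
      if (beta == 0) free_step(x, s, params, arch, masks)
      else nudged_step(x, s, params, arch, y, beta, masks),
      error = function(e)
        stop("relaxation failed at step ", t, ": ", conditionMessage(e)))
    snew <- st$state
    num <- 0; den <- 0
    for (n in seq_along(s)) {
      num <- num + sum((snew[[n]] - s[[n]])^2)
      den <- den + sum(s[[n]]^2)
    }
    residuals[t] <- sqrt(num) / (sqrt(den) + 1e-12)
    pool_idx[[t]] <- st$idx
    if (record) traj[[t]] <- snew
    s <- snew
  }
  structure(list(final_state = s, trajectory = traj, pool_idx = pool_idx,
                 residuals = residuals, beta_used = beta, steps = steps),
            class = "ep_phase")
}

#' Class scores and predicted labels at a steady state
#'
#' In \code{ce_readout} mode, scores are \code{softmax(w_out . s_top)} (rows
#' sum to one); in \code{mse_output_layer} mode the output-layer state is
#' used directly.
#'
#' @inheritParams primitive_value
#' @param s_star a free-phase steady state.
#' @return list with \code{scores} (n x C matrix) and \code{labels}
#'   (0-based argmax).
#' @export
predict_state <- function(x, s_star, params, arch) {
  N <- arch$n_tot
  if (arch$loss == "ce_readout") {
    scores <- softmax_rows(tcrossprod(flat(s_star[[N]]), params$w_out))
  } else {
    scores <- flat(s_star[[N]])
  }
  list(scores = scores, labels = max.col(scores, ties.method = "first") - 1L)
}

#' Mean loss at the steady state of the free phase
#'
#' Runs a free relaxation from zero for \code{steps} steps and evaluates the
#' batch-mean loss: squared error \code{0.5 ||yhat - y||^2} in mse mode,
#' cross-entropy of the softmax readout in ce mode. Used as the target of
#' finite-difference oracles.
#'
#' @inheritParams nudged_step
#' @param steps free-phase length.
#' @return scalar mean loss.
#' @export
steady_state_loss <- function(x, y, params, arch, steps) {
  ph <- relax(x, zero_state(arch, dim(x)[1]), params, arch, steps)
  state_loss(x, ph$final_state, y, params, arch)
}

state_loss <- function(x, s, y, params, arch) {
  y1 <- one_hot(y, arch$n_classes)
  N <- arch$n_tot
  if (arch$loss == "mse_output_layer") {
    mean(rowSums((flat(s[[N]]) - y1)^2) / 2)
  } else {
    z <- tcrossprod(flat(s[[N]]), params$w_out)
    z <- z - apply(z, 1, max)
    logp <- z - log(rowSums(exp(z)))
    -mean(logp[cbind(seq_along(y), y + 1L)])
  }
}
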