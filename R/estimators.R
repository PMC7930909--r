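# EP gradient estimators.
#
# All estimators are built from two contraction primitives:
#  * phi_param_grad: dPhi/dtheta at fixed states (the local Hebbian-like
#    rule; fc weights get outer products of adjacent states, conv weights
#    the correlation of the unpooled upper state with the lower state).
#  * ep_dF_theta: (dF/dtheta)^T . d for an arbitrary layer-shaped vector d,
#    split into the bottom-up (forward-weight) and top-down
#    (backward-weight) contributions so the vector-field estimators can
#    address theta_f and theta_b separately.

# sum over batch, spatial dims -> per output channel (for conv biases)
chan_sum <- function(u) {
  d <- dim(u)
  cs <- colSums(matrix(u, d[1]))
  rowSums(matrix(cs, d[2]))
}

#' Parameter-gradient of the primitive at fixed states
#'
#' Returns the batch-mean derivative of \code{\link{primitive_value}} with
#' respect to every forward parameter, states held fixed. For an fc weight
#' this is the outer product of the adjacent layer states; for a conv
#' kernel it is the correlation of the upper state, scattered through the
#' argmax positions of the max pool recomputed at \code{s}, with the lower
#' state. Requires bidirectional coupling (the primitive must exist).
#'
#' @inheritParams primitive_value
#' @return estimate-shaped list with \code{w} and \code{b} slots.
#' @export
phi_param_grad <- function(x, s, params, arch) {
  if (arch$coupling != "bidirectional")
    stop("no primitive exists for unidirectional coupling")
  pass <- ep_pass(x, s, params, arch)
  n_batch <- dim(x)[1]
  d <- lapply(s, identity)  # contraction vector = the states themselves
  con <- ep_dF_theta(x, s, d, pass, params, arch, bottomup_only = TRUE)
  list(w = lapply(con$fw_w, function(g) g / n_batch),
       b = lapply(con$fw_b, function(g) if (is.null(g)) NULL else g / n_batch),
       wb = NULL, w_out = NULL)
}

# (dF/dtheta)^T . d with states held fixed, as unnormalized batch sums.
# d is a list of layer-shaped arrays. Returns:
#   fw_w, fw_b : contributions through the bottom-up drive of each layer
#                (the theta_f slots)
#   td_w       : contributions through the top-down drive (the theta_b
#                slots; entry n is shaped like w[[n]], defined for n >= 2)
# When bottomup_only = TRUE the top-down contraction is skipped (that is
# exactly dPhi/dtheta when d = s, since each parameter appears once in Phi).
ep_dF_theta <- function(x, s, d, pass, params, arch, bottomup_only = FALSE) {
  N <- arch$n_tot
  fw_w <- vector("list", N); fw_b <- vector("list", N)
  td_w <- vector("list", N)
  prev <- input_for_layer1(x, arch)
  for (n in seq_len(N)) {
    l <- arch$layers[[n]]
    if (l$type == "conv") {
      u <- if (!is.null(l$pool)) {
        if (is.null(pass$idx[[n]]))
          stop("missing pooling indices for conv layer ", n)
        cpp_unpool(d[[n]], pass$idx[[n]], l$conv_shape[2], l$conv_shape[3])
      } else d[[n]]
      fw_w[[n]] <- cpp_conv2d_bwd_weight(prev, u, l$stride, l$pad,
                                         l$kernel, l$kernel)
      if (!is.null(params$b[[n]])) fw_b[[n]] <- chan_sum(u)
    } else {
      fw_w[[n]] <- crossprod(d[[n]], flat(prev))
      if (!is.null(params$b[[n]])) fw_b[[n]] <- colSums(d[[n]])
    }
    prev <- s[[n]]
  }
  if (!bottomup_only) {
    for (n in seq_len(N - 1L)) {
      lu <- arch$layers[[n + 1L]]
      if (lu$type == "conv") {
        u_up <- if (!is.null(lu$pool))
          cpp_unpool(s[[n + 1L]], pass$idx[[n + 1L]],
                     lu$conv_shape[2], lu$conv_shape[3])
        else s[[n + 1L]]
        td_w[[n + 1L]] <- cpp_conv2d_bwd_weight(d[[n]], u_up, lu$stride,
                                                lu$pad, lu$kernel, lu$kernel)
      } else {
        td_w[[n + 1L]] <- crossprod(s[[n + 1L]], flat(d[[n]]))
      }
    }
  }
  list(fw_w = fw_w, fw_b = fw_b, td_w = td_w)
}

# adjoint of one synchronous step at fixed linearization point:
# given masked adjoints d (= mask * a), return a_new with
#   a_new^{n-1} += bottomup_n^T d^n,  a_new^{n+1} += topdown_n^T d^n
ep_adjoint_step <- function(d, pass, params, arch, n_batch) {
  N <- arch$n_tot
  a <- vector("list", N)
  dims <- state_dims(arch, n_batch)
  for (n in seq_len(N)) a[[n]] <- array(0, dim = dims[[n]])
  for (n in seq_len(N)) {
    l <- arch$layers[[n]]
    if (n >= 2) {
      if (l$type == "conv") {
        u <- if (!is.null(l$pool))
          cpp_unpool(d[[n]], pass$idx[[n]], l$conv_shape[2], l$conv_shape[3])
        else d[[n]]
        a[[n - 1L]] <- a[[n - 1L]] +
          cpp_conv2d_bwd_data(u, params$w[[n]], l$stride, l$pad,
                              l$in_shape[2], l$in_shape[3])
      } else {
        a[[n - 1L]] <- a[[n - 1L]] +
          unflat(d[[n]] %*% params$w[[n]], arch$layers[[n - 1L]]$state_shape)
      }
    }
    if (n <= N - 1L) {
      lu <- arch$layers[[n + 1L]]
      wt <- topdown_weight(params, arch, n + 1L)
      if (lu$type == "conv") {
        z <- cpp_conv2d_fwd(d[[n]], wt, NULL, lu$stride, lu$pad)
        a[[n + 1L]] <- a[[n + 1L]] +
          (if (!is.null(lu$pool)) cpp_pool_gather(z, pass$idx[[n + 1L]]) else z)
      } else {
        a[[n + 1L]] <- a[[n + 1L]] + tcrossprod(flat(d[[n]]), wt)
      }
    }
  }
  a
}

# forward Jacobian-vector product of one step at fixed linearization point
ep_jvp <- function(v, pass, mask, params, arch) {
  N <- arch$n_tot
  out <- vector("list", N)
  for (n in seq_len(N)) {
    l <- arch$layers[[n]]
    acc <- NULL
    if (n >= 2) {
      if (l$type == "conv") {
        z <- cpp_conv2d_fwd(v[[n - 1L]], params$w[[n]], NULL, l$stride, l$pad)
        acc <- if (!is.null(l$pool)) cpp_pool_gather(z, pass$idx[[n]]) else z
      } else {
        acc <- tcrossprod(flat(v[[n - 1L]]), params$w[[n]])
      }
    }
    if (n <= N - 1L) {
      lu <- arch$layers[[n + 1L]]
      wt <- topdown_weight(params, arch, n + 1L)
      tdv <- if (lu$type == "conv") {
        u <- if (!is.null(lu$pool))
          cpp_unpool(v[[n + 1L]], pass$idx[[n + 1L]],
                     lu$conv_shape[2], lu$conv_shape[3])
        else v[[n + 1L]]
        cpp_conv2d_bwd_data(u, wt, lu$stride, lu$pad,
                            l$state_shape[2], l$state_shape[3])
      } else {
        unflat(v[[n + 1L]] %*% wt, l$state_shape)
      }
      acc <- if (is.null(acc)) tdv else acc + tdv
    }
    if (is.null(acc)) acc <- array(0, dim = dim_or_len(v[[n]]))
    out[[n]] <- mask[[n]] * acc
  }
  out
}

new_estimate <- function(est, kind, beta, steps = NULL) {
  attr(est, "kind") <- kind
  attr(est, "beta") <- beta
  attr(est, "steps") <- steps
  class(est) <- "ep_estimate"
  est
}

#' One-sided (two-phase) EP gradient estimate
#'
#' \code{(1/beta) * (dPhi/dtheta(s_*^beta) - dPhi/dtheta(s_*))}; entrywise
#' for fc weights this is the local rule
#' \code{(s_i^b s_j^b - s_i s_j)/beta}. Carries an O(beta) bias.
#'
#' @param x input batch.
#' @param free free-phase result (\code{\link{relax}} with \code{beta = 0}).
#' @param nudged nudged-phase result started from the free steady state.
#' @param params,arch parameters and architecture.
#' @return an \code{ep_estimate} (batch-mean, ascent direction, i.e. an
#'   estimate of \code{-dL/dtheta}).
#' @export
one_sided_estimate <- function(x, free, nudged, params, arch) {
  beta <- nudged$beta_used
  if (beta == 0) stop("one-sided estimate requires a nonzero nudging beta")
  gp <- phi_param_grad(x, nudged$final_state, params, arch)
  g0 <- phi_param_grad(x, free$final_state, params, arch)
  est <- est_map2(gp, g0, function(a, b) (a - b) / beta)
  new_estimate(est, "one_sided", beta, c(free$steps, nudged$steps))
}

#' Symmetric (three-phase) EP gradient estimate
#'
#' \code{(1/2beta) * (dPhi/dtheta(s_*^{+beta}) - dPhi/dtheta(s_*^{-beta}))}.
#' Algebraically equal to the average of the one-sided estimates at
#' \code{+beta} and \code{-beta}; the O(beta) bias cancels, leaving
#' O(beta^2).
#'
#' @inheritParams one_sided_estimate
#' @param pos,neg nudged-phase results at \code{+beta} and \code{-beta},
#'   both started from the same free steady state.
#' @return an \code{ep_estimate}.
#' @export
symmetric_estimate <- function(x, pos, neg, params, arch) {
  beta <- pos$beta_used
  if (beta == 0 || neg$beta_used != -beta)
    stop("symmetric estimate requires phases at +beta and -beta (got ",
         pos$beta_used, " and ", neg$beta_used, ")")
  gp <- phi_param_grad(x, pos$final_state, params, arch)
  gn <- phi_param_grad(x, neg$final_state, params, arch)
  est <- est_map2(gp, gn, function(a, b) (a - b) / (2 * beta))
  new_estimate(est, "symmetric", abs(beta), c(pos$steps, neg$steps))
}

#' Random-sign one-sided EP estimate
#'
#' Draws the sign of \code{beta} uniformly (consuming the R RNG), runs a
#' single nudged phase with that signed strength via \code{run_nudged}, and
#' returns the one-sided estimate. Its expectation over the sign equals the
#' symmetric estimate; its variance is larger.
#'
#' @inheritParams one_sided_estimate
#' @param run_nudged function of one argument (the signed beta) returning a
#'   nudged \code{ep_phase} started from the free steady state.
#' @param beta positive nudging strength.
#' @return an \code{ep_estimate} with attribute \code{sign}.
#' @export
random_sign_estimate <- function(x, free, run_nudged, beta, params, arch) {
  stopifnot(beta > 0)
  sgn <- if (runif(1) < 0.5) 1 else -1
  nudged <- run_nudged(sgn * beta)
  est <- one_sided_estimate(x, free, nudged, params, arch)
  attr(est, "kind") <- "random_sign"
  attr(est, "sign") <- sgn
  est
}

#' Vector-field (VF) gradient estimate
#'
#' \code{(1/beta) * (dF/dtheta)^T(x, s_*, theta) . (s_*^beta - s_*)}, the
#' theta-gradient of \code{F(x, s_*, theta) . (s_*^beta - s_*)} with states
#' held fixed. Valid for general transition functions F, in particular with
#' unidirectional weights; when F derives from the primitive it agrees with
#' the one-sided estimate in the limit \code{beta -> 0}.
#'
#' @inheritParams one_sided_estimate
#' @return an \code{ep_estimate}; in unidirectional mode the \code{wb}
#'   slots hold the backward-weight estimates.
#' @export
vf_estimate <- function(x, free, nudged, params, arch) {
  beta <- nudged$beta_used
  if (beta == 0) stop("VF estimate requires a nonzero nudging beta")
  s0 <- free$final_state
  pass <- ep_pass(x, s0, params, arch)
  m <- pass_mask(pass)
  d <- lapply(seq_along(s0), function(n)
    m[[n]] * (nudged$final_state[[n]] - s0[[n]]))
  con <- ep_dF_theta(x, s0, d, pass, params, arch)
  n_batch <- dim(x)[1]
  assemble_vf(con, params, arch, 1 / (beta * n_batch), "vf", abs(beta))
}

#' Symmetric vector-field estimate
#'
#' The symmetric-difference analogue of \code{\link{vf_estimate}}:
#' \code{(1/2beta) (dF/dtheta)^T(x, s_*, theta) . (s_*^{+b} - s_*^{-b})},
#' with the forward and backward weight slots each receiving their own
#' contraction (which is what lets forward and backward weights drift
#' apart during training, unlike the Kolen-Pollack rule).
#'
#' @inheritParams symmetric_estimate
#' @param free free-phase result.
#' @return an \code{ep_estimate}.
#' @export
sym_vf_estimate <- function(x, free, pos, neg, params, arch) {
  beta <- pos$beta_used
  if (beta == 0 || neg$beta_used != -beta)
    stop("symmetric VF estimate requires phases at +beta and -beta")
  s0 <- free$final_state
  pass <- ep_pass(x, s0, params, arch)
  m <- pass_mask(pass)
  d <- lapply(seq_along(s0), function(n)
    m[[n]] * (pos$final_state[[n]] - neg$final_state[[n]]))
  con <- ep_dF_theta(x, s0, d, pass, params, arch)
  n_batch <- dim(x)[1]
  assemble_vf(con, params, arch, 1 / (2 * beta * n_batch), "sym_vf", abs(beta))
}

assemble_vf <- function(con, params, arch, scale, kind, beta) {
  est <- est_zero(params)
  N <- arch$n_tot
  for (n in seq_len(N)) {
    est$w[[n]] <- con$fw_w[[n]] * scale
    if (!is.null(con$fw_b[[n]])) est$b[[n]] <- con$fw_b[[n]] * scale
  }
  if (arch$coupling == "bidirectional") {
    for (n in seq_len(N)) if (!is.null(con$td_w[[n]]))
      est$w[[n]] <- est$w[[n]] + con$td_w[[n]] * scale
  } else {
    for (n in seq_len(N)) if (!is.null(params$wb[[n]]))
      est$wb[[n]] <- con$td_w[[n]] * scale
  }
  est$w_out <- NULL
  new_estimate(est, kind, beta)
}

#' Kolen-Pollack vector-field (KP-VF) estimate
#'
#' Three-phase estimate for unidirectional weights in which forward and
#' backward connections receive the identical update. For each of
#' \code{theta_f} and \code{theta_b} the symmetric contraction
#' \code{(1/2beta) [ (dF/dtheta_i)^T(s^{+b}) . s^{+b} -
#' (dF/dtheta_i)^T(s^{-b}) . s^{-b} ]} is formed, and the two shape-matched
#' halves are averaged into a single shared estimate assigned to both the
#' forward and backward slots of every connection that has a backward
#' weight. Pooling and unpooling share the argmax index maps.
#'
#' @inheritParams symmetric_estimate
#' @return an \code{ep_estimate} whose \code{w[[n]]} and \code{wb[[n]]}
#'   entries are identical arrays for every backward-connected layer.
#' @export
kp_vf_estimate <- function(x, pos, neg, params, arch) {
  if (is.null(params$wb))
    stop("KP-VF estimate requires unidirectional coupling (backward weights)")
  beta <- pos$beta_used
  if (beta == 0 || neg$beta_used != -beta)
    stop("KP-VF estimate requires phases at +beta and -beta")
  n_batch <- dim(x)[1]
  contract_at <- function(ph) {
    s <- ph$final_state
    pass <- ep_pass(x, s, params, arch)
    m <- pass_mask(pass)
    d <- lapply(seq_along(s), function(n) m[[n]] * s[[n]])
    ep_dF_theta(x, s, d, pass, params, arch)
  }
  cp <- contract_at(pos)
  cn <- contract_at(neg)
  sc <- 1 / (2 * beta * n_batch)
  est <- est_zero(params)
  N <- arch$n_tot
  for (n in seq_len(N)) {
    gf <- (cp$fw_w[[n]] - cn$fw_w[[n]]) * sc
    if (!is.null(cp$fw_b[[n]]))
      est$b[[n]] <- (cp$fw_b[[n]] - cn$fw_b[[n]]) * sc
    if (!is.null(params$wb[[n]])) {
      gb <- (cp$td_w[[n]] - cn$td_w[[n]]) * sc
      shared <- (gf + gb) / 2
      est$w[[n]] <- shared
      est$wb[[n]] <- shared
    } else {
      est$w[[n]] <- gf
    }
  }
  est$w_out <- NULL
  new_estimate(est, "kp_vf", abs(beta))
}

#' Readout-weight estimate (cross-entropy mode)
#'
#' The exact ascent direction \code{(y - yhat_*) . s_top^T} of the negative
#' cross-entropy at the free steady state (the free state does not depend
#' on \code{w_out}, so this carries no nudging bias). Local in pre- and
#' post-synaptic activity.
#'
#' @inheritParams one_sided_estimate
#' @param s_star free steady state.
#' @param y integer labels.
#' @return matrix shaped like \code{params$w_out}.
#' @export
readout_estimate <- function(x, s_star, y, params, arch) {
  if (arch$loss != "ce_readout") stop("readout estimate only exists in ce_readout mode")
  top <- flat(s_star[[arch$n_tot]])
  yhat <- softmax_rows(tcrossprod(top, params$w_out))
  crossprod(one_hot(y, arch$n_classes) - yhat, top) / dim(x)[1]
}

#' Apply a gradient-ascent update to the parameters
#'
#' SGD on the EP estimate (which approximates \code{-dL/dtheta}, so ascent
#' on the estimate descends the loss), with momentum, decoupled weight
#' decay, and -- for the KP-VF rule -- an equal leakage \code{-eta*lambda*theta}
#' on forward and backward weights so that with plain SGD one step contracts
#' \code{theta_f - theta_b} by exactly \code{(1 - eta*lambda)}.
#'
#' @param params current \code{ep_params}.
#' @param est an \code{ep_estimate} (slots may be \code{NULL} to skip).
#' @param lr numeric vector of per-layer learning rates, one per layer
#'   (connection \code{n} uses \code{lr[n]}; \code{w_out}, when present in
#'   the estimate, uses the last element).
#' @param momentum,weight_decay scalars.
#' @param lambda KP leakage (applied to \code{w}/\code{wb} only; 0 disables).
#' @param opt_state momentum buffers from the previous call, or \code{NULL}.
#' @return list with updated \code{params} and \code{opt_state}.
#' @export
apply_update <- function(params, est, lr, momentum = 0, weight_decay = 0,
                         lambda = 0, opt_state = NULL) {
  if (any(lr < 0)) stop("learning rates must be nonnegative")
  if (is.null(opt_state)) opt_state <- list()
  N <- length(params$w)
  upd <- function(p, g, eta, key, leak) {
    if (is.null(g) || eta == 0) return(p)
    buf <- opt_state[[key]]
    buf <- if (is.null(buf)) g else momentum * buf + g
    opt_state[[key]] <<- buf
    p + eta * buf - eta * weight_decay * p - eta * leak * p
  }
  for (n in seq_len(N)) {
    paired <- !is.null(params$wb) && !is.null(params$wb[[n]])
    # leakage only acts on forward/backward pairs (it exists to pull the
    # two members of a pair onto each other; unpaired weights get none)
    params$w[[n]] <- upd(params$w[[n]], est$w[[n]], lr[n],
                         paste0("w", n), if (paired) lambda else 0)
    if (!is.null(params$b[[n]]))
      params$b[[n]] <- upd(params$b[[n]], est$b[[n]], lr[n],
                           paste0("b", n), 0)
    if (paired)
      params$wb[[n]] <- upd(params$wb[[n]], est$wb[[n]], lr[n],
                            paste0("wb", n), lambda)
  }
  if (!is.null(params$w_out) && !is.null(est$w_out))
    params$w_out <- upd(params$w_out, est$w_out, lr[length(lr)], "w_out", 0)
  list(params = params, opt_state = opt_state)
}
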