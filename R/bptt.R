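# Truncated BPTT reference gradients.
#
# Under the convergence hypothesis (s_{T-t} = ... = s_T = s_*), every
# Jacobian of the unrolled free phase can be evaluated at the steady state,
# so the reverse accumulation needs no stored trajectory and is O(1) in
# memory. The adjoint is seeded with dl/ds at s_* and propagated through
# the masked linearization of the synchronous step; parameter gradients
# accumulate through (dF/dtheta)^T at every unrolled step. The returned
# arrays are negated so they are loss-DECREASING directions, directly
# comparable with EP estimates (which approximate -dL/dtheta).

# initial adjoint dl/ds at state s (batch-mean loss): list of layer arrays
loss_adjoint <- function(x, s, y, params, arch) {
  N <- arch$n_tot
  nb <- dim(x)[1]
  a <- lapply(state_dims(arch, nb), function(d) array(0, dim = d))
  y1 <- one_hot(y, arch$n_classes)
  if (arch$loss == "mse_output_layer") {
    a[[N]] <- (flat(s[[N]]) - y1) / nb
  } else {
    yhat <- softmax_rows(tcrossprod(flat(s[[N]]), params$w_out))
    a[[N]] <- unflat((yhat - y1) %*% params$w_out / nb,
                     arch$layers[[N]]$state_shape)
  }
  a
}

#' Gradient by BPTT truncated to the last t time steps
#'
#' Reference gradient of the steady-state loss obtained by reverse
#' accumulation through \code{t} unrolled free-phase steps, all Jacobians
#' evaluated at the converged steady state \code{s_star}. \code{t = 0}
#' returns zeros; large \code{t} gives the full steady-state gradient
#' (checkable against finite differences of
#' \code{\link{steady_state_loss}}). In \code{ce_readout} mode the
#' \code{w_out} slot holds the direct cross-entropy gradient (included for
#' every \code{t >= 1}; it does not flow through time).
#'
#' @param x input batch.
#' @param s_star converged free steady state.
#' @param params,arch parameters and architecture.
#' @param y integer labels.
#' @param t truncation length (number of unrolled steps).
#' @param residual optional final free-phase residual; if above
#'   \code{conv_tol} a warning string is attached as attribute
#'   \code{"convergence_warning"}.
#' @param conv_tol residual tolerance for the convergence hypothesis.
#' @return estimate-shaped list of loss-decreasing directions
#'   (\code{-dL/dtheta} slots \code{w}, \code{b}, \code{wb}, \code{w_out}).
#' @export
bptt_truncated <- function(x, s_star, params, arch, y, t,
                           residual = NULL, conv_tol = 1e-6) {
  stopifnot(t >= 0)
  nb <- dim(x)[1]
  pass <- ep_pass(x, s_star, params, arch)
  m <- pass_mask(pass)
  g <- est_zero(params)
  if (t >= 1) {
    a <- loss_adjoint(x, s_star, y, params, arch)
    for (k in seq_len(t)) {
      d <- lapply(seq_along(a), function(n) m[[n]] * a[[n]])
      con <- ep_dF_theta(x, s_star, d, pass, params, arch)
      for (n in seq_len(arch$n_tot)) {
        g$w[[n]] <- g$w[[n]] + con$fw_w[[n]]
        if (!is.null(con$fw_b[[n]])) g$b[[n]] <- g$b[[n]] + con$fw_b[[n]]
        if (!is.null(con$td_w[[n]])) {
          if (arch$coupling == "bidirectional") {
            g$w[[n]] <- g$w[[n]] + con$td_w[[n]]
          } else if (!is.null(g$wb[[n]])) {
            g$wb[[n]] <- g$wb[[n]] + con$td_w[[n]]
          }
        }
      }
      if (k < t) a <- ep_adjoint_step(d, pass, params, arch, nb)
    }
    g <- est_scale(g, -1)
    if (arch$loss == "ce_readout") {
      top <- flat(s_star[[arch$n_tot]])
      yhat <- softmax_rows(tcrossprod(top, params$w_out))
      g$w_out <- crossprod(one_hot(y, arch$n_classes) - yhat, top) / nb
    }
  }
  if (!is.null(residual) && residual > conv_tol)
    attr(g, "convergence_warning") <-
      sprintf("free phase residual %.3g exceeds tolerance %.3g",
              residual, conv_tol)
  g
}

#' Per-timestep EP vs BPTT gradient curves (GDU diagnostic)
#'
#' Computes, for every parameter group and every nudged-phase step
#' \code{t = 1..K}, the one-sided EP estimates at \code{+beta} and
#' \code{-beta}, their symmetric combination, and the BPTT gradient
#' truncated to \code{t} steps. The gradient-matching property states that
#' the symmetric curve tracks the BPTT curve as \code{beta -> 0}.
#'
#' Groups are the forward weights (\code{w1..wN}) and biases
#' (\code{b1..bN}); the readout matrix is excluded (the primitive does not
#' contain it and its free-phase learning rule is already exact).
#'
#' @param x,y input batch and labels.
#' @param params,arch parameters and architecture (bidirectional).
#' @param beta positive nudging strength.
#' @param T free-phase length.
#' @param K nudged-phase length (\code{K <= T}).
#' @return an object of class \code{ep_gdu}: a list of per-group lists with
#'   \code{K x n_param} matrices \code{ep_pos}, \code{ep_neg},
#'   \code{ep_sym}, \code{bptt}, plus metadata (\code{beta}, \code{T},
#'   \code{K}, \code{free_residual}).
#' @export
gdu_curves <- function(x, y, params, arch, beta, T, K) {
  if (K > T) stop("K (", K, ") must not exceed T (", T, ")")
  if (beta == 0) stop("beta must be nonzero")
  if (arch$coupling != "bidirectional")
    stop("GDU curves require bidirectional coupling (the primitive)")
  nb <- dim(x)[1]
  free <- relax(x, zero_state(arch, nb), params, arch, T)
  s_star <- free$final_state
  pos <- relax(x, s_star, params, arch, K, y = y, beta = beta, record = TRUE)
  neg <- relax(x, s_star, params, arch, K, y = y, beta = -beta, record = TRUE)
  g0 <- phi_param_grad(x, s_star, params, arch)
  groups <- group_names(params, arch)
  series <- lapply(groups, function(gn) {
    P <- length(group_slot(g0, gn))
    list(ep_pos = matrix(0, K, P), ep_neg = matrix(0, K, P),
         ep_sym = matrix(0, K, P), bptt = matrix(0, K, P))
  })
  names(series) <- groups
  for (t in seq_len(K)) {
    gp <- phi_param_grad(x, pos$trajectory[[t]], params, arch)
    gn <- phi_param_grad(x, neg$trajectory[[t]], params, arch)
    gb <- bptt_truncated(x, s_star, params, arch, y, t)
    for (gname in groups) {
      p0 <- group_slot(g0, gname)
      pp <- group_slot(gp, gname); pn <- group_slot(gn, gname)
      series[[gname]]$ep_pos[t, ] <- (pp - p0) / beta
      series[[gname]]$ep_neg[t, ] <- (pn - p0) / (-beta)
      series[[gname]]$ep_sym[t, ] <- (pp - pn) / (2 * beta)
      series[[gname]]$bptt[t, ] <- group_slot(gb, gname)
    }
  }
  structure(list(series = series, beta = beta, T = T, K = K,
                 free_residual = free$residuals[T]),
            class = "ep_gdu")
}

group_names <- function(params, arch) {
  N <- arch$n_tot
  c(paste0("w", seq_len(N)),
    if (arch$has_biases) paste0("b", seq_len(N)))
}

group_slot <- function(est, gname) {
  kind <- substr(gname, 1, 1)
  n <- as.integer(substring(gname, 2))
  as.numeric(if (kind == "w") est$w[[n]] else est$b[[n]])
}

#' Relative RMS deviation of the symmetric EP curve from BPTT
#'
#' For each group, the per-step L2 deviation between \code{ep_sym[t]} and
#' \code{bptt[t]} is normalized by the largest BPTT gradient norm over the
#' window, and the maximum over t is reported.
#'
#' @param curves an \code{ep_gdu}.
#' @return named numeric vector of max relative deviations per group.
#' @export
gdu_rel_dev <- function(curves) {
  vapply(curves$series, function(sr) {
    ref <- sqrt(rowSums(sr$bptt^2))
    dev <- sqrt(rowSums((sr$ep_sym - sr$bptt)^2))
    max(dev) / (max(ref) + 1e-300)
  }, numeric(1))
}

# ---- spectral norm of the step linearization (fixture construction) ------

# Power iteration for ||J||_2 of one synchronous step linearized at state s.
# With interior_mask = TRUE the hard-sigmoid mask is replaced by all ones
# (the worst case over saturation patterns).
step_spectral_norm <- function(x, s, params, arch, iters = 30,
                               interior_mask = TRUE) {
  pass <- ep_pass(x, s, params, arch)
  nb <- dim(x)[1]
  m <- if (interior_mask)
    lapply(state_dims(arch, nb), function(d) array(1, dim = d))
  else pass_mask(pass)
  v <- lapply(state_dims(arch, nb), function(d)
    array(rnorm(prod(d)), dim = d))
  nrm <- function(u) sqrt(sum(vapply(u, function(a) sum(a^2), numeric(1))))
  sig <- 0
  for (i in seq_len(iters)) {
    v <- lapply(v, function(a) a / (nrm(v) + 1e-300))
    u <- ep_jvp(v, pass, m, params, arch)
    sig <- nrm(u)
    d <- lapply(seq_along(u), function(n) m[[n]] * u[[n]])
    v <- ep_adjoint_step(d, pass, params, arch, nb)
  }
  sig
}
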