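# Full EP training loop: per-batch free phase (T steps from zero), one or
# two nudged phases (K steps each, started from the free steady state),
# gradient estimate, SGD step with per-layer learning rates, momentum,
# decoupled weight decay, cosine-annealed schedule, optional fixed-mask
# dropout, and per-epoch evaluation / weight-alignment monitoring.

#' Training configuration
#'
#' Desk-scale analogue of the CIFAR-10 recipe: free phase of \code{T} steps,
#' nudged phases of \code{K} steps, nudging strength \code{beta}, SGD with
#' momentum and weight decay, cosine annealing of per-layer learning rates
#' down to \code{lr_final} over \code{cosine_decay_epochs}.
#'
#' @param T,K free / nudged phase lengths (\code{K <= T}).
#' @param beta positive nudging strength.
#' @param batch_size mini-batch size.
#' @param lr_per_layer numeric vector: one rate per layer, plus one for
#'   \code{w_out} in ce mode.
#' @param lr_final floor of the cosine schedule.
#' @param weight_decay,momentum SGD hyper-parameters.
#' @param epochs number of epochs.
#' @param cosine_decay_epochs length of the cosine decay (constant at
#'   \code{lr_final} afterwards).
#' @param estimator one of \code{"one_sided"}, \code{"random_sign"},
#'   \code{"symmetric"}, \code{"vf"}, \code{"sym_vf"}, \code{"kp_vf"}.
#' @param lambda KP-VF leakage (ignored by other estimators).
#' @param dropout_p dropout probability in [0, 1) for the designated layer.
#' @param seed integer seed controlling shuffling, dropout and random signs.
#' @return list of class \code{ep_train_config}.
#' @export
train_config <- function(T = 30, K = 10, beta = 1.0, batch_size = 20,
                         lr_per_layer, lr_final = 1e-5,
                         weight_decay = 3e-4, momentum = 0.9,
                         epochs = 10, cosine_decay_epochs = epochs,
                         estimator = "symmetric", lambda = 0.25,
                         dropout_p = 0, seed = 1) {
  estimator <- match.arg(estimator, c("one_sided", "random_sign", "symmetric",
                                      "vf", "sym_vf", "kp_vf"))
  stopifnot(K <= T, beta > 0, batch_size >= 1, lr_final >= 0,
            weight_decay >= 0, momentum >= 0, epochs >= 0, lambda >= 0,
            dropout_p >= 0, dropout_p < 1)
  structure(list(T = as.integer(T), K = as.integer(K), beta = beta,
                 batch_size = as.integer(batch_size),
                 lr_per_layer = as.numeric(lr_per_layer),
                 lr_final = lr_final, weight_decay = weight_decay,
                 momentum = momentum, epochs = as.integer(epochs),
                 cosine_decay_epochs = as.integer(cosine_decay_epochs),
                 estimator = estimator, lambda = lambda,
                 dropout_p = dropout_p, seed = as.integer(seed)),
            class = "ep_train_config")
}

#' Cosine-annealed per-layer learning rates
#'
#' Cosine interpolation from \code{lr_per_layer} down to \code{lr_final}
#' over \code{cosine_decay_epochs}; constant at \code{lr_final} afterwards.
#'
#' @param epoch 0-based epoch index.
#' @param cfg an \code{ep_train_config}.
#' @return numeric vector of current rates.
#' @export
cosine_lr <- function(epoch, cfg) {
  stopifnot(epoch >= 0)
  E <- cfg$cosine_decay_epochs
  if (E <= 0 || epoch >= E) return(rep(cfg$lr_final, length(cfg$lr_per_layer)))
  cfg$lr_final + 0.5 * (cfg$lr_per_layer - cfg$lr_final) *
    (1 + cos(pi * epoch / E))
}

#' Angle between forward and backward weights
#'
#' Per layer, the arccosine (in degrees) of the cosine similarity between
#' the flattened forward and backward kernels. Both are parameterized in
#' the same orientation (the backward kernel is applied as the adjoint of
#' the forward convolution), so no flip is needed. Undefined for the first
#' layer, whose input is clamped.
#'
#' @param params an \code{ep_params} with backward weights.
#' @param arch the matching \code{ep_arch}.
#' @return named numeric vector (\code{layer2 ... layerN}) of angles in
#'   [0, 180] degrees.
#' @export
alignment_angle <- function(params, arch) {
  if (is.null(params$wb))
    stop("alignment angle requires unidirectional coupling")
  idx <- which(!vapply(params$wb, is.null, logical(1)))
  ang <- vapply(idx, function(n) {
    f <- as.numeric(params$w[[n]]); b <- as.numeric(params$wb[[n]])
    nf <- sqrt(sum(f^2)); nb <- sqrt(sum(b^2))
    if (nf == 0 || nb == 0) stop("zero-norm weights at layer ", n)
    acos(min(1, max(-1, sum(f * b) / (nf * nb)))) * 180 / pi
  }, numeric(1))
  names(ang) <- paste0("layer", idx)
  ang
}

#' Inverted-dropout masks for one mini-batch iteration
#'
#' Bernoulli keep masks (probability \code{1 - p}) scaled by
#' \code{1/(1-p)}, drawn for the designated layer (by default the last
#' convolutional layer, the one read out) and per sample, and held fixed
#' across all time steps and phases of the mini-batch. \code{p = 0} gives
#' identity masks; evaluation never applies dropout.
#'
#' @param arch an \code{ep_arch}.
#' @param p dropout probability in [0, 1).
#' @param n batch size.
#' @param layer 1-based index of the masked layer (default: last conv
#'   layer, or the penultimate layer of an fc-only net).
#' @return list of per-layer masks (\code{NULL} = identity), or \code{NULL}
#'   when \code{p = 0}.
#' @export
dropout_mask <- function(arch, p, n, layer = NULL) {
  if (p < 0 || p >= 1) stop("dropout probability must lie in [0, 1)")
  if (p == 0) return(NULL)
  if (is.null(layer))
    layer <- if (arch$n_conv > 0) arch$n_conv else max(1L, arch$n_tot - 1L)
  masks <- vector("list", arch$n_tot)
  d <- c(n, arch$layers[[layer]]$state_shape)
  keep <- rbinom(prod(d), 1, 1 - p)
  masks[[layer]] <- array(keep / (1 - p), dim = d)
  masks
}

#' Classification error of a parameter set on a dataset
#'
#' Free phase per batch (no dropout, no nudging), argmax prediction,
#' returns \code{100 * (1 - accuracy)}.
#'
#' @param params,arch parameters and architecture.
#' @param batch an \code{ep_batch}.
#' @param T free-phase length.
#' @param batch_size evaluation batch size.
#' @return error percentage in [0, 100].
#' @export
evaluate_error <- function(params, arch, batch, T, batch_size = 50) {
  n <- dim(batch$x)[1]
  wrong <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    xb <- batch$x[i:j, , , , drop = FALSE]
    ph <- relax(xb, zero_state(arch, j - i + 1L), params, arch, T)
    pr <- predict_state(xb, ph$final_state, params, arch)
    wrong <- wrong + sum(pr$labels != batch$y[i:j])
    i <- j + 1L
  }
  100 * wrong / n
}

# run the configured estimator for one mini-batch; returns the estimate
run_estimator <- function(xb, yb, free, params, arch, cfg, masks) {
  s_star <- free$final_state
  go <- function(b) relax(xb, s_star, params, arch, cfg$K, y = yb, beta = b,
                          masks = masks)
  est <- switch(cfg$estimator,
    one_sided = one_sided_estimate(xb, free, go(cfg$beta), params, arch),
    random_sign = random_sign_estimate(xb, free, go, cfg$beta, params, arch),
    symmetric = symmetric_estimate(xb, go(cfg$beta), go(-cfg$beta),
                                   params, arch),
    vf = vf_estimate(xb, free, go(cfg$beta), params, arch),
    sym_vf = sym_vf_estimate(xb, free, go(cfg$beta), go(-cfg$beta),
                             params, arch),
    kp_vf = kp_vf_estimate(xb, go(cfg$beta), go(-cfg$beta), params, arch))
  if (arch$loss == "ce_readout")
    est$w_out <- readout_estimate(xb, s_star, yb, params, arch)
  est
}

#' Train a network with Equilibrium Propagation
#'
#' Per mini-batch: free phase (\code{T} steps from the all-zero state),
#' nudged phase(s) of \code{K} steps from the free steady state as required
#' by the estimator, gradient estimate, optimizer step. Per epoch: train
#' and test error, mean final free-phase residual, current learning rate,
#' and (unidirectional coupling) per-layer alignment angles. Deterministic
#' given \code{cfg$seed}.
#'
#' @param arch an \code{ep_arch}.
#' @param params initial \code{ep_params}.
#' @param data list with \code{train} and \code{test}
#'   \code{\link{ep_batch}}es.
#' @param cfg an \code{ep_train_config}.
#' @param quiet suppress per-epoch progress lines on stderr.
#' @return list with final \code{params} and \code{metrics} (long-format
#'   data frame: epoch, split, error_pct, residual, lr, angles).
#' @export
train <- function(arch, params, data, cfg, quiet = TRUE) {
  check_estimator_coupling(cfg$estimator, arch$coupling)
  n_groups <- arch$n_tot + (arch$loss == "ce_readout")
  if (length(cfg$lr_per_layer) != n_groups)
    stop("lr_per_layer must have ", n_groups, " entries (got ",
         length(cfg$lr_per_layer), ")")
  set.seed(cfg$seed)
  n <- dim(data$train$x)[1]
  opt_state <- NULL
  metrics <- list()
  record_epoch <- function(epoch, lrs, resid) {
    ang <- if (arch$coupling == "unidirectional")
      as.list(alignment_angle(params, arch)) else NULL
    for (split in c("train", "test")) {
      err <- evaluate_error(params, arch,
                            if (split == "train") data$train else data$test,
                            cfg$T, max(cfg$batch_size, 50L))
      row <- c(list(epoch = epoch, split = split, error_pct = err,
                    residual = resid, lr = lrs[1]), ang)
      metrics[[length(metrics) + 1L]] <<- row
      if (!quiet)
        message(sprintf("epoch %3d %-5s error %6.2f%%", epoch, split, err))
    }
  }
  record_epoch(0L, cosine_lr(0, cfg), NA_real_)
  for (epoch in seq_len(cfg$epochs)) {
    lrs <- cosine_lr(epoch - 1L, cfg)
    ord <- sample.int(n)
    resid_sum <- 0; n_batches <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      sel <- ord[i:j]
      xb <- data$train$x[sel, , , , drop = FALSE]
      yb <- data$train$y[sel]
      masks <- dropout_mask(arch, cfg$dropout_p, length(sel))
      free <- relax(xb, zero_state(arch, length(sel)), params, arch, cfg$T,
                    masks = masks)
      est <- run_estimator(xb, yb, free, params, arch, cfg, masks)
      if (any(!is.finite(est_unlist(est, include_w_out = TRUE))))
        stop("training diverged (non-finite estimate) at epoch ", epoch,
             ", batch ", n_batches + 1L)
      up <- apply_update(params, est, lrs, cfg$momentum, cfg$weight_decay,
                         lambda = if (cfg$estimator == "kp_vf") cfg$lambda else 0,
                         opt_state = opt_state)
      params <- up$params
      opt_state <- up$opt_state
      resid_sum <- resid_sum + free$residuals[cfg$T]
      n_batches <- n_batches + 1L
      i <- j + 1L
    }
    record_epoch(epoch, lrs, resid_sum / n_batches)
  }
  metrics <- do.call(rbind, lapply(metrics, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(params = params, metrics = metrics)
}

check_estimator_coupling <- function(estimator, coupling) {
  bidir <- c("one_sided", "random_sign", "symmetric")
  unidir <- c("kp_vf")
  if (estimator %in% bidir && coupling != "bidirectional")
    stop("estimator '", estimator, "' requires bidirectional coupling")
  if (estimator %in% unidir && coupling != "unidirectional")
    stop("estimator '", estimator, "' requires unidirectional coupling")
  invisible(TRUE)
}
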