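#' Define a network architecture
#'
#' Describes the layer topology of a convergent recurrent network: a stack of
#' convolutional layers (optionally max-pooled) followed by fully connected
#' layers, with either shared bidirectional weights or distinct forward and
#' backward weights, and one of two output couplings:
#' \describe{
#'   \item{\code{mse_output_layer}}{the topmost layer of the dynamics is the
#'     prediction and is nudged elastically toward the one-hot target
#'     (squared-error loss); it must have \code{n_classes} units.}
#'   \item{\code{ce_readout}}{the prediction is a softmax readout
#'     \code{softmax(w_out . s_top)} that does not take part in the free
#'     dynamics; nudging feeds the cross-entropy error back through
#'     \code{w_out}.}
#' }
#'
#' @param input_shape integer vector \code{c(channels, height, width)}.
#' @param conv list of convolutional layer descriptions, each a list with
#'   \code{channels}, \code{kernel}, and optionally \code{stride} (default 1),
#'   \code{pad} (default 0) and \code{pool = list(window, stride)}.
#' @param fc integer vector of fully connected layer sizes (may be empty).
#' @param n_classes number of classes \code{C}.
#' @param coupling \code{"bidirectional"} (shared weights, a primitive
#'   function exists) or \code{"unidirectional"} (independent backward
#'   weights).
#' @param loss \code{"ce_readout"} or \code{"mse_output_layer"}.
#' @param has_biases logical; forward layers carry biases (backward weights
#'   never do).
#' @return an object of class \code{ep_arch} with derived per-layer state
#'   shapes.
#' @export
ep_arch <- function(input_shape, conv = list(), fc = integer(),
                    n_classes, coupling = c("bidirectional", "unidirectional"),
                    loss = c("ce_readout", "mse_output_layer"),
                    has_biases = TRUE) {
  coupling <- match.arg(coupling)
  loss <- match.arg(loss)
  stopifnot(length(input_shape) == 3, all(input_shape >= 1), n_classes >= 1)
  input_shape <- as.integer(input_shape)
  n_conv <- length(conv)
  fc <- as.integer(fc)
  n_fc <- length(fc)
  n_tot <- n_conv + n_fc
  if (n_tot < 1) stop("architecture needs at least one layer")
  if (loss == "mse_output_layer") {
    if (n_fc < 1 || fc[n_fc] != n_classes)
      stop("mse_output_layer mode requires the topmost fc layer to have ",
           n_classes, " units (the output layer is part of the dynamics)")
  }

  layers <- vector("list", n_tot)
  cur <- input_shape  # (C, H, W) of the layer-(n-1) state
  for (n in seq_len(n_conv)) {
    cl <- conv[[n]]
    if (is.null(cl$channels) || is.null(cl$kernel))
      stop("conv layer ", n, ": 'channels' and 'kernel' are required")
    stride <- if (is.null(cl$stride)) 1L else as.integer(cl$stride)
    pad <- if (is.null(cl$pad)) 0L else as.integer(cl$pad)
    k <- as.integer(cl$kernel)
    ch <- as.integer(cl$channels)
    conv_h <- (cur[2] + 2L * pad - k) %/% stride + 1L
    conv_w <- (cur[3] + 2L * pad - k) %/% stride + 1L
    if (conv_h < 1 || conv_w < 1)
      stop("conv layer ", n, ": non-positive output size (",
           conv_h, "x", conv_w, ")")
    pool <- NULL
    out_h <- conv_h; out_w <- conv_w
    if (!is.null(cl$pool)) {
      pw <- as.integer(cl$pool$window)
      ps <- if (is.null(cl$pool$stride)) pw else as.integer(cl$pool$stride)
      out_h <- (conv_h - pw) %/% ps + 1L
      out_w <- (conv_w - pw) %/% ps + 1L
      if (out_h < 1 || out_w < 1)
        stop("conv layer ", n, ": non-positive pooled size")
      pool <- list(window = pw, stride = ps)
    }
    layers[[n]] <- list(
      type = "conv", c_in = cur[1], c_out = ch, kernel = k,
      stride = stride, pad = pad,
      in_shape = cur, conv_shape = c(ch, conv_h, conv_w), pool = pool,
      state_shape = c(ch, out_h, out_w))
    cur <- c(ch, out_h, out_w)
  }
  for (j in seq_len(n_fc)) {
    n <- n_conv + j
    layers[[n]] <- list(
      type = "fc", n_in = prod(cur), n_out = fc[j],
      in_shape = cur, state_shape = fc[j])
    cur <- fc[j]
  }

  structure(list(
    input_shape = input_shape, n_conv = n_conv, n_fc = n_fc, n_tot = n_tot,
    n_classes = as.integer(n_classes), coupling = coupling, loss = loss,
    has_biases = isTRUE(has_biases), layers = layers,
    top_dim = as.integer(prod(layers[[n_tot]]$state_shape))),
    class = "ep_arch")
}

#' @export
print.ep_arch <- function(x, ...) {
  cat(sprintf("<ep_arch> input %s | %d conv + %d fc layers | C=%d | %s | %s\n",
              paste(x$input_shape, collapse = "x"), x$n_conv, x$n_fc,
              x$n_classes, x$coupling, x$loss))
  for (n in seq_len(x$n_tot)) {
    l <- x$layers[[n]]
    if (l$type == "conv") {
      cat(sprintf("  [%d] conv %dx%d k=%d s=%d p=%d%s -> state %s\n",
                  n, l$c_in, l$c_out, l$kernel, l$stride, l$pad,
                  if (is.null(l$pool)) "" else
                    sprintf(" pool %d/%d", l$pool$window, l$pool$stride),
                  paste(l$state_shape, collapse = "x")))
    } else {
      cat(sprintf("  [%d] fc %d -> %d\n", n, l$n_in, l$n_out))
    }
  }
  invisible(x)
}

# per-layer state array dims for batch size n
state_dims <- function(arch, n) {
  lapply(arch$layers, function(l) c(n, l$state_shape))
}

#' All-zero network state
#'
#' The conventional starting point of every free phase.
#'
#' @param arch an \code{ep_arch}.
#' @param n batch size.
#' @return list of per-layer arrays of zeros, class \code{ep_state}.
#' @export
zero_state <- function(arch, n) {
  s <- lapply(state_dims(arch, n), function(d) array(0, dim = d))
  class(s) <- "ep_state"
  s
}

#' Validate a network state against an architecture
#'
#' Checks shapes and the state-space constraint that every activation lies
#' in [0, 1].
#'
#' @param s state (list of per-layer arrays).
#' @param arch an \code{ep_arch}.
#' @param n expected batch size (inferred from the first layer if missing).
#' @return invisibly \code{TRUE}; errors name the offending layer.
#' @export
validate_state <- function(s, arch, n = NULL) {
  if (length(s) != arch$n_tot)
    stop("state has ", length(s), " layers; architecture expects ", arch$n_tot)
  if (is.null(n)) n <- dim_or_len(s[[1]])[1]
  dims <- state_dims(arch, n)
  for (k in seq_along(s)) {
    dk <- dim_or_len(s[[k]])
    if (!identical(as.integer(dk), as.integer(dims[[k]])))
      stop("layer ", k, ": state shape (", paste(dk, collapse = ","),
           ") does not match expected (", paste(dims[[k]], collapse = ","), ")")
    if (any(!is.finite(s[[k]])))
      stop("layer ", k, ": non-finite values in state")
    if (any(s[[k]] < 0 | s[[k]] > 1))
      stop("layer ", k, ": state values outside [0, 1]")
  }
  invisible(TRUE)
}

dim_or_len <- function(a) {
  d <- dim(a)
  if (is.null(d)) length(a) else d
}

#' A labeled input batch
#'
#' @param x input array \code{(n, channels, height, width)} with values in
#'   [0, 1].
#' @param y integer class labels in \code{0 .. C-1}.
#' @return list with class \code{ep_batch}.
#' @export
ep_batch <- function(x, y) {
  stopifnot(length(dim(x)) == 4)
  y <- as.integer(y)
  if (dim(x)[1] != length(y))
    stop("batch size mismatch: x has ", dim(x)[1], " rows, y has ", length(y))
  structure(list(x = x, y = y), class = "ep_batch")
}

# one-hot matrix (n x C), labels 0-based
one_hot <- function(y, C) {
  m <- matrix(0, length(y), C)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

# flatten an (n, ...) array to an n x D matrix; identity on matrices
flat <- function(a) {
  d <- dim(a)
  if (is.null(d) || length(d) == 2) return(a)
  dim(a) <- c(d[1], prod(d[-1]))
  a
}

unflat <- function(m, shape) {
  if (length(shape) == 1) return(m)
  array(m, dim = c(nrow(m), shape))
}
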