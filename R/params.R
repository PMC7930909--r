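#' Initialize network parameters
#'
#' Forward weights and biases are drawn from the uniform Kaiming fan-in
#' distribution \code{U(-1/sqrt(fan_in), 1/sqrt(fan_in))}. In unidirectional
#' coupling mode, independent backward weights of the same shapes are drawn
#' for every connection except the first (the input layer is clamped, so no
#' feedback reaches it); backward weights carry no bias. In \code{ce_readout}
#' mode a readout matrix \code{w_out} of shape \code{C x top_dim} is added.
#'
#' @param arch an \code{ep_arch}.
#' @param seed optional integer seed (uses and advances the global RNG when
#'   \code{NULL}).
#' @return an object of class \code{ep_params} with fields \code{w} (list of
#'   per-layer forward weights), \code{b} (biases or \code{NULL}s),
#'   \code{wb} (backward weights, layers 2..N, unidirectional only) and
#'   \code{w_out} (readout or \code{NULL}).
#' @export
init_params <- function(arch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- arch$n_tot
  w <- vector("list", N); b <- vector("list", N)
  for (n in seq_len(N)) {
    l <- arch$layers[[n]]
    if (l$type == "conv") {
      fan <- l$c_in * l$kernel^2
      bd <- 1 / sqrt(fan)
      w[[n]] <- array(runif(l$c_out * l$c_in * l$kernel^2, -bd, bd),
                      dim = c(l$c_out, l$c_in, l$kernel, l$kernel))
      b[[n]] <- if (arch$has_biases) runif(l$c_out, -bd, bd) else NULL
    } else {
      bd <- 1 / sqrt(l$n_in)
      w[[n]] <- matrix(runif(l$n_out * l$n_in, -bd, bd), l$n_out, l$n_in)
      b[[n]] <- if (arch$has_biases) runif(l$n_out, -bd, bd) else NULL
    }
  }
  wb <- NULL
  if (arch$coupling == "unidirectional" && N >= 2) {
    wb <- vector("list", N)
    for (n in 2:N) {
      l <- arch$layers[[n]]
      if (l$type == "conv") {
        bd <- 1 / sqrt(l$c_in * l$kernel^2)
        wb[[n]] <- array(runif(length(w[[n]]), -bd, bd), dim = dim(w[[n]]))
      } else {
        bd <- 1 / sqrt(l$n_in)
        wb[[n]] <- matrix(runif(length(w[[n]]), -bd, bd), l$n_out, l$n_in)
      }
    }
  }
  w_out <- NULL
  if (arch$loss == "ce_readout") {
    bd <- 1 / sqrt(arch$top_dim)
    w_out <- matrix(runif(arch$n_classes * arch$top_dim, -bd, bd),
                    arch$n_classes, arch$top_dim)
  }
  structure(list(w = w, b = b, wb = wb, w_out = w_out), class = "ep_params")
}

# the weight used for the top-down contribution of connection n (layer n-1 <- n)
topdown_weight <- function(params, arch, n) {
  if (arch$coupling == "bidirectional") return(params$w[[n]])
  wb <- params$wb[[n]]
  if (is.null(wb))
    stop("unidirectional coupling: backward weight for layer ", n,
         " is missing")
  wb
}

#' Save / load a parameter checkpoint
#'
#' Checkpoints round-trip bit-exactly. The architecture is embedded both as
#' the live object and as a JSON descriptor for external inspection.
#'
#' @param params an \code{ep_params}.
#' @param arch the matching \code{ep_arch}.
#' @param path file path (conventionally \code{.rds}).
#' @return \code{save_checkpoint} returns \code{path} invisibly;
#'   \code{load_checkpoint} returns \code{list(params, arch)}.
#' @export
save_checkpoint <- function(params, arch, path) {
  desc <- jsonlite::toJSON(unclass(arch), auto_unbox = TRUE, digits = NA,
                           null = "null")
  saveRDS(list(params = params, arch = arch, arch_json = as.character(desc)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  list(params = ck$params, arch = ck$arch)
}

# --- small arithmetic helpers over parameter-shaped nested lists ----------

# apply f entrywise over matching slots of two param/estimate-shaped lists
est_map2 <- function(a, b, f) {
  out <- a
  for (nm in c("w", "b", "wb")) {
    if (is.null(a[[nm]])) next
    out[[nm]] <- lapply(seq_along(a[[nm]]), function(i) {
      if (is.null(a[[nm]][[i]])) NULL else f(a[[nm]][[i]], b[[nm]][[i]])
    })
  }
  if (!is.null(a$w_out)) out$w_out <- f(a$w_out, b$w_out)
  out
}

est_scale <- function(a, k) {
  for (nm in c("w", "b", "wb")) {
    if (is.null(a[[nm]])) next
    a[[nm]] <- lapply(a[[nm]], function(x) if (is.null(x)) NULL else x * k)
  }
  if (!is.null(a$w_out)) a$w_out <- a$w_out * k
  a
}

# flatten all (non-NULL) slots into one numeric vector, fixed order
est_unlist <- function(a, include_w_out = FALSE) {
  parts <- list()
  for (nm in c("w", "b", "wb")) {
    if (is.null(a[[nm]])) next
    for (x in a[[nm]]) if (!is.null(x)) parts[[length(parts) + 1L]] <- as.numeric(x)
  }
  if (include_w_out && !is.null(a$w_out))
    parts[[length(parts) + 1L]] <- as.numeric(a$w_out)
  unlist(parts, use.names = FALSE)
}

# zero estimate mirroring params
est_zero <- function(params) {
  z <- function(x) if (is.null(x)) NULL else array(0, dim = dim_or_len(x))
  out <- list(w = lapply(params$w, z), b = lapply(params$b, z),
              wb = if (is.null(params$wb)) NULL else lapply(params$wb, z),
              w_out = if (is.null(params$w_out)) NULL else
                matrix(0, nrow(params$w_out), ncol(params$w_out)))
  # keep matrix shapes for fc weights
  for (i in seq_along(params$w)) {
    if (is.matrix(params$w[[i]]))
      out$w[[i]] <- matrix(0, nrow(params$w[[i]]), ncol(params$w[[i]]))
    if (!is.null(params$wb) && !is.null(params$wb[[i]]) &&
        is.matrix(params$wb[[i]]))
      out$wb[[i]] <- matrix(0, nrow(params$wb[[i]]), ncol(params$wb[[i]]))
  }
  out
}
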