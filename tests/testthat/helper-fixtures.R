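# Shared test helpers: numeric differentiation oracles and tiny nets.

# central finite difference of scalar-valued f at selected flat indices of
# the array `x` inside a container accessed by get/set closures
fd_grad_at <- function(f, get, set, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    x0 <- get()
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    set(xp); fp <- f()
    set(xm); fm <- f()
    set(x0)
    (fp - fm) / (2 * eps)
  }, numeric(1))
}

# one fc layer on a 2-pixel input, squared-error mode, single class:
# Phi = s1 . (w x + b), dynamics s1 <- clamp(w x + b [+ nudge])
tiny_fc <- function(w = c(0.5, -0.25), b = 0) {
  arch <- ep_arch(c(1, 1, 2), fc = 1, n_classes = 1,
                  loss = "mse_output_layer")
  params <- init_params(arch)
  params$w[[1]] <- matrix(w, 1, 2)
  params$b[[1]] <- b
  list(arch = arch, params = params)
}

# deterministic probe batch + labels for a fixture net
probe_batch <- function(arch, n = 4) {
  x <- eqprop:::probe_inputs(arch)[seq_len(n), , , , drop = FALSE]
  list(x = x, y = (seq_len(n) - 1L) %% arch$n_classes)
}

flat_est <- function(est) eqprop:::est_unlist(est)

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / (sqrt(sum(b^2)) + 1e-300)
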