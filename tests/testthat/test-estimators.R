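# Gradient estimators and the parameter update rule.

test_that("parameter-gradient of the primitive is the local outer-product rule", {
  net <- tiny_fc(w = c(0.1, 0.2))
  x <- array(c(1, 0), c(1, 1, 1, 2))
  s <- zero_state(net$arch, 1)
  s[[1]][1, 1] <- 0.5
  g <- phi_param_grad(x, s, net$params, net$arch)
  expect_equal(g$w[[1]], matrix(c(0.5, 0), 1, 2))
  expect_equal(g$b[[1]], 0.5)

  s[[1]][1, 1] <- 0  # zero upper state kills the layer's gradient
  g0 <- phi_param_grad(x, s, net$params, net$arch)
  expect_equal(as.numeric(g0$w[[1]]), c(0, 0))
})

test_that("closed-form primitive gradients agree with numeric differentiation", {
  fx <- make_fixture_net("conv_small", loss = "ce_readout", seed = 3)
  arch <- fx$arch
  p <- fx$params
  pb <- probe_batch(arch, 2)
  s <- relax(pb$x, zero_state(arch, 2), p, arch, 60)$final_state
  g <- phi_param_grad(pb$x, s, p, arch)
  set.seed(21)
  for (n in seq_len(arch$n_tot)) {
    idx <- sample(length(p$w[[n]]), 5)
    fd <- fd_grad_at(
      f = function() mean(primitive_value(pb$x, s, p, arch)),
      get = function() p$w[[n]],
      set = function(v) p$w[[n]] <<- v,
      idx = idx)
    expect_lt(max(abs(fd - g$w[[n]][idx]) / (abs(fd) + 1e-8)), 1e-5)
    bidx <- seq_along(p$b[[n]])
    fdb <- fd_grad_at(
      f = function() mean(primitive_value(pb$x, s, p, arch)),
      get = function() p$b[[n]],
      set = function(v) p$b[[n]] <<- v,
      idx = bidx)
    expect_lt(max(abs(fdb - g$b[[n]]) / (abs(fdb) + 1e-8)), 1e-5)
  }
})

test_that("one-sided estimate: zero for identical phases, local rule entrywise", {
  net <- tiny_fc(w = c(0.4, 0.2))
  x <- array(c(1, 0.5), c(1, 1, 1, 2))
  free <- relax(x, zero_state(net$arch, 1), net$params, net$arch, 50)
  same <- free
  same$beta_used <- 0.1
  est <- one_sided_estimate(x, free, same, net$params, net$arch)
  expect_equal(as.numeric(est$w[[1]]), c(0, 0))

  nudged <- relax(x, free$final_state, net$params, net$arch, 50,
                  y = 0L, beta = 0.1)
  est <- one_sided_estimate(x, free, nudged, net$params, net$arch)
  sb <- as.numeric(nudged$final_state[[1]])
  s0 <- as.numeric(free$final_state[[1]])
  hand <- (sb * c(1, 0.5) - s0 * c(1, 0.5)) / 0.1
  expect_equal(as.numeric(est$w[[1]]), hand)

  expect_error(one_sided_estimate(x, free, free, net$params, net$arch),
               "nonzero")
})

test_that("symmetric estimate equals the average of one-sided estimates", {
  for (kind in c("fc_small", "conv_small")) {
    fx <- make_fixture_net(kind, loss = "ce_readout", seed = 7)
    pb <- probe_batch(fx$arch)
    free <- relax(pb$x, zero_state(fx$arch, 4), fx$params, fx$arch, 150)
    b <- 0.1
    pos <- relax(pb$x, free$final_state, fx$params, fx$arch, 60,
                 y = pb$y, beta = b)
    neg <- relax(pb$x, free$final_state, fx$params, fx$arch, 60,
                 y = pb$y, beta = -b)
    sym <- symmetric_estimate(pb$x, pos, neg, fx$params, fx$arch)
    ep <- one_sided_estimate(pb$x, free, pos, fx$params, fx$arch)
    en <- one_sided_estimate(pb$x, free, neg, fx$params, fx$arch)
    avg <- (flat_est(ep) + flat_est(en)) / 2
    expect_lt(rel_err(avg, flat_est(sym)), 1e-12)

    expect_error(symmetric_estimate(pb$x, pos, pos, fx$params, fx$arch),
                 "\\+beta and -beta")
  }
})

test_that("estimator bias orders in beta hold on the scalar fixture", {
  fx <- make_fixture_net("scalar")
  sc <- bias_scan(fx$arch, fx$params, NULL, betas = c(0.2, 0.1, 0.05),
                  steps = 300, oracle_t = 200)
  expect_gt(sc$slopes[["one_sided"]], 0.7)
  expect_lt(sc$slopes[["one_sided"]], 1.3)
  expect_gt(sc$slopes[["symmetric"]], 1.7)
  expect_lt(sc$slopes[["symmetric"]], 2.3)
})

test_that("random-sign estimator is seeded, antithetic, and higher-variance", {
  fx <- make_fixture_net("scalar")
  x <- array(1, c(1, 1, 1, 1)); y <- 0L
  free <- relax(x, zero_state(fx$arch, 1), fx$params, fx$arch, 50)
  go <- function(b) relax(x, free$final_state, fx$params, fx$arch, 50,
                          y = y, beta = b)
  set.seed(123)
  e1 <- random_sign_estimate(x, free, go, 0.2, fx$params, fx$arch)
  set.seed(123)
  e2 <- random_sign_estimate(x, free, go, 0.2, fx$params, fx$arch)
  expect_identical(flat_est(e1), flat_est(e2))
  expect_true(attr(e1, "sign") %in% c(-1, 1))

  # the two-sign (antithetic) average equals the symmetric estimate exactly
  pos <- go(0.2); neg <- go(-0.2)
  ep <- one_sided_estimate(x, free, pos, fx$params, fx$arch)
  en <- one_sided_estimate(x, free, neg, fx$params, fx$arch)
  sym <- symmetric_estimate(x, pos, neg, fx$params, fx$arch)
  expect_equal((flat_est(ep) + flat_est(en)) / 2, flat_est(sym))

  # Monte-Carlo variance over the sign exceeds the symmetric estimator's
  set.seed(7)
  draws <- replicate(100, flat_est(
    random_sign_estimate(x, free, go, 0.2, fx$params, fx$arch))[1])
  expect_length(unique(draws), 2)  # both signs realized
  expect_gt(var(draws), 0)  # the symmetric estimate is deterministic (var 0)
  # and the draws scatter around the symmetric value
  expect_lt(abs(mean(draws) - flat_est(sym)[1]), sd(draws))
})

test_that("vector-field estimate: zero case and closed form on interior fc units", {
  fx <- make_fixture_net("fc_small", coupling = "unidirectional",
                         loss = "mse_output_layer", seed = 5)
  arch <- fx$arch; p <- fx$params
  pb <- probe_batch(arch, 2)
  free <- relax(pb$x, zero_state(arch, 2), p, arch, 300)
  same <- free; same$beta_used <- 0.05
  z <- vf_estimate(pb$x, free, same, p, arch)
  expect_equal(max(abs(flat_est(z))), 0)

  b <- 0.05
  nudged <- relax(pb$x, free$final_state, p, arch, 300, y = pb$y, beta = b)
  est <- vf_estimate(pb$x, free, nudged, p, arch)
  # hand evaluation: forward fc slot (s_i^b - s_i) * s_j / beta, batch mean
  n <- 2
  delta <- nudged$final_state[[n]] - free$final_state[[n]]
  pre <- eqprop:::ep_pass(pb$x, free$final_state, p, arch)$pre[[n]]
  expect_true(all(pre > 0 & pre < 1))  # interior, so the mask is 1
  hand <- crossprod(delta, free$final_state[[n - 1]]) / (b * 2)
  expect_equal(est$w[[n]], hand)

  # bidirectional check: vf tends to the one-sided estimate as beta -> 0
  fb <- make_fixture_net("fc_small", loss = "mse_output_layer", seed = 5)
  freeb <- relax(pb$x, zero_state(fb$arch, 2), fb$params, fb$arch, 400)
  nb <- relax(pb$x, freeb$final_state, fb$params, fb$arch, 400,
              y = pb$y, beta = 1e-3)
  v <- vf_estimate(pb$x, freeb, nb, fb$params, fb$arch)
  o <- one_sided_estimate(pb$x, freeb, nb, fb$params, fb$arch)
  expect_lt(rel_err(flat_est(v), flat_est(o)), 1e-2)
})

test_that("KP-VF estimate shares slots, vanishes for equal phases, matches numeric oracle", {
  fx <- make_fixture_net("fc_small", coupling = "unidirectional",
                         loss = "mse_output_layer", seed = 8)
  arch <- fx$arch; p <- fx$params
  pb <- probe_batch(arch, 2)
  free <- relax(pb$x, zero_state(arch, 2), p, arch, 300)
  b <- 0.1
  pos <- relax(pb$x, free$final_state, p, arch, 300, y = pb$y, beta = b)
  neg <- relax(pb$x, free$final_state, p, arch, 300, y = pb$y, beta = -b)

  same_pos <- pos; same_neg <- pos
  same_neg$beta_used <- -b
  z <- kp_vf_estimate(pb$x, same_pos, same_neg, p, arch)
  expect_equal(max(abs(flat_est(z))), 0)

  est <- kp_vf_estimate(pb$x, pos, neg, p, arch)
  for (n in 2:arch$n_tot) expect_identical(est$w[[n]], est$wb[[n]])

  # numeric oracle for Eq-20-style contraction: d/dtheta of F(x,s,theta).s
  # with the states frozen at each nudged steady state
  contract <- function(ph) {
    s <- ph$final_state
    function() {
      nxt <- free_step(pb$x, s, p, arch)$state
      sum(vapply(seq_along(s), function(n) sum(nxt[[n]] * s[[n]]),
                 numeric(1)))
    }
  }
  nb <- 2  # probe batch size; contractions are batch sums, estimates means
  set.seed(3)
  for (n in 1:2) {
    idx <- sample(length(p$w[[n]]), 3)
    fd_f <- (fd_grad_at(contract(pos), function() p$w[[n]],
                        function(v) p$w[[n]] <<- v, idx) -
             fd_grad_at(contract(neg), function() p$w[[n]],
                        function(v) p$w[[n]] <<- v, idx)) / (2 * b * nb)
    if (n == 1) {
      # first layer has no backward twin: estimate is the forward half alone
      expect_lt(max(abs(fd_f - est$w[[1]][idx]) / (abs(fd_f) + 1e-8)), 1e-4)
    } else {
      fd_b <- (fd_grad_at(contract(pos), function() p$wb[[n]],
                          function(v) p$wb[[n]] <<- v, idx) -
               fd_grad_at(contract(neg), function() p$wb[[n]],
                          function(v) p$wb[[n]] <<- v, idx)) / (2 * b * nb)
      shared <- (fd_f + fd_b) / 2
      expect_lt(max(abs(shared - est$w[[n]][idx]) / (abs(shared) + 1e-8)),
                1e-4)
    }
  }
  expect_error(kp_vf_estimate(pb$x, pos, neg,
                              make_fixture_net("fc_small", seed = 8)$params,
                              arch),
               "unidirectional")
})

test_that("readout estimate is the exact cross-entropy gradient", {
  fx <- make_fixture_net("fc_small", loss = "ce_readout", seed = 9)
  arch <- fx$arch; p <- fx$params
  pb <- probe_batch(arch, 3)
  free <- relax(pb$x, zero_state(arch, 3), p, arch, 200)
  est <- readout_estimate(pb$x, free$final_state, pb$y, p, arch)
  set.seed(31)
  idx <- sample(length(p$w_out), 6)
  fd <- fd_grad_at(
    f = function() eqprop:::state_loss(pb$x, free$final_state, pb$y, p, arch),
    get = function() p$w_out,
    set = function(v) p$w_out <<- v,
    idx = idx)
  expect_lt(max(abs(-fd - est[idx]) / (abs(fd) + 1e-10)), 1e-6)
})

test_that("the KP update contracts the forward/backward difference exactly", {
  fx <- make_fixture_net("fc_small", coupling = "unidirectional",
                         loss = "mse_output_layer", seed = 10)
  arch <- fx$arch
  pb <- probe_batch(arch, 2)
  free <- relax(pb$x, zero_state(arch, 2), fx$params, arch, 200)
  pos <- relax(pb$x, free$final_state, fx$params, arch, 200, y = pb$y,
               beta = 0.1)
  neg <- relax(pb$x, free$final_state, fx$params, arch, 200, y = pb$y,
               beta = -0.1)
  est <- kp_vf_estimate(pb$x, pos, neg, fx$params, arch)

  eta <- 0.05; lam <- 0.3
  # eta = 0 leaves parameters untouched
  up0 <- apply_update(fx$params, est, rep(0, arch$n_tot))
  expect_identical(up0$params, fx$params)

  # plain SGD: one step scales ||theta_f - theta_b|| by exactly (1-eta*lam)
  up <- apply_update(fx$params, est, rep(eta, arch$n_tot), momentum = 0,
                     weight_decay = 0, lambda = lam)
  for (n in 2:arch$n_tot) {
    d0 <- sqrt(sum((fx$params$w[[n]] - fx$params$wb[[n]])^2))
    d1 <- sqrt(sum((up$params$w[[n]] - up$params$wb[[n]])^2))
    expect_lt(abs(d1 - (1 - eta * lam) * d0) / d0, 1e-12)
  }

  # theta_f = theta_b is preserved indefinitely under KP updates
  p <- fx$params
  for (n in 2:arch$n_tot) p$wb[[n]] <- p$w[[n]]
  os <- NULL
  for (it in 1:3) {
    fr <- relax(pb$x, zero_state(arch, 2), p, arch, 150)
    ps <- relax(pb$x, fr$final_state, p, arch, 150, y = pb$y, beta = 0.1)
    ng <- relax(pb$x, fr$final_state, p, arch, 150, y = pb$y, beta = -0.1)
    e <- kp_vf_estimate(pb$x, ps, ng, p, arch)
    up <- apply_update(p, e, rep(eta, arch$n_tot), momentum = 0.9,
                       weight_decay = 1e-3, lambda = lam, opt_state = os)
    p <- up$params; os <- up$opt_state
    for (n in 2:arch$n_tot) expect_identical(p$w[[n]], p$wb[[n]])
  }

  expect_error(apply_update(fx$params, est, c(-1, rep(0, arch$n_tot - 1))),
               "nonnegative")
})
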