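# Network data model, primitive function, and relaxation dynamics.

test_that("primitive value matches hand evaluation and is bilinear", {
  net <- tiny_fc()
  x <- array(c(1, 0), c(1, 1, 1, 2))
  s <- zero_state(net$arch, 1)

  expect_equal(primitive_value(x, s, net$params, net$arch), 0)

  s[[1]][1, 1] <- 1
  expect_equal(primitive_value(x, s, net$params, net$arch), 0.5)

  p2 <- net$params
  p2$w[[1]] <- 2 * p2$w[[1]]
  expect_equal(primitive_value(x, s, p2, net$arch),
               2 * primitive_value(x, s, net$params, net$arch))

  uni <- make_fixture_net("fc_small", coupling = "unidirectional",
                          loss = "mse_output_layer", seed = 1)
  su <- zero_state(uni$arch, 1)
  xu <- array(0.5, c(1, uni$arch$input_shape))
  expect_error(primitive_value(xu, su, uni$params, uni$arch),
               "no primitive")
})

test_that("free step matches hand evaluation, zero case and fixed points", {
  net <- tiny_fc()
  x <- array(c(1, 0), c(1, 1, 1, 2))
  st <- free_step(x, zero_state(net$arch, 1), net$params, net$arch)
  expect_equal(as.numeric(st$state[[1]]), 0.5)

  p0 <- net$params
  p0$w[[1]][] <- 0
  st0 <- free_step(x, zero_state(net$arch, 1), p0, net$arch)
  expect_equal(as.numeric(st0$state[[1]]), 0)

  # a converged steady state maps to itself
  fx <- make_fixture_net("fc_small", loss = "mse_output_layer", seed = 2)
  pb <- probe_batch(fx$arch)
  ph <- relax(pb$x, zero_state(fx$arch, 4), fx$params, fx$arch, 300)
  nxt <- free_step(pb$x, ph$final_state, fx$params, fx$arch)
  for (n in seq_along(nxt$state))
    expect_lt(max(abs(nxt$state[[n]] - ph$final_state[[n]])), 1e-12)
})

test_that("nudged step reduces to the free step at beta = 0, bit for bit", {
  for (loss in c("mse_output_layer", "ce_readout")) {
    fx <- make_fixture_net("conv_small", loss = loss, seed = 3)
    pb <- probe_batch(fx$arch)
    s <- relax(pb$x, zero_state(fx$arch, 4), fx$params, fx$arch, 7)$final_state
    a <- free_step(pb$x, s, fx$params, fx$arch)
    b <- nudged_step(pb$x, s, fx$params, fx$arch, pb$y, beta = 0)
    expect_identical(a$state, b$state)
  }
})

test_that("mse nudging adds beta * (target - output) to the output pre-activation", {
  net <- tiny_fc(w = c(0.3, 0.1), b = 0)
  x <- array(c(1, 1), c(1, 1, 1, 2))
  s <- zero_state(net$arch, 1)
  s[[1]][1, 1] <- 0.2
  # free pre = 0.4; nudge with y one-hot = 1, beta = 0.5 adds 0.5*(1-0.2)
  st <- nudged_step(x, s, net$params, net$arch, y = 0L, beta = 0.5)
  expect_equal(as.numeric(st$state[[1]]), 0.4 + 0.4)
})

test_that("relaxation converges on fixtures, records residuals, handles steps = 0", {
  fx <- make_fixture_net("fc_small", loss = "mse_output_layer", seed = 1)
  pb <- probe_batch(fx$arch)
  s0 <- zero_state(fx$arch, 4)
  ph0 <- relax(pb$x, s0, fx$params, fx$arch, 0)
  expect_identical(ph0$final_state, s0)
  expect_length(ph0$residuals, 0)

  ph <- relax(pb$x, s0, fx$params, fx$arch, 100)
  expect_length(ph$residuals, 100)
  expect_lt(ph$residuals[100], 1e-6)
  # residuals shrink once the contraction takes over
  expect_lt(ph$residuals[100], ph$residuals[10])
  expect_lt(ph$residuals[50], 1e-4)

  expect_error(relax(pb$x, s0, fx$params, fx$arch, 5, beta = 0.1),
               "requires labels")
})

test_that("states stay in [0,1] after any step, for random nets and states", {
  set.seed(99)
  for (rep in 1:5) {
    fx <- make_fixture_net("conv_small", loss = "ce_readout", seed = rep)
    p <- fx$params
    for (n in seq_along(p$w)) p$w[[n]] <- p$w[[n]] * 3  # break contraction
    s <- lapply(eqprop:::state_dims(fx$arch, 2),
                function(d) array(runif(prod(d)), dim = d))
    x <- array(runif(2 * prod(fx$arch$input_shape)),
               c(2, fx$arch$input_shape))
    st <- free_step(x, s, p, fx$arch)
    expect_true(validate_state(st$state, fx$arch, 2))
    stn <- nudged_step(x, s, p, fx$arch, y = c(0L, 1L), beta = 0.7)
    expect_true(validate_state(stn$state, fx$arch, 2))
  }
})

test_that("pooling scatter followed by gather is the identity on pooled arrays", {
  set.seed(5)
  z <- array(rnorm(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  pr <- eqprop:::cpp_maxpool(z, 2L, 2L)
  u <- eqprop:::cpp_unpool(pr$values, pr$idx, 6L, 6L)
  expect_equal(eqprop:::cpp_pool_gather(u, pr$idx), pr$values)
  # gathering at the argmax positions reproduces the pooling itself
  expect_equal(eqprop:::cpp_pool_gather(z, pr$idx), pr$values)
})

test_that("the dynamics are the clamped state-gradient of the primitive", {
  # pre-activations must equal dPhi/ds, checked against central differences
  fx <- make_fixture_net("fc_small", loss = "mse_output_layer", seed = 4)
  pb <- probe_batch(fx$arch, 2)
  ph <- relax(pb$x, zero_state(fx$arch, 2), fx$params, fx$arch, 200)
  s <- ph$final_state
  pass <- eqprop:::ep_pass(pb$x, s, fx$params, fx$arch)
  set.seed(11)
  for (n in seq_len(fx$arch$n_tot)) {
    idx <- sample(length(s[[n]]), 4)
    fd <- fd_grad_at(
      f = function() sum(primitive_value(pb$x, s, fx$params, fx$arch)),
      get = function() s[[n]],
      set = function(v) s[[n]] <<- v,
      idx = idx)
    expect_lt(max(abs(fd - pass$pre[[n]][idx]) / (abs(fd) + 1e-8)), 1e-6)
  }
})

test_that("prediction scores behave like a softmax readout", {
  arch <- ep_arch(c(1, 1, 1), fc = 1, n_classes = 2, loss = "ce_readout")
  params <- init_params(arch)
  s <- zero_state(arch, 1)
  s[[1]][1, 1] <- 1
  x <- array(0.5, c(1, 1, 1, 1))

  params$w_out <- matrix(0, 2, 1)
  pr <- predict_state(x, s, params, arch)
  expect_equal(as.numeric(pr$scores), c(0.5, 0.5))

  params$w_out <- matrix(c(log(2), 0), 2, 1)
  pr <- predict_state(x, s, params, arch)
  expect_equal(as.numeric(pr$scores), c(2 / 3, 1 / 3))
  expect_equal(sum(pr$scores), 1)

  # argmax invariant to a constant shift of the logits
  params2 <- params
  params2$w_out <- params$w_out + 5
  expect_identical(predict_state(x, s, params2, arch)$labels, pr$labels)
})

test_that("state validation names the offending layer", {
  fx <- make_fixture_net("fc_small", loss = "mse_output_layer", seed = 1)
  s <- zero_state(fx$arch, 2)
  s[[2]] <- s[[2]][, 1:8]
  expect_error(validate_state(s, fx$arch, 2), "layer 2")
  s <- zero_state(fx$arch, 2)
  s[[1]][1, 1] <- 1.5
  expect_error(validate_state(s, fx$arch, 2), "outside")
})

test_that("checkpoints round-trip bit-exactly", {
  fx <- make_fixture_net("conv_small", coupling = "unidirectional",
                         loss = "ce_readout", seed = 6)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fx$params, fx$arch, path)
  ck <- load_checkpoint(path)
  expect_identical(ck$params, fx$params)
  expect_identical(ck$arch, fx$arch)
  unlink(path)
})
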