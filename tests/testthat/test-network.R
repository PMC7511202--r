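# Network construction, forward/backward, training loop, checkpointing.

test_that("init_network builds the documented shapes and states", {
  m <- init_network(c(784, 50, 10), "ip", seed = 1)
  expect_length(m$layers, 2L)
  expect_identical(dim(m$layers[[1]]$W), c(50L, 784L))
  expect_identical(dim(m$layers[[2]]$W), c(10L, 50L))
  # intrinsic states on input + hidden neurons: 784 + 50 = 834
  expect_identical(length(m$layers[[1]]$state$a) + length(m$layers[[2]]$state$a),
                   834L)
  expect_true(all(m$layers[[1]]$state$a == 1) && all(m$layers[[1]]$state$b == 0))
  m2 <- init_network(c(3072, 150, 10), "standard", seed = 2)
  expect_identical(dim(m2$layers[[1]]$W), c(150L, 3072L))
  expect_null(m2$layers[[1]]$state)
  expect_error(init_network(c(10, 5), "ip"), ">= 3")
})

test_that("initialisation is seed-deterministic and matched across rule kinds", {
  a <- init_network(c(8, 5, 3), "ip", seed = 7)
  b <- init_network(c(8, 5, 3), "ip", seed = 7)
  expect_identical(a$layers[[1]]$W, b$layers[[1]]$W)
  # same seed, different rule: bitwise-identical weights
  s <- init_network(c(8, 5, 3), "standard", seed = 7)
  im <- init_network(c(8, 5, 3), "infomax", seed = 7)
  expect_identical(a$layers[[1]]$W, s$layers[[1]]$W)
  expect_identical(a$layers[[2]]$W, im$layers[[2]]$W)
  expect_false(identical(a$layers[[1]]$W,
                         init_network(c(8, 5, 3), "ip", seed = 8)$layers[[1]]$W))
})

test_that("forward_pass composes transform, weights and output ReLU", {
  # hand-built 3-2-2 net: W1 selects the first two tanh outputs, W2 = I
  m <- init_network(c(3, 2, 2), "standard", seed = 1)
  m$layers[[1]]$W <- rbind(c(1, 0, 0), c(0, 1, 0))
  m$layers[[1]]$B_add <- c(0, 0)
  m$layers[[2]]$W <- diag(2)
  m$layers[[2]]$B_add <- c(0, 0)
  x <- matrix(c(0.5, -2, 9), nrow = 1)
  cache <- forward_pass(m, x)
  expect_equal(cache$y_out, matrix(pmax(tanh(tanh(c(0.5, -2))), 0), nrow = 1))
  # zero input, zero biases: everything zero
  z <- forward_pass(m, matrix(0, 1, 3))
  expect_identical(z$y_out, matrix(0, 1, 2))
  expect_error(forward_pass(m, matrix(0, 1, 4)), "features")
})

test_that("an IP network at its initial state runs the same forward pass as standard", {
  ip <- init_network(c(6, 4, 3), "ip", seed = 3)
  st <- init_network(c(6, 4, 3), "standard", seed = 3)
  x <- matrix(rnorm(5 * 6), nrow = 5)
  expect_identical(forward_pass(ip, x), forward_pass(st, x))
})

test_that("intrinsic_step applies the per-neuron rule updates from the cache", {
  m <- init_network(c(1, 2, 2), "ip", seed = 1)
  cache <- forward_pass(m, matrix(c(1, -1), ncol = 1))
  m2 <- intrinsic_step(m, cache, intrinsic_rates(0.1))
  # the input neuron sees x = [1, -1]: same oracle as the ip_update example
  expect_equal(m2$layers[[1]]$state$a, 0.9 + 0.1 * 2 * tanh(1), tolerance = 1e-12)
  expect_identical(m2$layers[[1]]$state$b, 0)
  # a standard model passes through untouched
  s <- init_network(c(1, 2, 2), "standard", seed = 1)
  expect_identical(intrinsic_step(s, forward_pass(s, matrix(1)), intrinsic_rates(0.1)), s)
})

test_that("backprop gradients match central finite differences", {
  ds <- tiny_blobs()
  x <- ds$inputs[1:7, , drop = FALSE]; t <- ds$targets[1:7]
  for (rule in c("standard", "ip", "infomax", "bn_incremental")) {
    m <- init_network(c(6, 5, 4, 4), rule, seed = 9)
    if (rule == "ip") {  # move the gains off 1 so du/dx = 1/a actually matters
      m$layers[[1]]$state$a <- runif(6, 0.5, 2)
      m$layers[[2]]$state$b <- runif(5, -0.2, 0.2)
    }
    cache <- forward_pass(m, x)
    gr <- ipnet:::network_gradients(m, cache, t)
    for (probe in list(c(1, 3), c(2, 7), c(3, 2))) {
      l <- probe[1]; i <- probe[2]
      fd <- fd_gradient(m, x, t, l, "W", i)
      expect_equal(gr$dW[[l]][i], fd, tolerance = 1e-4)
    }
    fdb <- fd_gradient(m, x, t, 2, "B_add", 1)
    expect_equal(gr$dB[[2]][1], fdb, tolerance = 1e-4)
  }
})

test_that("halving the gain doubles the gradient through that layer's transform", {
  ds <- tiny_blobs()
  x <- ds$inputs[1:5, , drop = FALSE]; t <- ds$targets[1:5]
  m <- init_network(c(6, 5, 4), "ip", seed = 2)
  g1 <- ipnet:::network_gradients(m, forward_pass(m, x), t)
  # double the input-layer gain: the cache changes too, so compare in the
  # small-gain regime where tanh is near-linear and the 1/a scaling dominates
  m$layers[[1]]$state$a <- rep(100, 6)
  m2 <- m
  m2$layers[[1]]$state$a <- rep(200, 6)
  ga <- ipnet:::network_gradients(m, forward_pass(m, x), t)
  gb <- ipnet:::network_gradients(m2, forward_pass(m2, x), t)
  # gradients w.r.t. the input-layer weights scale like y ~ x/a
  expect_equal(ga$dW[[1]], gb$dW[[1]] * 2, tolerance = 0.02)
})

test_that("weight_step with zero learning rate returns the loss but leaves weights", {
  ds <- tiny_blobs()
  m <- init_network(c(6, 5, 4), "ip", seed = 4)
  cfg <- train_config(synaptic_lr = 0, epochs = 1)
  cache <- forward_pass(m, ds$inputs)
  out <- weight_step(m, cache, ds$targets, cfg)
  expect_identical(out$model$layers[[1]]$W, m$layers[[1]]$W)
  expect_identical(out$model$layers[[2]]$B_add, m$layers[[2]]$B_add)
  expect_true(is.finite(out$loss) && out$loss > 0)
})

test_that("train learns a separable task, is deterministic, honours epochs = 0", {
  ds <- tiny_blobs()
  m <- init_network(c(6, 8, 4), "standard", seed = 5)
  cfg <- train_config(synaptic_lr = 0.01, epochs = 8, batch_size = 32, seed = 5)
  rec <- train(m, ds, cfg)
  expect_length(rec$epoch_loss, 8L)
  expect_lt(tail(rec$epoch_loss, 1), rec$epoch_loss[1])
  rec2 <- train(m, ds, cfg)
  expect_identical(rec$epoch_loss, rec2$epoch_loss)
  rec0 <- train(m, ds, train_config(epochs = 0))
  expect_length(rec0$epoch_loss, 0L)
  expect_identical(rec0$model$layers, m$layers)
})

test_that("IP with a frozen intrinsic rate reproduces the standard loss trace bitwise", {
  ds <- tiny_blobs()
  ip <- init_network(c(6, 8, 4), "ip", seed = 6)
  st <- init_network(c(6, 8, 4), "standard", seed = 6)
  cfg_ip <- train_config(synaptic_lr = 0.02, intrinsic_eta = 0, epochs = 5, seed = 6)
  rec_ip <- train(ip, ds, cfg_ip)
  rec_st <- train(st, ds, cfg_ip)
  expect_identical(rec_ip$epoch_loss, rec_st$epoch_loss)
  expect_identical(rec_ip$model$layers[[1]]$W, rec_st$model$layers[[1]]$W)
  expect_true(all(rec_ip$model$layers[[1]]$state$a == 1))
})

test_that("checkpoints round-trip bit-exactly", {
  ds <- tiny_blobs()
  m <- init_network(c(6, 5, 4), "ip", seed = 8)
  rec <- train(m, ds, train_config(synaptic_lr = 0.01, intrinsic_eta = 0.01,
                                   epochs = 2, seed = 8))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(rec$model, path)
  back <- load_checkpoint(path)
  expect_identical(back, rec$model)
  unlink(path)
})

test_that("training records export as tidy tables", {
  ds <- tiny_blobs()
  ds$test <- list(inputs = ds$inputs[1:10, ], targets = ds$targets[1:10])
  m <- init_network(c(6, 5, 4), "ip", seed = 1)
  rec <- train(m, ds, train_config(synaptic_lr = 0.01, epochs = 3, seed = 1))
  tab <- record_to_table(rec, run_id = "r1")
  expect_identical(names(tab), c("run_id", "seed", "epoch", "split", "loss"))
  expect_identical(nrow(tab), 6L)   # 3 train + 3 test rows
  expect_setequal(unique(tab$split), c("train", "test"))
})
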