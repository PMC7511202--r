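# Unit tests for the rule math: forward transforms, batch statistics and
# one-step updates, against closed-form oracles.

test_that("forward transforms evaluate the affine-tanh closed forms", {
  expect_identical(ip_transform(0, ip_state(a = 1, b = 0)), tanh(0))
  expect_equal(ip_transform(1, ip_state(a = 1, b = 0)), tanh(1))
  expect_equal(ip_transform(3, ip_state(a = 2, b = 1)), tanh(1))
  expect_equal(infomax_transform(0, infomax_state()), 0)
  expect_equal(infomax_transform(1, infomax_state(alpha = 1, beta = 0)), tanh(1))
  expect_equal(infomax_transform(0.5, infomax_state(alpha = 2, beta = 0)), tanh(1))
  expect_equal(bn_transform(2, bn_state(a_bn = 1, b_bn = 2)), 0)
  expect_equal(bn_transform(1, bn_state()), tanh(1))
})

test_that("transforms map finite inputs into (-1,1), increase in x, reject non-finite", {
  # keep |u| moderate: IEEE tanh rounds to exactly 1 beyond |u| ~ 19
  x <- c(-12, -3.2, 0, 0.5, 7, 15)
  for (st in list(ip_state(a = 1.5, b = 2), bn_state(a_bn = 5, b_bn = -1))) {
    y <- if (inherits(st, "ip_state")) ip_transform(x, st) else bn_transform(x, st)
    expect_true(all(y > -1 & y < 1))
    expect_true(all(diff(y) > 0))
  }
  y <- infomax_transform(x, infomax_state(alpha = 0.7, beta = 3))
  expect_true(all(y > -1 & y < 1))
  expect_true(all(diff(y) > 0))
  expect_error(ip_transform(c(1, NaN), ip_state()), "non-finite")
  expect_error(infomax_transform(Inf, infomax_state()), "non-finite")
})

test_that("IP and Infomax parameterisations are equivalent under (alpha, beta) = (1/a, -b/a)", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.2, 4); b <- runif(1, -3, 3); x <- rnorm(50, 0, 3)
    y_ip <- ip_transform(x, ip_state(a = a, b = b))
    y_im <- infomax_transform(x, infomax_state(alpha = 1 / a, beta = -b / a))
    expect_equal(y_ip, y_im, tolerance = 1e-12)
  }
})

test_that("batch statistics are population moments of the current batch", {
  s <- compute_batch_stats(c(1, -1), c(tanh(1), -tanh(1)))
  expect_identical(s$e_y, 0)
  expect_equal(s$e_xy, tanh(1))
  s2 <- compute_batch_stats(c(3, 1), tanh(c(3, 1)))
  expect_identical(s2$e_x, 2)
  expect_identical(s2$spread_x, 1)   # divide-by-n convention
  # matrix form agrees with column-wise vector form
  xm <- matrix(rnorm(20), ncol = 2); ym <- tanh(xm)
  sm <- compute_batch_stats(xm, ym)
  expect_equal(sm$e_xy[2], compute_batch_stats(xm[, 2], ym[, 2])$e_xy)
  expect_error(compute_batch_stats(numeric(0), numeric(0)), "empty")
  expect_error(compute_batch_stats(1:3, 1:2), "shape")
})

test_that("ip_update reproduces the hand-computed examples and fixed point", {
  rates <- intrinsic_rates(0.1)           # eta_b = 0.05 by the half-rate convention
  st <- ip_update(ip_state(), compute_batch_stats(c(1, -1), tanh(c(1, -1))), rates)
  expect_equal(st$a, 0.9 + 0.1 * 2 * tanh(1), tolerance = 1e-12)
  expect_identical(st$b, 0)
  # two-sample batch x = [2, 2]
  stats <- compute_batch_stats(c(2, 2), tanh(c(2, 2)))
  st2 <- ip_update(ip_state(), stats, rates)
  expect_equal(st2$a, 0.9 + 0.1 * 2 * 2 * tanh(2), tolerance = 1e-12)
  expect_equal(st2$b, 0.05 * 4 * (2 * tanh(2)) * tanh(2), tolerance = 1e-12)
  # fixed point: a = 2 E[xy], E[y] = 0 leaves the state untouched
  fp <- list(e_xy = 0.8, e_y = 0, e_x = 0, spread_x = 1)
  st3 <- ip_update(ip_state(a = 1.6, b = 0.3), fp, rates)
  expect_equal(st3$a, 1.6, tolerance = 1e-15)
  expect_identical(st3$b, 0.3)
})

test_that("the single-factor gain variant targets E[xy] instead of 2 E[xy]", {
  stats <- list(e_xy = 0.8, e_y = 0)
  st <- ip_update(ip_state(a = 2), stats, intrinsic_rates(0.1), gain_variant = "single")
  expect_equal(st$a, 0.9 * 2 + 0.1 * 0.8, tolerance = 1e-12)
})

test_that("infomax_update reproduces the hand-computed examples and fixed point", {
  st <- infomax_update(infomax_state(),
                       compute_batch_stats(c(1, -1), tanh(c(1, -1))), eta = 0.1)
  expect_equal(st$alpha, 1 + 0.1 * (1 - 2 * tanh(1)), tolerance = 1e-12)
  expect_identical(st$beta, 0)
  # alpha = 2: batch x = [1, -1] gives y = tanh(+-2), e_xy = tanh(2)
  s2 <- compute_batch_stats(c(1, -1), tanh(c(2, -2)))
  st2 <- infomax_update(infomax_state(alpha = 2), s2, eta = 0.1)
  expect_equal(st2$alpha, 2 + 0.1 * (0.5 - 2 * tanh(2)), tolerance = 1e-12)
  # fixed point alpha = 1/(2 E[xy]), e_y = 0
  fp <- list(e_xy = 0.625, e_y = 0)
  st3 <- infomax_update(infomax_state(alpha = 1 / (2 * 0.625), beta = 0.2), fp, 0.1)
  expect_equal(st3$alpha, 0.8, tolerance = 1e-15)
  expect_identical(st3$beta, 0.2)
})

test_that("bn_update tracks batch mean and sd and stays at its fixed point", {
  s_fp <- compute_batch_stats(c(1, -1), tanh(c(1, -1)))   # e_x = 0, sd = 1
  st <- bn_update(bn_state(), s_fp, eta = 0.1)
  expect_identical(st$a_bn, 1)
  expect_identical(st$b_bn, 0)
  s <- compute_batch_stats(c(3, 1), tanh(c(3, 1)))        # e_x = 2, sd = 1
  st2 <- bn_update(bn_state(), s, eta = 0.1)
  expect_equal(st2$a_bn, 1)
  expect_equal(st2$b_bn, 0.2, tolerance = 1e-15)
})

test_that("repeated updates on frozen stats converge geometrically", {
  eta <- 0.1
  stats <- list(e_xy = 1.3, e_y = 0.2, e_x = 2.5, spread_x = 0.7)
  rates <- intrinsic_rates(eta, eta / 2)
  ip <- ip_state(a = 3); bn <- bn_state(b_bn = -1)
  for (k in 1:25) {
    ip <- ip_update(ip, stats, rates)
    bn <- bn_update(bn, stats, eta)
    expect_equal(abs(ip$a - 2 * stats$e_xy), (1 - eta)^k * abs(3 - 2 * stats$e_xy),
                 tolerance = 1e-10)
    expect_equal(abs(bn$b_bn - stats$e_x), (1 - eta)^k * abs(-1 - stats$e_x),
                 tolerance = 1e-10)
    expect_equal(abs(bn$a_bn - stats$spread_x), (1 - eta)^k * abs(1 - stats$spread_x),
                 tolerance = 1e-10)
  }
})

test_that("the bias drive points toward the sample median (fixed gain)", {
  set.seed(5)
  samples <- list(gauss = rnorm(20000, 1, 2), expo = rexp(20000, 1),
                  unif = runif(20000, -1, 3))
  for (x in samples) {
    m <- median(x)
    for (a in c(0.5, 1, 2)) {
      for (b in m + c(-1, -0.3)) {
        s <- compute_batch_stats(x, ip_transform(x, ip_state(a = a, b = b)))
        expect_gte(4 * s$e_xy * s$e_y, -1e-3)
      }
      for (b in m + c(0.3, 1)) {
        s <- compute_batch_stats(x, ip_transform(x, ip_state(a = a, b = b)))
        expect_lte(4 * s$e_xy * s$e_y, 1e-3)
      }
    }
  }
})

test_that("gain flooring is applied, counted and never raised", {
  stats <- list(e_xy = -5, e_y = 0, e_x = 0, spread_x = 0)
  st <- ip_update(ip_state(), stats, intrinsic_rates(0.5))
  expect_identical(st$a, GAIN_FLOOR)
  expect_identical(st$floored, 1L)
  stb <- bn_update(bn_state(a_bn = GAIN_FLOOR), list(e_x = 0, spread_x = 0), eta = 0.5)
  expect_identical(stb$a_bn, GAIN_FLOOR)
  # alpha' = 1 + 0.2 * (1 - 2 * 3) = 0 exactly -> floored to +GAIN_FLOOR
  sti <- infomax_update(infomax_state(alpha = 1),
                        list(e_xy = 3, e_y = 0), eta = 0.2)
  expect_identical(sti$alpha, GAIN_FLOOR)
  expect_identical(sti$floored, 1L)
})

test_that("activation_gradient is 1 - y^2 on (-1,1) and rejects saturation", {
  expect_identical(activation_gradient(0), 1)
  expect_equal(activation_gradient(tanh(1)), 1 - tanh(1)^2)
  y <- tanh(seq(-5, 5, length.out = 101))
  g <- activation_gradient(y)
  expect_true(all(g > 0 & g <= 1))
  expect_error(activation_gradient(1), "impossible")
})
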