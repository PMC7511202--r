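# Core math of the three local normalisation rules. Everything here is
# stateless and vectorised over neurons: a "state" is a list of parameter
# vectors (one entry per neuron), and updates are pure functions
# state x stats -> state.

#' Default lower bound on gain magnitudes
#'
#' Gains (`a`, `a_bn`, `|alpha|`) must stay away from zero: the forward
#' transforms divide by `a`, and the Infomax update contains `1/alpha`.
#' After every update the gain is floored at this value so that degenerate
#' (e.g. constant-input) neurons remain finite without otherwise altering
#' the dynamics.
#'
#' @export
GAIN_FLOOR <- 1e-4

#' Construct an intrinsic-plasticity (IP) state
#'
#' The IP rule parameterises each neuron's activation as
#' `y = tanh((x - b) / a)`: `a` is the gain (steepness, in input units) and
#' `b` the bias (centre, in input units). Both are per-neuron vectors;
#' scalars are accepted for single-neuron work.
#'
#' @param a gain vector, strictly positive (default 1, the initial value
#'   used when a network is built).
#' @param b bias vector (default 0).
#' @param a_floor lower bound enforced on `a`.
#' @return an object of class `ip_state`.
#' @export
ip_state <- function(a = 1, b = 0, a_floor = GAIN_FLOOR) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b) || length(b) == 1L || length(a) == 1L)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("ip_state: parameters must be finite")
  if (any(a < a_floor))
    stop("ip_state: gain `a` must be >= a_floor (", a_floor, ")")
  structure(list(a = a, b = b, a_floor = a_floor, floored = 0L),
            class = c("ip_state", "rule_state"))
}

#' Construct an Infomax state
#'
#' The Infomax rule parameterises the pre-activation as `u = alpha * x + beta`
#' (note the gain multiplies rather than divides, so `alpha ~ 1/a` relative
#' to the IP parameterisation).
#'
#' @param alpha gain vector, `|alpha| >= alpha_floor`.
#' @param beta bias vector.
#' @param alpha_floor lower bound on `|alpha|`.
#' @return an object of class `infomax_state`.
#' @export
infomax_state <- function(alpha = 1, beta = 0, alpha_floor = GAIN_FLOOR) {
  if (!all(is.finite(alpha)) || !all(is.finite(beta)))
    stop("infomax_state: parameters must be finite")
  if (any(abs(alpha) < alpha_floor))
    stop("infomax_state: |alpha| must be >= alpha_floor (", alpha_floor, ")")
  structure(list(alpha = alpha, beta = beta, alpha_floor = alpha_floor,
                 floored = 0L),
            class = c("infomax_state", "rule_state"))
}

#' Construct an incremental batch-normalisation state
#'
#' Incremental BN uses the same forward transform as the IP rule,
#' `y = tanh((x - b_bn) / a_bn)`, but its parameters track the batch mean
#' and standard deviation of the input as slowly-updated persistent
#' estimates rather than being driven by the output statistics.
#'
#' @param a_bn scale estimate (input units), `>= a_floor`.
#' @param b_bn location estimate (input units).
#' @param a_floor lower bound on `a_bn`.
#' @return an object of class `bn_state`.
#' @export
bn_state <- function(a_bn = 1, b_bn = 0, a_floor = GAIN_FLOOR) {
  if (!all(is.finite(a_bn)) || !all(is.finite(b_bn)))
    stop("bn_state: parameters must be finite")
  if (any(a_bn < a_floor))
    stop("bn_state: scale `a_bn` must be >= a_floor (", a_floor, ")")
  structure(list(a_bn = a_bn, b_bn = b_bn, a_floor = a_floor, floored = 0L),
            class = c("bn_state", "rule_state"))
}

#' Intrinsic learning rates
#'
#' The gain rate `eta` and bias rate `eta_b`. By convention the bias rate
#' is half the gain rate; pass `eta_b` explicitly to override (single-neuron
#' entropy experiments use the full rate for both).
#'
#' @param eta gain learning rate, in (0, 1).
#' @param eta_b bias learning rate; defaults to `eta / 2`.
#' @return a list with elements `eta` and `eta_b`.
#' @export
intrinsic_rates <- function(eta, eta_b = eta / 2) {
  stopifnot(is.numeric(eta), length(eta) == 1L, eta >= 0, eta < 1,
            is.numeric(eta_b), length(eta_b) == 1L, eta_b >= 0, eta_b < 1)
  list(eta = eta, eta_b = eta_b)
}

check_finite_input <- function(x, what) {
  if (!all(is.finite(x)))
    stop(what, ": non-finite input values (corrupted upstream activations?)")
}

#' IP forward transform
#'
#' Applies `u = (x - b) / a`, `y = tanh(u)`. Vectorised over `x`; for a
#' multi-neuron state, `x` must be a matrix with one column per neuron.
#'
#' @param x input values (vector, or samples-by-neurons matrix).
#' @param state an [ip_state()].
#' @param return_u if `TRUE`, return `list(u =, y =)` instead of just `y`.
#' @return activations in (-1, 1).
#' @export
ip_transform <- function(x, state, return_u = FALSE) {
  check_finite_input(x, "ip_transform")
  u <- if (is.matrix(x)) sweep(sweep(x, 2L, state$b, "-"), 2L, state$a, "/")
       else (x - state$b) / state$a
  y <- tanh(u)
  if (return_u) list(u = u, y = y) else y
}

#' Infomax forward transform: `y = tanh(alpha * x + beta)`
#'
#' @inheritParams ip_transform
#' @param state an [infomax_state()].
#' @export
infomax_transform <- function(x, state, return_u = FALSE) {
  check_finite_input(x, "infomax_transform")
  u <- if (is.matrix(x)) sweep(sweep(x, 2L, state$alpha, "*"), 2L, state$beta, "+")
       else state$alpha * x + state$beta
  y <- tanh(u)
  if (return_u) list(u = u, y = y) else y
}

#' Incremental-BN forward transform: `y = tanh((x - b_bn) / a_bn)`
#'
#' @inheritParams ip_transform
#' @param state a [bn_state()].
#' @export
bn_transform <- function(x, state, return_u = FALSE) {
  check_finite_input(x, "bn_transform")
  u <- if (is.matrix(x)) sweep(sweep(x, 2L, state$b_bn, "-"), 2L, state$a_bn, "/")
       else (x - state$b_bn) / state$a_bn
  y <- tanh(u)
  if (return_u) list(u = u, y = y) else y
}

#' Per-neuron batch statistics
#'
#' Computes the moments that feed every update rule: `e_xy = E[x y]`,
#' `e_y = E[y]`, `e_x = E[x]` and `spread_x = sd(x)` (population,
#' divide-by-n convention), as arithmetic means over the current batch only.
#' Accepts vectors (single neuron) or samples-by-neurons matrices, in which
#' case each field is a per-neuron vector.
#'
#' @param x_batch per-neuron inputs.
#' @param y_batch per-neuron tanh outputs, aligned sample-wise with `x_batch`.
#' @return an object of class `neuron_batch_stats`.
#' @export
compute_batch_stats <- function(x_batch, y_batch) {
  if (is.matrix(x_batch) || is.matrix(y_batch)) {
    if (!is.matrix(x_batch) || !is.matrix(y_batch) ||
        !identical(dim(x_batch), dim(y_batch)))
      stop("compute_batch_stats: x and y must have identical shape")
  } else if (length(x_batch) != length(y_batch)) {
    stop("compute_batch_stats: x and y must have identical shape")
  }
  n <- if (is.matrix(x_batch)) nrow(x_batch) else length(x_batch)
  if (n < 1L) stop("compute_batch_stats: empty batch")
  cm <- function(m) if (is.matrix(m)) colMeans(m) else mean(m)
  e_x <- cm(x_batch)
  e_y <- cm(y_batch)
  e_xy <- cm(x_batch * y_batch)
  e_x2 <- cm(x_batch * x_batch)
  spread_x <- sqrt(pmax(e_x2 - e_x^2, 0))
  structure(list(e_xy = e_xy, e_y = e_y, e_x = e_x, spread_x = spread_x, n = n),
            class = "neuron_batch_stats")
}

# Flooring is logged, never raised: each state carries a running count of
# flooring events in `floored`, and a message is emitted when
# options(ipnet.verbose_floor = TRUE).
floor_gain <- function(g, floor, label) {
  hit <- g < floor
  if (any(hit)) {
    if (isTRUE(getOption("ipnet.verbose_floor", FALSE)))
      message(sprintf("%s: %d gain value(s) floored at %g", label, sum(hit), floor))
    g[hit] <- floor
  }
  list(g = g, n = sum(hit))
}

#' One IP update step
#'
#' The gain decays toward twice the input-output correlation and the bias
#' drifts along the product drive:
#' `a' = (1 - eta) a + eta * 2 E[xy]`,
#' `b' = b + eta_b * 4 E[xy] E[y]`.
#' Both updates are computed from the same pre-update statistics. The gain
#' is floored at `a_floor` afterwards (flooring is reported via `message()`,
#' never an error).
#'
#' The `"doubled"` gain variant (default) drives `a` toward `2 E[xy]`, the
#' value that makes the gain update a fixed point of the Infomax dynamics;
#' `"single"` drives it toward `E[xy]` (a stated restatement of the rule
#' without the factor 2), kept as an option for sensitivity checks — the
#' smaller equilibrium gain sharpens the sigmoid and pulls the bias
#' equilibrium closer to the input median.
#'
#' @param state an [ip_state()].
#' @param stats a [compute_batch_stats()] result from this state's batch.
#' @param rates an [intrinsic_rates()] list.
#' @param gain_variant `"doubled"` (target `2 E[xy]`) or `"single"`
#'   (target `E[xy]`).
#' @return the updated `ip_state`.
#' @export
ip_update <- function(state, stats, rates, gain_variant = c("doubled", "single")) {
  gain_factor <- if (match.arg(gain_variant) == "doubled") 2 else 1
  a_new <- (1 - rates$eta) * state$a + rates$eta * (gain_factor * stats$e_xy)
  b_new <- state$b + rates$eta_b * (4 * stats$e_xy * stats$e_y)
  fl <- floor_gain(a_new, state$a_floor, "ip_update")
  state$a <- fl$g
  state$b <- b_new
  state$floored <- state$floored + fl$n
  state
}

#' One Infomax update step
#'
#' `alpha' = alpha + eta (1/alpha - 2 E[xy])`, `beta' = beta - eta 2 E[y]`.
#' `|alpha|` is floored at `alpha_floor` afterwards (sign preserved).
#'
#' @param state an [infomax_state()].
#' @param stats batch statistics from this state's transform.
#' @param eta learning rate.
#' @return the updated `infomax_state`.
#' @export
infomax_update <- function(state, stats, eta) {
  alpha_new <- state$alpha + eta * (1 / state$alpha - 2 * stats$e_xy)
  beta_new <- state$beta + eta * (-2 * stats$e_y)
  hit <- abs(alpha_new) < state$alpha_floor
  if (any(hit)) {
    if (isTRUE(getOption("ipnet.verbose_floor", FALSE)))
      message(sprintf("infomax_update: %d gain value(s) floored at %g",
                      sum(hit), state$alpha_floor))
    alpha_new[hit] <- sign(alpha_new[hit] + (alpha_new[hit] == 0)) * state$alpha_floor
  }
  state$alpha <- alpha_new
  state$beta <- beta_new
  state$floored <- state$floored + sum(hit)
  state
}

#' One incremental-BN update step
#'
#' The scale and location estimates decay toward the batch standard
#' deviation and mean of the input:
#' `a_bn' = (1 - eta) a_bn + eta * sd(x)`,
#' `b_bn' = (1 - eta) b_bn + eta * E[x]`.
#'
#' @param state a [bn_state()].
#' @param stats batch statistics.
#' @param eta learning rate.
#' @return the updated `bn_state`.
#' @export
bn_update <- function(state, stats, eta) {
  a_new <- (1 - eta) * state$a_bn + eta * stats$spread_x
  b_new <- (1 - eta) * state$b_bn + eta * stats$e_x
  fl <- floor_gain(a_new, state$a_floor, "bn_update")
  state$a_bn <- fl$g
  state$b_bn <- b_new
  state$floored <- state$floored + fl$n
  state
}

#' Derivative of tanh expressed through its output
#'
#' For `y = tanh(u)`, `dy/du = 1 - y^2`. This is the per-neuron activation
#' gradient probed when studying the vanishing-gradient problem.
#'
#' @param y tanh activations, all strictly inside (-1, 1).
#' @return `1 - y^2`, in (0, 1].
#' @export
activation_gradient <- function(y) {
  if (any(abs(y) >= 1))
    stop("activation_gradient: |y| >= 1 is impossible for a genuine tanh output")
  1 - y^2
}

# Dispatch helpers used by the network/analysis layers -----------------------

rule_transform <- function(x, state, return_u = FALSE) {
  if (inherits(state, "ip_state")) ip_transform(x, state, return_u)
  else if (inherits(state, "infomax_state")) infomax_transform(x, state, return_u)
  else if (inherits(state, "bn_state")) bn_transform(x, state, return_u)
  else stop("unknown rule state")
}

rule_update <- function(state, stats, rates) {
  if (inherits(state, "ip_state")) ip_update(state, stats, rates)
  else if (inherits(state, "infomax_state")) infomax_update(state, stats, rates$eta)
  else if (inherits(state, "bn_state")) bn_update(state, stats, rates$eta)
  else stop("unknown rule state")
}

# 1/(d u / d x): the effective gain the backward pass divides by when the
# intrinsic parameters are treated as constants of the forward pass.
rule_du_dx <- function(state) {
  if (inherits(state, "ip_state")) 1 / state$a
  else if (inherits(state, "infomax_state")) state$alpha
  else if (inherits(state, "bn_state")) 1 / state$a_bn
  else stop("unknown rule state")
}
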