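# Verification instruments: histogram differential entropy on the tanh
# output support, single-neuron fixed-distribution convergence runs, the
# numerical gain/bias equilibrium solver, and a layer gradient probe.

#' Histogram estimate of differential entropy on (-1, 1)
#'
#' Plug-in (Riemann) estimator on the fixed support of a tanh output:
#' the support `[-1, 1]` is split into `n_bins` equal bins of width
#' `delta = 2/n_bins`, and `H = -sum(p_i log p_i) + log(delta)` over
#' occupied bins (empty bins contribute zero; no smoothing). The estimate
#' is bounded above by `log(2)` nats, attained by the uniform distribution.
#'
#' @param y_samples samples, all inside `[-1, 1]`.
#' @param n_bins number of bins (>= 2; default 100).
#' @return differential entropy estimate in nats.
#' @export
histogram_entropy <- function(y_samples, n_bins = 100L) {
  if (n_bins < 2L) stop("histogram_entropy: n_bins must be >= 2")
  if (any(y_samples < -1 | y_samples > 1) || !all(is.finite(y_samples)))
    stop("histogram_entropy: samples must lie inside [-1, 1]")
  delta <- 2 / n_bins
  bin <- pmin(floor((y_samples + 1) / delta) + 1L, n_bins)  # y = 1 joins the last bin
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts[counts > 0] / length(y_samples)
  -sum(p * log(p)) + log(delta)
}

#' Single-neuron entropy convergence on a frozen input batch
#'
#' Draws one batch from the distribution spec and repeatedly applies a
#' rule's forward transform and one-step update to that same batch,
#' recording the histogram entropy of the output each iteration. This is
#' the information-potential experiment: an information-maximising rule
#' should push the entropy toward the `log(2)` ceiling of the tanh support.
#'
#' The same intrinsic rate is used for gain and bias here (the comparison
#' puts all rules on one shared rate); pass `eta_b` to restore the
#' half-rate convention.
#'
#' @param rule `"ip"`, `"infomax"`, or `"bn_incremental"`.
#' @param dist a [distribution_spec()] (the batch is drawn once, with its
#'   seed).
#' @param eta intrinsic learning rate.
#' @param iterations number of update iterations.
#' @param n_bins entropy histogram bins.
#' @param eta_b bias rate (defaults to `eta`).
#' @return a list of class `entropy_trace`: `rule`, `entropy_nats`
#'   (per-iteration), `final_state`, `n_bins`, `diverged` flag.
#' @export
run_fixed_distribution <- function(rule = c("ip", "infomax", "bn_incremental"),
                                   dist, eta, iterations = 4000L,
                                   n_bins = 100L, eta_b = eta) {
  rule <- match.arg(rule)
  x <- sample_distribution(dist)
  state <- switch(rule, ip = ip_state(), infomax = infomax_state(),
                  bn_incremental = bn_state())
  rates <- intrinsic_rates(eta, eta_b)
  entropy <- numeric(iterations)
  diverged <- FALSE
  for (it in seq_len(iterations)) {
    y <- rule_transform(x, state)
    entropy[it] <- histogram_entropy(y, n_bins)
    state <- rule_update(state, compute_batch_stats(x, y), rates)
    params <- unlist(state[1:2])
    if (!all(is.finite(params))) {
      entropy <- entropy[seq_len(it)]
      diverged <- TRUE
      break
    }
  }
  structure(list(rule = rule, entropy_nats = entropy, final_state = state,
                 n_bins = n_bins, eta = eta, diverged = diverged),
            class = "entropy_trace")
}

#' @export
print.entropy_trace <- function(x, ...) {
  cat(sprintf("Entropy trace (%s): %d iteration(s), final %.4f nats (ceiling %.4f)%s\n",
              x$rule, length(x$entropy_nats), utils::tail(x$entropy_nats, 1), log(2),
              if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Numerical equilibrium of the IP rule on an empirical sample
#'
#' Solves the coupled fixed point of the gain/bias dynamics on a frozen
#' sample: `E[tanh((x - b)/a)] = 0` (the bias drive vanishes) and
#' `a = 2 E[x tanh((x - b)/a)]` (the gain decay balances). The bias root is
#' found by bisection (`uniroot`) within the sample range for each trial
#' gain, inside a fixed-point iteration on the gain. This is the
#' independent oracle against which the incremental dynamics are checked;
#' the solved bias is predicted to sit near the sample median.
#'
#' @param x empirical sample with non-zero spread.
#' @param a_init starting gain.
#' @param tol_b bisection tolerance on `|E[y]|`.
#' @param tol_a relative-change tolerance on the gain fixed point.
#' @param max_iter cap on the gain iterations.
#' @param gain_factor 2 for the default gain rule (`a -> 2 E[xy]`), 1 for
#'   the single-factor variant.
#' @return `list(a_star =, b_star =, e_y =, iterations =)`.
#' @export
equilibrium_oracle <- function(x, a_init = 1, tol_b = 1e-6, tol_a = 1e-8,
                               max_iter = 500L, gain_factor = 2) {
  if (stats::sd(x) == 0) stop("equilibrium_oracle: degenerate sample (zero spread)")
  e_y <- function(b, a) mean(tanh((x - b) / a))
  solve_b <- function(a) {
    lo <- min(x); hi <- max(x)
    if (e_y(lo, a) < 0 || e_y(hi, a) > 0)
      stop("equilibrium_oracle: no sign change for the bias root within the sample range")
    stats::uniroot(e_y, c(lo, hi), a = a, tol = tol_b / 10)$root
  }
  a <- a_init
  for (it in seq_len(max_iter)) {
    b <- solve_b(a)
    a_next <- gain_factor * mean(x * tanh((x - b) / a))
    if (a_next <= 0) stop("equilibrium_oracle: gain fixed point left the positive domain")
    rel <- abs(a_next - a) / a
    a <- a_next
    if (rel < tol_a) break
  }
  b <- solve_b(a)
  list(a_star = a, b_star = b, e_y = e_y(b, a), iterations = it)
}

#' Iterate the IP update to convergence on a frozen sample
#'
#' Convenience driver for checking that the incremental dynamics reach the
#' [equilibrium_oracle()] fixed point: repeatedly transforms the sample and
#' applies [ip_update()] (same rate on gain and bias) until the parameter
#' change falls below `tol` or `max_iter` is hit.
#'
#' @param x frozen sample.
#' @param eta intrinsic rate for both parameters.
#' @param max_iter iteration cap.
#' @param tol stop when both parameter step sizes fall below this.
#' @param gain_variant passed to [ip_update()].
#' @return `list(a =, b =, e_y =, e_xy =, iterations =)`.
#' @export
iterate_ip_to_convergence <- function(x, eta = 0.02, max_iter = 20000L, tol = 1e-7,
                                      gain_variant = "doubled") {
  state <- ip_state()
  rates <- intrinsic_rates(eta, eta)
  for (it in seq_len(max_iter)) {
    y <- ip_transform(x, state)
    stats <- compute_batch_stats(x, y)
    nxt <- ip_update(state, stats, rates, gain_variant)
    if (max(abs(nxt$a - state$a), abs(nxt$b - state$b)) < tol) { state <- nxt; break }
    state <- nxt
  }
  y <- ip_transform(x, state)
  stats <- compute_batch_stats(x, y)
  list(a = state$a, b = state$b, e_y = stats$e_y, e_xy = stats$e_xy,
       iterations = it)
}

#' Probe activation gradients at a layer during training
#'
#' Trains the model while recording, after every forward pass, the mean of
#' `1 - y^2` over the batch and the neurons of the probed (non-output)
#' layer. Large values mean the layer's tanh units are operating away from
#' saturation, i.e. backpropagated error is not being crushed there.
#'
#' @param model an [init_network()] model.
#' @param dataset as in [train()].
#' @param config a [train_config()].
#' @param layer_index non-output layer to probe (1 = input layer).
#' @return a list of class `gradient_trace`: `layer_index`, `grad_mean`
#'   (one value per batch), and the full training `record`.
#' @export
probe_gradients <- function(model, dataset, config, layer_index) {
  if (layer_index < 1L || layer_index > length(model$layers))
    stop("probe_gradients: layer_index must name a non-output layer")
  record <- train(model, dataset, config, probe_layer = layer_index)
  structure(list(layer_index = layer_index, grad_mean = record$grad_trace,
                 record = record),
            class = "gradient_trace")
}

#' Export an analysis trace as a tidy table
#'
#' @param trace an `entropy_trace` or `gradient_trace`.
#' @return a data.frame with columns (rule, iteration, entropy_nats) or
#'   (layer_index, iteration, grad_mean).
#' @export
trace_to_table <- function(trace) {
  if (inherits(trace, "entropy_trace"))
    data.frame(rule = trace$rule, iteration = seq_along(trace$entropy_nats),
               entropy_nats = trace$entropy_nats)
  else if (inherits(trace, "gradient_trace"))
    data.frame(layer_index = trace$layer_index,
               iteration = seq_along(trace$grad_mean),
               grad_mean = trace$grad_mean)
  else stop("trace_to_table: not a trace object")
}
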