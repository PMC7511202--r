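# Fully connected feedforward network with per-layer intrinsic mechanisms.
#
# Layer convention: for layer_sizes of length L there are L-1 parameterised
# layers. Layer l (1 <= l <= L-1) holds the intrinsic state for its
# layer_sizes[l] neurons (the transform applied to that layer's input), the
# weight matrix W (layer_sizes[l+1] x layer_sizes[l]) and additive bias
# B_add feeding the next layer. The output layer (index L) applies ReLU to
# its pre-activation and carries no intrinsic state. Batches are stored
# samples-by-features.

#' Build a feedforward network
#'
#' Weights are drawn uniformly in `(-1/sqrt(n_in), 1/sqrt(n_in))` (fan-in
#' scaling) from the given seed; additive biases start at zero. Intrinsic
#' gains start at 1 and biases at 0 on every non-output layer (including the
#' input layer). The output layer never carries an intrinsic state. State
#' initialisation consumes no random numbers, so two networks built from the
#' same seed have bitwise-identical weights regardless of `rule_kind` — the
#' matched-initialisation contract the experiment harness relies on.
#'
#' @param layer_sizes integer vector of at least 3 sizes
#'   (input, hidden..., output/class count).
#' @param rule_kind one of `"ip"`, `"infomax"`, `"bn_incremental"`,
#'   `"standard"` (plain tanh layers, no intrinsic adaptation).
#' @param seed integer seed for the weight draw.
#' @return an object of class `ipnet_model`.
#' @export
init_network <- function(layer_sizes, rule_kind = c("ip", "infomax", "bn_incremental", "standard"),
                         seed = 1L) {
  rule_kind <- match.arg(rule_kind)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 3L || any(layer_sizes < 1L))
    stop("init_network: need >= 3 positive layer sizes (input, hidden..., output)")
  n_layers <- length(layer_sizes) - 1L
  layers <- withr::with_seed(seed, {
    lapply(seq_len(n_layers), function(l) {
      n_in <- layer_sizes[l]; n_out <- layer_sizes[l + 1L]
      W <- matrix(stats::runif(n_out * n_in, -1 / sqrt(n_in), 1 / sqrt(n_in)),
                  nrow = n_out, ncol = n_in)
      list(W = W, B_add = numeric(n_out))
    })
  })
  for (l in seq_len(n_layers)) {
    n <- layer_sizes[l]
    layers[[l]]$state <- switch(rule_kind,
      ip = ip_state(a = rep(1, n), b = rep(0, n)),
      infomax = infomax_state(alpha = rep(1, n), beta = rep(0, n)),
      bn_incremental = bn_state(a_bn = rep(1, n), b_bn = rep(0, n)),
      standard = NULL)
  }
  structure(list(layer_sizes = layer_sizes, rule_kind = rule_kind,
                 layers = layers, seed = seed, opt = NULL),
            class = "ipnet_model")
}

#' @export
print.ipnet_model <- function(x, ...) {
  cat("Feedforward network (", paste(x$layer_sizes, collapse = "-"),
      "), rule: ", x$rule_kind, "\n", sep = "")
  invisible(x)
}

# tanh layer for "standard" networks; written so that an IP layer at the
# initial state (a = 1, b = 0) is bitwise identical: (x - 0)/1 == x exactly.
standard_transform <- function(x) list(u = x, y = tanh(x))

#' Forward pass through the network
#'
#' Each non-output layer applies its rule's affine-tanh transform to its
#' input and feeds `W %*% y + B_add` to the next layer; the output layer
#' applies ReLU to its pre-activation. All intermediates are cached for the
#' intrinsic update and backpropagation.
#'
#' @param model an [init_network()] model.
#' @param inputs numeric matrix, samples by input features (a vector is
#'   treated as a single sample).
#' @return a list of class `ipnet_cache` with per-layer `x`, `u`, `y`
#'   (lists over non-output layers), the output pre-activation `x_out`,
#'   and the ReLU output `y_out`.
#' @export
forward_pass <- function(model, inputs) {
  if (!is.matrix(inputs)) inputs <- matrix(inputs, nrow = 1L)
  if (ncol(inputs) != model$layer_sizes[1L])
    stop("forward_pass: input has ", ncol(inputs), " features; model expects ",
         model$layer_sizes[1L])
  n_layers <- length(model$layers)
  x_l <- vector("list", n_layers); u_l <- vector("list", n_layers)
  y_l <- vector("list", n_layers)
  x <- inputs
  for (l in seq_len(n_layers)) {
    st <- model$layers[[l]]$state
    tr <- if (is.null(st)) standard_transform(x) else rule_transform(x, st, return_u = TRUE)
    if (!all(is.finite(tr$y)))
      stop("forward_pass: non-finite activations at layer ", l)
    x_l[[l]] <- x; u_l[[l]] <- tr$u; y_l[[l]] <- tr$y
    x <- tcrossprod(tr$y, model$layers[[l]]$W)
    x <- sweep(x, 2L, model$layers[[l]]$B_add, "+")
  }
  if (!all(is.finite(x)))
    stop("forward_pass: non-finite pre-activations at the output layer")
  structure(list(x = x_l, u = u_l, y = y_l, x_out = x, y_out = pmax(x, 0)),
            class = "ipnet_cache")
}

#' Intrinsic parameter update from a cached batch
#'
#' For every neuron of every non-output layer, computes the batch statistics
#' from the cached pre-transform inputs and activations of that batch and
#' applies the layer rule's one-step update. A `"standard"` model is
#' returned unchanged. The cache must come from the current parameters:
#' statistics and update are simultaneous within a step.
#'
#' @param model the model that produced `cache`.
#' @param cache a [forward_pass()] cache.
#' @param rates an [intrinsic_rates()] list.
#' @return the model with updated intrinsic states.
#' @export
intrinsic_step <- function(model, cache, rates) {
  if (model$rule_kind == "standard") return(model)
  for (l in seq_along(model$layers)) {
    st <- model$layers[[l]]$state
    stats <- compute_batch_stats(cache$x[[l]], cache$y[[l]])
    model$layers[[l]]$state <- rule_update(st, stats, rates)
  }
  model
}

# Numerically stable softmax cross-entropy on the ReLU outputs.
# Returns mean loss and the gradient w.r.t. the ReLU outputs (already
# divided by batch size).
softmax_xent <- function(z, targets) {
  n <- nrow(z)
  zmax <- apply(z, 1L, max)
  zs <- z - zmax
  lse <- log(rowSums(exp(zs))) + zmax
  idx <- cbind(seq_len(n), targets + 1L)
  loss <- mean(lse - z[idx])
  p <- exp(zs) / rowSums(exp(zs))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n)
}

# Backpropagation through the cached forward pass. Intrinsic parameters are
# constants of the pass: each transform contributes (1 - y^2) * du/dx with
# du/dx = 1/a (IP, BN) or alpha (Infomax), or 1 for standard tanh layers.
# The loss is softmax cross-entropy over the ReLU outputs y_out.
network_gradients <- function(model, cache, targets) {
  n_layers <- length(model$layers)
  sm <- softmax_xent(cache$y_out, targets)
  relu_mask <- cache$x_out > 0
  delta <- sm$grad * relu_mask          # dL/d x_{L} (output pre-activation)
  dW <- vector("list", n_layers); dB <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    dW[[l]] <- crossprod(delta, cache$y[[l]])   # (n_out x n) x  -> t(delta) %*% y
    dB[[l]] <- colSums(delta)
    if (l > 1L) {
      dy <- delta %*% model$layers[[l]]$W       # dL/d y_{l}
      st <- model$layers[[l]]$state
      du_dx <- if (is.null(st)) 1 else rule_du_dx(st)
      dtanh <- 1 - cache$y[[l]]^2
      delta <- if (length(du_dx) == 1L && du_dx == 1) dy * dtanh
               else sweep(dy * dtanh, 2L, du_dx, "*")
    }
  }
  list(loss = sm$loss, dW = dW, dB = dB)
}

adam_init <- function(layers) {
  list(t = 0L, m = lapply(layers, function(l) list(W = l$W * 0, B = l$B_add * 0)),
       v = lapply(layers, function(l) list(W = l$W * 0, B = l$B_add * 0)))
}

#' Synaptic weight update (Adam on softmax cross-entropy)
#'
#' Computes the cross-entropy loss of the cached output against integer
#' class targets and applies one Adam step to the weight matrices and
#' additive biases only — intrinsic parameters are never touched by the
#' synaptic pathway. Gradients flow through the intrinsic transforms with
#' the gain/bias treated as constants of the forward pass. Adam moment
#' estimates persist inside the model (`model$opt`).
#'
#' @param model the model that produced `cache`.
#' @param cache a [forward_pass()] cache for `targets`' batch.
#' @param targets integer class labels in `[0, n_classes)`.
#' @param config a [train_config()].
#' @return `list(model =, loss =)` with the mean batch loss.
#' @export
weight_step <- function(model, cache, targets, config) {
  gr <- network_gradients(model, cache, targets)
  if (!is.finite(gr$loss))
    stop("weight_step: non-finite loss (training diverged)")
  if (is.null(model$opt)) model$opt <- adam_init(model$layers)
  opt <- model$opt
  opt$t <- opt$t + 1L
  lr <- config$synaptic_lr
  b1 <- config$adam_beta1; b2 <- config$adam_beta2; eps <- config$adam_eps
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (l in seq_along(model$layers)) {
    opt$m[[l]]$W <- b1 * opt$m[[l]]$W + (1 - b1) * gr$dW[[l]]
    opt$v[[l]]$W <- b2 * opt$v[[l]]$W + (1 - b2) * gr$dW[[l]]^2
    opt$m[[l]]$B <- b1 * opt$m[[l]]$B + (1 - b1) * gr$dB[[l]]
    opt$v[[l]]$B <- b2 * opt$v[[l]]$B + (1 - b2) * gr$dB[[l]]^2
    model$layers[[l]]$W <- model$layers[[l]]$W -
      lr * (opt$m[[l]]$W / bc1) / (sqrt(opt$v[[l]]$W / bc2) + eps)
    model$layers[[l]]$B_add <- model$layers[[l]]$B_add -
      lr * (opt$m[[l]]$B / bc1) / (sqrt(opt$v[[l]]$B / bc2) + eps)
  }
  model$opt <- opt
  list(model = model, loss = gr$loss)
}

#' Training configuration
#'
#' @param synaptic_lr Adam learning rate for weights and additive biases.
#' @param intrinsic_eta intrinsic learning rate for the gain; the bias rate
#'   defaults to half of it (override via `intrinsic_eta_b`).
#' @param intrinsic_eta_b bias learning rate.
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the data.
#' @param seed seed governing the per-epoch reshuffle.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment/stability constants.
#' @return a list of class `train_config`.
#' @export
train_config <- function(synaptic_lr = 0.03, intrinsic_eta = 1e-4,
                         intrinsic_eta_b = intrinsic_eta / 2,
                         batch_size = 64L, epochs = 10L, seed = 1L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(synaptic_lr >= 0, intrinsic_eta >= 0, batch_size >= 1L, epochs >= 0L)
  structure(list(synaptic_lr = synaptic_lr, intrinsic_eta = intrinsic_eta,
                 intrinsic_eta_b = intrinsic_eta_b, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "train_config")
}

#' Train a network
#'
#' Runs the five-step loop: forward pass, intrinsic update from the cached
#' batch, Adam weight update from the same cache, for every mini-batch, with
#' a seeded reshuffle of the data each epoch. Within one batch the intrinsic
#' update and the weight gradients both use the cache produced by the
#' pre-update parameters, so the intrinsic update never alters the gradients
#' of its own batch.
#'
#' @param model an [init_network()] model.
#' @param dataset a list with `inputs` (matrix, samples x features) and
#'   `targets` (integer labels in `[0, n_classes)`), e.g. from
#'   [make_blob_task()]; an optional `test` element of the same shape is
#'   scored (loss only) after each epoch.
#' @param config a [train_config()].
#' @param probe_layer optional non-output layer index: record the mean of
#'   `1 - y^2` over batch and neurons at that layer after every forward pass.
#' @return a list of class `ipnet_record`: `model` (final), `epoch_loss`
#'   (mean training loss per epoch), `test_loss` (if a test split was
#'   given), `grad_trace` (if probed), `diverged` flag.
#' @export
train <- function(model, dataset, config, probe_layer = NULL) {
  n <- nrow(dataset$inputs)
  if (is.null(n) || n < 1L) stop("train: empty dataset")
  if (!is.null(probe_layer) &&
      (probe_layer < 1L || probe_layer > length(model$layers)))
    stop("train: probe_layer must index a non-output layer")
  rates <- intrinsic_rates(config$intrinsic_eta, config$intrinsic_eta_b)
  epoch_loss <- numeric(0); test_loss <- numeric(0); grad_trace <- numeric(0)
  diverged <- FALSE
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        xb <- dataset$inputs[idx, , drop = FALSE]
        tb <- dataset$targets[idx]
        step <- tryCatch({
          cache <- forward_pass(model, xb)
          if (!is.null(probe_layer))
            grad_trace[length(grad_trace) + 1L] <- mean(1 - cache$y[[probe_layer]]^2)
          # weight gradients are taken at the pre-update intrinsic parameters
          # (the ones that produced the cache); the intrinsic step then acts
          # on the same cache — simultaneous semantics within the batch.
          ws <- weight_step(model, cache, tb, config)
          model <- intrinsic_step(ws$model, cache, rates)
          batch_losses[bi] <- ws$loss
          TRUE
        }, error = function(e) {
          if (grepl("non-finite", conditionMessage(e))) FALSE else stop(e)
        })
        if (!isTRUE(step)) { diverged <- TRUE; break }
      }
      if (diverged) break
      epoch_loss[ep] <- mean(batch_losses)
      if (!is.null(dataset$test)) {
        tc <- forward_pass(model, dataset$test$inputs)
        test_loss[ep] <- softmax_xent(tc$y_out, dataset$test$targets)$loss
      }
    }
  })
  structure(list(model = model, epoch_loss = epoch_loss, test_loss = test_loss,
                 grad_trace = grad_trace, diverged = diverged, config = config),
            class = "ipnet_record")
}

#' @export
print.ipnet_record <- function(x, ...) {
  cat("Training record:", length(x$epoch_loss), "epoch(s)")
  if (length(x$epoch_loss))
    cat(sprintf("; loss %.4f -> %.4f", x$epoch_loss[1], utils::tail(x$epoch_loss, 1)))
  if (x$diverged) cat(" [DIVERGED]")
  cat("\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single hierarchical file with one group per layer
#' (`W`, `B_add`, rule-state vectors) plus metadata (`rule_kind`,
#' `layer_sizes`, seed). Round-trips are bit-exact on weights and states.
#'
#' @param model an `ipnet_model`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ipnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ipnet_model")) stop("load_checkpoint: not a model checkpoint")
  model
}

#' Export a training record as a tidy table
#'
#' @param record an `ipnet_record` from [train()].
#' @param run_id identifier column value.
#' @return a data.frame with columns run_id, seed, epoch, split, loss.
#' @export
record_to_table <- function(record, run_id = "run") {
  out <- data.frame(run_id = run_id, seed = record$config$seed,
                    epoch = seq_along(record$epoch_loss), split = "train",
                    loss = record$epoch_loss)
  if (length(record$test_loss))
    out <- rbind(out, data.frame(run_id = run_id, seed = record$config$seed,
                                 epoch = seq_along(record$test_loss),
                                 split = "test", loss = record$test_loss))
  out
}
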