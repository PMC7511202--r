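# Shared fixtures, all built in code at test time.

# Small pixel-like blob task used by the network-level tests.
tiny_blobs <- function(seed = 42L, n_classes = 4L, dims = 6L, n_per_class = 30L,
                       noise_sigma = 0.05) {
  make_blob_task(blob_task_spec(n_classes = n_classes, dims = dims,
                                n_per_class = n_per_class,
                                noise_sigma = noise_sigma, seed = seed))
}

# The deep architecture of the reduced-scale experiments: 9 layers in total
# (input, seven hidden, output).
deep_arch <- function() c(20L, rep(30L, 7L), 10L)

# The blob task the deep-network claims are evaluated on.
deep_blobs <- function(seed = 42L) make_blob_task(blob_task_spec(seed = seed))

deep_train_config <- function(synaptic_lr, seed, epochs = 15L)
  train_config(synaptic_lr = synaptic_lr, intrinsic_eta = 0.005,
               batch_size = 64L, epochs = epochs, seed = seed)

# Central finite difference of the mean batch loss w.r.t. one parameter of
# the model; the independent oracle for the backprop gradients.
fd_loss <- function(model, inputs, targets) {
  cache <- forward_pass(model, inputs)
  z <- cache$y_out   # softmax cross-entropy on the ReLU outputs
  zmax <- apply(z, 1L, max)
  lse <- log(rowSums(exp(z - zmax))) + zmax
  mean(lse - z[cbind(seq_len(nrow(z)), targets + 1L)])
}

fd_gradient <- function(model, inputs, targets, layer, param, index, eps = 1e-5) {
  bump <- function(h) {
    m <- model
    m$layers[[layer]][[param]][index] <- m$layers[[layer]][[param]][index] + h
    fd_loss(m, inputs, targets)
  }
  (bump(eps) - bump(-eps)) / (2 * eps)
}
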