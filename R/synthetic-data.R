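# Seeded generators for every input the experiments need, plus optional
# readers (and tiny fixture writers) for the MNIST IDX and CIFAR-10 binary
# formats. All generators are pure functions of their spec: identical spec
# (seed included) gives identical output.

#' Specify a scalar input distribution
#'
#' The single-neuron experiments draw from parametric families: uniform
#' (given width and centre), Gaussian (mean and sd), exponential (rate), or
#' a user-supplied sample (`custom`). The analytic median is stored when
#' known — it is the quantity the bias is predicted to converge to.
#'
#' @param family one of `"uniform"`, `"gaussian"`, `"exponential"`, `"custom"`.
#' @param n sample count.
#' @param seed seed for the draw.
#' @param width,center uniform parameters (support `center +/- width/2`).
#' @param mu,sigma Gaussian parameters.
#' @param rate exponential rate.
#' @param sample the sample itself, for `family = "custom"`.
#' @return a list of class `distribution_spec` with the analytic `median`
#'   (NA for custom samples).
#' @export
distribution_spec <- function(family = c("uniform", "gaussian", "exponential", "custom"),
                              n = 10000L, seed = 1L,
                              width = 4, center = 1, mu = 1, sigma = 2,
                              rate = 1, sample = NULL) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (family != "custom" && n < 1L) stop("distribution_spec: n must be >= 1")
  med <- switch(family,
    uniform = { if (width <= 0) stop("uniform width must be > 0"); center },
    gaussian = { if (sigma <= 0) stop("gaussian sigma must be > 0"); mu },
    exponential = { if (rate <= 0) stop("exponential rate must be > 0"); log(2) / rate },
    custom = { if (is.null(sample) || !length(sample)) stop("custom family needs a sample"); NA_real_ })
  structure(list(family = family, n = if (family == "custom") length(sample) else n,
                 seed = as.integer(seed), width = width, center = center,
                 mu = mu, sigma = sigma, rate = rate, sample = sample,
                 median = med),
            class = "distribution_spec")
}

#' Draw the sample described by a distribution spec
#'
#' @param spec a [distribution_spec()].
#' @return a numeric vector of length `spec$n`; reproducible from the seed.
#' @export
sample_distribution <- function(spec) {
  stopifnot(inherits(spec, "distribution_spec"))
  if (spec$family == "custom") return(spec$sample)
  withr::with_seed(spec$seed, switch(spec$family,
    uniform = stats::runif(spec$n, spec$center - spec$width / 2,
                           spec$center + spec$width / 2),
    gaussian = stats::rnorm(spec$n, spec$mu, spec$sigma),
    exponential = stats::rexp(spec$n, spec$rate)))
}

#' Specify a Gaussian-blob classification task
#'
#' A seeded, perfectly class-balanced synthetic task standing in for image
#' benchmarks, so its features behave like scaled pixels: class centres are
#' drawn from `N(centre_mean, centre_sd^2)` per dimension, samples from
#' isotropic Gaussians of sd `noise_sigma` around them, and (by default)
#' values are clipped to `[0, 1]`. The default centre at 0.5 gives
#' non-negative, non-centred inputs — the property of pixel data that makes
#' activation centering matter. With `noise_sigma` well below the typical
#' centre separation the task is near-separable.
#'
#' @param n_classes number of classes (>= 2).
#' @param dims input dimensionality.
#' @param n_per_class training samples per class (> 0).
#' @param n_test_per_class held-out samples per class (0 for no test split).
#' @param noise_sigma within-class spread (> 0).
#' @param centre_mean,centre_sd location and spread of the class centres.
#' @param clip clip features to `[0, 1]` like pixel intensities (default
#'   TRUE; set FALSE for unbounded Gaussian blobs).
#' @param seed seed for centres and samples.
#' @return a list of class `blob_task_spec`.
#' @export
blob_task_spec <- function(n_classes = 10L, dims = 20L, n_per_class = 100L,
                           n_test_per_class = 0L, noise_sigma = 0.15,
                           centre_mean = 0.5, centre_sd = 0.15, clip = TRUE,
                           seed = 1L) {
  stopifnot(n_classes >= 2L, dims >= 1L, noise_sigma > 0, centre_sd > 0)
  if (n_per_class < 1L) stop("blob_task_spec: n_per_class must be >= 1 (empty dataset)")
  structure(list(n_classes = as.integer(n_classes), dims = as.integer(dims),
                 n_per_class = as.integer(n_per_class),
                 n_test_per_class = as.integer(n_test_per_class),
                 noise_sigma = noise_sigma, centre_mean = centre_mean,
                 centre_sd = centre_sd, clip = isTRUE(clip),
                 seed = as.integer(seed)),
            class = "blob_task_spec")
}

#' Generate a Gaussian-blob dataset
#'
#' @param spec a [blob_task_spec()].
#' @return a list with `inputs` (matrix, samples x dims), `targets`
#'   (integer labels `0..n_classes-1`, balanced by construction), `centres`,
#'   and optionally `test` (same shape) when the spec requests a held-out
#'   split.
#' @export
make_blob_task <- function(spec) {
  stopifnot(inherits(spec, "blob_task_spec"))
  withr::with_seed(spec$seed, {
    centres <- matrix(stats::rnorm(spec$n_classes * spec$dims, spec$centre_mean,
                                   spec$centre_sd),
                      nrow = spec$n_classes)
    draw <- function(n_per) {
      n <- n_per * spec$n_classes
      targets <- rep(seq_len(spec$n_classes) - 1L, each = n_per)
      inputs <- centres[targets + 1L, , drop = FALSE] +
        matrix(stats::rnorm(n * spec$dims, 0, spec$noise_sigma), nrow = n)
      if (spec$clip) inputs <- pmin(pmax(inputs, 0), 1)
      list(inputs = inputs, targets = targets)
    }
    train <- draw(spec$n_per_class)
    out <- list(inputs = train$inputs, targets = train$targets, centres = centres)
    if (spec$n_test_per_class > 0L) out$test <- draw(spec$n_test_per_class)
    out
  })
}

# --- MNIST IDX format -------------------------------------------------------

read_be_int <- function(con) readBin(con, "integer", 1L, size = 4L, endian = "big")

#' Read an MNIST-style IDX image/label file pair
#'
#' Parses the big-endian IDX format (magic 2051 for images, 2049 for
#' labels). Pixels are scaled to `[0, 1]` by default.
#'
#' @param images_path path to the idx3-ubyte image file.
#' @param labels_path path to the idx1-ubyte label file.
#' @param scale divide pixel values by 255 (default TRUE).
#' @return a list with `inputs` (n x rows*cols matrix) and `targets`
#'   (integer labels).
#' @export
read_mnist_idx <- function(images_path, labels_path, scale = TRUE) {
  icon <- file(images_path, "rb"); on.exit(close(icon), add = TRUE)
  if (read_be_int(icon) != 2051L) stop("read_mnist_idx: bad image magic number")
  n <- read_be_int(icon); nr <- read_be_int(icon); nc <- read_be_int(icon)
  px <- readBin(icon, "integer", n * nr * nc, size = 1L, signed = FALSE)
  if (length(px) != n * nr * nc) stop("read_mnist_idx: truncated image file")
  lcon <- file(labels_path, "rb"); on.exit(close(lcon), add = TRUE)
  if (read_be_int(lcon) != 2049L) stop("read_mnist_idx: bad label magic number")
  nl <- read_be_int(lcon)
  if (nl != n) stop("read_mnist_idx: image/label counts differ (", n, " vs ", nl, ")")
  labels <- readBin(lcon, "integer", nl, size = 1L, signed = FALSE)
  if (length(labels) != nl) stop("read_mnist_idx: truncated label file")
  inputs <- matrix(px, nrow = n, ncol = nr * nc, byrow = TRUE)
  if (scale) inputs <- inputs / 255
  list(inputs = inputs, targets = as.integer(labels))
}

#' Write a tiny IDX fixture (inverse of [read_mnist_idx()])
#'
#' Intended for tests and examples; writes valid idx3/idx1 headers.
#'
#' @param inputs integer pixel matrix (n x rows*cols), values 0..255.
#' @param targets integer labels.
#' @param images_path,labels_path output paths.
#' @param rows,cols image geometry (`rows * cols` must equal `ncol(inputs)`).
#' @export
write_mnist_idx <- function(inputs, targets, images_path, labels_path,
                            rows = 28L, cols = 28L) {
  stopifnot(nrow(inputs) == length(targets), ncol(inputs) == rows * cols)
  icon <- file(images_path, "wb"); on.exit(close(icon), add = TRUE)
  writeBin(c(2051L, nrow(inputs), as.integer(rows), as.integer(cols)),
           icon, size = 4L, endian = "big")
  writeBin(as.raw(t(inputs)), icon)
  lcon <- file(labels_path, "wb"); on.exit(close(lcon), add = TRUE)
  writeBin(c(2049L, length(targets)), lcon, size = 4L, endian = "big")
  writeBin(as.raw(targets), lcon)
  invisible(NULL)
}

# --- CIFAR-10 binary batches ------------------------------------------------

#' Read CIFAR-10 binary batch files
#'
#' Each record is 3073 bytes: one label byte followed by 3072 pixel bytes
#' (32 x 32 x 3 channels). Reads every `*.bin` file in `batch_dir` (or the
#' explicit files given) and scales pixels to `[0, 1]` by default.
#'
#' @param batch_dir directory containing `*.bin` batches (or a character
#'   vector of file paths).
#' @param scale divide pixel values by 255 (default TRUE).
#' @return a list with `inputs` (n x 3072 matrix) and `targets`.
#' @export
read_cifar10 <- function(batch_dir, scale = TRUE) {
  files <- if (length(batch_dir) == 1L && dir.exists(batch_dir))
    list.files(batch_dir, pattern = "\\.bin$", full.names = TRUE)
  else batch_dir
  if (!length(files) || !all(file.exists(files)))
    stop("read_cifar10: no .bin batch files found")
  rec <- 3073L
  parts <- lapply(files, function(f) {
    sz <- file.size(f)
    if (is.na(sz) || sz == 0L || sz %% rec != 0L)
      stop("read_cifar10: ", f, " is not a whole number of 3073-byte records")
    raw <- readBin(f, "integer", sz, size = 1L, signed = FALSE)
    m <- matrix(raw, nrow = rec)
    list(targets = as.integer(m[1L, ]), inputs = t(m[-1L, , drop = FALSE]))
  })
  inputs <- do.call(rbind, lapply(parts, `[[`, "inputs"))
  if (scale) inputs <- inputs / 255
  list(inputs = inputs, targets = unlist(lapply(parts, `[[`, "targets")))
}

#' Write a tiny CIFAR-10 binary fixture (inverse of [read_cifar10()])
#'
#' @param inputs integer pixel matrix (n x 3072), values 0..255.
#' @param targets integer labels 0..9.
#' @param path output `.bin` file.
#' @export
write_cifar10 <- function(inputs, targets, path) {
  stopifnot(nrow(inputs) == length(targets), ncol(inputs) == 3072L)
  con <- file(path, "wb"); on.exit(close(con), add = TRUE)
  recs <- cbind(as.integer(targets), inputs)
  writeBin(as.raw(t(recs)), con)
  invisible(NULL)
}
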