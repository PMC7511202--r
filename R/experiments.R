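# Config-driven experiment harness: matched-initialisation rule
# comparisons with repetition averaging, presets mirroring the shallow and
# deep benchmark designs, and tidy CSV/JSON outputs. The command-line
# interface in inst/cli/ipnet is a thin wrapper over these functions.

#' Build an experiment configuration
#'
#' Describes one sweep: a dataset, an architecture, the rule variants to
#' compare, and the repetition/seed structure. Within each repetition every
#' rule variant is initialised from the same seed, so all variants start
#' from bitwise-identical weights (the matched-initialisation contract).
#'
#' @param experiment label: `"shallow"`, `"deep"`, `"rule_comparison"`,
#'   `"gradient_probe"`, or `"entropy"`.
#' @param dataset `"blobs"`, `"mnist"`, or `"cifar10"`.
#' @param architecture integer layer sizes, input to output.
#' @param rules character vector of rule kinds to compare.
#' @param synaptic_lr Adam learning rate (one value per run of the sweep).
#' @param intrinsic_eta shared intrinsic learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param repetitions number of repetitions; `seeds` must supply one seed
#'   per repetition (default `1:repetitions`).
#' @param seeds integer seeds, one per repetition.
#' @param blob_spec a [blob_task_spec()] when `dataset = "blobs"`.
#' @param data_path directory/file paths for the real-data readers.
#' @param probe_layer probed layer for gradient-probe experiments.
#' @param output_dir where [run_experiment()] writes results.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = "rule_comparison",
                              dataset = c("blobs", "mnist", "cifar10"),
                              architecture = c(20L, 30L, 10L),
                              rules = c("ip", "standard"),
                              synaptic_lr = 0.01,
                              intrinsic_eta = 1e-4,
                              epochs = 10L, batch_size = 64L,
                              repetitions = 1L, seeds = seq_len(repetitions),
                              blob_spec = NULL, data_path = NULL,
                              probe_layer = 4L,
                              output_dir = "ipnet-results") {
  dataset <- match.arg(dataset)
  if (repetitions < 1L) stop("experiment_config: repetitions must be >= 1")
  if (length(seeds) != repetitions)
    stop("experiment_config: need exactly one seed per repetition")
  if (dataset == "blobs" && is.null(blob_spec))
    blob_spec <- blob_task_spec(n_classes = architecture[length(architecture)],
                                dims = architecture[1L])
  structure(list(experiment = experiment, dataset = dataset,
                 architecture = as.integer(architecture), rules = rules,
                 synaptic_lr = synaptic_lr, intrinsic_eta = intrinsic_eta,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 repetitions = as.integer(repetitions), seeds = as.integer(seeds),
                 blob_spec = blob_spec, data_path = data_path,
                 probe_layer = as.integer(probe_layer), output_dir = output_dir),
            class = "experiment_config")
}

#' Benchmark presets
#'
#' Named configurations mirroring the reference experiment designs:
#' `shallow_mnist` (784-50-10, Adam lr 0.03, eta 1e-4, 20 epochs, 10 reps),
#' `shallow_cifar10` (3072-150-10, lr 0.001, 40 epochs),
#' `deep_mnist` / `deep_cifar10` (seven hidden layers; lr sweeps
#' {0.003, 0.01, 0.012} and {0.0006, 0.001, 0.0013}),
#' `rule_comparison_mnist` / `rule_comparison_cifar10` (IP vs Infomax vs
#' incremental BN at a shared eta of 1e-4, lr 0.005 / 0.001), and
#' `gradient_probe_mnist` (9 layers total, probe layer 4, lr 0.005).
#' Hidden widths for the deep presets default to the shallow widths
#' (50 MNIST-scale, 150 CIFAR-scale); they are configurable because no
#' canonical value exists.
#'
#' @param name preset name (see above).
#' @param dataset override the preset's dataset (e.g. `"blobs"` to run the
#'   same design on the synthetic task).
#' @param ... further overrides passed to [experiment_config()].
#' @return an `experiment_config`.
#' @export
experiment_preset <- function(name = c("shallow_mnist", "shallow_cifar10",
                                       "deep_mnist", "deep_cifar10",
                                       "rule_comparison_mnist",
                                       "rule_comparison_cifar10",
                                       "gradient_probe_mnist"),
                              dataset = NULL, ...) {
  name <- match.arg(name)
  deep <- function(w, n_in) c(n_in, rep(w, 7L), 10L)
  base <- switch(name,
    shallow_mnist = list(experiment = "shallow", dataset = "mnist",
                         architecture = c(784L, 50L, 10L), rules = c("ip", "standard"),
                         synaptic_lr = 0.03, epochs = 20L, repetitions = 10L),
    shallow_cifar10 = list(experiment = "shallow", dataset = "cifar10",
                           architecture = c(3072L, 150L, 10L), rules = c("ip", "standard"),
                           synaptic_lr = 0.001, epochs = 40L, repetitions = 10L),
    deep_mnist = list(experiment = "deep", dataset = "mnist",
                      architecture = deep(50L, 784L), rules = c("ip", "standard"),
                      synaptic_lr = c(0.003, 0.01, 0.012), epochs = 20L,
                      repetitions = 10L),
    deep_cifar10 = list(experiment = "deep", dataset = "cifar10",
                        architecture = deep(150L, 3072L), rules = c("ip", "standard"),
                        synaptic_lr = c(0.0006, 0.001, 0.0013), epochs = 40L,
                        repetitions = 10L),
    rule_comparison_mnist = list(experiment = "rule_comparison", dataset = "mnist",
                                 architecture = deep(50L, 784L),
                                 rules = c("ip", "infomax", "bn_incremental"),
                                 synaptic_lr = 0.005, epochs = 20L, repetitions = 10L),
    rule_comparison_cifar10 = list(experiment = "rule_comparison", dataset = "cifar10",
                                   architecture = deep(150L, 3072L),
                                   rules = c("ip", "infomax", "bn_incremental"),
                                   synaptic_lr = 0.001, epochs = 40L, repetitions = 10L),
    gradient_probe_mnist = list(experiment = "gradient_probe", dataset = "mnist",
                                architecture = deep(50L, 784L),
                                rules = c("ip", "standard"),
                                synaptic_lr = 0.005, epochs = 20L, repetitions = 5L))
  base$intrinsic_eta <- 1e-4
  if (!is.null(dataset)) {
    base$dataset <- dataset
    if (dataset == "blobs")  # keep the depth, shrink the width to blob scale
      base$architecture <- c(20L, rep(30L, length(base$architecture) - 2L), 10L)
  }
  over <- list(...)
  base[names(over)] <- over
  do.call(experiment_config, base)
}

load_experiment_dataset <- function(config) {
  switch(config$dataset,
    blobs = make_blob_task(config$blob_spec),
    mnist = {
      if (is.null(config$data_path) || length(config$data_path) < 2L)
        stop("mnist dataset needs data_path = c(images, labels)")
      read_mnist_idx(config$data_path[1L], config$data_path[2L])
    },
    cifar10 = {
      if (is.null(config$data_path))
        stop("cifar10 dataset needs data_path = batch directory")
      read_cifar10(config$data_path)
    })
}

#' Run an experiment sweep
#'
#' For every synaptic learning rate in the config and every repetition,
#' initialises one network per rule variant from the repetition's seed
#' (matched weights across variants), trains each, and collects per-epoch
#' losses. Divergent runs are recorded (`diverged = TRUE`, curve truncated)
#' without aborting the sweep. Results are written to `output_dir`:
#' `curves.csv` (tidy per-epoch losses), `summary.json` (final-loss table
#' and resolved config), and `run.log`.
#'
#' @param config an [experiment_config()].
#' @param write_files set `FALSE` to skip writing and just return results.
#' @return invisibly, a list with `curves` (data.frame: rule, synaptic_lr,
#'   seed, epoch, loss, diverged), `summary` (from [summarise_experiment()])
#'   and `config`.
#' @export
run_experiment <- function(config, write_files = TRUE) {
  dataset <- load_experiment_dataset(config)
  rows <- list()
  logline <- character(0)
  for (lr in config$synaptic_lr) {
    for (rep_i in seq_len(config$repetitions)) {
      seed <- config$seeds[rep_i]
      for (rule in config$rules) {
        model <- init_network(config$architecture, rule, seed = seed)
        tc <- train_config(synaptic_lr = lr, intrinsic_eta = config$intrinsic_eta,
                           batch_size = config$batch_size, epochs = config$epochs,
                           seed = seed)
        rec <- train(model, dataset, tc)
        if (rec$diverged)
          logline <- c(logline, sprintf(
            "DIVERGED rule=%s lr=%g seed=%d after %d epoch(s)",
            rule, lr, seed, length(rec$epoch_loss)))
        if (length(rec$epoch_loss))
          rows[[length(rows) + 1L]] <- data.frame(
            rule = rule, synaptic_lr = lr, seed = seed,
            epoch = seq_along(rec$epoch_loss), loss = rec$epoch_loss,
            diverged = rec$diverged)
      }
    }
  }
  curves <- do.call(rbind, rows)
  summary <- summarise_curves(curves)
  out <- list(curves = curves, summary = summary, config = config)
  if (write_files) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(curves, file.path(config$output_dir, "curves.csv"),
                     row.names = FALSE)
    cfg <- config
    cfg$blob_spec <- unclass(cfg$blob_spec)
    jsonlite::write_json(list(summary = summary, config = unclass(cfg)),
                         file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(sprintf("experiment=%s dataset=%s", config$experiment,
                         config$dataset), logline),
               file.path(config$output_dir, "run.log"))
  }
  invisible(out)
}

summarise_curves <- function(curves) {
  agg <- stats::aggregate(loss ~ rule + synaptic_lr + epoch, data = curves,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  curve_table <- data.frame(rule = agg$rule, synaptic_lr = agg$synaptic_lr,
                            epoch = agg$epoch,
                            mean_loss = agg$loss[, "mean"],
                            sd_loss = ifelse(is.na(agg$loss[, "sd"]), 0,
                                             agg$loss[, "sd"]),
                            n = agg$loss[, "n"])
  final_ep <- stats::aggregate(epoch ~ rule + synaptic_lr + seed, data = curves,
                               FUN = max)
  finals <- merge(final_ep, curves)
  final_table <- stats::aggregate(loss ~ rule + synaptic_lr, data = finals,
                                  FUN = mean)
  names(final_table)[names(final_table) == "loss"] <- "final_mean_loss"
  best <- final_table[order(final_table$final_mean_loss), ][1L, ]
  list(curve = curve_table, final = final_table,
       best_rule = as.character(best$rule), best_lr = best$synaptic_lr)
}

#' Summarise a results directory
#'
#' Reads the `curves.csv` written by [run_experiment()] (recursively, so a
#' directory of sweeps can be pooled) and recomputes the mean +/- sd
#' learning curves and the final-loss comparison, flagging the rule with
#' the lowest final mean loss.
#'
#' @param results_dir directory containing one or more `curves.csv`.
#' @return a list with `curve` (mean/sd per epoch per rule), `final`
#'   (final mean loss per rule and learning rate), `best_rule`, `best_lr`.
#' @export
summarise_experiment <- function(results_dir) {
  files <- list.files(results_dir, pattern = "^curves\\.csv$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("summarise_experiment: no curves.csv under ", results_dir)
  curves <- do.call(rbind, lapply(files, utils::read.csv))
  summarise_curves(curves)
}
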