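# Pipeline orchestration: hierarchical run configuration, staged execution
# with on-disk artifacts, and a JSON manifest that suffices to re-run any
# deterministic stage bit-identically.

SCENARIOS <- list(two_level = c(0L, 4L),
                  three_level = c(0L, 2L, 4L),
                  five_level = 0:4)

#' Hierarchical run configuration
#'
#' Bundles the per-stage configurations with a scenario, a global seed and
#' an output directory. Scenarios select the fatigue levels under study:
#' two-level (normal vs complete fatigue), three-level (normal / mid /
#' complete) and five-level (all states).
#'
#' @param scenario one of `"two_level"`, `"three_level"`, `"five_level"`.
#' @param n_per_class synthetic recordings per level.
#' @param synth a [synth_config()].
#' @param preprocess a [preprocess_config()].
#' @param gan a [gan_spec()] (its generator output length must equal
#'   channels x samples of the preprocessed epochs when augmentation is
#'   run).
#' @param augment_total target dataset size after augmentation (`NULL`
#'   disables augmentation in the `all` chain).
#' @param activation activation variant for the classifier.
#' @param train a [train_config()].
#' @param input_mode `"concat"` (channels concatenated into one vector) or
#'   `"multichannel"`.
#' @param seed global seed; all stage seeds derive from it.
#' @param out_dir output directory for stage artifacts.
#' @return a list of class `run_config`.
#' @export
run_config <- function(scenario = c("five_level", "three_level", "two_level"),
                       n_per_class = 100,
                       synth = synth_config(),
                       preprocess = preprocess_config(),
                       gan = NULL,
                       augment_total = NULL,
                       activation = c("t2f", "relu", "leaky_relu"),
                       train = train_config(optimizer = "adam",
                                            learning_rate = 0.001,
                                            max_epochs = 40),
                       input_mode = c("concat", "multichannel"),
                       seed = 1,
                       out_dir = "fatiguenet-run") {
  if (is.character(scenario) && !scenario[1] %in% names(SCENARIOS))
    stop_arg("unknown scenario '%s'; valid scenarios: %s", scenario[1],
             paste(names(SCENARIOS), collapse = ", "))
  scenario <- match.arg(scenario)
  activation <- match.arg(activation)
  input_mode <- match.arg(input_mode)
  structure(list(scenario = scenario, levels = SCENARIOS[[scenario]],
                 n_classes = length(SCENARIOS[[scenario]]),
                 n_per_class = n_per_class, synth = synth,
                 preprocess = preprocess, gan = gan,
                 augment_total = augment_total, activation = activation,
                 train = train, input_mode = input_mode,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p) else list(stages = list())
}

update_manifest <- function(out_dir, stage, files, config, seed) {
  man <- read_manifest(out_dir)
  man$package <- "fatiguenet"
  man$version <- as.character(utils::packageVersion("fatiguenet"))
  man$config_hash <- config_hash(config)
  man$global_seed <- config$seed
  man$stages[[stage]] <- list(
    files = as.list(files),
    md5 = as.list(unname(tools::md5sum(files))),
    stage_seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(man, manifest_path(out_dir), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(man)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop_arg("missing artifact '%s'; run the '%s' stage first", path, producer)
  path
}

arch_from_config <- function(config, n_samples_per_channel, n_channels) {
  if (config$input_mode == "concat")
    arch_spec(n_classes = config$n_classes,
              input_len = n_samples_per_channel * n_channels,
              in_channels = 1L, activation = config$activation)
  else
    arch_spec(n_classes = config$n_classes,
              input_len = n_samples_per_channel,
              in_channels = n_channels, activation = config$activation)
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments (`scenario`,
#' `n_per_class`, `activation`, `input_mode`, `seed`, `out_dir`); a `train`
#' section may set `optimizer`, `learning_rate`, `batch_size`,
#' `max_epochs`, `lr_decay`; a `gan` section (with at least `epochs`)
#' enables augmentation together with `augment_total`. Unknown keys are an
#' error naming the valid ones.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_arg("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  valid <- c("scenario", "n_per_class", "activation", "input_mode", "seed",
             "out_dir", "augment_total", "train", "gan")
  unknown <- setdiff(names(y), valid)
  if (length(unknown))
    stop_arg("unknown config keys: %s (valid keys: %s)",
             paste(unknown, collapse = ", "), paste(valid, collapse = ", "))
  tr_args <- y$train %||% list()
  valid_tr <- names(formals(train_config))
  bad_tr <- setdiff(names(tr_args), valid_tr)
  if (length(bad_tr))
    stop_arg("unknown train keys: %s (valid keys: %s)",
             paste(bad_tr, collapse = ", "), paste(valid_tr, collapse = ", "))
  args <- y[setdiff(names(y), c("train", "gan"))]
  args$train <- do.call(train_config, tr_args)
  if (!is.null(y$gan)) args$gan <- do.call(gan_spec, y$gan)
  do.call(run_config, args)
}

#' Run a pipeline stage
#'
#' Stages: `synth` (generate recordings), `preprocess` (epoch dataset),
#' `train-gan` (per-class GANs), `augment`, `train` (classifier),
#' `evaluate` (metrics report on the held-out test split), `robustness`
#' (SNR curve), or `all` (chain in pipeline order, skipping GAN stages when
#' `config$gan` is `NULL`). Every stage writes its artifacts under
#' `config$out_dir` and records them with md5 hashes, its derived seed and
#' the config hash in `manifest.json`.
#'
#' @param command stage name.
#' @param config a [run_config()].
#' @return invisibly, the list of files the stage wrote.
#' @export
run_command <- function(command = c("all", "synth", "preprocess", "train-gan",
                                    "augment", "train", "evaluate",
                                    "robustness"),
                        config = run_config()) {
  command <- match.arg(command)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (command == "all") {
    stages <- c("synth", "preprocess",
                if (!is.null(config$gan)) c("train-gan", "augment"),
                "train", "evaluate", "robustness")
    out <- lapply(stages, run_command, config = config)
    return(invisible(unlist(out)))
  }
  od <- config$out_dir
  paths <- list(recordings = file.path(od, "recordings.rds"),
                epochs = file.path(od, "epochs.rds"),
                gans = file.path(od, "gans.rds"),
                augmented = file.path(od, "epochs_augmented.rds"),
                model = file.path(od, "model.rds"),
                split = file.path(od, "split.rds"),
                metrics = file.path(od, "metrics.json"),
                history = file.path(od, "history.csv"),
                robustness = file.path(od, "robustness.csv"))
  seed <- derive_seed(config$seed, command)
  files <- switch(command,
    synth = {
      rset <- generate_dataset(config$n_per_class, config$levels,
                               epoch_len_s = config$preprocess$window_s,
                               config = config$synth, seed = seed)
      saveRDS(rset, paths$recordings, version = 2)
      paths$recordings
    },
    preprocess = {
      rset <- readRDS(require_artifact(paths$recordings, "synth"))
      ds <- preprocess_dataset(rset, config$preprocess)
      write_epoch_dataset(ds, paths$epochs)
      c(paths$epochs, paste0(paths$epochs, ".json"))
    },
    `train-gan` = {
      ds <- read_epoch_dataset(require_artifact(paths$epochs, "preprocess"))
      spec <- config$gan %||% stop_arg("config$gan is NULL; set a gan_spec to train GANs")
      gans <- list()
      for (lv in sort(unique(ds$labels))) {
        sub <- ds_subset(ds, ds$labels == lv)
        gans[[as.character(lv)]] <-
          train_gan(sub, spec, seed = derive_seed(seed, paste0("gan", lv)))
      }
      saveRDS(gans, paths$gans, version = 2)
      curves <- do.call(rbind, lapply(names(gans), function(lv)
        cbind(class = lv, gans[[lv]]$history)))
      utils::write.csv(curves, file.path(od, "gan_history.csv"),
                       row.names = FALSE)
      c(paths$gans, file.path(od, "gan_history.csv"))
    },
    augment = {
      ds <- read_epoch_dataset(require_artifact(paths$epochs, "preprocess"))
      gans <- readRDS(require_artifact(paths$gans, "train-gan"))
      total <- config$augment_total %||% stop_arg("config$augment_total is NULL")
      aug <- augment_dataset(ds, gans, total, seed = seed)
      write_epoch_dataset(aug, paths$augmented)
      c(paths$augmented, paste0(paths$augmented, ".json"))
    },
    train = {
      src <- if (file.exists(paths$augmented)) paths$augmented else
        require_artifact(paths$epochs, "preprocess")
      ds <- read_epoch_dataset(src)
      sp <- split_dataset(ds, seed = derive_seed(seed, "split"))
      arch <- arch_from_config(config, dim(ds$x)[3L], dim(ds$x)[2L])
      fit <- train_classifier(sp$train, sp$validation, arch, config$train,
                              seed = seed)
      saveRDS(sp, paths$split, version = 2)
      save_cnn(fit, paths$model)
      utils::write.csv(fit$history, paths$history, row.names = FALSE)
      c(paths$model, paths$split, paths$history)
    },
    evaluate = {
      fit <- readRDS(require_artifact(paths$model, "train"))
      sp <- readRDS(require_artifact(paths$split, "train"))
      pred <- predict(fit, sp$test)
      rep <- confusion_and_metrics(sp$test$labels, pred,
                                   classes = fit$class_levels)
      write_metrics_json(rep, paths$metrics)
      paths$metrics
    },
    robustness = {
      fit <- readRDS(require_artifact(paths$model, "train"))
      sp <- readRDS(require_artifact(paths$split, "train"))
      curve <- robustness_curve(list(model = fit), sp$test,
                                snr_grid = c(Inf, 20, 10, 0, -10),
                                replicates = 3, seed = seed)
      utils::write.csv(as.data.frame(curve), paths$robustness,
                       row.names = FALSE)
      paths$robustness
    })
  update_manifest(od, command, files, config, seed)
  invisible(files)
}
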