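# End-to-end pipeline: phantoms (or supplied images) -> preprocessing ->
# training -> prediction -> evaluation -> overlays, written into a
# self-describing run directory.

#' Pipeline configuration
#'
#' Bundles the stage configurations and a single global seed that is
#' propagated to every stochastic stage. Values may be supplied as the
#' component objects or plain lists of their fields (as from a YAML file).
#'
#' @param phantom A [phantom_spec()] (or list of fields).
#' @param n_phantoms Number of phantoms to generate.
#' @param expand_to Dataset size after augmentation (`NULL` = no expansion).
#' @param split_ratios Train/val/test weights.
#' @param clahe A [clahe_params()]; `NULL` disables CLAHE preprocessing.
#' @param net A [net_config()].
#' @param train A [train_config()].
#' @param overlay An [overlay_params()].
#' @param rng_seed Global seed; stage seeds are derived from it.
#' @param out_dir Parent directory for run directories.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(phantom = phantom_spec(image_size = 64L,
                                                   noise_sigma = 6),
                            n_phantoms = 12L, expand_to = NULL,
                            split_ratios = c(0.7, 0.2, 0.1),
                            clahe = clahe_params(tile_grid = c(4L, 4L)),
                            net = net_config(base_channels = 8L),
                            train = train_config(epochs = 5L,
                                                 learning_rate = 1e-3),
                            overlay = overlay_params(),
                            rng_seed = 1L, out_dir = tempdir()) {
  as_cfg <- function(x, ctor, class) {
    if (is.null(x) || inherits(x, class)) x else do.call(ctor, x)
  }
  phantom <- as_cfg(phantom, phantom_spec, "phantom_spec")
  clahe <- as_cfg(clahe, clahe_params, "clahe_params")
  net <- as_cfg(net, net_config, "net_config")
  train <- as_cfg(train, train_config, "train_config")
  overlay <- as_cfg(overlay, overlay_params, "overlay_params")
  if (length(split_ratios) != 3L || any(split_ratios < 0) ||
      sum(split_ratios) <= 0)
    stop("split_ratios must be 3 nonnegative weights with positive sum")
  if (n_phantoms < 3L) stop("need at least 3 phantoms to split")
  structure(list(phantom = phantom, n_phantoms = as.integer(n_phantoms),
                 expand_to = expand_to, split_ratios = split_ratios,
                 clahe = clahe, net = net, train = train, overlay = overlay,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full segmentation pipeline
#'
#' Executes all stages in order: phantom generation (seeded), optional
#' dataset expansion by augmentation, CLAHE preprocessing, 7:2:1-style
#' splitting, training with per-epoch validation, test-set evaluation, and
#' overlay rendering for the test images. All artifacts (images, masks,
#' checkpoints, per-epoch log, metrics report, overlays, the resolved
#' configuration and a stage log) are written into a timestamped run
#' directory. Re-running with the same configuration and seed reproduces all
#' artifacts.
#'
#' @param cfg A [pipeline_config()].
#' @param run_name Directory name; default derived from the timestamp.
#' @return The run directory path, invisibly; the evaluation report and fit
#'   are attached as attributes `"report"` and `"fit"`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), run_name = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(run_name))
    run_name <- format(Sys.time(), "run_%Y%m%d_%H%M%S")
  run_dir <- file.path(cfg$out_dir, run_name)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "pipeline.log")
  say <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                           append = TRUE)
  stage <- function(name, expr) {
    say("[%s] start", name)
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("[%s] done", name)
    res
  }

  writeLines(yaml::as.yaml(list(
    rng_seed = cfg$rng_seed, n_phantoms = cfg$n_phantoms,
    expand_to = cfg$expand_to, split_ratios = cfg$split_ratios,
    phantom = unclass(cfg$phantom), clahe = unclass(cfg$clahe),
    net = unclass(cfg$net), train = unclass(cfg$train),
    overlay = unclass(cfg$overlay),
    spineseg_version = as.character(utils::packageVersion("spineseg")))),
    file.path(run_dir, "config.yaml"))

  pairs <- stage("phantoms", {
    sp <- cfg$phantom
    lapply(seq_len(cfg$n_phantoms), function(i) {
      sp$rng_seed <- cfg$rng_seed + i - 1L
      generate_phantom(sp)[c("image", "mask")]
    })
  })
  if (!is.null(cfg$expand_to))
    pairs <- stage("expand", expand_dataset(pairs, cfg$expand_to,
                                            rng_seed = cfg$rng_seed + 1000L))
  if (!is.null(cfg$clahe))
    pairs <- stage("preprocess", lapply(pairs, function(p) {
      p$image <- clahe(p$image, cfg$clahe)
      p
    }))
  split <- stage("split", split_dataset(pairs, cfg$split_ratios,
                                        rng_seed = cfg$rng_seed + 2000L))
  say("split sizes: train=%d val=%d test=%d", length(split$train),
      length(split$val), length(split$test))

  tr_cfg <- cfg$train
  tr_cfg$rng_seed <- cfg$rng_seed + 3000L
  tr_cfg$checkpoint_dir <- file.path(run_dir, "checkpoints")
  fit <- stage("train", {
    model <- with_rng(cfg$rng_seed + 4000L, build_model(cfg$net))
    train_model(model, split$train, split$val, tr_cfg)
  })
  utils::write.csv(fit$log, file.path(run_dir, "train_log.csv"),
                   row.names = FALSE)
  for (ep in seq_len(nrow(fit$log)))
    say("epoch %d: train loss %.4f, val loss %.4f, val Dice %.2f%%",
        ep, fit$log$train_loss[ep], fit$log$val_loss[ep], fit$log$val_dice[ep])

  ev <- stage("evaluate", evaluate_model(fit, split$test))
  utils::write.csv(ev$report, file.path(run_dir, "metrics.csv"),
                   row.names = FALSE)

  stage("overlay", {
    ov_dir <- file.path(run_dir, "overlays")
    dir.create(ov_dir, showWarnings = FALSE)
    for (i in seq_along(split$test)) {
      img <- split$test[[i]]$image
      pm <- ev$predictions[[i]]
      write_rgb_png(overlay_mask(img, pm, cfg$overlay),
                    file.path(ov_dir, sprintf("fill_%03d.png", i)))
      write_rgb_png(overlay_edges(img, pm, cfg$overlay),
                    file.path(ov_dir, sprintf("edges_%03d.png", i)))
      write_mask_png(pm, file.path(ov_dir, sprintf("pred_%03d.png", i)))
    }
  })
  say("run complete")
  invisible(structure(run_dir, report = ev$report, fit = fit))
}
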