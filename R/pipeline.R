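# Reproducible end-to-end commands: generate a synthetic dataset, train,
# evaluate, and analyze topology — each driven by a YAML/JSON run config
# with explicit seeds.  The exported cmd_* functions are what the bundled
# command-line script (inst/cli/ionseg.R) dispatches to.

#' Read and validate a run configuration
#'
#' @param path YAML (or JSON) file, or a named list.
#' @return a validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  assert_that(is.list(cfg), "config must be a named list or a YAML file")
  defaults <- list(
    seed = 1L,
    data = list(dir = "dataset", n = 10L, synthetic = syn_default_config()),
    preprocess = "er_default",
    model = list(base_channels = 8L, depth = 4L, input_size = c(64L, 64L),
                 mre = TRUE),
    training = list(steps = 100L, lr = 1e-3, base = "soft_iou",
                    checkpoint = "checkpoint.json", log = "train_log.csv",
                    val_fraction = 0.2),
    evaluation = list(threshold = 0.5, betti_mode = "organelle",
                      out_csv = "metrics.csv", out_json = "metrics.json"),
    analysis = list(min_area = 30, out_csv = "network_properties.csv"))
  cfg <- utils::modifyList(defaults, cfg)
  assert_that(cfg$data$n >= 1, "data$n must be >= 1")
  assert_that(cfg$evaluation$betti_mode %in% c("organelle", "vessel"),
              "evaluation$betti_mode must be 'organelle' or 'vessel'")
  cfg
}

resolve_preprocess <- function(p) {
  if (is.character(p)) {
    if (p == "none") preprocess_spec(character(0)) else preprocess_preset(p)
  } else do.call(preprocess_spec, p)
}

#' Generate and write a synthetic dataset from a run config
#'
#' @param config run config (list or path); uses the `data` block.
#' @return invisibly, the manifest data frame.
#' @export
cmd_generate <- function(config) {
  cfg <- read_run_config(config)
  syn <- utils::modifyList(syn_default_config(), cfg$data$synthetic)
  syn$height <- cfg$model$input_size[1]
  syn$width <- cfg$model$input_size[2]
  samples <- generate_dataset(cfg$data$n, syn, rng_seed = cfg$seed)
  write_dataset(samples, cfg$data$dir)
}

#' Train a model from a run config
#'
#' Splits the dataset into train/validation, trains, writes the per-step
#' loss log as CSV and keeps the checkpoint with the best validation IoU.
#'
#' @param config run config (list or path).
#' @return invisibly, a list with the trained model, the log and the best
#'   validation IoU.
#' @export
cmd_train <- function(config) {
  cfg <- read_run_config(config)
  assert_that(file.exists(file.path(cfg$data$dir, "manifest.csv")),
              paste("dataset not found in", cfg$data$dir, "- run cmd_generate first"))
  samples <- read_dataset(cfg$data$dir)
  n_val <- max(1L, floor(cfg$training$val_fraction * length(samples)))
  if (length(samples) == 1L) n_val <- 0L
  val <- if (n_val > 0) tail(samples, n_val) else list()
  tr <- if (n_val > 0) head(samples, length(samples) - n_val) else samples
  mc <- mre_config(base_channels = cfg$model$base_channels,
                   depth = cfg$model$depth,
                   input_size = cfg$model$input_size, mre = cfg$model$mre)
  model <- build_mre_unet(mc, rng_seed = cfg$seed)
  spec <- resolve_preprocess(cfg$preprocess)
  # train in segments, checkpointing on validation IoU
  seg_len <- max(10L, ceiling(cfg$training$steps / 5))
  done <- 0L
  best_iou <- -Inf
  logs <- list()
  res <- NULL
  while (done < cfg$training$steps) {
    k <- min(seg_len, cfg$training$steps - done)
    res <- train_model(model, tr, steps = k, lr = cfg$training$lr,
                       rng_seed = cfg$seed, base = cfg$training$base,
                       preprocess = spec, resume = res)
    logs[[length(logs) + 1]] <- res$log
    done <- done + k
    iou <- if (length(val) > 0) {
      mean(vapply(val, function(s) {
        pm <- segment(model, s$image, threshold = cfg$evaluation$threshold,
                      rng_seed = cfg$seed, preprocess = spec)
        confusion_scores(pm, s$mask)$iou
      }, 0))
    } else -done  # no validation set: keep the last checkpoint
    if (iou > best_iou || length(val) == 0) {
      best_iou <- iou
      save_checkpoint(model, cfg$training$checkpoint)
    }
  }
  log <- do.call(rbind, logs)
  write.csv(log, cfg$training$log, row.names = FALSE)
  invisible(list(model = model, log = log, best_val_iou = best_iou))
}

#' Evaluate a trained checkpoint on a dataset
#'
#' Writes a per-image metric CSV and a summary JSON.  With
#' `n_inference_seeds > 1` the inference is repeated under different crop
#' seeds and a per-seed IoU table with a standard-deviation column is
#' attached (seed-robustness study).
#'
#' @param config run config (list or path).
#' @param checkpoint checkpoint path; defaults to the config's.
#' @param n_inference_seeds number of inference crop seeds.
#' @return invisibly, a list with `per_image`, `summary` and (optionally)
#'   `seed_study`.
#' @export
cmd_evaluate <- function(config, checkpoint = NULL, n_inference_seeds = 1L) {
  cfg <- read_run_config(config)
  ckpt <- checkpoint %||% cfg$training$checkpoint
  assert_that(file.exists(ckpt), paste("checkpoint not found:", ckpt))
  model <- load_checkpoint(ckpt)
  samples <- read_dataset(cfg$data$dir)
  spec <- resolve_preprocess(cfg$preprocess)
  mode <- cfg$evaluation$betti_mode
  rows <- do.call(rbind, lapply(samples, function(s) {
    out <- predict(model, apply_pipeline(s$image, spec),
                   rng_seed = cfg$seed, preprocess = "none")
    pm <- segmentation_map(out)
    cbind(id = s$id,
          evaluate_masks(pm, as_mask(pm >= cfg$evaluation$threshold),
                         s$mask, dataset_mode = mode))
  }))
  summary <- summarize_metrics(rows)
  write.csv(rows, cfg$evaluation$out_csv, row.names = FALSE)
  jsonlite::write_json(as.list(summary), cfg$evaluation$out_json,
                       auto_unbox = TRUE, digits = NA)
  seed_study <- NULL
  if (n_inference_seeds > 1) {
    seeds <- vapply(seq_len(n_inference_seeds), function(i)
      derive_seed(cfg$seed, 1000L + i), 0L)
    ious <- vapply(seeds, function(sd) {
      mean(vapply(samples, function(s) {
        pm <- segment(model, s$image, threshold = cfg$evaluation$threshold,
                      rng_seed = sd, preprocess = spec)
        confusion_scores(pm, s$mask)$iou
      }, 0))
    }, 0)
    seed_study <- data.frame(seed = seeds, mean_iou = ious)
    attr(seed_study, "sd") <- sd(ious)
  }
  invisible(list(per_image = rows, summary = summary,
                 seed_study = seed_study))
}

#' Topology analysis of a folder of masks
#'
#' Computes [network_summary()] for every mask PNG in a directory; when a
#' paired ground-truth directory is given, adds per-property two-sample
#' t-tests between predicted and ground-truth property distributions.
#'
#' @param config run config (list or path).
#' @param mask_dir directory of prediction mask PNGs.
#' @param gt_dir optional directory of matching ground-truth mask PNGs.
#' @return invisibly, a list with `properties` (one row per image) and
#'   `tests` (NULL without `gt_dir`).
#' @export
cmd_analyze <- function(config, mask_dir, gt_dir = NULL) {
  cfg <- read_run_config(config)
  files <- sort(list.files(mask_dir, pattern = "\\.png$", full.names = TRUE))
  assert_that(length(files) > 0, paste("no mask PNGs found in", mask_dir))
  masks <- lapply(files, function(f) as_mask(png::readPNG(f)))
  props <- do.call(rbind, lapply(masks, network_summary,
                                 min_area = cfg$analysis$min_area))
  props <- cbind(id = basename(files), props)
  write.csv(props, cfg$analysis$out_csv, row.names = FALSE)
  tests <- NULL
  if (!is.null(gt_dir)) {
    gfiles <- sort(list.files(gt_dir, pattern = "\\.png$", full.names = TRUE))
    assert_that(length(gfiles) == length(files),
                "mask and ground-truth directories differ in size")
    gmasks <- lapply(gfiles, function(f) as_mask(png::readPNG(f)))
    tests <- compare_network_properties(masks, gmasks,
                                        min_area = cfg$analysis$min_area)$tests
  }
  invisible(list(properties = props, tests = tests))
}
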