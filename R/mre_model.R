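# The multi-resolution encoder (MRE) on a U-Net backbone.
#
# Five inputs I_j (j = 0..4) are random crops of the image at sizes
# (H/2^j, W/2^j); per-stage low-level extractors (two 3x3 convolutions)
# produce LF_j with base_channels * 2^j channels; these are concatenated
# with the encoder's down-sampled features DF_j into mixture feature maps
# MF_j, which serve as the skip connections.  A 1x1 convolution on each MF_j
# yields five multi-resolution predictions; each of the four decoder
# up-sampling stages additionally feeds an independent transposed-convolution
# head producing a full-size prediction — nine prediction maps in total.

#' Model configuration
#'
#' @param base_channels channels of the first stage; stage `j` uses
#'   `base_channels * 2^j` (the canonical 64 gives 64-128-256-512-1024).
#' @param depth number of down-sampling stages (4 gives the five-resolution,
#'   nine-head configuration).
#' @param input_size `(H, W)`; both must be divisible by `2^depth`.
#' @param backbone backbone family; only `"u-net"` is implemented.
#' @param mre attach the multi-resolution encoder branch (`FALSE` gives the
#'   plain U-Net baseline with a single prediction head).
#' @return an object of class `mre_config`.
#' @export
mre_config <- function(base_channels = 64L, depth = 4L,
                       input_size = c(256L, 256L), backbone = "u-net",
                       mre = TRUE) {
  assert_that(backbone == "u-net", "only the u-net backbone is implemented")
  assert_that(depth >= 1 && depth <= 6, "depth must be in 1..6")
  assert_that(all(input_size %% 2^depth == 0),
              sprintf("input size must be divisible by %d; pad the image first",
                      2^depth))
  structure(list(base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 input_size = as.integer(input_size), backbone = backbone,
                 mre = isTRUE(mre)),
            class = "mre_config")
}

#' Channels at a given stage
#'
#' @param config an [mre_config()].
#' @param j stage index in `0..depth`.
#' @return `base_channels * 2^j`.
#' @export
stage_channels <- function(config, j) {
  assert_that(j >= 0 && j <= config$depth,
              sprintf("stage j must be in 0..%d", config$depth))
  as.integer(config$base_channels * 2^as.integer(j))
}

# ---- multi-resolution crops ----------------------------------------------

#' Random multi-resolution crops of an image/label pair
#'
#' Stage `j` receives a crop of size `(H/2^j, W/2^j)`; stage 0 is the whole
#' image.  Crop offsets are uniform over all valid positions, drawn
#' independently per stage, and labels are cropped with identical
#' coordinates.  The same procedure is used during training and inference.
#'
#' @param image numeric matrix, dims divisible by `2^depth`.
#' @param label binary matrix of the same shape (may be `NULL`).
#' @param rng_seed integer seed; fixed seed gives identical crops.
#' @param depth number of halvings.
#' @return an object of class `multires_batch`: `images`, `labels`, `crops`
#'   (each crop a list with `stage`, `top`, `left`, `height`, `width`;
#'   offsets 0-based).
#' @export
make_multires_crops <- function(image, label = NULL, rng_seed = 1L,
                                depth = 4L) {
  H <- nrow(image); W <- ncol(image)
  assert_that(H %% 2^depth == 0 && W %% 2^depth == 0,
              sprintf("image dims must be divisible by %d; pad the image first",
                      2^depth))
  if (is.null(label)) label <- matrix(0L, H, W)
  assert_that(all(dim(label) == c(H, W)), "label shape differs from image")
  with_seed(rng_seed, {
    images <- vector("list", depth + 1)
    labels <- vector("list", depth + 1)
    crops <- vector("list", depth + 1)
    for (j in 0:depth) {
      hj <- H %/% 2^j; wj <- W %/% 2^j
      top <- if (j == 0) 0L else sample.int(H - hj + 1L, 1L) - 1L
      left <- if (j == 0) 0L else sample.int(W - wj + 1L, 1L) - 1L
      images[[j + 1]] <- image[top + seq_len(hj), left + seq_len(wj)]
      labels[[j + 1]] <- label[top + seq_len(hj), left + seq_len(wj)]
      crops[[j + 1]] <- list(stage = j, top = top, left = left,
                             height = hj, width = wj)
    }
    structure(list(images = images, labels = labels, crops = crops),
              class = "multires_batch")
  })
}

# ---- model construction ---------------------------------------------------

#' Build an MRE U-Net (or the plain U-Net baseline)
#'
#' @param config an [mre_config()].
#' @param rng_seed seed for the weight initialization (He-scaled normal).
#' @return an object of class `mre_unet` holding the configuration and a
#'   named list of parameter environments (weights are updated in place by
#'   the trainer).
#' @export
build_mre_unet <- function(config, rng_seed = 1L) {
  assert_that(inherits(config, "mre_config"), "config must be an mre_config")
  d <- config$depth
  ch <- function(j) stage_channels(config, j)
  params <- list()
  with_seed(rng_seed, {
    for (j in 0:d) {
      cin <- if (j == 0) 1L else ch(j - 1)
      params[[paste0("enc", j, "_1")]] <- param_conv(cin, ch(j), 3L)
      params[[paste0("enc", j, "_2")]] <- param_conv(ch(j), ch(j), 3L)
    }
    if (config$mre) {
      for (j in 0:d) {
        params[[paste0("lle", j, "_1")]] <- param_conv(1L, ch(j), 3L)
        params[[paste0("lle", j, "_2")]] <- param_conv(ch(j), ch(j), 3L)
      }
    }
    skip_mult <- if (config$mre) 2L else 1L
    for (j in (d - 1):0) {
      cin_up <- if (j == d - 1) skip_mult * ch(d) else ch(j + 1)
      params[[paste0("up", j)]] <- param_tconv(cin_up, ch(j), 2L)
      params[[paste0("dec", j, "_1")]] <-
        param_conv(ch(j) + skip_mult * ch(j), ch(j), 3L)
      params[[paste0("dec", j, "_2")]] <- param_conv(ch(j), ch(j), 3L)
    }
    if (config$mre) {
      for (j in 0:d)
        params[[paste0("head_ml", j)]] <- param_conv(2L * ch(j), 1L, 1L)
      for (k in 1:d)
        params[[paste0("head_up", k)]] <- param_tconv(ch(d - k), 1L,
                                                      2L^(d - k))
    } else {
      params[["head_final"]] <- param_conv(ch(0), 1L, 1L)
    }
  })
  structure(list(config = config, params = params), class = "mre_unet")
}

#' Number of trainable parameters
#'
#' @param model an `mre_unet`.
#' @return total parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, param_count, 0))
}

#' @export
print.mre_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s (%s): base %d, depth %d, input %dx%d, %d heads, %s parameters\n",
              if (cfg$mre) "MRE U-Net" else "U-Net", cfg$backbone,
              cfg$base_channels, cfg$depth, cfg$input_size[1],
              cfg$input_size[2],
              if (cfg$mre) 2L * cfg$depth + 1L else 1L,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

conv_block <- function(g, x, p1, p2) {
  ag_relu(g, ag_conv2d(g, ag_relu(g, ag_conv2d(g, x, p1)), p2))
}

# Forward pass on a multires_batch; returns the graph and the head nodes.
mre_forward <- function(model, batch, zero_mre = FALSE) {
  cfg <- model$config
  d <- cfg$depth
  P <- model$params
  g <- ag_graph()
  xs <- lapply(batch$images, function(im) ag_input(g, im))
  # encoder
  E <- vector("list", d + 1)
  cur <- xs[[1]]
  for (j in 0:d) {
    if (j > 0) cur <- ag_maxpool2(g, E[[j]])
    E[[j + 1]] <- conv_block(g, cur, P[[paste0("enc", j, "_1")]],
                             P[[paste0("enc", j, "_2")]])
  }
  # mixture feature maps
  MF <- vector("list", d + 1)
  if (cfg$mre) {
    for (j in 0:d) {
      LF <- conv_block(g, xs[[j + 1]], P[[paste0("lle", j, "_1")]],
                       P[[paste0("lle", j, "_2")]])
      if (zero_mre) LF <- ag_scale(g, LF, 0)
      MF[[j + 1]] <- ag_concat(g, LF, E[[j + 1]])
    }
  } else {
    MF <- E
  }
  # decoder
  D <- vector("list", d + 1)   # D[[j + 1]] at resolution H / 2^j
  D[[d + 1]] <- MF[[d + 1]]
  for (j in (d - 1):0) {
    U <- ag_relu(g, ag_tconv(g, D[[j + 2]], P[[paste0("up", j)]]))
    D[[j + 1]] <- conv_block(g, ag_concat(g, U, MF[[j + 1]]),
                             P[[paste0("dec", j, "_1")]],
                             P[[paste0("dec", j, "_2")]])
  }
  if (cfg$mre) {
    ml_nodes <- lapply(0:d, function(j)
      ag_sigmoid(g, ag_conv2d(g, MF[[j + 1]], P[[paste0("head_ml", j)]])))
    up_nodes <- lapply(1:d, function(k)
      ag_sigmoid(g, ag_tconv(g, D[[d - k + 1]], P[[paste0("head_up", k)]])))
    list(graph = g, ml_nodes = ml_nodes, up_nodes = up_nodes)
  } else {
    final <- ag_sigmoid(g, ag_conv2d(g, D[[1]], P[["head_final"]]))
    list(graph = g, ml_nodes = list(final), up_nodes = list())
  }
}

node_to_map <- function(node) node$value[, , 1]

#' Run inference: preprocessing, random crops, forward pass
#'
#' Deterministic given (weights, image, seed); the random cropping of the
#' auxiliary inputs is performed exactly as during training.
#'
#' @param object an `mre_unet`.
#' @param image numeric matrix with dims divisible by `2^depth`.
#' @param rng_seed crop seed (pinned default for reproducible inference).
#' @param preprocess a [preprocess_spec()], preset name, or `"none"`.
#' @param zero_mre internal wiring check: zero the low-level extractor
#'   features before mixing.
#' @param ... unused.
#' @return an object of class `model_outputs` with `multires_preds` (list of
#'   probability maps at sizes `H/2^j`, full resolution first) and
#'   `upsampled_preds` (full-size probability maps from the decoder heads,
#'   deepest stage first; the last one is the decoder's final readout).
#' @export
predict.mre_unet <- function(object, image, rng_seed = 42L,
                             preprocess = "none", zero_mre = FALSE, ...) {
  img <- apply_pipeline(image, if (is.character(preprocess) &&
                                     preprocess == "none")
    preprocess_spec(character(0)) else preprocess)
  batch <- make_multires_crops(img, NULL, rng_seed = rng_seed,
                               depth = object$config$depth)
  fw <- mre_forward(object, batch, zero_mre = zero_mre)
  structure(list(multires_preds = lapply(fw$ml_nodes, node_to_map),
                 upsampled_preds = lapply(fw$up_nodes, node_to_map),
                 crops = batch$crops),
            class = "model_outputs")
}

#' Segment an image with a trained model
#'
#' Thresholds the full-resolution probability map; ties (`p == threshold`)
#' are foreground.  By default the decoder's final full-size readout is
#' used; `head = "top_multires"` instead thresholds the full-resolution
#' mixture-feature-map head.
#'
#' @param model an `mre_unet`.
#' @param image numeric matrix.
#' @param threshold probability threshold in (0, 1).
#' @param rng_seed crop seed.
#' @param preprocess as in [predict.mre_unet()].
#' @param head `"decoder"` or `"top_multires"`.
#' @return a binary mask matrix.
#' @export
segment <- function(model, image, threshold = 0.5, rng_seed = 42L,
                    preprocess = "none",
                    head = c("decoder", "top_multires")) {
  head <- match.arg(head)
  assert_that(threshold > 0 && threshold < 1, "threshold must be in (0,1)")
  out <- predict(model, image, rng_seed = rng_seed, preprocess = preprocess)
  pm <- segmentation_map(out, head)
  as_mask(pm >= threshold)
}

segmentation_map <- function(outputs, head = "decoder") {
  if (head == "decoder" && length(outputs$upsampled_preds) > 0)
    outputs$upsampled_preds[[length(outputs$upsampled_preds)]]
  else outputs$multires_preds[[1]]
}

# ---- training -------------------------------------------------------------

#' Train a model on synthetic or loaded samples
#'
#' Adam optimization with one sample per step (cycled in order).  For MRE
#' models the hierarchical fusion loss over all heads is used; for the plain
#' U-Net the base loss on its single prediction.
#'
#' @param model an `mre_unet` (updated in place and returned).
#' @param samples list of samples, each with `image` and `mask`.
#' @param steps number of optimization steps.
#' @param lr Adam learning rate.
#' @param rng_seed seed controlling crop draws.
#' @param base base loss name (default `"soft_iou"`).
#' @param weights a [loss_weights()] for the fusion loss; defaults to
#'   [default_weights()].
#' @param preprocess preprocessing applied to every image before cropping.
#' @param loss_params extra base-loss parameters.
#' @param resume result of a previous [train_model()] call on the same
#'   model: training continues with its optimizer state and step counter,
#'   exactly as if the runs had been one.
#' @return a list with `model`, `log` (per-step loss report rows),
#'   `optimizer` and `steps_done`.
#' @export
train_model <- function(model, samples, steps = 100L, lr = 1e-3,
                        rng_seed = 1L, base = "soft_iou", weights = NULL,
                        preprocess = "none", loss_params = list(),
                        resume = NULL) {
  cfg <- model$config
  d <- cfg$depth
  if (is.null(weights)) weights <- default_weights(depth = d)
  spec <- if (is.character(preprocess) && preprocess == "none")
    preprocess_spec(character(0)) else preprocess
  imgs <- lapply(samples, function(s) apply_pipeline(s$image, spec))
  masks <- lapply(samples, function(s) as_mask(s$mask))
  opt <- if (!is.null(resume)) resume$optimizer
         else adam_new(model$params, lr = lr)
  step0 <- if (!is.null(resume)) resume$steps_done else 0L
  log_rows <- vector("list", steps)
  for (step in seq_len(steps)) {
    gstep <- step0 + step
    i <- (gstep - 1L) %% length(samples) + 1L
    batch <- make_multires_crops(imgs[[i]], masks[[i]],
                                 rng_seed = derive_seed(rng_seed, gstep),
                                 depth = d)
    fw <- mre_forward(model, batch)
    seeds <- list()
    if (cfg$mre) {
      up_terms <- numeric(d)
      ml_terms <- numeric(d + 1)
      for (k in seq_len(d)) {
        lg <- base_loss_grad(base, node_to_map(fw$up_nodes[[k]]), masks[[i]],
                             loss_params)
        up_terms[k] <- lg$value
        seeds[[length(seeds) + 1]] <- list(
          node = fw$up_nodes[[k]],
          grad = array(weights$alpha[k] * lg$grad,
                       dim = dim(fw$up_nodes[[k]]$value)))
      }
      for (j in 0:d) {
        lg <- base_loss_grad(base, node_to_map(fw$ml_nodes[[j + 1]]),
                             batch$labels[[j + 1]], loss_params)
        ml_terms[j + 1] <- lg$value
        seeds[[length(seeds) + 1]] <- list(
          node = fw$ml_nodes[[j + 1]],
          grad = array(weights$beta[j + 1] * lg$grad,
                       dim = dim(fw$ml_nodes[[j + 1]]$value)))
      }
      report <- structure(list(total = sum(weights$alpha * up_terms) +
                                 sum(weights$beta * ml_terms),
                               up = sum(weights$alpha * up_terms),
                               ml = sum(weights$beta * ml_terms),
                               up_terms = up_terms, ml_terms = ml_terms,
                               weights = weights, base = base),
                          class = "loss_report")
    } else {
      lg <- base_loss_grad(base, node_to_map(fw$ml_nodes[[1]]), masks[[i]],
                           loss_params)
      seeds[[1]] <- list(node = fw$ml_nodes[[1]],
                         grad = array(lg$grad,
                                      dim = dim(fw$ml_nodes[[1]]$value)))
      report <- structure(list(total = lg$value, up = 0, ml = lg$value,
                               up_terms = numeric(0), ml_terms = lg$value,
                               weights = weights, base = base),
                          class = "loss_report")
    }
    ag_backward(fw$graph, seeds)
    adam_step(opt, model$params)
    log_rows[[step]] <- loss_report_row(report, gstep)
  }
  list(model = model, log = do.call(rbind, log_rows), optimizer = opt,
       steps_done = step0 + steps)
}

# ---- checkpoints ----------------------------------------------------------

#' Save model weights and configuration
#'
#' Weights are written as a plain-text JSON checkpoint next to a readable
#' config sidecar.
#'
#' @param model an `mre_unet`.
#' @param path output file (`.json`).
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config = unclass(model$config),
              params = lapply(model$params, function(p)
                list(W = as.numeric(p$W), dimW = dim(p$W),
                     b = as.numeric(p$b), kind = p$kind,
                     k = p$k, stride = p$stride)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return an `mre_unet`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(mre_config, obj$config[c("base_channels", "depth",
                                          "input_size", "backbone", "mre")])
  params <- lapply(obj$params, function(p) {
    new_param(matrix(p$W, nrow = p$dimW[1]), p$b, p$kind,
              k = if (is.null(p$k) || all(is.na(p$k))) NULL else p$k,
              stride = if (is.null(p$stride) || all(is.na(p$stride))) NULL
                       else p$stride)
  })
  structure(list(config = cfg, params = params), class = "mre_unet")
}
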