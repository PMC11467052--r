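# Segmentation losses: the base family (BCE, weighted BCE, soft IoU, Dice,
# focal) and the hierarchical fusion loss that combines the nine prediction
# heads of the multi-resolution encoder.
#
# All base losses take probability maps; pixel sums (not means) are used
# inside the soft IoU ratio, exactly as the loss is defined, while the
# cross-entropy family is averaged per pixel.  Each loss also has an
# analytic gradient with respect to the probabilities, used by the trainer
# and validated against numerical differentiation in the test suite.

EPS_PROB <- 1e-7

#' Soft IoU loss
#'
#' `1 - sum(p * y) / (sum(p + y - p * y) + eta)`, summed over all pixels.
#' Zero for a perfect prediction (up to the smoothing term `eta`), one for a
#' total miss.
#'
#' @param pred probability map in `[0, 1]`.
#' @param target binary map of the same shape.
#' @param eta smoothing constant (> 0) guarding the empty-union case.
#' @return a scalar loss.
#' @export
soft_iou_loss <- function(pred, target, eta = 1e-6) {
  check_pred_target(pred, target)
  assert_that(eta > 0, "eta must be positive")
  inter <- sum(pred * target)
  union <- sum(pred + target - pred * target)
  1 - inter / (union + eta)
}

soft_iou_grad <- function(pred, target, eta = 1e-6) {
  inter <- sum(pred * target)
  union <- sum(pred + target - pred * target)
  den <- union + eta
  val <- 1 - inter / den
  grad <- -(target * den - inter * (1 - target)) / den^2
  list(value = val, grad = grad)
}

check_pred_target <- function(pred, target) {
  assert_that(all(dim(pred) == dim(target)) ||
                length(pred) == length(target),
              "pred and target shapes differ")
  invisible(NULL)
}

#' Base segmentation losses
#'
#' @param name one of `"bce"`, `"wbce"`, `"soft_iou"`, `"dice"`, `"focal"`.
#' @param pred probability map.
#' @param target binary map.
#' @param params optional parameters: `eta` (soft IoU / dice smoothing),
#'   `pos_weight` (WBCE foreground weight; defaults to the per-image
#'   background/foreground pixel ratio), `gamma` and `alpha` (focal loss,
#'   defaults 2 and 0.25; `alpha = NULL` disables class weighting).
#' @return a scalar loss.
#' @export
base_loss <- function(name, pred, target, params = list()) {
  base_loss_grad(name, pred, target, params)$value
}

base_loss_grad <- function(name, pred, target, params = list()) {
  check_pred_target(pred, target)
  n <- length(pred)
  p <- pmin(pmax(pred, EPS_PROB), 1 - EPS_PROB)
  y <- target
  switch(name,
    soft_iou = soft_iou_grad(pred, target,
                             eta = params$eta %||% 1e-6),
    bce = {
      val <- -mean(y * log(p) + (1 - y) * log(1 - p))
      grad <- (-y / p + (1 - y) / (1 - p)) / n
      list(value = val, grad = grad)
    },
    wbce = {
      w <- params$pos_weight %||% {
        fg <- sum(y)
        if (fg == 0) 1 else (n - fg) / fg
      }
      val <- -mean(w * y * log(p) + (1 - y) * log(1 - p))
      grad <- (-w * y / p + (1 - y) / (1 - p)) / n
      list(value = val, grad = grad)
    },
    dice = {
      s <- params$eta %||% 1e-6
      inter <- sum(p * y)
      tot <- sum(p) + sum(y)
      val <- 1 - (2 * inter + s) / (tot + s)
      grad <- -(2 * y * (tot + s) - (2 * inter + s)) / (tot + s)^2
      list(value = val, grad = grad)
    },
    focal = {
      gamma <- params$gamma %||% 2
      alpha <- if (!("alpha" %in% names(params))) 0.25 else params$alpha
      a1 <- if (is.null(alpha)) 1 else alpha
      a0 <- if (is.null(alpha)) 1 else 1 - alpha
      val <- mean(-a1 * y * (1 - p)^gamma * log(p) -
                    a0 * (1 - y) * p^gamma * log(1 - p))
      g1 <- -a1 * (-gamma * (1 - p)^pmax(gamma - 1, 0) * log(p) +
                     (1 - p)^gamma / p)
      g0 <- -a0 * (gamma * p^pmax(gamma - 1, 0) * log(1 - p) -
                     p^gamma / (1 - p))
      grad <- (y * g1 + (1 - y) * g0) / n
      list(value = val, grad = grad)
    },
    stop("unknown loss name: ", name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hierarchical fusion loss weights
#'
#' @param alpha weights of the up-sampled terms (one per decoder head).
#' @param beta weights of the multi-resolution terms (one per resolution
#'   stage, full resolution first).
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(alpha, beta) {
  assert_that(all(alpha >= 0) && all(beta >= 0),
              "loss weights must be non-negative")
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}

#' Default hierarchical fusion loss weights
#'
#' Half of the total weight (`beta[1] = 0.5`) is placed on the
#' full-resolution multi-resolution head so the model attends most to the
#' original resolution; the remaining eight heads share the rest equally
#' (`0.0625` each), so all nine weights sum to one.
#'
#' @param depth number of down-sampling stages (4 gives the nine-head
#'   configuration with weights 0.5 and 8 x 0.0625).
#' @return a [loss_weights()] object.
#' @export
default_weights <- function(depth = 4L) {
  k <- 2L * depth  # heads besides the full-resolution one
  w <- 0.5 / k
  loss_weights(alpha = rep(w, depth), beta = c(0.5, rep(w, depth)))
}

#' Hierarchical fusion loss over the nine model outputs
#'
#' Combines the up-sampled losses (full-size decoder-head predictions versus
#' the original label) and the multi-resolution losses (per-stage
#' mixture-feature-map predictions versus the correspondingly cropped
#' labels):
#' `L_hf = L_up + L_ml`, `L_up = sum_j alpha_j L_j_up`,
#' `L_ml = sum_j beta_j L_j_ml`.
#'
#' @param outputs a `model_outputs` object (or a list with `multires_preds`
#'   and `upsampled_preds`).
#' @param original_label full-size binary label.
#' @param batch the `multires_batch` whose cropped `labels` pair with the
#'   multi-resolution predictions.
#' @param weights a [loss_weights()]; defaults to [default_weights()].
#' @param base base loss name, `"soft_iou"` by default.
#' @param params extra parameters passed to [base_loss()].
#' @return an object of class `loss_report`: `total`, `up`, `ml`, and the
#'   per-term vectors `up_terms`, `ml_terms`.
#' @export
hierarchical_fusion_loss <- function(outputs, original_label, batch,
                                     weights = NULL, base = "soft_iou",
                                     params = list()) {
  n_up <- length(outputs$upsampled_preds)
  n_ml <- length(outputs$multires_preds)
  if (is.null(weights)) weights <- default_weights(depth = n_up)
  assert_that(length(weights$alpha) == n_up,
              sprintf("expected %d up-sampled heads, got %d alpha weights",
                      n_up, length(weights$alpha)))
  assert_that(length(weights$beta) == n_ml,
              sprintf("expected %d multi-resolution heads, got %d beta weights",
                      n_ml, length(weights$beta)))
  missing_ml <- which(vapply(outputs$multires_preds, is.null, TRUE))
  missing_up <- which(vapply(outputs$upsampled_preds, is.null, TRUE))
  assert_that(length(missing_ml) == 0 && length(missing_up) == 0,
              paste("missing prediction heads:",
                    paste(c(sprintf("ml[%d]", missing_ml),
                            sprintf("up[%d]", missing_up)), collapse = ", ")))
  up_terms <- vapply(seq_len(n_up), function(j) {
    base_loss(base, outputs$upsampled_preds[[j]], original_label, params)
  }, 0)
  ml_terms <- vapply(seq_len(n_ml), function(j) {
    base_loss(base, outputs$multires_preds[[j]], batch$labels[[j]], params)
  }, 0)
  up <- sum(weights$alpha * up_terms)
  ml <- sum(weights$beta * ml_terms)
  structure(list(total = up + ml, up = up, ml = ml,
                 up_terms = up_terms, ml_terms = ml_terms,
                 weights = weights, base = base),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("hierarchical fusion loss (%s): total %.6f = up %.6f + ml %.6f\n",
              x$base, x$total, x$up, x$ml))
  invisible(x)
}

loss_report_row <- function(report, step = NA_integer_) {
  row <- data.frame(step = step, total = report$total, up = report$up,
                    ml = report$ml)
  for (j in seq_along(report$up_terms))
    row[[paste0("L", j, "_up")]] <- report$up_terms[j]
  for (j in seq_along(report$ml_terms))
    row[[paste0("L", j - 1, "_ml")]] <- report$ml_terms[j]
  row
}
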