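# Evaluation metrics for curvilinear-network segmentation: volumetric
# (IoU, accuracy, AUC), topological (centerline Dice, Betti error) and
# distance (Hausdorff) scores.  IoU, ACC, AUC and clDice are reported as
# percentages; Betti error is a count and Hausdorff distance is in pixels.
#
# Connectivity convention (used consistently across the package):
# foreground 8-connected, background 4-connected.

#' Confusion-matrix scores: IoU and accuracy
#'
#' @param pred_mask,gt_mask binary matrices of equal shape.
#' @return list with `iou` and `acc`, both percentages.  When prediction and
#'   ground truth are both empty the IoU is 100 (empty-union convention).
#' @export
confusion_scores <- function(pred_mask, gt_mask) {
  assert_that(all(dim(pred_mask) == dim(gt_mask)), "mask shapes differ")
  p <- pred_mask != 0
  g <- gt_mask != 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  iou <- if (tp + fp + fn == 0) 100 else 100 * tp / (tp + fp + fn)
  acc <- 100 * (tp + tn) / length(p)
  list(iou = iou, acc = acc)
}

#' Pixel-wise area under the ROC curve
#'
#' Computed over all thresholds via the rank (Mann-Whitney) statistic, with
#' midranks for ties.
#'
#' @param prob_map numeric probability map.
#' @param gt_mask binary mask with at least one positive and one negative
#'   pixel.
#' @return AUC as a percentage.
#' @export
auc_score <- function(prob_map, gt_mask) {
  assert_that(all(dim(prob_map) == dim(gt_mask)), "shapes differ")
  y <- as.integer(gt_mask != 0)
  n1 <- sum(y); n0 <- length(y) - n1
  assert_that(n1 > 0 && n0 > 0,
              "AUC undefined: ground truth must contain both classes")
  r <- rank(as.numeric(prob_map))
  100 * (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Centerline Dice (clDice)
#'
#' With `S_P`, `S_G` the one-pixel skeletons of prediction and ground truth,
#' topology precision is `|S_P intersect G| / |S_P|`, topology sensitivity is
#' `|S_G intersect P| / |S_G|`, and clDice is their harmonic mean (x100).
#' Conventions: both skeletons empty gives 100, exactly one empty gives 0.
#'
#' @param pred_mask,gt_mask binary matrices of equal shape.
#' @return clDice as a percentage.
#' @export
cl_dice <- function(pred_mask, gt_mask) {
  assert_that(all(dim(pred_mask) == dim(gt_mask)), "mask shapes differ")
  p <- pred_mask != 0
  g <- gt_mask != 0
  sp <- skeletonize(p)
  sg <- skeletonize(g)
  nsp <- sum(sp); nsg <- sum(sg)
  if (nsp == 0 && nsg == 0) return(100)
  if (nsp == 0 || nsg == 0) return(0)
  tprec <- sum(sp & g) / nsp
  tsens <- sum(sg & p) / nsg
  if (tprec + tsens == 0) return(0)
  100 * 2 * tprec * tsens / (tprec + tsens)
}

#' Betti numbers of a binary mask
#'
#' `beta0` is the number of 8-connected foreground components; `beta1` is
#' the number of holes, i.e. the number of 4-connected background components
#' of the border-padded mask minus one (the unbounded background).
#'
#' @param mask binary matrix.
#' @return list with `beta0` and `beta1`.
#' @export
betti_numbers <- function(mask) {
  m <- mask != 0
  beta0 <- max(cpp_label_components(m, 8L))
  pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  beta1 <- max(cpp_label_components(!pad, 4L)) - 1L
  list(beta0 = beta0, beta1 = beta1)
}

#' Betti error between two masks
#'
#' @param pred_mask,gt_mask binary matrices of equal shape.
#' @param mode `"sum"` (|d beta0| + |d beta1|, organelle-network convention)
#'   or `"loops_only"` (|d beta1|, retinal-vessel convention).
#' @return a non-negative count.
#' @export
betti_error <- function(pred_mask, gt_mask, mode = c("sum", "loops_only")) {
  mode <- match.arg(mode)
  assert_that(all(dim(pred_mask) == dim(gt_mask)), "mask shapes differ")
  bp <- betti_numbers(pred_mask)
  bg <- betti_numbers(gt_mask)
  if (mode == "sum") abs(bp$beta0 - bg$beta0) + abs(bp$beta1 - bg$beta1)
  else abs(bp$beta1 - bg$beta1)
}

boundary_pixels <- function(mask) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  # foreground pixels with a 4-neighbour outside the mask
  inner <- pad[2:(H + 1), 2:(W + 1)] & pad[1:H, 2:(W + 1)] &
    pad[3:(H + 2), 2:(W + 1)] & pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which_pixels(m & !inner)
}

#' Hausdorff distance between mask boundaries
#'
#' The symmetric Hausdorff distance (Euclidean, in pixels) between the
#' boundary pixel sets of the two masks.  Both masks empty gives 0; exactly
#' one empty returns the image diagonal as a sentinel, with a warning.
#'
#' @param pred_mask,gt_mask binary matrices of equal shape.
#' @return distance in pixels.
#' @export
hausdorff <- function(pred_mask, gt_mask) {
  assert_that(all(dim(pred_mask) == dim(gt_mask)), "mask shapes differ")
  a <- boundary_pixels(pred_mask)
  b <- boundary_pixels(gt_mask)
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (nrow(a) == 0 || nrow(b) == 0) {
    warning("one mask is empty: returning the image diagonal as sentinel")
    return(sqrt(sum(dim(pred_mask)^2)))
  }
  max(cpp_hausdorff_directed(a * 1.0, b * 1.0),
      cpp_hausdorff_directed(b * 1.0, a * 1.0))
}

#' Full metric report for one prediction
#'
#' @param prob_map probability map (may be `NULL`; AUC is then `NA`).
#' @param pred_mask binary predicted mask.
#' @param gt_mask binary ground-truth mask.
#' @param dataset_mode `"organelle"` (Betti error on beta0 + beta1) or
#'   `"vessel"` (beta1 only).
#' @return a one-row data frame with `iou`, `acc`, `auc`, `cldice`,
#'   `betti_error`, `hausdorff`.
#' @export
evaluate_masks <- function(prob_map, pred_mask, gt_mask,
                           dataset_mode = c("organelle", "vessel")) {
  dataset_mode <- match.arg(dataset_mode)
  cs <- confusion_scores(pred_mask, gt_mask)
  auc <- if (is.null(prob_map)) NA_real_ else auc_score(prob_map, gt_mask)
  data.frame(
    iou = cs$iou, acc = cs$acc, auc = auc,
    cldice = cl_dice(pred_mask, gt_mask),
    betti_error = betti_error(pred_mask, gt_mask,
                              mode = if (dataset_mode == "organelle") "sum"
                                     else "loops_only"),
    hausdorff = hausdorff(pred_mask, gt_mask))
}

#' Average per-image metric reports over a dataset
#'
#' @param reports data frame of per-image rows from [evaluate_masks()].
#' @return a one-row data frame of unweighted column means.
#' @export
summarize_metrics <- function(reports) {
  as.data.frame(lapply(reports[, c("iou", "acc", "auc", "cldice",
                                   "betti_error", "hausdorff")],
                       mean))
}
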