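# Independent brute-force oracles used to validate the package's metric and
# topology implementations.  These deliberately use different algorithms
# (pixel adjacency graphs, exhaustive threshold sweeps, all-pairs distances)
# from the implementations they check.

# connected components by building the explicit pixel adjacency graph
# (sparse: adjacency found by coordinate-key matching per offset)
oracle_components <- function(mask, connectivity = 8) {
  px <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0) return(0L)
  span <- max(dim(mask)) + 2
  key <- px[, 1] * span + px[, 2]
  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  edges <- matrix(integer(0), ncol = 2)
  for (o in offs) {
    nb <- match((px[, 1] + o[1]) * span + (px[, 2] + o[2]), key)
    sel <- which(!is.na(nb))
    if (length(sel) > 0) edges <- rbind(edges, cbind(sel, nb[sel]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

# Betti numbers from flood-fill component counts (fg 8-connected,
# bg 4-connected on the border-padded complement)
oracle_betti <- function(mask) {
  m <- mask != 0
  pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  list(beta0 = oracle_components(m, 8),
       beta1 = oracle_components(!pad, 4) - 1L)
}

# pixel-based Euler characteristic via Gray's 2x2 quad counts
# (8-connectivity variant); checked against disk/annulus in the tests
oracle_euler <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask))
  pad <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  H <- nrow(pad); W <- ncol(pad)
  a <- pad[1:(H - 1), 1:(W - 1)]
  b <- pad[1:(H - 1), 2:W]
  cc <- pad[2:H, 1:(W - 1)]
  d <- pad[2:H, 2:W]
  s <- a + b + cc + d
  q1 <- sum(s == 1)
  q3 <- sum(s == 3)
  qd <- sum(s == 2 & ((a == 1 & d == 1) | (b == 1 & cc == 1)))
  (q1 - q3 - 2 * qd) / 4
}

# exhaustive-threshold ROC area
oracle_auc <- function(prob, gt) {
  y <- as.integer(gt != 0)
  ths <- sort(unique(as.numeric(prob)), decreasing = TRUE)
  tpr <- c(0); fpr <- c(0)
  for (t in ths) {
    p <- as.numeric(prob) >= t
    tpr <- c(tpr, sum(p & y == 1) / sum(y == 1))
    fpr <- c(fpr, sum(p & y == 0) / sum(y == 0))
  }
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  100 * sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# all-pairs max-min Hausdorff distance on boundary pixel sets
oracle_hausdorff <- function(a_mask, b_mask) {
  bdry <- function(m) {
    m <- m != 0
    H <- nrow(m); W <- ncol(m)
    pad <- matrix(FALSE, H + 2, W + 2)
    pad[2:(H + 1), 2:(W + 1)] <- m
    inner <- pad[2:(H + 1), 2:(W + 1)] & pad[1:H, 2:(W + 1)] &
      pad[3:(H + 2), 2:(W + 1)] & pad[2:(H + 1), 1:W] &
      pad[2:(H + 1), 3:(W + 2)]
    which(m & !inner, arr.ind = TRUE)
  }
  A <- bdry(a_mask); B <- bdry(b_mask)
  D <- sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

# term-by-term scripted evaluation of the fusion loss
oracle_soft_iou <- function(pred, target, eta = 1e-6) {
  1 - sum(pred * target) / (sum(pred) + sum(target) - sum(pred * target) + eta)
}

oracle_lhf <- function(outputs, label, batch, alpha, beta, eta = 1e-6) {
  lup <- 0
  for (j in seq_along(outputs$upsampled_preds))
    lup <- lup + alpha[j] * oracle_soft_iou(outputs$upsampled_preds[[j]],
                                            label, eta)
  lml <- 0
  for (j in seq_along(outputs$multires_preds))
    lml <- lml + beta[j] * oracle_soft_iou(outputs$multires_preds[[j]],
                                           batch$labels[[j]], eta)
  list(total = lup + lml, up = lup, ml = lml)
}

# ---- deterministic pixel fixtures ----------------------------------------

# filled disk of radius r centred in an n x n image
fixture_disk <- function(n = 15, r = 5) {
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) as.integer((i - ctr)^2 + (j - ctr)^2 <= r^2))
}

# square annulus (one loop)
fixture_annulus <- function(n = 15, margin = 3) {
  m <- matrix(0L, n, n)
  m[margin:(n - margin + 1), margin:(n - margin + 1)] <- 1L
  m[(margin + 1):(n - margin), (margin + 1):(n - margin)] <- 0L
  m
}

# Y-shaped one-pixel skeleton: three arms of the given length from a centre
fixture_y_skeleton <- function(arm = 10) {
  n <- 2 * arm + 5
  m <- matrix(0L, n, n)
  c0 <- arm + 3
  m[cbind(c0 - 0:arm, c0)] <- 1L              # north arm
  m[cbind(c0 + 0:arm, c0 - 0:arm)] <- 1L      # south-west arm
  m[cbind(c0 + 0:arm, c0 + 0:arm)] <- 1L      # south-east arm
  m
}

# straight horizontal one-pixel line
fixture_line <- function(len = 12, n = 20) {
  m <- matrix(0L, n, n)
  m[10, 4:(4 + len - 1)] <- 1L
  m
}

random_mask <- function(n = 12, p = 0.4) {
  matrix(rbinom(n * n, 1, p), n, n)
}
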