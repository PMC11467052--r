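# Minimal reverse-mode autodiff over (H, W, C) arrays, sufficient for the
# encoder-decoder networks in this package.  A graph is a tape of nodes in
# creation order; creation order is a valid topological order, so the
# backward sweep just walks the tape in reverse.

ag_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$tape <- list()
  g$n <- 0L
  g
}

ag_push <- function(g, value, back = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$back <- back
  g$n <- g$n + 1L
  g$tape[[g$n]] <- node
  node
}

ag_accum <- function(node, grad) {
  node$grad <- if (is.null(node$grad)) grad else node$grad + grad
  invisible(NULL)
}

ag_input <- function(g, value) {
  if (is.matrix(value)) dim(value) <- c(dim(value), 1L)
  ag_push(g, value)
}

#' @noRd
ag_backward <- function(g, seeds) {
  for (s in seeds) ag_accum(s$node, s$grad)
  for (i in rev(seq_len(g$n))) {
    node <- g$tape[[i]]
    if (!is.null(node$grad) && !is.null(node$back)) node$back(node$grad)
  }
  invisible(NULL)
}

# --- parameters ------------------------------------------------------------

# A parameter holds a weight matrix W, bias b, their gradient accumulators
# and Adam state.  Weight layout matches the C++ kernels.
new_param <- function(W, b, kind, k = NULL, stride = NULL) {
  p <- new.env(parent = emptyenv())
  p$W <- W
  p$b <- b
  p$gW <- W * 0
  p$gb <- b * 0
  p$kind <- kind
  p$k <- k
  p$stride <- stride
  p
}

param_conv <- function(cin, cout, k) {
  sd <- sqrt(2 / (k * k * cin))
  new_param(matrix(rnorm(cout * k * k * cin, sd = sd), nrow = cout),
            numeric(cout), "conv", k = k)
}

param_tconv <- function(cin, cout, stride) {
  sd <- sqrt(2 / cin)
  new_param(matrix(rnorm(cin * stride * stride * cout, sd = sd), nrow = cin),
            numeric(cout), "tconv", stride = stride)
}

param_count <- function(p) length(p$W) + length(p$b)

zero_grads <- function(params) {
  for (p in params) {
    p$gW <- p$W * 0
    p$gb <- p$b * 0
  }
  invisible(NULL)
}

# --- ops -------------------------------------------------------------------

ag_conv2d <- function(g, x, p, pad = (p$k - 1L) %/% 2L) {
  y <- cpp_conv2d_forward(x$value, p$W, p$b, p$k, pad)
  ag_push(g, y, back = function(gy) {
    r <- cpp_conv2d_backward(x$value, p$W, gy, p$k, pad)
    p$gW <- p$gW + r$gW
    p$gb <- p$gb + r$gb
    ag_accum(x, r$gx)
  })
}

ag_tconv <- function(g, x, p) {
  y <- cpp_tconv_forward(x$value, p$W, p$b, p$stride)
  ag_push(g, y, back = function(gy) {
    r <- cpp_tconv_backward(x$value, p$W, gy, p$stride)
    p$gW <- p$gW + r$gW
    p$gb <- p$gb + r$gb
    ag_accum(x, r$gx)
  })
}

ag_relu <- function(g, x) {
  mask <- x$value > 0
  ag_push(g, x$value * mask, back = function(gy) ag_accum(x, gy * mask))
}

ag_sigmoid <- function(g, x) {
  y <- 1 / (1 + exp(-x$value))
  ag_push(g, y, back = function(gy) ag_accum(x, gy * y * (1 - y)))
}

ag_maxpool2 <- function(g, x) {
  H <- dim(x$value)[1]
  W <- dim(x$value)[2]
  r <- cpp_maxpool2_forward(x$value)
  ag_push(g, r$y, back = function(gy) {
    ag_accum(x, cpp_maxpool2_backward(r$idx, gy, H, W))
  })
}

ag_concat <- function(g, a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  stopifnot(da[1:2] == db[1:2])
  y <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3] + db[3]))
  ag_push(g, y, back = function(gy) {
    ag_accum(a, gy[, , seq_len(da[3]), drop = FALSE])
    ag_accum(b, gy[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

ag_scale <- function(g, x, s) {
  ag_push(g, x$value * s, back = function(gy) ag_accum(x, gy * s))
}

# --- Adam ------------------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr
  st$beta1 <- beta1
  st$beta2 <- beta2
  st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  st$v <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  st
}

adam_step <- function(st, params) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    for (fld in c("W", "b")) {
      gfld <- paste0("g", fld)
      grad <- p[[gfld]]
      st$m[[i]][[fld]] <- st$beta1 * st$m[[i]][[fld]] + (1 - st$beta1) * grad
      st$v[[i]][[fld]] <- st$beta2 * st$v[[i]][[fld]] + (1 - st$beta2) * grad^2
      mhat <- st$m[[i]][[fld]] / bc1
      vhat <- st$v[[i]][[fld]] / bc2
      p[[fld]] <- p[[fld]] - st$lr * mhat / (sqrt(vhat) + st$eps)
    }
  }
  zero_grads(params)
  invisible(NULL)
}
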