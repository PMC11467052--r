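# Preprocessing methods for high-bit-depth fluorescence micrographs:
# contrast-limited adaptive histogram equalization (CLAHE), standardization,
# edge enhancement, and intensity inversion, composable into ordered
# pipelines.  CLAHE alone is the default for ER-like data; CLAHE followed by
# standardization for thicker mitochondrial networks.

#' Preprocessing pipeline specification
#'
#' @param steps character vector, an ordered subset of
#'   `c("clahe", "standardize", "edge_enhance", "invert")` (no duplicates).
#' @param clahe_clip CLAHE clip limit (multiples of the uniform bin height).
#' @param clahe_tiles CLAHE tile grid, length-2 integer vector.
#' @param edge_kernel edge-enhancement kernel, `"laplacian"` or `"sobel"`.
#' @return an object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(steps = character(0), clahe_clip = 2,
                            clahe_tiles = c(8L, 8L),
                            edge_kernel = "laplacian") {
  allowed <- c("clahe", "standardize", "edge_enhance", "invert")
  assert_that(all(steps %in% allowed),
              paste("steps must be drawn from:", paste(allowed, collapse = ", ")))
  assert_that(!anyDuplicated(steps), "steps must not contain duplicates")
  structure(list(steps = steps, clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 edge_kernel = edge_kernel),
            class = "preprocess_spec")
}

#' Named preprocessing presets
#'
#' `er_default` applies CLAHE only; `mito_default` applies CLAHE followed by
#' standardization (mitochondrial tubules are thicker and benefit from
#' foreground rescaling); `none` is the identity.
#'
#' @param name one of `"er_default"`, `"mito_default"`, `"none"`.
#' @return a [preprocess_spec()].
#' @export
preprocess_preset <- function(name = c("er_default", "mito_default", "none")) {
  name <- match.arg(name)
  switch(name,
         er_default = preprocess_spec("clahe"),
         mito_default = preprocess_spec(c("clahe", "standardize")),
         none = preprocess_spec(character(0)))
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is min-max rescaled to `[0, 1]`, equalized tile-wise with
#' clipped histograms, and returned in `[0, 1]`.  A constant image is
#' returned as all zeros (no contrast to equalize).
#'
#' @param image numeric matrix, finite-valued.
#' @param clip clip limit.
#' @param tiles tile grid (nx, ny).
#' @return numeric matrix in `[0, 1]`.
#' @export
clahe <- function(image, clip = 2, tiles = c(8L, 8L)) {
  assert_that(all(is.finite(image)), "image must be finite-valued")
  rng <- range(image)
  if (diff(rng) == 0) return(image * 0)
  x <- (image - rng[1]) / diff(rng)
  # EBImage works column-major on (x, y); transpose so tiles follow (nx, ny)
  out <- EBImage::clahe(t(x), nx = tiles[1], ny = tiles[2], limit = clip)
  t(as.matrix(out))
}

#' Standardize an image to zero mean and unit variance
#'
#' @param image numeric matrix.
#' @return numeric matrix with mean 0 and sd 1; a constant image returns all
#'   zeros with a warning.
#' @export
standardize <- function(image) {
  s <- stats::sd(image)
  if (!is.finite(s) || s == 0) {
    warning("constant image: standardization returns zeros")
    return(image * 0)
  }
  (image - mean(image)) / s
}

#' Edge enhancement by Laplacian or gradient-magnitude sharpening
#'
#' Adds the (negated) Laplacian response, or the Sobel gradient magnitude, to
#' the min-max-rescaled image and clips to `[0, 1]`.
#'
#' @param image numeric matrix.
#' @param kernel `"laplacian"` or `"sobel"`.
#' @param amount response gain added to the image.
#' @return numeric matrix in `[0, 1]`.
#' @export
edge_enhance <- function(image, kernel = "laplacian", amount = 1) {
  assert_that(kernel %in% c("laplacian", "sobel"),
              "unknown edge kernel; use 'laplacian' or 'sobel'")
  rng <- range(image)
  x <- if (diff(rng) == 0) image * 0 else (image - rng[1]) / diff(rng)
  if (kernel == "laplacian") {
    k <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
    resp <- conv2_same(x, k)
  } else {
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    ky <- t(kx)
    resp <- sqrt(conv2_same(x, kx)^2 + conv2_same(x, ky)^2)
  }
  pmin(pmax(x + amount * resp, 0), 1)
}

# 2-D correlation with zero padding, via the conv kernel used by the network
conv2_same <- function(x, k) {
  arr <- array(x, dim = c(dim(x), 1L))
  Wm <- matrix(as.numeric(t(k)), nrow = 1)  # row-major (a, b) layout
  out <- cpp_conv2d_forward(arr, Wm, 0, nrow(k), (nrow(k) - 1L) %/% 2L)
  out[, , 1]
}

#' Intensity inversion
#'
#' Returns `max(image) + min(image) - image`, an involution that swaps the
#' roles of bright and dark structures.
#'
#' @param image numeric matrix.
#' @return numeric matrix on the same scale.
#' @export
invert <- function(image) {
  max(image) + min(image) - image
}

#' Apply a preprocessing pipeline
#'
#' @param image numeric matrix.
#' @param spec a [preprocess_spec()] or preset name accepted by
#'   [preprocess_preset()].
#' @return the processed image; an empty step list is the identity.
#' @export
apply_pipeline <- function(image, spec = preprocess_preset("er_default")) {
  if (is.character(spec)) spec <- preprocess_preset(spec)
  assert_that(inherits(spec, "preprocess_spec"),
              "spec must be a preprocess_spec or a preset name")
  out <- image
  for (s in spec$steps) {
    out <- switch(s,
                  clahe = clahe(out, spec$clahe_clip, spec$clahe_tiles),
                  standardize = standardize(out),
                  edge_enhance = edge_enhance(out, spec$edge_kernel),
                  invert = invert(out))
  }
  out
}
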