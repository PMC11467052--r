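# Multi-resolution crops, architecture contracts, and inference behaviour.
# Training behaviour is exercised at scale in test-acceptance.R; here a tiny
# configuration checks the mechanics.

tiny_cfg <- function(mre = TRUE) {
  mre_config(base_channels = 2L, depth = 2L, input_size = c(16L, 16L),
             mre = mre)
}

test_that("stage channels double per stage from the base width", {
  cfg <- mre_config()              # canonical base 64
  expect_equal(vapply(0:4, function(j) stage_channels(cfg, j), 0L),
               c(64L, 128L, 256L, 512L, 1024L))
  cfg8 <- mre_config(base_channels = 8)
  expect_equal(stage_channels(cfg8, 2), 32L)
  expect_error(stage_channels(cfg, 5), "stage j")
})

test_that("multi-resolution crops halve per stage and stage 0 is the image", {
  img <- matrix(runif(256 * 256), 256, 256)
  b <- make_multires_crops(img, rng_seed = 1)
  expect_equal(vapply(b$images, nrow, 0L), c(256L, 128L, 64L, 32L, 16L))
  expect_identical(b$images[[1]], img)
  expect_equal(b$crops[[1]]$top, 0L)

  lab <- matrix(rbinom(256 * 256, 1, 0.5), 256, 256)
  bl <- make_multires_crops(img, lab, rng_seed = 2)
  for (j in 1:5) {
    cs <- bl$crops[[j]]
    expect_identical(bl$labels[[j]],
                     lab[cs$top + seq_len(cs$height),
                         cs$left + seq_len(cs$width)])
    expect_lte(cs$top + cs$height, 256)
    expect_lte(cs$left + cs$width, 256)
  }
  expect_error(make_multires_crops(matrix(0, 100, 100)), "pad")
})

test_that("crop draws are seed-deterministic and vary across seeds", {
  img <- matrix(runif(32 * 32), 32, 32)
  a <- make_multires_crops(img, rng_seed = 7)
  b <- make_multires_crops(img, rng_seed = 7)
  expect_identical(a, b)
  offsets <- vapply(1:20, function(s) {
    cr <- make_multires_crops(img, rng_seed = s)$crops[[3]]
    cr$top * 100 + cr$left
  }, 0)
  expect_gt(length(unique(offsets)), 5)
})

test_that("the MRE forward pass emits the full prediction pyramid", {
  model <- build_mre_unet(mre_config(4L, 4L, c(64L, 64L)), rng_seed = 1)
  img <- matrix(runif(64 * 64), 64, 64)
  out <- predict(model, img, rng_seed = 3)
  expect_length(out$multires_preds, 5)
  expect_length(out$upsampled_preds, 4)
  expect_equal(vapply(out$multires_preds, nrow, 0L),
               c(64L, 32L, 16L, 8L, 4L))
  expect_true(all(vapply(out$upsampled_preds, nrow, 0L) == 64L))
  all_maps <- c(out$multires_preds, out$upsampled_preds)
  expect_true(all(vapply(all_maps, function(m) all(m >= 0 & m <= 1), TRUE)))

  out2 <- predict(model, img, rng_seed = 3)
  expect_identical(out, out2)
  out3 <- predict(model, img, rng_seed = 4)
  expect_false(identical(out$multires_preds[[3]], out3$multires_preds[[3]]))
})

test_that("zeroing the low-level extractor features leaves the wiring intact", {
  model <- build_mre_unet(tiny_cfg(), rng_seed = 2)
  img <- matrix(runif(256), 16, 16)
  full <- predict(model, img, rng_seed = 1)
  gated <- predict(model, img, rng_seed = 1, zero_mre = TRUE)
  expect_length(gated$multires_preds, 3)
  expect_false(identical(full$multires_preds[[1]], gated$multires_preds[[1]]))
})

test_that("the parameter count matches the architecture arithmetic", {
  base <- 4L; depth <- 4L
  cfg <- mre_config(base, depth, c(64L, 64L))
  model <- build_mre_unet(cfg, rng_seed = 1)
  conv_n <- function(cin, cout, k) cout * k^2 * cin + cout
  ch <- function(j) base * 2^j
  expected <- 0
  for (j in 0:depth) {   # encoder
    cin <- if (j == 0) 1 else ch(j - 1)
    expected <- expected + conv_n(cin, ch(j), 3) + conv_n(ch(j), ch(j), 3)
  }
  for (j in 0:depth)     # low-level extractors
    expected <- expected + conv_n(1, ch(j), 3) + conv_n(ch(j), ch(j), 3)
  for (j in (depth - 1):0) {  # decoder: up-conv + two 3x3 on concat
    cin_up <- if (j == depth - 1) 2 * ch(depth) else ch(j + 1)
    expected <- expected + (cin_up * 4 * ch(j) + ch(j)) +
      conv_n(3 * ch(j), ch(j), 3) + conv_n(ch(j), ch(j), 3)
  }
  for (j in 0:depth)     # multi-resolution heads
    expected <- expected + conv_n(2 * ch(j), 1, 1)
  for (k in 1:depth) {   # up-sampled heads (stride-s transposed conv)
    s <- 2^(depth - k)
    expected <- expected + ch(depth - k) * s^2 + 1
  }
  expect_equal(n_parameters(model), expected)

  # the plain backbone differs by the extractors, the heads, and the wider
  # mixture-fed decoder inputs
  plain <- build_mre_unet(mre_config(base, depth, c(64L, 64L), mre = FALSE),
                          rng_seed = 1)
  expect_lt(n_parameters(plain), n_parameters(model))
})

test_that("segmentation thresholds the full-resolution decoder readout", {
  model <- build_mre_unet(tiny_cfg(), rng_seed = 3)
  img <- matrix(runif(256), 16, 16)
  out <- predict(model, img, rng_seed = 5)
  sm <- ionseg:::segmentation_map(out)
  expect_identical(sm, out$upsampled_preds[[2]])
  mask <- segment(model, img, threshold = 0.5, rng_seed = 5)
  expect_identical(mask, ionseg:::as_mask(sm >= 0.5))  # ties are foreground
  expect_true(all(mask %in% c(0L, 1L)))
  expect_error(segment(model, img, threshold = 1.2), "threshold")

  top <- segment(model, img, rng_seed = 5, head = "top_multires")
  expect_identical(top, ionseg:::as_mask(out$multires_preds[[1]] >= 0.5))
})

test_that("a few optimization steps run, log all per-head terms, and are reproducible", {
  mask <- matrix(0L, 16, 16); mask[6:8, 3:14] <- 1L
  d <- list(image = mask * 40 + 10 +
              matrix(withr::with_seed(1, rnorm(256)), 16, 16), mask = mask)
  model <- build_mre_unet(tiny_cfg(), rng_seed = 4)
  res <- train_model(model, list(d), steps = 3, lr = 1e-3, rng_seed = 9)
  expect_equal(nrow(res$log), 3)
  expect_true(all(c("total", "up", "ml", "L1_up", "L2_up",
                    "L0_ml", "L1_ml", "L2_ml") %in% names(res$log)))
  expect_equal(res$log$total, res$log$up + res$log$ml, tolerance = 1e-12)

  model2 <- build_mre_unet(tiny_cfg(), rng_seed = 4)
  res2 <- train_model(model2, list(d), steps = 3, lr = 1e-3, rng_seed = 9)
  expect_equal(res$log$total, res2$log$total, tolerance = 1e-12)
})

test_that("checkpoints round-trip weights and predictions through JSON", {
  model <- build_mre_unet(tiny_cfg(), rng_seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  img <- matrix(runif(256), 16, 16)
  expect_equal(predict(back, img, rng_seed = 2),
               predict(model, img, rng_seed = 2), tolerance = 1e-12)
})
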