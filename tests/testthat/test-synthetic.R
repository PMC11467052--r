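# The synthetic generator must deliver masks whose topology is exactly the
# recorded truth, since every downstream stage is validated against it.

manual_geometry <- function(pts, edge_idx, h = 64, w = 64) {
  edges <- lapply(edge_idx, function(e)
    list(from = e[1], to = e[2], path = pts[e, , drop = FALSE],
         length = sqrt(sum((pts[e[1], ] - pts[e[2], ])^2))))
  structure(list(node_coords = pts, edges = edges, loop_faces = list(),
                 component_count = 1L, graph_component_count = 1L,
                 sheet_regions = list(), height = h, width = w),
            class = "network_geometry")
}

test_that("planar face tracing finds the single bounded face of a 4-cycle", {
  pts <- rbind(c(10, 10), c(50, 10), c(50, 50), c(10, 50))
  geom <- manual_geometry(pts, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  faces <- ionseg:::trace_faces(pts, geom$edges)
  bounded <- Filter(function(f) f$signed_area > 0.5, faces)
  expect_length(bounded, 1)
  expect_equal(bounded[[1]]$signed_area, 40 * 40)
})

test_that("spanning-tree-only geometries have no loops and loop count equals cycle rank", {
  tree <- generate_geometry(96, 96, n_seeds = 12, loop_fraction = 0,
                            rng_seed = 11)
  expect_length(tree$loop_faces, 0)

  for (s in c(5, 21)) {
    g <- generate_geometry(160, 160, n_seeds = 30, loop_fraction = 0.3,
                           rng_seed = s)
    el <- do.call(rbind, lapply(g$edges, function(e) c(e$from, e$to)))
    ig <- igraph::graph_from_edgelist(el, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, nrow(g$node_coords) -
                                         igraph::vcount(ig)))
    cycle_rank <- igraph::ecount(ig) - igraph::vcount(ig) +
      igraph::components(ig)$no
    expect_equal(length(g$loop_faces), cycle_rank)
  }
})

test_that("degenerate geometry arguments are rejected", {
  expect_error(generate_geometry(16, 64, n_seeds = 5), "at least 32")
  expect_error(generate_geometry(64, 64, n_seeds = 1), "at least 2")
})

test_that("rasterization draws inclusive Bresenham strokes", {
  pts <- rbind(c(5, 10), c(25, 10))
  geom <- manual_geometry(pts, list(c(1, 2)), h = 32, w = 32)
  m <- rasterize_mask(geom, tubule_width = 1)
  # endpoints-inclusive: a horizontal segment of length 20 covers 21 pixels
  expect_equal(sum(m), 21)
  expect_true(all(m[10, 5:25] == 1))

  empty <- manual_geometry(pts[0, , drop = FALSE], list(), 32, 32)
  expect_equal(sum(rasterize_mask(empty, 1)), 0)

  expect_error(rasterize_mask(geom, tubule_width = 64), "exceeds")
})

test_that("a rasterized 4-cycle is one component with one hole", {
  pts <- rbind(c(12, 12), c(44, 12), c(44, 44), c(12, 44))
  geom <- manual_geometry(pts, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
                          h = 56, w = 56)
  m <- rasterize_mask(geom, tubule_width = 3)
  ob <- oracle_betti(m)
  expect_equal(ob$beta0, 1)
  expect_equal(ob$beta1, 1)
  b <- betti_numbers(m)
  expect_equal(b$beta0, ob$beta0)
  expect_equal(b$beta1, ob$beta1)
})

test_that("noise-free blur-free rendering is an affine transform of the mask", {
  m <- fixture_annulus(20, 4)
  img <- simulate_microscopy(m, psf_sigma = 0, peak_snr = Inf,
                             background_level = 10)
  vals <- sort(unique(as.numeric(img)))
  expect_length(vals, 2)
  expect_equal(as_thresholded <- (img > mean(vals)) * 1L, m * 1L,
               ignore_attr = TRUE)
  # any threshold strictly between background and signal recovers the mask
  img2 <- simulate_microscopy(m, psf_sigma = 0, peak_snr = 8,
                              background_level = 20, noise = FALSE)
  mid <- mean(range(img2))
  expect_equal(matrix(as.integer(img2 > mid), nrow(m)), m)
})

test_that("an empty mask renders as pure background with the stated mean", {
  m <- matrix(0L, 48, 48)
  img <- simulate_microscopy(m, psf_sigma = 1, peak_snr = 8,
                             background_level = 20, rng_seed = 5,
                             read_noise_sd = 2)
  se <- sqrt((20 + 4) / length(img))
  expect_lt(abs(mean(img) - 20), 3 * se + 0.05)  # small truncation bias at 0
  expect_true(all(img >= 0))
})

test_that("the microscopy renderer is deterministic in its seed", {
  m <- fixture_disk(24, 6)
  a <- simulate_microscopy(m, rng_seed = 9)
  b <- simulate_microscopy(m, rng_seed = 9)
  cc <- simulate_microscopy(m, rng_seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, cc))
})

test_that("generated datasets are reproducible and self-consistent", {
  cfg <- list(height = 96, width = 96, n_seeds = 14, loop_fraction = 0.3)
  d1 <- generate_dataset(5, cfg, rng_seed = 42)
  d2 <- generate_dataset(5, cfg, rng_seed = 42)
  expect_identical(d1, d2)
  expect_length(d1, 5)
  expect_length(unique(vapply(d1, `[[`, 0L, "seed")), 5)

  for (s in d1) {
    ob <- oracle_betti(s$mask)
    expect_equal(s$truth$beta0, ob$beta0)
    expect_equal(s$truth$beta1, ob$beta1)
    # Euler characteristic consistency (pixel-based oracle)
    expect_equal(s$truth$beta0 - s$truth$beta1, oracle_euler(s$mask))
    # arc-length truth against per-segment recomputation
    len <- sum(vapply(s$geometry$edges, function(e) {
      sum(sqrt(rowSums((e$path[-1, , drop = FALSE] -
                          e$path[-nrow(e$path), , drop = FALSE])^2)))
    }, 0))
    expect_lt(abs(len - s$truth$total_edge_length) /
                s$truth$total_edge_length, 0.01)
  }
})

test_that("sheet blobs add isolated components to the truth", {
  d <- generate_dataset(2, list(height = 128, width = 128, n_seeds = 12,
                                loop_fraction = 0.2, n_sheets = 2),
                        rng_seed = 8)
  for (s in d) {
    expect_equal(s$truth$beta0, oracle_betti(s$mask)$beta0)
    expect_gte(s$truth$beta0, 2)
  }
})

test_that("skeleton graphs recover the true junction count on thin tubules", {
  # junction-clump merge radius set to ~2.5x the stroke width
  cfg <- list(height = 160, width = 160, n_seeds = 20, loop_fraction = 0.3,
              tubule_width = 3)
  for (s in generate_dataset(4, cfg, rng_seed = 77)) {
    gr <- build_graph(skeletonize(s$mask), merge_dist = 8)
    expect_lte(abs(nrow(gr$nodes) - s$truth$junction_count) /
                 s$truth$junction_count, 0.1)
  }
})

test_that("datasets round-trip through the on-disk format", {
  dir <- withr::local_tempdir()
  d <- generate_dataset(3, list(height = 64, width = 64, n_seeds = 8,
                                loop_fraction = 0.2), rng_seed = 3)
  write_dataset(d, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "_img\\.tif$"), 3)
  back <- read_dataset(dir)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, d[[i]]$mask)
    expect_equal(back[[i]]$truth$beta1, d[[i]]$truth$beta1)
    expect_lt(max(abs(back[[i]]$image - d[[i]]$image)), 1.01)  # 16-bit grid
  }
})
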