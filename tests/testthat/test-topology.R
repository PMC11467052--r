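# Skeletonization, graph construction and the junction/network properties,
# against hand-enumerated fixtures.

manual_skeleton_graph <- function(n, edge_spec, coords = NULL) {
  # edge_spec: list of c(from, to, length)
  nodes <- data.frame(id = seq_len(n),
                      y = if (is.null(coords)) rep(0, n) else coords[, 1],
                      x = if (is.null(coords)) seq_len(n) else coords[, 2],
                      kind = "branch")
  edges <- lapply(edge_spec, function(e)
    list(from = e[1], to = e[2], path = matrix(0, 0, 2), length = e[3]))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) {
    el <- do.call(rbind, lapply(edges, function(e) c(e$from, e$to)))
    g <- igraph::add_edges(g, t(el))
    igraph::E(g)$weight <- vapply(edges, `[[`, 0, "length")
  }
  structure(list(nodes = nodes, edges = edges, graph = g,
                 skeleton = matrix(0L, 4, 4)),
            class = "skeleton_graph")
}

test_that("small-blob removal keeps only components above the area threshold", {
  m <- matrix(0L, 30, 30)
  m[5:24, 10:14] <- 1L     # 100-px component
  m[28, 2:4] <- 1L         # 3-px blob
  expect_identical(remove_small_components(m, 0), m)
  cleaned <- remove_small_components(m, 10)
  expect_equal(sum(cleaned), 100)
  expect_equal(oracle_components(cleaned, 8), 1)
  expect_equal(max(ionseg:::cpp_label_components(cleaned == 1, 8L)),
               sum(table(ionseg:::cpp_label_components(m == 1, 8L)[m == 1]) >=
                     10))
})

test_that("skeletonization thins bars to centerlines and preserves topology", {
  bar <- matrix(0L, 12, 30); bar[5:7, 4:27] <- 1L
  sk <- skeletonize(bar)
  expect_true(all(sk <= bar))
  # a single one-pixel line of comparable length (thinning erodes the ends)
  expect_true(abs(sum(sk) - 24) <= 4)
  expect_equal(oracle_components(sk, 8), 1)
  expect_equal(max(table(which(sk, arr.ind = TRUE)[, "row"])), sum(sk))

  expect_equal(sum(skeletonize(matrix(0L, 8, 8))), 0)

  ann <- fixture_annulus(21, 4)
  bsk <- betti_numbers(skeletonize(ann))
  expect_equal(bsk$beta0, 1)
  expect_equal(bsk$beta1, 1)
})

test_that("graph construction resolves Y, line, and cycle skeletons exactly", {
  y <- fixture_y_skeleton(arm = 10)
  gy <- build_graph(y)
  expect_equal(nrow(gy$nodes), 4)
  expect_equal(sum(gy$nodes$kind == "terminal"), 3)
  expect_equal(sum(gy$nodes$kind == "branch"), 1)
  expect_length(gy$edges, 3)
  lens <- sort(vapply(gy$edges, `[[`, 0, "length"))
  expect_equal(lens, sort(c(10, 10 * sqrt(2), 10 * sqrt(2))),
               tolerance = 1e-9)

  line <- fixture_line(12)
  gl <- build_graph(line)
  expect_equal(nrow(gl$nodes), 2)
  expect_true(all(gl$nodes$kind == "terminal"))
  expect_length(gl$edges, 1)
  expect_equal(gl$edges[[1]]$length, 11)

  ring <- skeletonize(fixture_annulus(21, 4))
  gr <- build_graph(ring)
  expect_equal(nrow(gr$nodes), 1)           # anchor on the isolated cycle
  expect_length(gr$edges, 1)
  expect_equal(gr$edges[[1]]$from, gr$edges[[1]]$to)
})

test_that("every skeleton pixel is on an edge path or is a node pixel", {
  for (s in c(2, 9)) {
    d <- generate_dataset(1, list(height = 128, width = 128, n_seeds = 16,
                                  loop_fraction = 0.3), rng_seed = s)[[1]]
    sk <- skeletonize(d$mask)
    gr <- build_graph(sk, simplify = FALSE)
    cov <- matrix(0L, nrow(sk), ncol(sk))
    for (e in gr$edges) cov[e$path] <- 1L
    uncovered <- sum(sk & cov == 0)
    expect_lte(uncovered, 2)  # at most a couple of residue pixels
  }
})

test_that("junction properties match enumeration on star, triangle and path graphs", {
  star <- manual_skeleton_graph(5, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1),
                                        c(1, 5, 1)))
  ps <- junction_properties(star)
  expect_equal(ps$degree, c(4, 1, 1, 1, 1))
  expect_equal(ps$degree_centrality, c(4, 1, 1, 1, 1) / 5)
  expect_equal(ps$effective_size, c(4, 1, 1, 1, 1))
  expect_equal(ps$closeness_centrality, c(1, 1.75, 1.75, 1.75, 1.75))

  tri <- manual_skeleton_graph(3, list(c(1, 2, 1), c(2, 3, 1), c(3, 1, 1)))
  pt <- junction_properties(tri)
  expect_equal(pt$degree, rep(2, 3))
  expect_equal(pt$effective_size, rep(0, 3))
  expect_equal(pt$degree_centrality, rep(2 / 3, 3))
  # conventional normalizer divides by N - 1 instead
  expect_equal(junction_properties(tri, conventional_normalizer = TRUE)$
                 degree_centrality, rep(1, 3))

  path <- manual_skeleton_graph(3, list(c(1, 2, 1), c(2, 3, 1)))
  pp <- junction_properties(path)
  expect_equal(pp$closeness_centrality, c(1.5, 1, 1.5))

  single <- manual_skeleton_graph(1, list())
  expect_true(is.na(junction_properties(single)$closeness_centrality))
})

test_that("self-loops count twice in degree and the degree sum equals 2E", {
  g <- manual_skeleton_graph(2, list(c(1, 2, 5), c(1, 1, 12)))
  p <- junction_properties(g)
  expect_equal(p$degree, c(3, 1))
  expect_equal(sum(p$degree), 2 * length(g$edges))
})

test_that("mesh density compares enclosed loop area to the convex hull", {
  ann <- fixture_annulus(41, 5)            # single square loop
  g <- build_graph(skeletonize(ann))
  md <- mesh_density(g, ann)
  expect_gt(md, 0.8)
  expect_lte(md, 1)

  y <- fixture_y_skeleton(10)              # tree: no loops
  expect_equal(mesh_density(build_graph(y), y), 0)

  # two disjoint loops: enclosed areas add over the joint hull
  two <- matrix(0L, 30, 62)
  two[6:25, 6:25] <- fixture_annulus(20, 1)
  two[6:25, 37:56] <- fixture_annulus(20, 1)
  g2 <- build_graph(skeletonize(two))
  md2 <- mesh_density(g2, two)
  # pixel-fill oracle on the skeleton
  sk <- g2$skeleton
  pad <- matrix(0L, nrow(sk) + 2, ncol(sk) + 2)
  pad[2:(nrow(sk) + 1), 2:(ncol(sk) + 1)] <- sk
  lab <- ionseg:::cpp_label_components(pad == 0, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  enclosed <- sum(lab > 0 & !(lab %in% border))
  fg <- which(two != 0, arr.ind = TRUE)
  hull <- fg[chull(fg[, 2], fg[, 1]), ]
  hull_area <- abs(ionseg:::shoelace(cbind(hull[, 2], hull[, 1])))
  expect_equal(md2, enclosed / hull_area, tolerance = 1e-12)
})

test_that("junction density is junctions per arc length and rotation-stable", {
  line <- fixture_line(12)
  gl <- build_graph(line)
  expect_equal(junction_density(gl), 2 / 11)

  y <- fixture_y_skeleton(10)
  gy <- build_graph(y)
  expect_equal(junction_density(gy),
               4 / (10 + 2 * 10 * sqrt(2)), tolerance = 1e-9)

  d <- generate_dataset(1, list(height = 96, width = 96, n_seeds = 12,
                                loop_fraction = 0.3), rng_seed = 4)[[1]]
  jd <- junction_density(build_graph(skeletonize(d$mask)))
  rot <- t(d$mask)[ncol(d$mask):1, ]       # 90-degree rotation
  jd_rot <- junction_density(build_graph(skeletonize(rot)))
  expect_lt(abs(jd - jd_rot) / jd, 0.05)
})

test_that("network summaries average the per-junction properties", {
  y <- fixture_y_skeleton(10)
  s <- network_summary(y, min_area = 0)
  expect_equal(s$mean_degree, 1.5)         # (1 + 1 + 1 + 3) / 4
  expect_equal(s$n_junctions, 4)
  expect_equal(s$n_tubules, 3)

  expect_warning(empty <- network_summary(matrix(0L, 16, 16)), "empty")
  expect_true(is.na(empty$mean_degree))

  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(s, f, row.names = FALSE)
  expect_equal(read.csv(f)$mean_degree, 1.5)
})

test_that("the graph Euler relation holds on synthetic networks", {
  for (s in c(3, 12, 19)) {
    d <- generate_dataset(1, list(height = 128, width = 128, n_seeds = 16,
                                  loop_fraction = 0.35), rng_seed = s)[[1]]
    sk <- skeletonize(d$mask)
    gr <- build_graph(sk)
    loops <- length(gr$edges) - nrow(gr$nodes) +
      igraph::components(gr$graph)$no
    expect_equal(loops, betti_numbers(sk)$beta1)
    expect_equal(sum(igraph::degree(gr$graph, loops = TRUE)),
                 2 * length(gr$edges))
  }
})

test_that("the predicted-vs-truth property comparison harness runs end to end", {
  d <- generate_dataset(4, list(height = 96, width = 96, n_seeds = 12,
                                loop_fraction = 0.3), rng_seed = 31)
  masks <- lapply(d, `[[`, "mask")
  noisy <- lapply(masks, function(m) {
    m[1:3, 1:3] <- 1L  # small spurious blob, removed by cleaning
    m
  })
  cmp <- compare_network_properties(noisy, masks, min_area = 30)
  expect_equal(nrow(cmp$tests), 6)
  expect_true(all(c("property", "p_value") %in% names(cmp$tests)))
  expect_true(all(is.na(cmp$tests$p_value) |
                    (cmp$tests$p_value >= 0 & cmp$tests$p_value <= 1)))
})
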