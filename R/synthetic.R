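# Synthetic planar tubular-network generator.
#
# Networks are built from scattered seed points joined by a Euclidean minimum
# spanning tree plus a controlled fraction of extra non-crossing chords, so
# the ground-truth topology (components, loops, junctions, edge lengths, face
# areas) is known exactly.  Masks are rasterized from the geometry and images
# are rendered with a Gaussian PSF and Poisson-plus-Gaussian noise, emulating
# low-SNR fluorescence micrographs of tubular organelle networks.

# ---- small planar-geometry helpers ---------------------------------------

seg_cross <- function(p1, p2, p3, p4) {
  # proper crossing of open segments (shared endpoints do not count)
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

point_seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

seg_seg_dist <- function(p1, p2, p3, p4) {
  if (seg_cross(p1, p2, p3, p4)) return(0)
  min(point_seg_dist(p1, p3, p4), point_seg_dist(p2, p3, p4),
      point_seg_dist(p3, p1, p2), point_seg_dist(p4, p1, p2))
}

shoelace <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]) / 2
}

# ---- planar face enumeration ---------------------------------------------

# Classic rotation-system face tracing: at each arrival vertex, the walk
# turns to the next neighbour in rotation order.  Bounded faces are the
# traced cycles with positive shoelace area in (x, y) pixel coordinates with
# y increasing downwards; degenerate (tree) walks have area ~0.
trace_faces <- function(coords, edges) {
  n <- nrow(coords)
  if (length(edges) == 0 || n == 0) return(list())
  em <- do.call(rbind, lapply(edges, function(e) c(e$from, e$to)))
  nbrs <- vector("list", n)
  for (r in seq_len(nrow(em))) {
    nbrs[[em[r, 1]]] <- c(nbrs[[em[r, 1]]], em[r, 2])
    nbrs[[em[r, 2]]] <- c(nbrs[[em[r, 2]]], em[r, 1])
  }
  for (v in seq_len(n)) {
    if (length(nbrs[[v]]) == 0) next
    ang <- atan2(coords[nbrs[[v]], 2] - coords[v, 2],
                 coords[nbrs[[v]], 1] - coords[v, 1])
    nbrs[[v]] <- nbrs[[v]][order(ang)]
  }
  key <- function(u, v) u * (n + 1L) + v
  visited <- new.env(parent = emptyenv())
  faces <- list()
  for (r in seq_len(nrow(em))) {
    for (dir in 1:2) {
      u0 <- em[r, if (dir == 1) 1 else 2]
      v0 <- em[r, if (dir == 1) 2 else 1]
      if (!is.null(visited[[as.character(key(u0, v0))]])) next
      walk <- integer(0)
      u <- u0; v <- v0
      repeat {
        visited[[as.character(key(u, v))]] <- TRUE
        walk <- c(walk, v)
        nb <- nbrs[[v]]
        pos <- match(u, nb)
        w <- nb[if (pos == 1) length(nb) else pos - 1L]  # next in CW rotation
        u <- v; v <- w
        if (u == u0 && v == v0) break
      }
      area <- shoelace(coords[walk, , drop = FALSE])
      faces[[length(faces) + 1L]] <- list(vertices = walk, signed_area = area)
    }
  }
  faces
}

# ---- geometry generation --------------------------------------------------

#' Generate a random planar tubular-network geometry
#'
#' Scatters seed points with a minimum separation, joins them by a Euclidean
#' minimum spanning tree (per component), then adds extra non-crossing chords
#' to create enclosed loops (meshes).  Crossing candidates and candidates
#' passing too close to existing tubules are rejected, so the planar face
#' bookkeeping (loop count and areas) is exact.
#'
#' @param height,width image dimensions in pixels (each >= 32).
#' @param n_seeds number of scattered junction seed points (>= 2).
#' @param loop_fraction target number of extra loop-forming chords as a
#'   fraction of the spanning-tree edge count, in `[0, 1]`.
#' @param rng_seed integer seed; the geometry is a pure function of the
#'   arguments.
#' @param n_components number of disconnected network components.
#' @param n_sheets number of sheet-like elliptical blobs placed clear of the
#'   tubules (each adds one connected component).
#' @param min_separation minimum seed-point distance in px.
#' @param clearance minimum distance allowed between a new chord and any
#'   non-adjacent tubule, in px; keeps rasterized strokes from merging.
#' @param min_angle minimum angle (degrees) between edges sharing an
#'   endpoint; prevents sliver holes where overlapping strokes diverge.
#' @param margin border kept free of geometry, px.
#' @return an object of class `network_geometry`: a list with `node_coords`
#'   (n x 2 matrix of (x, y) pixel coordinates), `edges` (list of
#'   `list(from, to, path, length)`), `loop_faces` (list of
#'   `list(vertices, area)`), `component_count` (tubule-graph components plus
#'   sheets), and `sheet_regions` (list of polygon matrices).
#' @export
generate_geometry <- function(height, width, n_seeds = 25,
                              loop_fraction = 0.35, rng_seed = 1L,
                              n_components = 1L, n_sheets = 0L,
                              min_separation = 12, clearance = 7,
                              min_angle = 30, margin = 8) {
  assert_that(height >= 32 && width >= 32,
              "image dimensions must be at least 32 px")
  assert_that(n_seeds >= 2, "n_seeds must be at least 2")
  assert_that(loop_fraction >= 0 && loop_fraction <= 1,
              "loop_fraction must lie in [0, 1]")
  with_seed(rng_seed, {
    # scatter seeds with rejection sampling
    pts <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(pts) < n_seeds && tries < 2000L * n_seeds) {
      tries <- tries + 1L
      cand <- c(runif(1, margin, width - margin),
                runif(1, margin, height - margin))
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
          min_separation)
        pts <- rbind(pts, cand)
    }
    assert_that(nrow(pts) == n_seeds,
                "could not place the requested seeds; enlarge the image or reduce n_seeds/min_separation")
    grp <- if (n_components > 1)
      stats::kmeans(pts, centers = min(n_components, n_seeds - 1),
                    nstart = 5)$cluster
    else rep(1L, n_seeds)

    edges <- list()
    add_edge <- function(i, j) {
      len <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      edges[[length(edges) + 1L]] <<- list(
        from = i, to = j, path = pts[c(i, j), , drop = FALSE], length = len)
    }
    angle_at <- function(v, a, b) {
      # angle at shared vertex v between directions to a and b
      u1 <- pts[a, ] - pts[v, ]
      u2 <- pts[b, ] - pts[v, ]
      acos(pmin(pmax(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2)), -1), 1)) *
        180 / pi
    }
    ok_candidate <- function(i, j) {
      a <- pts[i, ]; b <- pts[j, ]
      for (e in edges) {
        shared <- intersect(c(e$from, e$to), c(i, j))
        if (length(shared) > 0) {
          # shallow angles make rasterized strokes overlap and trap slivers
          v <- shared[1]
          oth_e <- setdiff(c(e$from, e$to), v)
          oth_c <- setdiff(c(i, j), v)
          if (angle_at(v, oth_e, oth_c) < min_angle) return(FALSE)
        } else if (seg_seg_dist(a, b, pts[e$from, ], pts[e$to, ]) < clearance)
          return(FALSE)
      }
      for (v in seq_len(nrow(pts))) {
        if (v %in% c(i, j)) next
        if (point_seg_dist(pts[v, ], a, b) < clearance) return(FALSE)
      }
      TRUE
    }
    # all same-group vertex pairs, shortest first
    cand <- which(upper.tri(matrix(0, n_seeds, n_seeds)), arr.ind = TRUE)
    cand <- cand[grp[cand[, 1]] == grp[cand[, 2]], , drop = FALSE]
    lens <- sqrt(rowSums((pts[cand[, 1], , drop = FALSE] -
                            pts[cand[, 2], , drop = FALSE])^2))
    cand <- cand[order(lens), , drop = FALSE]
    # constrained Kruskal spanning forest
    parent <- seq_len(n_seeds)
    find_root <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    tree_used <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (find_root(i) == find_root(j)) next
      if (!ok_candidate(i, j)) next
      add_edge(i, j)
      parent[find_root(i)] <- find_root(j)
      tree_used[r] <- TRUE
    }
    n_tree <- length(edges)
    # extra loop-forming chords, shortest first
    n_extra <- round(loop_fraction * n_tree)
    added <- 0L
    for (r in seq_len(nrow(cand))) {
      if (added >= n_extra) break
      if (tree_used[r]) next
      if (ok_candidate(cand[r, 1], cand[r, 2])) {
        add_edge(cand[r, 1], cand[r, 2])
        added <- added + 1L
      }
    }

    # sheet blobs (ellipses) placed clear of all tubules
    sheets <- list()
    if (n_sheets > 0) {
      tries <- 0L
      while (length(sheets) < n_sheets && tries < 500L * n_sheets) {
        tries <- tries + 1L
        rx <- runif(1, 4, 9); ry <- runif(1, 4, 9)
        cx <- runif(1, margin + rx, width - margin - rx)
        cy <- runif(1, margin + ry, height - margin - ry)
        th <- seq(0, 2 * pi, length.out = 25)[-25]
        poly <- cbind(cx + rx * cos(th), cy + ry * sin(th))
        clear <- all(vapply(edges, function(e) {
          point_seg_dist(c(cx, cy), pts[e$from, ], pts[e$to, ]) >
            max(rx, ry) + clearance
        }, TRUE))
        clear <- clear && all(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) >
                                max(rx, ry) + clearance)
        clear <- clear && all(vapply(sheets, function(s)
          sqrt((attr(s, "center")[1] - cx)^2 + (attr(s, "center")[2] - cy)^2) >
            max(rx, ry) + 12, TRUE))
        if (clear) {
          attr(poly, "center") <- c(cx, cy)
          sheets[[length(sheets) + 1L]] <- poly
        }
      }
    }

    em <- do.call(rbind, lapply(edges, function(e) c(e$from, e$to)))
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n_seeds - igraph::vcount(g)))
    n_comp_graph <- igraph::components(g)$no

    faces <- trace_faces(pts, edges)
    loop_faces <- Filter(function(f) f$signed_area > 0.5, faces)
    loop_faces <- lapply(loop_faces, function(f)
      list(vertices = f$vertices, area = f$signed_area))

    structure(list(node_coords = pts, edges = edges, loop_faces = loop_faces,
                   component_count = n_comp_graph + length(sheets),
                   graph_component_count = n_comp_graph,
                   sheet_regions = sheets,
                   height = height, width = width),
              class = "network_geometry")
  })
}

#' @export
print.network_geometry <- function(x, ...) {
  cat(sprintf(
    "network_geometry: %d nodes, %d edges, %d loops, %d component(s), %d sheet(s) in %dx%d px\n",
    nrow(x$node_coords), length(x$edges), length(x$loop_faces),
    x$component_count, length(x$sheet_regions), x$height, x$width))
  invisible(x)
}

# ---- rasterization --------------------------------------------------------

bresenham <- function(x0, y0, x1, y1) {
  # inclusive integer line; returns cbind(x, y)
  x0 <- round(x0); y0 <- round(y0); x1 <- round(x1); y1 <- round(y1)
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  out <- matrix(integer(0), ncol = 2)
  x <- x0; y <- y0
  repeat {
    out <- rbind(out, c(x, y))
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  out
}

fill_polygon <- function(poly, height, width) {
  # even-odd rule on pixel centers within the polygon's bounding box
  out <- matrix(0L, height, width)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  cols <- max(1, floor(xr[1])):min(width, ceiling(xr[2]))
  rows <- max(1, floor(yr[1])):min(height, ceiling(yr[2]))
  n <- nrow(poly)
  for (i in rows) {
    crossings <- numeric(0)
    for (k in seq_len(n)) {
      a <- poly[k, ]; b <- poly[if (k == n) 1 else k + 1, ]
      if ((a[2] <= i) != (b[2] <= i)) {
        x <- a[1] + (i - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
        crossings <- c(crossings, x)
      }
    }
    crossings <- sort(crossings)
    if (length(crossings) >= 2) {
      for (k in seq(1, length(crossings) - 1, by = 2)) {
        cc <- cols[cols >= crossings[k] & cols <= crossings[k + 1]]
        out[i, cc] <- 1L
      }
    }
  }
  out
}

#' Rasterize a network geometry into a binary mask
#'
#' Tubule centerlines are drawn with Bresenham's algorithm (endpoints
#' inclusive) and thickened by stamping a disk of radius `(tubule_width-1)/2`
#' at every centerline pixel, so `tubule_width = 1` yields an 8-connected
#' one-pixel line.  Even widths round down to the next odd width.  Sheet
#' regions are filled by an even-odd polygon scan.
#'
#' @param geometry a `network_geometry`.
#' @param tubule_width stroke width in px (>= 1).
#' @param height,width output dimensions; default to the geometry's.
#' @return an integer matrix in `{0, 1}`.
#' @export
rasterize_mask <- function(geometry, tubule_width = 3,
                           height = geometry$height,
                           width = geometry$width) {
  assert_that(tubule_width >= 1, "tubule_width must be >= 1")
  assert_that(tubule_width <= min(height, width),
              "tubule_width exceeds the image size")
  mask <- matrix(0L, height, width)
  r <- (tubule_width - 1) %/% 2
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2 + 1e-9, , drop = FALSE]
  for (e in geometry$edges) {
    path <- e$path
    for (s in seq_len(nrow(path) - 1)) {
      px <- bresenham(path[s, 1], path[s, 2], path[s + 1, 1], path[s + 1, 2])
      for (o in seq_len(nrow(offs))) {
        xx <- px[, 1] + offs$dx[o]
        yy <- px[, 2] + offs$dy[o]
        keep <- xx >= 1 & xx <= width & yy >= 1 & yy <= height
        mask[cbind(yy[keep], xx[keep])] <- 1L
      }
    }
  }
  for (poly in geometry$sheet_regions)
    mask <- pmax(mask, fill_polygon(poly, height, width))
  # close sub-resolution pinholes trapped where strokes meet; genuine mesh
  # faces are far larger than the stroke width
  pad <- matrix(0L, height + 2, width + 2)
  pad[2:(height + 1), 2:(width + 1)] <- mask
  bg <- cpp_label_components(pad == 0L, 4L)
  border <- unique(c(bg[1, ], bg[height + 2, ], bg[, 1], bg[, width + 2]))
  hole_sizes <- tabulate(bg[bg > 0])
  tiny <- setdiff(which(hole_sizes < 4), border)
  if (length(tiny) > 0) {
    fillpx <- bg[2:(height + 1), 2:(width + 1)] %in% tiny
    mask[fillpx] <- 1L
  }
  mask
}

# ---- microscopy simulation ------------------------------------------------

#' Render a mask as a noisy fluorescence micrograph
#'
#' The binary mask is scaled to a signal amplitude chosen so that the peak
#' signal-to-noise ratio equals `peak_snr` under shot noise plus read noise,
#' blurred with an isotropic Gaussian PSF, and corrupted with Poisson shot
#' noise and additive Gaussian read noise (the standard hybrid noise model of
#' photon-limited fluorescence imaging).
#'
#' @param mask binary matrix.
#' @param psf_sigma Gaussian PSF standard deviation in px (0 disables blur).
#' @param peak_snr peak SNR, `s / sqrt(s + b + sigma_read^2)`; `Inf`
#'   disables noise.
#' @param background_level mean background intensity (photons).
#' @param rng_seed integer seed for the noise draw.
#' @param read_noise_sd Gaussian read-noise standard deviation.
#' @param noise set `FALSE` to return the noise-free expectation image.
#' @return a non-negative numeric matrix (photon-count scale).
#' @export
simulate_microscopy <- function(mask, psf_sigma = 1.2, peak_snr = 8,
                                background_level = 20, rng_seed = 1L,
                                read_noise_sd = 2, noise = TRUE) {
  assert_that(psf_sigma >= 0, "psf_sigma must be >= 0")
  assert_that(peak_snr > 0, "peak_snr must be positive")
  m <- matrix(as.numeric(mask != 0), nrow = nrow(mask))
  b <- background_level
  v0 <- b + read_noise_sd^2
  if (!is.finite(peak_snr)) {
    noise <- FALSE
    s <- 1
  } else {
    s <- (peak_snr^2 + peak_snr * sqrt(peak_snr^2 + 4 * v0)) / 2
  }
  blurred <- if (psf_sigma > 0) {
    bl <- EBImage::gblur(m, sigma = psf_sigma)
    pmax(bl, 0)
  } else m
  lambda <- b + s * blurred
  if (!noise) return(lambda)
  with_seed(rng_seed, {
    img <- rpois(length(lambda), lambda) +
      rnorm(length(lambda), sd = read_noise_sd)
    img <- pmax(img, 0)
    matrix(img, nrow = nrow(lambda))
  })
}

# ---- datasets -------------------------------------------------------------

syn_default_config <- function() {
  list(height = 128L, width = 128L, n_seeds = 25L, loop_fraction = 0.35,
       n_components = 1L, n_sheets = 0L, tubule_width = 3,
       min_separation = 12, clearance = 7, min_angle = 30, margin = 8,
       psf_sigma = 1.2, peak_snr = 8, background_level = 20,
       read_noise_sd = 2)
}

#' Generate a dataset of synthetic tubular-network samples
#'
#' @param n number of samples (>= 1).
#' @param config named list overriding the defaults of
#'   `syn_default_config()`: image size, seed count, loop fraction, tubule
#'   width, PSF width, peak SNR, background, read noise, components, sheets.
#' @param rng_seed master seed; each sample uses a distinct derived seed.
#' @return a list of `synthetic_sample` objects, each with `image`, `mask`,
#'   `geometry`, `truth` (beta0, beta1, junction_count, total_edge_length,
#'   mesh_area, convex_hull_area), `seed` and `id`.
#' @export
generate_dataset <- function(n, config = list(), rng_seed = 1L) {
  assert_that(n >= 1, "n must be >= 1")
  cfg <- utils::modifyList(syn_default_config(), config)
  lapply(seq_len(n), function(i) {
    seed_i <- derive_seed(rng_seed, i)
    geom <- generate_geometry(cfg$height, cfg$width, n_seeds = cfg$n_seeds,
                              loop_fraction = cfg$loop_fraction,
                              rng_seed = seed_i,
                              n_components = cfg$n_components,
                              n_sheets = cfg$n_sheets,
                              min_separation = cfg$min_separation,
                              clearance = cfg$clearance,
                              min_angle = cfg$min_angle, margin = cfg$margin)
    mask <- rasterize_mask(geom, tubule_width = cfg$tubule_width)
    img <- simulate_microscopy(mask, psf_sigma = cfg$psf_sigma,
                               peak_snr = cfg$peak_snr,
                               background_level = cfg$background_level,
                               rng_seed = derive_seed(seed_i, 7L),
                               read_noise_sd = cfg$read_noise_sd)
    deg <- tabulate(unlist(lapply(geom$edges, function(e) c(e$from, e$to))),
                    nbins = nrow(geom$node_coords))
    hull_pts <- rbind(geom$node_coords,
                      do.call(rbind, c(list(matrix(numeric(0), ncol = 2)),
                                       geom$sheet_regions)))
    hull <- hull_pts[chull(hull_pts), , drop = FALSE]
    truth <- list(
      beta0 = geom$component_count,
      beta1 = length(geom$loop_faces),
      junction_count = sum(deg == 1 | deg >= 3),
      total_edge_length = sum(vapply(geom$edges, `[[`, 0, "length")),
      mesh_area = sum(vapply(geom$loop_faces, `[[`, 0, "area")),
      convex_hull_area = abs(shoelace(hull)))
    structure(list(image = img, mask = mask, geometry = geom, truth = truth,
                   seed = seed_i, id = sprintf("syn%04d", i)),
              class = "synthetic_sample")
  })
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf(
    "synthetic_sample %s: %dx%d px, beta0=%d beta1=%d junctions=%d\n",
    x$id, nrow(x$mask), ncol(x$mask), x$truth$beta0, x$truth$beta1,
    x$truth$junction_count))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Each sample is written as `<id>_img.tif` (16-bit grayscale TIFF),
#' `<id>_mask.png` (binary PNG) and `<id>_truth.json`; a `manifest.csv`
#' records ids, seeds and generation parameters.
#'
#' @param samples list returned by [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    tiff::writeTIFF(pmin(s$image / 65535, 1), file.path(dir, paste0(s$id, "_img.tif")),
                    bits.per.sample = 16L)
    png::writePNG(matrix(as.numeric(s$mask), nrow(s$mask)),
                  file.path(dir, paste0(s$id, "_mask.png")))
    jsonlite::write_json(s$truth, file.path(dir, paste0(s$id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(id = s$id, seed = s$seed, height = nrow(s$mask),
               width = ncol(s$mask))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return a list of samples with `image`, `mask`, `truth`, `id`.
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$id[i]
    img <- tiff::readTIFF(file.path(dir, paste0(id, "_img.tif"))) * 65535
    mask <- as_mask(png::readPNG(file.path(dir, paste0(id, "_mask.png"))))
    truth <- jsonlite::read_json(file.path(dir, paste0(id, "_truth.json")),
                                 simplifyVector = TRUE)
    list(image = img, mask = mask, truth = truth, id = id)
  })
}
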