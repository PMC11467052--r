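# Skeleton-to-graph morphometry: clean the mask, extract a one-pixel
# skeleton, build a junction/tubule graph, and compute per-junction and
# network-wide properties (degree, degree centrality, closeness centrality,
# effective size, mesh density, junction density).

#' Remove small foreground components
#'
#' Deletes 8-connected foreground components whose pixel area is below
#' `min_area` — small isolated blobs produced by background noise.
#'
#' @param mask binary matrix.
#' @param min_area minimum component area in px^2 (0 keeps everything).
#' @return a cleaned binary matrix.
#' @export
remove_small_components <- function(mask, min_area = 30) {
  assert_that(min_area >= 0, "min_area must be >= 0")
  m <- mask != 0
  lab <- cpp_label_components(m, 8L)
  if (max(lab) == 0) return(as_mask(m))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  as_mask(matrix(lab %in% keep, nrow(m)))
}

#' Skeletonize a binary mask to one-pixel width
#'
#' Iterative Zhang-Suen thinning followed by removal of redundant staircase
#' corner pixels, yielding a strictly 8-thin skeleton.  The skeleton is a
#' subset of the mask and preserves its connected components and holes.
#'
#' @param mask binary matrix.
#' @return a logical matrix.
#' @export
skeletonize <- function(mask) {
  cpp_remove_redundant(cpp_thin_zhangsuen(mask != 0))
}

neighbor_counts <- function(skel) {
  H <- nrow(skel); W <- ncol(skel)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- skel
  cnt <- matrix(0L, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    cnt <- cnt + pad[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  }
  cnt
}

#' Build a junction/tubule graph from a one-pixel skeleton
#'
#' Junction pixels are skeleton pixels with one 8-neighbour (terminals) or
#' more than two 8-neighbours (branch points); adjacent branch pixels are
#' merged into a single node at their centroid.  Edges are the maximal
#' degree-2 pixel paths between junctions, with arc length counting axial
#' steps as 1 and diagonal steps as sqrt(2).  A component with no junction
#' (an isolated cycle) receives one anchor node carrying the cycle as a
#' self-loop.
#'
#' @param skeleton logical/binary matrix, one pixel wide.
#' @param simplify repair thinning artifacts (junction-clump merging, tiny
#'   self-loop removal, spur pruning, pass-through dissolution).
#' @param merge_dist contract branch-branch edges up to this arc length (junction clumps split by thinning scale with the stroke width), px.
#' @param prune_len remove terminal spurs shorter than this, px.
#' @param min_loop drop self-loops shorter than this circumference, px.
#' @return an object of class `skeleton_graph`: `nodes` (data frame with
#'   `id`, `y`, `x`, `kind`), `edges` (list of `list(from, to, path,
#'   length)`), `graph` (an igraph with edge weights = arc lengths) and
#'   `skeleton` (the input matrix).
#' @export
build_graph <- function(skeleton, simplify = TRUE, merge_dist = 5,
                        prune_len = 4, min_loop = 6) {
  skel <- matrix(as.integer(skeleton != 0), nrow(skeleton))
  H <- nrow(skel); W <- ncol(skel)
  cnt <- neighbor_counts(skel)
  # crossing number: 1 = terminal, 2 = path, >= 3 = branch
  ring <- cpp_crossing_number(skel == 1)
  is_node_px <- skel == 1 & (ring == 1 | ring >= 3 | cnt == 0)
  is_path_px <- skel == 1 & ring == 2

  node_lab <- cpp_label_components(is_node_px, 8L)
  n_clusters <- max(node_lab)
  nodes <- if (n_clusters > 0) {
    do.call(rbind, lapply(seq_len(n_clusters), function(k) {
      px <- which_pixels(node_lab == k)
      kind <- if (nrow(px) == 1 && ring[px] == 1) "terminal"
              else if (nrow(px) == 1 && cnt[px] == 0) "isolated"
              else "branch"
      data.frame(id = k, y = mean(px[, 1]), x = mean(px[, 2]), kind = kind)
    }))
  } else data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                    kind = character(0))

  nb_offsets <- cbind(
    di = c(-1, -1, -1, 0, 0, 1, 1, 1),
    dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  skel_at <- function(i, j) i >= 1 && i <= H && j >= 1 && j <= W && skel[i, j] == 1
  neighbors_of <- function(i, j) {
    out <- matrix(integer(0), ncol = 2)
    for (o in seq_len(8)) {
      ii <- i + nb_offsets[o, 1]; jj <- j + nb_offsets[o, 2]
      if (skel_at(ii, jj)) out <- rbind(out, c(ii, jj))
    }
    out
  }
  step_len <- function(a, b) sqrt(sum((a - b)^2))

  used <- matrix(FALSE, H, W)       # consumed path pixels
  pair_seen <- new.env(parent = emptyenv())  # direct node-node adjacencies
  edges <- list()
  add_edge <- function(from, to, path) {
    len <- 0
    if (nrow(path) > 1)
      for (s in seq_len(nrow(path) - 1))
        len <- len + step_len(path[s, ], path[s + 1, ])
    edges[[length(edges) + 1L]] <<- list(from = from, to = to, path = path,
                                         length = len)
  }

  node_px <- which_pixels(is_node_px)
  started_by_cluster <- vector("list", n_clusters)
  if (nrow(node_px) > 0) {
    for (r in seq_len(nrow(node_px))) {
      p <- node_px[r, ]
      from <- node_lab[p[1], p[2]]
      nbs <- neighbors_of(p[1], p[2])
      for (q_i in seq_len(nrow(nbs))) {
        q <- nbs[q_i, ]
        # adjacent launch pixels belong to the same emanating tubule group
        started <- started_by_cluster[[from]]
        if (!is.null(started) &&
            any(abs(started[, 1] - q[1]) <= 1 & abs(started[, 2] - q[2]) <= 1))
          next
        if (is_node_px[q[1], q[2]]) {
          to <- node_lab[q[1], q[2]]
          if (to == from) next  # same merged cluster
          key <- paste(sort(c(p[1] + (p[2] - 1) * H, q[1] + (q[2] - 1) * H)),
                       collapse = "_")
          if (!is.null(pair_seen[[key]])) next
          pair_seen[[key]] <- TRUE
          add_edge(from, to, rbind(p, q))
        } else if (!used[q[1], q[2]]) {
          # trace along interior path pixels
          started_by_cluster[[from]] <- rbind(started_by_cluster[[from]], q)
          path <- rbind(p, q)
          used[q[1], q[2]] <- TRUE
          prev <- p; cur <- q
          repeat {
            nxts <- neighbors_of(cur[1], cur[2])
            # drop the arrival group (prev and anything adjacent to it) and
            # pixels already consumed by another trace
            keep <- !(abs(nxts[, 1] - prev[1]) <= 1 &
                        abs(nxts[, 2] - prev[2]) <= 1) &
              (is_node_px[nxts] | !used[nxts])
            nxts <- nxts[keep, , drop = FALSE]
            if (nrow(nxts) == 0) {
              # blocked: close on an adjacent junction if one exists (it may
              # have been filtered with the arrival group), else self-stub
              nbs2 <- neighbors_of(cur[1], cur[2])
              ndh <- which(is_node_px[nbs2])
              if (length(ndh) > 0) {
                labs <- node_lab[nbs2[ndh, , drop = FALSE]]
                pick <- ndh[if (any(labs != from)) which(labs != from)[1] else 1]
                q2 <- nbs2[pick, ]
                add_edge(from, node_lab[q2[1], q2[2]], rbind(path, q2))
              } else add_edge(from, from, path)
              break
            }
            # prefer a node pixel, then an axial step
            nd <- which(is_node_px[nxts])
            nxt <- if (length(nd) > 0) nxts[nd[1], ]
            else {
              ax <- which(nxts[, 1] == cur[1] | nxts[, 2] == cur[2])
              if (length(ax) > 0) nxts[ax[1], ] else nxts[1, ]
            }
            path <- rbind(path, nxt)
            if (is_node_px[nxt[1], nxt[2]]) {
              add_edge(from, node_lab[nxt[1], nxt[2]], path)
              break
            }
            used[nxt[1], nxt[2]] <- TRUE
            prev <- cur; cur <- nxt
          }
        }
      }
    }
  }

  # leftovers: unconsumed path pixels form either pure cycles (components
  # with no junction at all) or chains missed by the launch heuristic; both
  # are recovered here.
  remaining <- is_path_px & !used
  rem_lab <- cpp_label_components(remaining, 8L)
  if (max(rem_lab) > 0) {
    adj_cluster <- function(pixel) {
      nbs <- neighbors_of(pixel[1], pixel[2])
      hit <- which(is_node_px[nbs])
      if (length(hit) > 0) {
        q <- nbs[hit[1], ]
        list(id = node_lab[q[1], q[2]], px = q)
      } else NULL
    }
    for (k in seq_len(max(rem_lab))) {
      px <- which_pixels(rem_lab == k)
      in_comp <- rem_lab == k
      wdeg <- vapply(seq_len(nrow(px)), function(r) {
        nbs <- neighbors_of(px[r, 1], px[r, 2])
        sum(in_comp[nbs])
      }, 0L)
      walk_chain <- function(start) {
        chain <- matrix(start, ncol = 2)
        seen <- matrix(FALSE, H, W)
        seen[start[1], start[2]] <- TRUE
        cur <- start
        repeat {
          nbs <- neighbors_of(cur[1], cur[2])
          cand <- which(in_comp[nbs] & !seen[nbs])
          if (length(cand) == 0) break
          cur <- nbs[cand[1], ]
          seen[cur[1], cur[2]] <- TRUE
          chain <- rbind(chain, cur)
        }
        chain
      }
      if (all(wdeg >= 2)) {          # pure cycle
        if (nrow(px) < 4) next       # too small to enclose a hole
        anchor <- px[1, ]
        aid <- nrow(nodes) + 1L
        nodes <- rbind(nodes, data.frame(id = aid, y = anchor[1],
                                         x = anchor[2], kind = "anchor"))
        chain <- walk_chain(anchor)
        used[chain] <- TRUE
        add_edge(aid, aid, rbind(chain, chain[1, ]))
      } else {                       # chain: reconnect to adjacent junctions
        start <- px[which(wdeg <= 1)[1], ]
        chain <- walk_chain(start)
        used[chain] <- TRUE
        a <- adj_cluster(chain[1, ])
        b <- adj_cluster(chain[nrow(chain), ])
        # a chain not anchored at junctions on both ends is tracing residue
        # (genuine tubule ends are junction pixels and were traced directly)
        if (is.null(a) || is.null(b)) next
        add_edge(a$id, b$id, rbind(a$px, chain, b$px))
      }
    }
  }

  if (simplify)
    res <- simplify_skeleton_graph(nodes, edges, merge_dist = merge_dist,
                                   prune_len = prune_len, min_loop = min_loop)
  else res <- list(nodes = nodes, edges = edges)
  nodes <- res$nodes
  edges <- res$edges

  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  if (length(edges) > 0) {
    el <- do.call(rbind, lapply(edges, function(e) c(e$from, e$to)))
    g <- igraph::add_edges(g, t(el))
    igraph::E(g)$weight <- vapply(edges, `[[`, 0, "length")
  }
  structure(list(nodes = nodes, edges = edges, graph = g, skeleton = skel),
            class = "skeleton_graph")
}

# Clean-up of thinning artifacts.  Eight-neighbour thinning splits a single
# anatomical junction into a clump of nearby branch pixels and produces
# staircase micro-cycles and short spurs; the graph is repaired by (1)
# contracting short branch-branch edges, (2) dropping self-loops shorter
# than a genuine mesh could be, (3) pruning short terminal spurs and (4)
# dissolving the resulting degree-2 pass-through nodes.
simplify_skeleton_graph <- function(nodes, edges, merge_dist = 5,
                                    prune_len = 4, min_loop = 6) {
  if (nrow(nodes) == 0) return(list(nodes = nodes, edges = edges))
  alive <- rep(TRUE, length(edges))
  deg_of <- function() {
    d <- integer(nrow(nodes))
    for (i in which(alive)) {
      e <- edges[[i]]
      d[e$from] <- d[e$from] + 1L
      d[e$to] <- d[e$to] + 1L
    }
    d
  }
  # (1) + (2): contract short branch-branch edges; drop tiny self-loops
  repeat {
    changed <- FALSE
    for (i in which(alive)) {
      e <- edges[[i]]
      if (e$from == e$to) {
        if (e$length < min_loop && nodes$kind[e$from] != "anchor") {
          alive[i] <- FALSE
          changed <- TRUE
        }
        next
      }
      if (e$length <= merge_dist &&
          nodes$kind[e$from] == "branch" && nodes$kind[e$to] == "branch") {
        keep <- e$from; drop <- e$to
        nodes$y[keep] <- (nodes$y[keep] + nodes$y[drop]) / 2
        nodes$x[keep] <- (nodes$x[keep] + nodes$x[drop]) / 2
        alive[i] <- FALSE
        for (k in which(alive)) {
          if (edges[[k]]$from == drop) edges[[k]]$from <- keep
          if (edges[[k]]$to == drop) edges[[k]]$to <- keep
        }
        nodes$kind[drop] <- "dead"
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  # (3) prune short terminal spurs
  repeat {
    d <- deg_of()
    spur <- NULL
    for (i in which(alive)) {
      e <- edges[[i]]
      if (e$from == e$to || e$length >= prune_len) next
      if (d[e$from] == 1L && nodes$kind[e$from] == "terminal") spur <- i
      else if (d[e$to] == 1L && nodes$kind[e$to] == "terminal") spur <- i
      if (!is.null(spur)) break
    }
    if (is.null(spur)) break
    e <- edges[[spur]]
    tip <- if (d[e$from] == 1L && nodes$kind[e$from] == "terminal") e$from
           else e$to
    nodes$kind[tip] <- "dead"
    alive[spur] <- FALSE
  }
  # (4) dissolve degree-2 pass-through nodes
  repeat {
    d <- deg_of()
    v <- which(d == 2L & nodes$kind == "branch")
    v <- v[vapply(v, function(u) {
      inc <- which(alive & vapply(edges, function(e)
        e$from == u || e$to == u, TRUE))
      length(inc) == 2L && all(vapply(inc, function(i)
        edges[[i]]$from != edges[[i]]$to, TRUE))
    }, TRUE)]
    if (length(v) == 0) break
    u <- v[1]
    inc <- which(alive & vapply(edges, function(e)
      e$from == u || e$to == u, TRUE))
    e1 <- edges[[inc[1]]]; e2 <- edges[[inc[2]]]
    a <- if (e1$from == u) e1$to else e1$from
    b <- if (e2$from == u) e2$to else e2$from
    p1 <- if (e1$to == u) e1$path else e1$path[rev(seq_len(nrow(e1$path))), ,
                                               drop = FALSE]
    p2 <- if (e2$from == u) e2$path else e2$path[rev(seq_len(nrow(e2$path))), ,
                                                 drop = FALSE]
    edges[[inc[1]]] <- list(from = a, to = b,
                            path = rbind(p1, p2[-1, , drop = FALSE]),
                            length = e1$length + e2$length)
    alive[inc[2]] <- FALSE
    nodes$kind[u] <- "dead"
  }
  # compact ids
  edges <- edges[alive]
  live <- sort(unique(c(which(nodes$kind != "dead"),
                        unlist(lapply(edges, function(e) c(e$from, e$to))))))
  remap <- integer(nrow(nodes))
  remap[live] <- seq_along(live)
  nodes <- nodes[live, , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes))
  rownames(nodes) <- NULL
  edges <- lapply(edges, function(e) {
    e$from <- remap[e$from]; e$to <- remap[e$to]; e
  })
  list(nodes = nodes, edges = edges)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d junctions (%s), %d tubules, total length %.1f px\n",
              nrow(x$nodes),
              paste(names(table(x$nodes$kind)), table(x$nodes$kind),
                    sep = ":", collapse = " "),
              length(x$edges),
              sum(vapply(x$edges, `[[`, 0, "length"))))
  invisible(x)
}

#' Per-junction properties of a skeleton graph
#'
#' Degree is the number of incident tubules (self-loops count twice for
#' degree, but a node is not its own neighbour).  Degree centrality divides
#' the degree by the total junction count `N` (set
#' `conventional_normalizer = TRUE` for the usual `N - 1`).  Closeness
#' centrality is reported as the mean shortest-path length (in px of tubule
#' arc length) to all other reachable junctions — smaller means more
#' central; unreachable pairs are excluded and flagged in the `reachable`
#' column.  Effective size counts the directly connected junctions that
#' share no common neighbour with the focal junction.
#'
#' @param graph a `skeleton_graph`.
#' @param conventional_normalizer use `N - 1` for degree centrality.
#' @return a data frame with one row per junction: `id`, `kind`, `degree`,
#'   `degree_centrality`, `closeness_centrality`, `effective_size`,
#'   `reachable`.
#' @export
junction_properties <- function(graph, conventional_normalizer = FALSE) {
  g <- graph$graph
  n <- igraph::vcount(g)
  assert_that(n >= 1, "graph has no junctions")
  deg <- igraph::degree(g, loops = TRUE)
  norm <- if (conventional_normalizer) max(n - 1, 1) else n
  dc <- deg / norm
  if (n >= 2) {
    d <- igraph::distances(g, weights = igraph::E(g)$weight)
    diag(d) <- NA
    cc <- apply(d, 1, function(row) mean(row[is.finite(row)], na.rm = TRUE))
    reach <- apply(d, 1, function(row) sum(is.finite(row), na.rm = TRUE))
  } else {
    cc <- NA_real_
    reach <- 0L
  }
  simple <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE)
  nbrs <- lapply(seq_len(n), function(v)
    as.integer(igraph::neighbors(simple, v)))
  es <- vapply(seq_len(n), function(u) {
    sum(vapply(nbrs[[u]], function(v) {
      common <- setdiff(intersect(nbrs[[u]], nbrs[[v]]), c(u, v))
      length(common) == 0
    }, TRUE))
  }, 0)
  data.frame(id = graph$nodes$id, kind = graph$nodes$kind, degree = deg,
             degree_centrality = dc, closeness_centrality = cc,
             effective_size = es, reachable = reach)
}

#' Mesh density of a network
#'
#' The summed area of all fully enclosed loops of the skeleton graph divided
#' by the area of the convex hull of the mask foreground.  Loop areas are
#' pixel counts of background regions completely enclosed by the skeleton;
#' the hull area is the polygon area of the convex hull of foreground pixel
#' centres.
#'
#' @param graph a `skeleton_graph`.
#' @param mask the (cleaned) binary mask the skeleton came from.
#' @return a ratio in `[0, 1]` (NA with a warning if the hull is degenerate).
#' @export
mesh_density <- function(graph, mask) {
  skel <- graph$skeleton
  H <- nrow(skel); W <- ncol(skel)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- skel
  bg <- cpp_label_components(pad == 0L, 4L)
  border_labels <- unique(c(bg[1, ], bg[H + 2, ], bg[, 1], bg[, W + 2]))
  enclosed <- bg > 0 & !(bg %in% border_labels)
  loop_area <- sum(enclosed)
  fg <- which_pixels(mask != 0)
  if (nrow(fg) < 3) {
    warning("degenerate convex hull: mesh density undefined")
    return(NA_real_)
  }
  hull <- fg[chull(fg[, 2], fg[, 1]), , drop = FALSE]
  hull_area <- abs(shoelace(cbind(hull[, 2], hull[, 1])))
  if (hull_area <= 0) {
    warning("degenerate convex hull: mesh density undefined")
    return(NA_real_)
  }
  loop_area / hull_area
}

#' Junction density of a network
#'
#' Total junction count divided by the total tubule arc length.
#'
#' @param graph a `skeleton_graph`.
#' @return junctions per px (NA with a warning for a zero-length network).
#' @export
junction_density <- function(graph) {
  total_len <- sum(vapply(graph$edges, `[[`, 0, "length"))
  if (total_len <= 0) {
    warning("zero-length network: junction density undefined")
    return(NA_real_)
  }
  nrow(graph$nodes) / total_len
}

#' Network-wide topology summary
#'
#' Runs the full pipeline — small-blob removal, skeletonization, graph
#' construction — then averages the per-junction properties and attaches the
#' mesh and junction densities.
#'
#' @param mask binary matrix.
#' @param min_area blob-removal threshold in px^2.
#' @param conventional_normalizer see [junction_properties()].
#' @param merge_dist junction-clump merge radius passed to [build_graph()];
#'   use ~2.5x the tubule width.
#' @return a one-row data frame: `mean_degree`, `mean_degree_centrality`,
#'   `mean_closeness_centrality`, `mean_effective_size`, `mesh_density`,
#'   `junction_density`, `n_junctions`, `n_tubules`, `total_length`.
#' @export
network_summary <- function(mask, min_area = 30,
                            conventional_normalizer = FALSE,
                            merge_dist = 5) {
  clean <- remove_small_components(mask, min_area)
  if (sum(clean) == 0) {
    warning("mask empty after cleaning: network summary undefined")
    return(data.frame(mean_degree = NA_real_,
                      mean_degree_centrality = NA_real_,
                      mean_closeness_centrality = NA_real_,
                      mean_effective_size = NA_real_, mesh_density = NA_real_,
                      junction_density = NA_real_, n_junctions = 0L,
                      n_tubules = 0L, total_length = 0))
  }
  skel <- skeletonize(clean)
  graph <- build_graph(skel, merge_dist = merge_dist)
  props <- junction_properties(graph, conventional_normalizer)
  data.frame(
    mean_degree = mean(props$degree),
    mean_degree_centrality = mean(props$degree_centrality),
    mean_closeness_centrality = mean(props$closeness_centrality, na.rm = TRUE),
    mean_effective_size = mean(props$effective_size),
    mesh_density = mesh_density(graph, clean),
    junction_density = junction_density(graph),
    n_junctions = nrow(graph$nodes),
    n_tubules = length(graph$edges),
    total_length = sum(vapply(graph$edges, `[[`, 0, "length")))
}

#' Compare network properties between two sets of masks
#'
#' Computes [network_summary()] for paired predicted and ground-truth masks
#' and compares each property with a two-sample t-test.
#'
#' @param pred_masks,gt_masks lists of binary matrices.
#' @param min_area blob-removal threshold.
#' @return a list with `pred` and `gt` per-image property tables and
#'   `tests`, a data frame of per-property means and t-test p-values.
#' @export
compare_network_properties <- function(pred_masks, gt_masks, min_area = 30) {
  tab <- function(masks) do.call(rbind, lapply(masks, network_summary,
                                               min_area = min_area))
  pt <- tab(pred_masks)
  gt <- tab(gt_masks)
  props <- c("mean_degree", "mean_degree_centrality",
             "mean_closeness_centrality", "mean_effective_size",
             "mesh_density", "junction_density")
  tests <- do.call(rbind, lapply(props, function(p) {
    a <- pt[[p]]; b <- gt[[p]]
    pv <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    data.frame(property = p, mean_pred = mean(a, na.rm = TRUE),
               mean_gt = mean(b, na.rm = TRUE), p_value = pv)
  }))
  list(pred = pt, gt = gt, tests = tests)
}
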