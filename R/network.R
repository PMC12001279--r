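#' Fold network: planar graph of fold valleys
#'
#' Nodes are junctions/endpoints in a 2D projection; edges are polylines
#' with arc length. After [classify_network_edges()] (called by
#' [simplify_network()] and [compute_metrics()]), edges partition into
#' cycle members (bounding "domains", the interior faces of the planar
#' embedding) and incomplete (dead-end/bridge) edges.
#'
#' @param nodes `n x 2` matrix of node positions.
#' @param edges List of edges, each `list(from, to, path, length)` where
#'   `path` is an `k x 2` polyline including both endpoints.
#' @param toepad_length Normalizing length (extent of the projected tissue
#'   outline along its principal axis).
#' @return An object of class `fold_network`.
#' @export
fold_network <- function(nodes, edges, toepad_length) {
  if (length(edges)) {
    stopifnot(all(vapply(edges, function(e) e$length, 0) > 0))
  }
  stopifnot(is.numeric(toepad_length), toepad_length > 0)
  structure(list(nodes = nodes, edges = edges,
                 toepad_length = toepad_length,
                 cycles = NULL, incomplete = NULL),
            class = "fold_network")
}

#' @export
print.fold_network <- function(x, ...) {
  cat(sprintf("<fold_network> %d nodes, %d edges (total length %.4g), toepad length %.4g\n",
              nrow(x$nodes), length(x$edges),
              sum(vapply(x$edges, function(e) e$length, 0)), x$toepad_length))
  if (!is.null(x$cycles))
    cat(sprintf("  %d cycles (domains), %d incomplete edges\n",
                length(x$cycles), length(x$incomplete)))
  invisible(x)
}

#' Total arc length of a fold network
#' @param net A [fold_network()].
#' @return Scalar.
#' @export
network_length <- function(net) {
  if (!length(net$edges)) return(0)
  sum(vapply(net$edges, function(e) e$length, 0))
}

net_igraph <- function(net) {
  el <- t(vapply(net$edges, function(e) c(e$from, e$to), c(0, 0)))
  igraph::graph_from_edgelist(matrix(el, ncol = 2), directed = FALSE)
}

#' Classify edges into cycle members and incomplete edges
#'
#' Bridges of the multigraph (edges on no cycle) are the incomplete
#' (dead-end) edges; the rest bound the planar faces. The interior faces
#' of the planar embedding of the bridge-free subgraph are the "domains";
#' they are found by angular face traversal and identified by positive
#' signed area.
#'
#' @param net A [fold_network()].
#' @return The network with `incomplete` (edge indices) and `cycles`
#'   (list of integer edge-index vectors, one per interior face) filled in.
#' @export
classify_network_edges <- function(net) {
  ne <- length(net$edges)
  if (ne == 0) {
    net$incomplete <- integer(0); net$cycles <- list()
    return(net)
  }
  g <- net_igraph(net)
  br <- igraph::bridges(g)
  # self-loops are never bridges; igraph handles multi-edges correctly
  net$incomplete <- sort(as.integer(br))
  keep <- setdiff(seq_len(ne), net$incomplete)
  net$cycles <- planar_faces(net, keep)
  net
}

# interior faces (positive signed area) of the sub-network given by edge ids
planar_faces <- function(net, edge_ids) {
  if (!length(edge_ids)) return(list())
  edges <- net$edges[edge_ids]
  # half-edge h: 2i-1 = forward (from -> to), 2i = backward
  nh <- 2L * length(edges)
  he_org <- integer(nh); he_ang <- numeric(nh)
  for (i in seq_along(edges)) {
    e <- edges[[i]]; p <- e$path
    d1 <- p[2, ] - p[1, ]
    d2 <- p[nrow(p) - 1, ] - p[nrow(p), ]
    he_org[2 * i - 1] <- e$from; he_ang[2 * i - 1] <- atan2(d1[2], d1[1])
    he_org[2 * i]     <- e$to;   he_ang[2 * i]     <- atan2(d2[2], d2[1])
  }
  twin <- function(h) if (h %% 2L == 1L) h + 1L else h - 1L
  # outgoing half-edges per node, sorted counter-clockwise by angle
  out <- split(seq_len(nh), he_org)
  nxt <- integer(nh)
  for (v in names(out)) {
    hs <- out[[v]]
    hs <- hs[order(he_ang[hs], hs)]
    # next(h) = rotate clockwise from twin(h) at the head node of h
    for (k in seq_along(hs)) {
      h <- hs[k]
      prevk <- if (k == 1L) length(hs) else k - 1L
      nxt_of_twin <- hs[prevk]
      nxt[twin(h)] <- nxt_of_twin
    }
  }
  visited <- logical(nh)
  faces <- list()
  for (h0 in seq_len(nh)) {
    if (visited[h0]) next
    cyc <- integer(0); h <- h0
    pts <- NULL
    repeat {
      visited[h] <- TRUE
      cyc <- c(cyc, h)
      i <- (h + 1L) %/% 2L
      p <- edges[[i]]$path
      if (h %% 2L == 0L) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      pts <- rbind(pts, p[-nrow(p), , drop = FALSE])
      h <- nxt[h]
      if (h == h0) break
    }
    # signed area (shoelace) of the face polygon
    x <- pts[, 1]; y <- pts[, 2]
    area <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    if (area > 0)
      faces[[length(faces) + 1L]] <- sort(unique(edge_ids[(cyc + 1L) %/% 2L]))
  }
  faces
}

#' Merge chains and prune short spurs
#'
#' Degree-2 chains are merged into single polyline edges (conserving arc
#' length exactly); dead-end spurs shorter than
#' `spur_fraction * toepad_length` are pruned iteratively; cycles are
#' recomputed. Idempotent.
#'
#' @param net A [fold_network()].
#' @param spur_fraction Fraction of the toepad length below which a
#'   dead-end edge is discarded (default 0.02).
#' @return A simplified, classified [fold_network()].
#' @export
simplify_network <- function(net, spur_fraction = 0.02) {
  stopifnot(inherits(net, "fold_network"))
  nodes <- net$nodes
  edges <- net$edges
  thr <- spur_fraction * net$toepad_length

  degree_of <- function(edges, n) {
    d <- integer(n)
    for (e in edges) {
      d[e$from] <- d[e$from] + 1L
      d[e$to] <- d[e$to] + 1L
    }
    d
  }
  repeat {
    changed <- FALSE
    n <- nrow(nodes)
    # merge degree-2 chains first: a spur is judged by its full arc length
    # from junction to tip, not by raster fragment lengths
    repeat {
      deg <- degree_of(edges, n)
      loops <- vapply(edges, function(e) e$from == e$to, TRUE)
      merged_any <- FALSE
      for (v in which(deg == 2L)) {
        inc <- which(vapply(edges, function(e) e$from == v || e$to == v, TRUE))
        if (length(inc) != 2L || any(loops[inc])) next
        e1 <- edges[[inc[1]]]; e2 <- edges[[inc[2]]]
        if (e1$from == v) {
          e1$path <- e1$path[rev(seq_len(nrow(e1$path))), , drop = FALSE]
          e1 <- list(from = e1$to, to = v, path = e1$path, length = e1$length)
        }
        if (e2$to == v) {
          e2$path <- e2$path[rev(seq_len(nrow(e2$path))), , drop = FALSE]
          e2 <- list(from = v, to = e2$from, path = e2$path, length = e2$length)
        }
        edges[[inc[1]]] <- list(from = e1$from, to = e2$to,
                                path = rbind(e1$path, e2$path[-1, , drop = FALSE]),
                                length = e1$length + e2$length)
        edges <- edges[-inc[2]]
        merged_any <- TRUE
        changed <- TRUE
        break
      }
      if (!merged_any) break
    }
    deg <- degree_of(edges, n)
    # prune short spurs (leaf edges) and degenerate self-loops
    drop <- logical(length(edges))
    for (i in seq_along(edges)) {
      e <- edges[[i]]
      if (e$from == e$to) {
        # degenerate out-and-back self-loops enclose no area; short
        # self-loops are raster junction artefacts
        x <- e$path[, 1]; y <- e$path[, 2]
        a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2)
        if (e$length < thr || a < 1e-9 * net$toepad_length^2) {
          drop[i] <- TRUE; changed <- TRUE
        }
        next
      }
      if ((deg[e$from] == 1L || deg[e$to] == 1L) && e$length < thr) {
        drop[i] <- TRUE
        deg[e$from] <- deg[e$from] - 1L   # avoid double-pruning at a junction
        deg[e$to] <- deg[e$to] - 1L
        changed <- TRUE
      }
    }
    edges <- edges[!drop]
    if (!changed) break
  }
  out <- fold_network(nodes, edges, net$toepad_length)
  classify_network_edges(out)
}

#' Two-component fold-pattern metric
#'
#' `c1` = sum of domain (cycle) perimeters, `c2` = sum of incomplete
#' (dead-end) edge lengths, both normalized by the toepad length. A cycle
#' perimeter is the boundary length of an interior face of the planar
#' embedding; an edge shared by two domains contributes to both.
#'
#' @param net A [fold_network()].
#' @return A `metric_vector`: named numeric `c(c1, c2)`.
#' @export
compute_metrics <- function(net) {
  stopifnot(inherits(net, "fold_network"))
  if (net$toepad_length <= 0) stop("toepad_length must be positive")
  if (is.null(net$cycles)) net <- classify_network_edges(net)
  len <- vapply(net$edges, function(e) e$length, 0)
  c1 <- if (length(net$cycles))
    sum(vapply(net$cycles, function(f) sum(len[f]), 0)) else 0
  c2 <- if (length(net$incomplete)) sum(len[net$incomplete]) else 0
  structure(c(c1 = c1 / net$toepad_length, c2 = c2 / net$toepad_length),
            class = "metric_vector")
}

#' Inter-sample metric normalizer
#'
#' Fits per-component mean and standard deviation across a set of samples;
#' normalized components are `(v - mean) / sd`.
#'
#' @param samples List (or matrix rows) of metric vectors.
#' @param sd_floor Lower bound applied to the fitted standard deviations
#'   (default 0). A degenerate fitting set (e.g. every sample cycle-free,
#'   so one component has zero spread) makes normalization singular; a
#'   small positive floor keeps the distance usable in that case. With the
#'   default floor of 0, zero spread is an error.
#' @return An object of class `metric_normalizer` with `mean` and `sd`.
#' @export
fit_normalizer <- function(samples, sd_floor = 0) {
  m <- do.call(rbind, lapply(samples, as.numeric))
  if (nrow(m) < 2) stop("need at least 2 samples to fit a normalizer")
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  if (any(s <= 0) && sd_floor <= 0)
    stop("zero inter-sample standard deviation; cannot normalize")
  structure(list(mean = mu, sd = pmax(s, sd_floor)),
            class = "metric_normalizer")
}

#' Normalize a metric vector
#' @param v Metric vector (length 2).
#' @param norm A `metric_normalizer`.
#' @return Normalized metric vector.
#' @export
normalize_metrics <- function(v, norm) {
  stopifnot(inherits(norm, "metric_normalizer"))
  out <- (as.numeric(v) - norm$mean) / norm$sd
  names(out) <- c("c1", "c2")
  out
}

#' Distance between two fold patterns
#'
#' Euclidean distance of the normalized two-component metric vectors.
#'
#' @param a,b Metric vectors (raw).
#' @param norm A `metric_normalizer` shared by both.
#' @return Non-negative scalar, zero iff the normalized vectors coincide.
#' @export
network_distance <- function(a, b, norm) {
  da <- normalize_metrics(a, norm)
  db <- normalize_metrics(b, norm)
  sqrt(sum((da - db)^2))
}
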