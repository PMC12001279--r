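#' Skeletonize a fold mask into a raw fold network
#'
#' The masked (fold-valley) region of the surface is projected along
#' `projection_axis`, rasterized (triangles whose three vertices are all
#' masked are filled), thinned to a unit-width skeleton (Guo-Hall), and
#' traced into a graph: junction/endpoint pixels become nodes, skeleton
#' runs become polyline edges. The toepad length is the extent of the
#' whole projected surface outline along its principal axis.
#'
#' @param surface A [surface_mesh()].
#' @param mask Logical per-vertex mask from [extract_fold_mask()].
#' @param projection_axis `"z"` (default), `"x"` or `"y"`: the viewing
#'   axis of the 2D projection.
#' @param pixel_size Raster pixel size; default 0.8 times the median
#'   projected edge length.
#' @return A raw [fold_network()] (run [simplify_network()] before
#'   computing metrics). Empty mask gives an empty network.
#' @export
skeletonize_fold_mask <- function(surface, mask, projection_axis = "z",
                                  pixel_size = NULL) {
  stopifnot(inherits(surface, "surface_mesh"),
            length(mask) == nrow(surface$vertices))
  ax <- match(match.arg(projection_axis, c("x", "y", "z")), c("x", "y", "z"))
  pts <- surface$vertices[, -ax, drop = FALSE]
  tl <- principal_extent(pts)

  if (!any(mask)) {
    return(fold_network(matrix(0, 0, 2), list(), tl))
  }
  tr <- surface$triangles
  if (is.null(pixel_size)) {
    e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
    el <- sqrt(rowSums((pts[e[, 1], , drop = FALSE] -
                        pts[e[, 2], , drop = FALSE])^2))
    pixel_size <- 0.8 * stats::median(el)
  }
  px <- pixel_size
  xmin <- min(pts[, 1]) - px; ymin <- min(pts[, 2]) - px
  nx <- ceiling((max(pts[, 1]) - xmin) / px) + 2L
  ny <- ceiling((max(pts[, 2]) - ymin) / px) + 2L
  img <- matrix(FALSE, nx, ny)

  toix <- function(x) pmin(pmax(floor((x - xmin) / px) + 1L, 1L), nx)
  toiy <- function(y) pmin(pmax(floor((y - ymin) / px) + 1L, 1L), ny)
  # masked vertices
  mv <- which(mask)
  img[cbind(toix(pts[mv, 1]), toiy(pts[mv, 2]))] <- TRUE
  # fill triangles with all three vertices masked
  full <- which(mask[tr[, 1]] & mask[tr[, 2]] & mask[tr[, 3]])
  for (t in full) {
    v <- pts[tr[t, ], , drop = FALSE]
    i0 <- toix(min(v[, 1])); i1 <- toix(max(v[, 1]))
    j0 <- toiy(min(v[, 2])); j1 <- toiy(max(v[, 2]))
    for (i in i0:i1) for (j in j0:j1) {
      if (img[i, j]) next
      p <- c(xmin + (i - 0.5) * px, ymin + (j - 0.5) * px)
      d1 <- (v[2, 1] - v[1, 1]) * (p[2] - v[1, 2]) - (v[2, 2] - v[1, 2]) * (p[1] - v[1, 1])
      d2 <- (v[3, 1] - v[2, 1]) * (p[2] - v[2, 2]) - (v[3, 2] - v[2, 2]) * (p[1] - v[2, 1])
      d3 <- (v[1, 1] - v[3, 1]) * (p[2] - v[3, 2]) - (v[1, 2] - v[3, 2]) * (p[1] - v[3, 1])
      if ((d1 >= 0 && d2 >= 0 && d3 >= 0) || (d1 <= 0 && d2 <= 0 && d3 <= 0))
        img[i, j] <- TRUE
    }
  }
  skel <- .thin_raster(img)
  trace_skeleton(skel, px, xmin, ymin, tl)
}

principal_extent <- function(pts) {
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  diff(range(cc %*% ev))
}

# trace a thinned binary image into a fold_network
trace_skeleton <- function(skel, px, xmin, ymin, toepad_length) {
  nx <- nrow(skel); ny <- ncol(skel)
  idx <- which(skel)
  if (!length(idx)) return(fold_network(matrix(0, 0, 2), list(), toepad_length))
  ii <- ((idx - 1L) %% nx) + 1L
  jj <- ((idx - 1L) %/% nx) + 1L
  inskel <- skel
  off <- cbind(c(-1, 0, 1, -1, 1, -1, 0, 1), c(-1, -1, -1, 0, 0, 1, 1, 1))
  nbrs <- function(i, j) {
    out <- cbind(i + off[, 1], j + off[, 2])
    ok <- out[, 1] >= 1 & out[, 1] <= nx & out[, 2] >= 1 & out[, 2] <= ny
    out <- out[ok, , drop = FALSE]
    out[inskel[out], , drop = FALSE]
  }
  deg <- integer(length(idx))
  key <- function(i, j) i + nx * (j - 1L)
  pos <- integer(nx * ny); pos[idx] <- seq_along(idx)
  for (q in seq_along(idx)) deg[q] <- nrow(nbrs(ii[q], jj[q]))

  isnode <- deg != 2L
  # cluster adjacent node pixels into single graph nodes
  nodecomp <- integer(length(idx))
  ncl <- 0L
  for (q in seq_along(idx)) {
    if (!isnode[q] || nodecomp[q]) next
    ncl <- ncl + 1L
    stack <- q
    nodecomp[q] <- ncl
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- nbrs(ii[cur], jj[cur])
      for (r in seq_len(nrow(nb))) {
        qq <- pos[key(nb[r, 1], nb[r, 2])]
        if (isnode[qq] && !nodecomp[qq]) {
          nodecomp[qq] <- ncl
          stack <- c(stack, qq)
        }
      }
    }
  }
  nodepos <- matrix(0, ncl, 2)
  if (ncl > 0)
    for (c in seq_len(ncl)) {
      sel <- nodecomp == c
      nodepos[c, ] <- c(mean(ii[sel]), mean(jj[sel]))
    }

  edges <- list()
  used_step <- new.env(hash = TRUE)  # directed first/last steps already traced
  step_key <- function(a, b) paste(a, b)
  for (q in seq_along(idx)) {
    if (!isnode[q]) next
    nb <- nbrs(ii[q], jj[q])
    for (r in seq_len(nrow(nb))) {
      qq <- pos[key(nb[r, 1], nb[r, 2])]
      if (isnode[qq] && nodecomp[qq] == nodecomp[q]) next  # internal to cluster
      sk <- step_key(q, qq)
      if (!is.null(used_step[[sk]])) next
      path_q <- c(q, qq)
      prev <- q; cur <- qq
      while (!isnode[cur]) {
        nb2 <- nbrs(ii[cur], jj[cur])
        cand <- pos[key(nb2[, 1], nb2[, 2])]
        cand <- cand[cand != prev]
        if (length(cand) == 0) break         # dangling end (shouldn't happen)
        if (length(cand) > 1) {
          # prefer a node pixel if present (diagonal ambiguity)
          cn <- cand[isnode[cand]]
          cand <- if (length(cn)) cn[1] else cand[1]
        }
        prev <- cur; cur <- cand
        path_q <- c(path_q, cur)
      }
      used_step[[sk]] <- TRUE
      used_step[[step_key(cur, prev)]] <- TRUE
      edges[[length(edges) + 1L]] <-
        make_edge(path_q, ii, jj, nodecomp, nodepos, px, xmin, ymin)
    }
  }
  # pure loops: degree-2 pixels not visited by any edge
  visited <- logical(length(idx))
  for (e in edges) visited[e$pixels] <- TRUE
  for (q in seq_along(idx)) {
    if (isnode[q] || visited[q]) next
    # start a loop here: walk until we return
    nb <- nbrs(ii[q], jj[q])
    start_nb <- pos[key(nb[1, 1], nb[1, 2])]
    path_q <- c(q, start_nb)
    prev <- q; cur <- start_nb
    while (cur != q) {
      nb2 <- nbrs(ii[cur], jj[cur])
      cand <- pos[key(nb2[, 1], nb2[, 2])]
      cand <- cand[cand != prev]
      if (!length(cand)) break
      prev <- cur; cur <- cand[1]
      path_q <- c(path_q, cur)
    }
    visited[path_q] <- TRUE
    # loop node at the start pixel
    ncl <- ncl + 1L
    nodepos <- rbind(nodepos, c(ii[q], jj[q]))
    nodecomp[q] <- ncl
    isnode[q] <- TRUE
    edges[[length(edges) + 1L]] <-
      make_edge(path_q, ii, jj, nodecomp, nodepos, px, xmin, ymin)
  }
  for (k in seq_along(edges)) edges[[k]]$pixels <- NULL
  nodes_world <- cbind(xmin + (nodepos[, 1] - 0.5) * px,
                       ymin + (nodepos[, 2] - 0.5) * px)
  fold_network(nodes_world, edges, toepad_length)
}

make_edge <- function(path_q, ii, jj, nodecomp, nodepos, px, xmin, ymin) {
  from <- nodecomp[path_q[1]]
  to <- nodecomp[path_q[length(path_q)]]
  pp <- cbind(ii[path_q], jj[path_q])
  # snap endpoints to the node cluster centroid so geometry is consistent
  pp[1, ] <- nodepos[from, ]
  pp[nrow(pp), ] <- nodepos[to, ]
  world <- cbind(xmin + (pp[, 1] - 0.5) * px, ymin + (pp[, 2] - 0.5) * px)
  len <- sum(sqrt(rowSums((world[-1, , drop = FALSE] -
                           world[-nrow(world), , drop = FALSE])^2)))
  list(from = from, to = to, path = world, length = max(len, 1e-12),
       pixels = path_q)
}

#' Fold-network extraction pipeline for a deformed surface
#'
#' Minimum principal curvature, quantile fold mask, raster skeletonization,
#' graph simplification and the two-component metric in one call.
#'
#' @param surface A [surface_mesh()] (e.g. `sim_state$surface`).
#' @param quantile Curvature quantile for [extract_fold_mask()].
#' @param spur_fraction Spur-pruning fraction for [simplify_network()].
#' @param projection_axis Viewing axis for the 2D projection.
#' @param pixel_size Optional raster pixel size.
#' @param min_curvature Curvature-magnitude floor passed to
#'   [extract_fold_mask()] (default 0).
#' @return List with `network` (simplified [fold_network()]) and `metrics`
#'   (raw metric vector).
#' @export
fold_pipeline <- function(surface, quantile = 0.3, spur_fraction = 0.02,
                          projection_axis = "z", pixel_size = NULL,
                          min_curvature = 0) {
  curv <- min_principal_curvature(surface)
  mask <- extract_fold_mask(curv, quantile, min_curvature)
  raw <- skeletonize_fold_mask(surface, mask, projection_axis, pixel_size)
  net <- simplify_network(raw, spur_fraction)
  list(network = net, metrics = compute_metrics(net))
}
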