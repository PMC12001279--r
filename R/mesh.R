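#' Layered tetrahedral mesh
#'
#' The geometric input of the simulator: node positions in the reference
#' configuration, tetrahedra, a tissue-layer label per element
#' (`"epidermis"` or `"dermis"`), the set of nodes clamped to the rigid
#' muscle core (or base), a unit reference normal per element (the direction
#' of normal growth), and the boundary surface triangulation with the outer
#' (skin) surface flagged.
#'
#' @param nodes Numeric matrix `n x 3` of reference positions.
#' @param tets Integer matrix `m x 4` (1-based node indices, positive volume).
#' @param layer Character vector length `m`, `"epidermis"` or `"dermis"`.
#' @param fixed_nodes Integer vector of clamped node indices.
#' @param normals Numeric matrix `m x 3` of unit reference normals.
#' @param surface_tris Integer matrix `k x 3`, outward oriented boundary
#'   triangles.
#' @param outer_tris Logical length `k`; `TRUE` for triangles on the outer
#'   epidermis surface.
#' @return An object of class `layered_tet_mesh`.
#' @export
layered_tet_mesh <- function(nodes, tets, layer, fixed_nodes, normals,
                             surface_tris, outer_tris) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L,
            length(layer) == nrow(tets),
            all(layer %in% c("epidermis", "dermis")),
            nrow(normals) == nrow(tets),
            all(fixed_nodes >= 1L), all(fixed_nodes <= nrow(nodes)))
  nrm <- sqrt(rowSums(normals^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("reference normals must be unit vectors")
  v <- tet_volumes(nodes, tets)
  if (any(v <= 0)) stop("mesh contains inverted or degenerate tetrahedra")
  structure(list(nodes = nodes, tets = tets, layer = layer,
                 fixed_nodes = as.integer(fixed_nodes),
                 normals = as.matrix(normals),
                 surface_tris = as.matrix(surface_tris),
                 outer_tris = outer_tris),
            class = "layered_tet_mesh")
}

#' @export
print.layered_tet_mesh <- function(x, ...) {
  cat(sprintf(
    "<layered_tet_mesh> %d nodes, %d tets (%d epidermis / %d dermis), %d fixed, %d surface tris\n",
    nrow(x$nodes), nrow(x$tets), sum(x$layer == "epidermis"),
    sum(x$layer == "dermis"), length(x$fixed_nodes), nrow(x$surface_tris)))
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param nodes `n x 3` position matrix.
#' @param tets `m x 4` index matrix.
#' @return Numeric vector of signed volumes.
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

#' Total mesh volume
#' @param mesh A [layered_tet_mesh()].
#' @return Scalar volume.
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh$nodes, mesh$tets))

#' Element quality (normalized volume-to-edge ratio)
#'
#' `q = 6 sqrt(2) V / l_max^3`, equal to 1 for the regular tetrahedron and
#' approaching 0 for slivers.
#'
#' @param mesh A [layered_tet_mesh()].
#' @return Numeric vector of per-element quality scores in `(0, 1]`.
#' @export
mesh_quality <- function(mesh) {
  v <- tet_volumes(mesh$nodes, mesh$tets)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  lmax2 <- rep(0, nrow(mesh$tets))
  for (p in seq_len(6)) {
    d <- mesh$nodes[mesh$tets[, pairs[p, 1]], , drop = FALSE] -
         mesh$nodes[mesh$tets[, pairs[p, 2]], , drop = FALSE]
    lmax2 <- pmax(lmax2, rowSums(d^2))
  }
  6 * sqrt(2) * v / lmax2^1.5
}

# Boundary faces of a tet mesh, outward oriented.
# Returns list(tris = k x 3 matrix, elem = owning element index).
boundary_faces <- function(nodes, tets) {
  # local faces with outward orientation for a positively oriented tet (a,b,c,d)
  faces <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
                 tets[, c(2, 3, 4)], tets[, c(1, 4, 3)])
  elem <- rep(seq_len(nrow(tets)), 4)
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  keep <- key %in% names(tab)[tab == 1L]
  list(tris = faces[keep, , drop = FALSE], elem = elem[keep])
}

# Orient each tet to positive volume by swapping two vertices where needed.
orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  flip <- which(v < 0)
  if (length(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  tets
}

#' Deformed boundary surface of a simulated mesh
#'
#' Builds a triangulated surface from the mesh's boundary using the supplied
#' nodal positions (typically the steady state of [relax_to_steady_state()]).
#'
#' @param mesh A [layered_tet_mesh()].
#' @param positions `n x 3` nodal positions; defaults to the reference.
#' @param which `"outer"` for the outer epidermis surface only, `"all"` for
#'   the whole boundary.
#' @return A [surface_mesh()].
#' @export
deformed_surface <- function(mesh, positions = mesh$nodes, which = "outer") {
  which <- match.arg(which, c("outer", "all"))
  tris <- if (which == "outer") {
    mesh$surface_tris[mesh$outer_tris, , drop = FALSE]
  } else mesh$surface_tris
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(mesh$nodes)); remap[used] <- seq_along(used)
  surface_mesh(positions[used, , drop = FALSE],
               matrix(remap[tris], ncol = 3))
}
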