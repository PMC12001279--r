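#' Specification of a rectangular bilayer skin slab
#'
#' Test geometry for the growth model: a flat epidermis film bonded to a
#' dermis substrate, clamped at its base (the rigid muscle). The outer
#' surface is the plane `z = 0`; the tissue occupies
#' `z` in `[-(t_e + t_d), 0]`.
#'
#' @param lateral_extent_x,lateral_extent_y Slab size in the plane (model
#'   length units).
#' @param thickness_epidermis,thickness_dermis Layer thicknesses.
#' @param target_edge_length Requested element edge length; must not exceed
#'   the thinner layer. The dermis is meshed with geometrically coarsening
#'   layers away from the interface (fine resolution is only needed where
#'   folds form).
#' @return An object of class `bilayer_slab_spec`.
#' @export
bilayer_slab_spec <- function(lateral_extent_x, lateral_extent_y,
                              thickness_epidermis, thickness_dermis,
                              target_edge_length) {
  s <- list(lateral_extent_x = lateral_extent_x,
            lateral_extent_y = lateral_extent_y,
            thickness_epidermis = thickness_epidermis,
            thickness_dermis = thickness_dermis,
            target_edge_length = target_edge_length)
  if (any(!vapply(s, function(v) is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, TRUE)))
    stop("all slab spec fields must be positive finite scalars")
  if (target_edge_length > min(thickness_epidermis, thickness_dermis) + 1e-12)
    stop("target_edge_length must not exceed the thinner layer")
  structure(s, class = "bilayer_slab_spec")
}

# geometric grading of layer heights from `h0` covering total thickness `tot`
graded_heights <- function(tot, h0, ratio = 1.4, hmax = Inf) {
  h <- numeric(0); s <- 0; cur <- h0
  while (s < tot - 1e-12) {
    h <- c(h, min(cur, hmax)); s <- s + h[length(h)]; cur <- cur * ratio
  }
  h * (tot / sum(h))   # rescale to fit exactly
}

# Kuhn/Freudenthal split of one hexahedron given its 8 corner ids
# corners indexed c[dx, dy, dz] with dx,dy,dz in 1:2
kuhn_tets <- function(cid) {
  # cid: function(dx, dy, dz) -> node id, offsets in 0/1
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- matrix(0L, 6, 4)
  for (p in seq_along(perms)) {
    e <- diag(3)[perms[[p]], , drop = FALSE]
    v1 <- c(0, 0, 0); v2 <- e[1, ]; v3 <- e[1, ] + e[2, ]; v4 <- c(1, 1, 1)
    out[p, ] <- c(cid(v1), cid(v2), cid(v3), cid(v4))
  }
  out
}

#' Generate a layered bilayer slab mesh
#'
#' Structured grid, each hexahedral cell split into six conforming
#' tetrahedra. Elements are labelled epidermis when their centroid depth
#' below the outer surface is less than `thickness_epidermis`; the bottom
#' face is clamped (rigid boundary) and the reference normal field is the
#' outward surface direction `(0, 0, 1)` everywhere.
#'
#' @param spec A [bilayer_slab_spec()].
#' @param clamp_sides `FALSE` (default, base only), `"x"` (also clamp the
#'   two faces normal to x) or `"all"` (clamp all four lateral faces).
#'   Clamping emulates skin confined by surrounding tissue, the boundary
#'   condition under which film growth is forced into compression (the
#'   classical film-on-substrate wrinkling setup); `"x"` leaves the y faces
#'   free so stripe modes uniform in y are admissible on narrow slabs.
#' @return A [layered_tet_mesh()].
#' @examples
#' m <- make_bilayer_slab(bilayer_slab_spec(1, 1, 0.05, 0.15, 0.05))
#' abs(mesh_volume(m) - 0.2) < 2e-3
#' @export
make_bilayer_slab <- function(spec, clamp_sides = FALSE) {
  stopifnot(inherits(spec, "bilayer_slab_spec"))
  h <- spec$target_edge_length
  nx <- max(2L, round(spec$lateral_extent_x / h))
  ny <- max(2L, round(spec$lateral_extent_y / h))
  xs <- seq(0, spec$lateral_extent_x, length.out = nx + 1L)
  ys <- seq(0, spec$lateral_extent_y, length.out = ny + 1L)
  n_epi <- max(2L, round(spec$thickness_epidermis / h))
  he <- rep(spec$thickness_epidermis / n_epi, n_epi)
  hd <- graded_heights(spec$thickness_dermis, h0 = he[1], ratio = 1.4,
                       hmax = 4 * h)
  zs <- c(0, -cumsum(c(he, hd)))          # from surface downwards
  nz <- length(zs) - 1L
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))[, c("x", "y", "z")]
  colnames(nodes) <- NULL

  tets <- vector("list", nx * ny * nz)
  idx <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    cid <- function(d) nid(i + d[1], j + d[2], k + d[3])
    idx <- idx + 1L
    tets[[idx]] <- kuhn_tets(cid)
  }
  tets <- do.call(rbind, tets)
  tets <- orient_tets(nodes, tets)

  cz <- (nodes[tets[, 1], 3] + nodes[tets[, 2], 3] +
         nodes[tets[, 3], 3] + nodes[tets[, 4], 3]) / 4
  layer <- ifelse(-cz < spec$thickness_epidermis, "epidermis", "dermis")
  fixed <- which(abs(nodes[, 3] - min(zs)) < 1e-12)
  if (!isFALSE(clamp_sides)) {
    clamp_sides <- match.arg(clamp_sides, c("x", "all"))
    eps <- 1e-12
    side <- nodes[, 1] < eps | nodes[, 1] > spec$lateral_extent_x - eps
    if (clamp_sides == "all")
      side <- side | nodes[, 2] < eps | nodes[, 2] > spec$lateral_extent_y - eps
    fixed <- sort(union(fixed, which(side)))
  }
  normals <- matrix(rep(c(0, 0, 1), each = nrow(tets)), ncol = 3)
  bf <- boundary_faces(nodes, tets)
  # outer surface = triangles lying in the z = 0 plane
  topc <- (nodes[bf$tris[, 1], 3] + nodes[bf$tris[, 2], 3] +
           nodes[bf$tris[, 3], 3]) / 3
  outer <- abs(topc) < 1e-12
  layered_tet_mesh(nodes, tets, layer, fixed, normals, bf$tris, outer)
}

#' Specification of a dome-shaped toepad mesh
#'
#' A spherical-cap bilayer shell: epidermis over dermis, resting on a rigid
#' muscle core whose interface sits at depth `rigid_core_offset` below the
#' outer surface. Interface nodes are clamped.
#'
#' @param base_radius Radius of the dome base (model length units).
#' @param dome_height Apex height above the base plane.
#' @param thickness_epidermis Epidermal shell thickness.
#' @param rigid_core_offset Depth of the dermis-muscle interface below the
#'   outer surface; must satisfy
#'   `thickness_epidermis < rigid_core_offset < dome_height`.
#' @param target_edge_length Requested in-plane element edge length.
#' @return An object of class `toepad_dome_spec`.
#' @export
toepad_dome_spec <- function(base_radius, dome_height, thickness_epidermis,
                             rigid_core_offset, target_edge_length) {
  s <- list(base_radius = base_radius, dome_height = dome_height,
            thickness_epidermis = thickness_epidermis,
            rigid_core_offset = rigid_core_offset,
            target_edge_length = target_edge_length)
  if (any(!vapply(s, function(v) is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, TRUE)))
    stop("all dome spec fields must be positive finite scalars")
  if (!(thickness_epidermis < rigid_core_offset && rigid_core_offset < dome_height))
    stop("need thickness_epidermis < rigid_core_offset < dome_height")
  structure(s, class = "toepad_dome_spec")
}

# Triangulated disc of radius R from an equilateral lattice of spacing a.
# Triangles whose centroid falls inside the disc are kept; vertices outside
# are radially snapped to the rim, giving full disc coverage.
disc_triangulation <- function(R, a) {
  jmax <- ceiling(R / (a * sqrt(3) / 2)) + 1L
  rows <- -jmax:jmax
  imax <- ceiling(2 * R / a) + jmax + 2L
  pts <- list(); id <- matrix(NA_integer_, length(rows), 2L * imax + 1L)
  cnt <- 0L
  for (jj in seq_along(rows)) {
    j <- rows[jj]
    for (ii in seq_len(2L * imax + 1L)) {
      i <- ii - imax - 1L
      x <- (i + j / 2) * a; y <- j * a * sqrt(3) / 2
      if (x * x + y * y <= (R + a)^2) {
        cnt <- cnt + 1L; id[jj, ii] <- cnt
        pts[[cnt]] <- c(x, y)
      }
    }
  }
  pts <- do.call(rbind, pts)
  tris <- list(); t <- 0L
  for (jj in seq_len(length(rows) - 1L)) for (ii in seq_len(2L * imax)) {
    # upward triangle (i,j) (i+1,j) (i,j+1); downward (i+1,j) (i+1,j+1) (i,j+1)
    v <- c(id[jj, ii], id[jj, ii + 1L], id[jj + 1L, ii])
    if (!anyNA(v)) { t <- t + 1L; tris[[t]] <- v }
    v <- c(id[jj, ii + 1L], id[jj + 1L, ii + 1L], id[jj + 1L, ii])
    if (!anyNA(v)) { t <- t + 1L; tris[[t]] <- v }
  }
  tris <- do.call(rbind, tris)
  signed_area <- function(p, tr) {
    ((p[tr[, 2], 1] - p[tr[, 1], 1]) * (p[tr[, 3], 2] - p[tr[, 1], 2]) -
     (p[tr[, 3], 1] - p[tr[, 1], 1]) * (p[tr[, 2], 2] - p[tr[, 1], 2])) / 2
  }
  inside <- rowSums(pts^2) <= R^2 * (1 + 1e-12)
  # keep triangles touching the disc; snap outside vertices to the rim
  keep <- inside[tris[, 1]] | inside[tris[, 2]] | inside[tris[, 3]]
  tris <- tris[keep, , drop = FALSE]
  a0 <- signed_area(pts, tris)
  r <- sqrt(rowSums(pts^2))
  out <- r > R
  pts[out, ] <- pts[out, , drop = FALSE] * (R / r[out])
  a1 <- signed_area(pts, tris)
  # drop triangles degenerated or flipped by the rim snap
  tris <- tris[a1 * sign(a0) > 1e-6 * a^2, , drop = FALSE]
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(pts)); remap[used] <- seq_along(used)
  list(pts = pts[used, , drop = FALSE], tris = matrix(remap[tris], ncol = 3))
}

# Dompierre-style conforming split of a prism (bottom tri b1 b2 b3,
# top tri t1 t2 t3 with ti above bi) into 3 tets, using global vertex ids
# so that shared quad faces of adjacent prisms receive the same diagonal.
split_prism <- function(v) {
  # v = c(b1, b2, b3, t1, t2, t3)
  perms <- rbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
                 c(4, 6, 5, 1, 3, 2), c(5, 4, 6, 2, 1, 3), c(6, 5, 4, 3, 2, 1))
  # rotate so the smallest global id sits in slot 1 (orientation-preserving)
  k <- which(apply(perms, 1, function(p) v[p[1]] == min(v)))[1]
  w <- v[perms[k, ]]
  if (min(w[2], w[6]) < min(w[3], w[5])) {
    rbind(w[c(1, 2, 3, 6)], w[c(1, 2, 6, 5)], w[c(1, 5, 6, 4)])
  } else {
    rbind(w[c(1, 2, 3, 5)], w[c(1, 3, 6, 5)], w[c(1, 5, 6, 4)])
  }
}

#' Generate a dome-shaped layered toepad mesh
#'
#' A spherical-cap shell between the outer skin surface and the rigid
#' muscle interface at depth `rigid_core_offset`, meshed as stacked prism
#' layers split into conforming tetrahedra. The epidermis is always at
#' least two element layers thick; interface nodes are clamped; the
#' reference normal of each element is the outward radial direction (the
#' smoothed normal of the nearest outer-surface triangle).
#'
#' @param spec A [toepad_dome_spec()].
#' @return A [layered_tet_mesh()].
#' @export
make_toepad_dome <- function(spec) {
  stopifnot(inherits(spec, "toepad_dome_spec"))
  R <- spec$base_radius; H <- spec$dome_height
  te <- spec$thickness_epidermis; off <- spec$rigid_core_offset
  a <- spec$target_edge_length
  if (a > te * 2) stop("epidermal shell thinner than two elements at this ",
                       "target_edge_length; refine the mesh")
  Rs <- (R^2 + H^2) / (2 * H)            # sphere radius of the outer cap
  zc <- H - Rs                            # sphere centre (0, 0, zc)
  disc <- disc_triangulation(R, a)

  n_epi <- max(2L, round(te / a))
  he <- rep(te / n_epi, n_epi)
  hd <- graded_heights(off - te, h0 = he[1], ratio = 1.4, hmax = 2 * a)
  depths <- c(0, cumsum(c(he, hd)))       # depth below outer surface
  nlay <- length(depths)

  npts <- nrow(disc$pts)
  nodes <- matrix(0, npts * nlay, 3)
  for (l in seq_len(nlay)) {
    x <- disc$pts[, 1]; y <- disc$pts[, 2]
    zo <- zc + sqrt(pmax(Rs^2 - x^2 - y^2, 0))
    u <- cbind(x, y, zo - zc); u <- u / sqrt(rowSums(u^2))
    p <- u * (Rs - depths[l]); p[, 3] <- p[, 3] + zc
    nodes[(l - 1L) * npts + seq_len(npts), ] <- p
  }

  tets <- vector("list", nrow(disc$tris) * (nlay - 1L)); idx <- 0L
  for (l in seq_len(nlay - 1L)) {
    topoff <- (l - 1L) * npts; botoff <- l * npts
    for (t in seq_len(nrow(disc$tris))) {
      tri <- disc$tris[t, ]
      idx <- idx + 1L
      tets[[idx]] <- split_prism(c(botoff + tri, topoff + tri))
    }
  }
  tets <- do.call(rbind, tets)
  tets <- orient_tets(nodes, tets)

  cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
          nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  dc <- sweep(cen, 2, c(0, 0, zc))
  depth_c <- Rs - sqrt(rowSums(dc^2))
  layer <- ifelse(depth_c < te, "epidermis", "dermis")
  normals <- dc / sqrt(rowSums(dc^2))

  fixed <- (nlay - 1L) * npts + seq_len(npts)   # muscle interface layer
  bf <- boundary_faces(nodes, tets)
  outer <- matrixStats_rowmax3(bf$tris) <= npts # all three vertices on layer 1
  layered_tet_mesh(nodes, tets, layer, fixed, normals, bf$tris, outer)
}

# max of the three columns, avoiding a matrixStats dependency
matrixStats_rowmax3 <- function(m) pmax(m[, 1], m[, 2], m[, 3])
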