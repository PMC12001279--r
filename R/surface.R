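#' Triangulated surface mesh
#'
#' @param vertices Numeric `n x 3` matrix.
#' @param triangles Integer `k x 3` matrix (1-based, consistently oriented
#'   with outward normals).
#' @return An object of class `surface_mesh` with area-weighted outward unit
#'   vertex `normals`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(triangles) == 3L,
            min(triangles) >= 1L, max(triangles) <= nrow(vertices))
  fn <- face_normals(vertices, triangles)            # area-weighted
  vn <- matrix(0, nrow(vertices), 3)
  for (c in 1:3) {
    for (j in 1:3) {
      vn[, j] <- vn[, j] + tabulate2(triangles[, c], fn[, j], nrow(vertices))
    }
  }
  nn <- sqrt(rowSums(vn^2)); nn[nn == 0] <- 1
  structure(list(vertices = vertices, triangles = triangles,
                 normals = vn / nn),
            class = "surface_mesh")
}

tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# per-face normals scaled by twice the area
face_normals <- function(v, tr) {
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Icosphere test surface
#'
#' Recursive subdivision of an icosahedron projected to the sphere, with
#' outward orientation. Used as an analytic fixture (curvature, thickness).
#'
#' @param subdivisions Number of 4-to-1 refinements (0 = icosahedron).
#' @param radius Sphere radius.
#' @return A [surface_mesh()].
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid[[key]]
      if (is.null(id)) {
        p <- v[a, ] + v[b, ]
        p <- p / sqrt(sum(p^2))
        v <<- rbind(v, p)
        id <- nrow(v)
        mid[[key]] <- id
      }
      id
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  surface_mesh(v * radius, f)
}

#' Minimum principal curvature of a surface mesh
#'
#' Discrete principal curvatures from the cotangent mean-curvature normal
#' and angle-defect Gaussian curvature, `kappa = H -/+ sqrt(H^2 - K)`.
#' Sign convention: a unit sphere with outward normals has
#' `kappa_min = +1`; fold valleys (concave creases) have `kappa_min < 0`.
#' Boundary vertices inherit the mean of their interior neighbours.
#'
#' @param surface A [surface_mesh()].
#' @return A list of class `curvature_field` with per-vertex `kappa_min`,
#'   `kappa_max`, `H`, `K`.
#' @export
min_principal_curvature <- function(surface) {
  stopifnot(inherits(surface, "surface_mesh"))
  v <- surface$vertices; tr <- surface$triangles
  n <- nrow(v); m <- nrow(tr)

  # edge manifoldness: every undirected edge in at most 2 triangles
  ekey <- c(paste(pmin(tr[, 1], tr[, 2]), pmax(tr[, 1], tr[, 2])),
            paste(pmin(tr[, 2], tr[, 3]), pmax(tr[, 2], tr[, 3])),
            paste(pmin(tr[, 3], tr[, 1]), pmax(tr[, 3], tr[, 1])))
  etab <- table(ekey)
  if (any(etab > 2)) stop("non-manifold surface: an edge borders > 2 triangles")
  boundary_edges <- names(etab)[etab == 1]

  Lx <- matrix(0, n, 3)   # cotan Laplacian applied to positions
  angsum <- numeric(n)
  corners <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  cot3 <- matrix(0, m, 3)
  ang3 <- matrix(0, m, 3)
  tarea <- numeric(m)
  for (c in 1:3) {
    id <- corners[[c]]
    a <- v[tr[, id[1]], , drop = FALSE]
    b <- v[tr[, id[2]], , drop = FALSE]
    d <- v[tr[, id[3]], , drop = FALSE]
    u1 <- b - a; u2 <- d - a
    cr <- face_normals_rows(u1, u2)
    crn <- sqrt(rowSums(cr^2)); crn[crn == 0] <- 1e-300
    cot3[, c] <- rowSums(u1 * u2) / crn              # cot of angle at id[1]
    ang3[, c] <- atan2(crn, rowSums(u1 * u2))
    angsum <- angsum + tabulate2(tr[, id[1]], ang3[, c], n)
    tarea <- crn / 2
  }
  # Meyer mixed-Voronoi vertex areas
  area <- numeric(n)
  obtuse <- ang3 > pi / 2
  anyobt <- obtuse[, 1] | obtuse[, 2] | obtuse[, 3]
  for (c in 1:3) {
    id <- corners[[c]]
    i <- tr[, id[1]]
    # voronoi part at corner c: 1/8 (|e_b|^2 cot(beta) + |e_c|^2 cot(gamma))
    eb <- v[tr[, id[3]], , drop = FALSE] - v[tr[, id[1]], , drop = FALSE]
    ec <- v[tr[, id[2]], , drop = FALSE] - v[tr[, id[1]], , drop = FALSE]
    avor <- (rowSums(eb^2) * cot3[, id[2]] + rowSums(ec^2) * cot3[, id[3]]) / 8
    amix <- ifelse(anyobt, ifelse(obtuse[, c], tarea / 2, tarea / 4), avor)
    area <- area + tabulate2(i, amix, n)
  }
  # cot at corner c weights edge (other two corners)
  for (c in 1:3) {
    id <- corners[[c]]
    i <- tr[, id[2]]; j <- tr[, id[3]]
    w <- cot3[, c] / 2
    dij <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    for (k in 1:3) {
      Lx[, k] <- Lx[, k] + tabulate2(i, w * dij[, k], n)
      Lx[, k] <- Lx[, k] - tabulate2(j, w * dij[, k], n)
    }
  }
  on_boundary <- rep(FALSE, n)
  if (length(boundary_edges)) {
    bidx <- unique(as.integer(unlist(strsplit(boundary_edges, " "))))
    on_boundary[bidx] <- TRUE
  }
  H <- -rowSums(Lx * surface$normals) / (2 * area)  # signed mean curvature
  K <- (2 * pi - angsum) / area
  disc <- pmax(H^2 - K, 0)
  kmin <- H - sqrt(disc)
  kmax <- H + sqrt(disc)

  if (any(on_boundary)) {
    # boundary vertices inherit the mean of their interior neighbours
    adj <- edges_of(tr)
    fill <- function(val) {
      val[on_boundary] <- NA
      for (rep in 1:4) {
        na <- which(is.na(val))
        if (!length(na)) break
        for (i in na) {
          vals <- val[adj[[i]]]
          vals <- vals[!is.na(vals)]
          if (length(vals)) val[i] <- mean(vals)
        }
      }
      val[is.na(val)] <- 0
      val
    }
    kmin <- fill(kmin)
    kmax <- fill(kmax)
  }
  structure(list(kappa_min = kmin, kappa_max = kmax, H = H, K = K,
                 boundary = on_boundary),
            class = "curvature_field")
}

face_normals_rows <- function(u1, u2) {
  cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
        u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
        u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
}

edges_of <- function(tr) {
  n <- max(tr)
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  split(e[, 2], factor(e[, 1], levels = seq_len(n)))
}

#' Select fold-valley vertices from a curvature field
#'
#' Vertices whose minimum principal curvature lies below both zero and the
#' `q`-quantile of the field: the most strongly concave fraction of the
#' surface, where fold valleys run.
#'
#' @param curv A `curvature_field` from [min_principal_curvature()].
#' @param q Quantile in (0, 1); default 0.3.
#' @param min_magnitude Optional curvature-magnitude floor (1/length,
#'   default 0): vertices must be concave by at least this much. Nearly
#'   flat surfaces carry shallow spurious valleys (boundary transitions,
#'   residual relaxation ripples) whose curvature is orders of magnitude
#'   below a true fold's `~1/thickness`; a floor excludes them.
#' @return Logical per-vertex mask.
#' @export
extract_fold_mask <- function(curv, q = 0.3, min_magnitude = 0) {
  stopifnot(inherits(curv, "curvature_field"), q > 0, q < 1,
            min_magnitude >= 0)
  thr <- stats::quantile(curv$kappa_min, q, names = FALSE)
  curv$kappa_min < pmin(thr, -min_magnitude)
}

#' Per-vertex layer thickness between two roughly parallel surfaces
#'
#' Distance from each vertex of `outer` to the closest point of the `inner`
#' triangulated surface (exact point-triangle distances).
#'
#' @param outer,inner [surface_mesh()] objects.
#' @return Numeric vector, one thickness per outer vertex.
#' @export
layer_thickness <- function(outer, inner) {
  stopifnot(inherits(outer, "surface_mesh"), inherits(inner, "surface_mesh"))
  .point_surface_dist(outer$vertices, inner$vertices, inner$triangles)
}
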