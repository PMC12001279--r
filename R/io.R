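#' Write a layered mesh as TetGen .node/.ele plus a sidecar JSON
#'
#' `<basename>.node` and `<basename>.ele` follow the TetGen ASCII format
#' (1-based indices); `<basename>.json` stores the per-element layer
#' labels, the fixed-node set, the reference normal field and the outer
#' surface triangles.
#'
#' @param mesh A [layered_tet_mesh()].
#' @param basename Path prefix (without extension).
#' @return `basename`, invisibly.
#' @export
write_mesh_tetgen <- function(mesh, basename) {
  nf <- paste0(basename, ".node")
  n <- nrow(mesh$nodes)
  cat(sprintf("%d 3 0 0\n", n), file = nf)
  utils::write.table(cbind(seq_len(n), mesh$nodes), nf, append = TRUE,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  ef <- paste0(basename, ".ele")
  m <- nrow(mesh$tets)
  cat(sprintf("%d 4 0\n", m), file = ef)
  utils::write.table(cbind(seq_len(m), mesh$tets), ef, append = TRUE,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  side <- list(layer = mesh$layer, fixed_nodes = mesh$fixed_nodes,
               normals = mesh$normals,
               surface_tris = mesh$surface_tris,
               outer_tris = mesh$outer_tris)
  jsonlite::write_json(side, paste0(basename, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(basename)
}

#' Read a layered mesh written by [write_mesh_tetgen()]
#' @param basename Path prefix used when writing.
#' @return A [layered_tet_mesh()].
#' @export
read_mesh_tetgen <- function(basename) {
  nd <- utils::read.table(paste0(basename, ".node"), skip = 1)
  el <- utils::read.table(paste0(basename, ".ele"), skip = 1)
  side <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  layered_tet_mesh(unname(as.matrix(nd[, 2:4])), unname(as.matrix(el[, 2:5])),
                   side$layer, side$fixed_nodes,
                   matrix(unlist(side$normals), ncol = 3),
                   matrix(as.integer(unlist(side$surface_tris)), ncol = 3),
                   side$outer_tris)
}

#' Write a surface mesh as ASCII PLY
#' @param surface A [surface_mesh()].
#' @param path Output file.
#' @export
write_surface_ply <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(surface$vertices); nf <- nrow(surface$triangles)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(surface$vertices, 1, paste, collapse = " "), con)
  writeLines(paste("3", surface$triangles[, 1] - 1L,
                   surface$triangles[, 2] - 1L, surface$triangles[, 3] - 1L),
             con)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#' @param path PLY file (ascii format, triangles only).
#' @return A [surface_mesh()].
#' @export
read_surface_ply <- function(path) {
  lines <- readLines(path)
  hend <- match("end_header", lines)
  if (is.na(hend)) stop("not a PLY file (no end_header)")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  if (any(grepl("format binary", lines[seq_len(hend)])))
    stop("binary PLY unsupported; write ascii")
  vd <- do.call(rbind, lapply(strsplit(trimws(lines[hend + seq_len(nv)]), "\\s+"),
                              function(s) as.numeric(s[1:3])))
  fd <- do.call(rbind, lapply(strsplit(trimws(lines[hend + nv + seq_len(nf)]), "\\s+"),
                              function(s) as.integer(s[2:4]) + 1L))
  surface_mesh(vd, fd)
}

#' Write a fold network as JSON
#'
#' Stores nodes, polyline edges (with endpoints and arc length), the cycle
#' (domain) edge sets, incomplete-edge ids and the toepad length.
#'
#' @param net A [fold_network()] (classified).
#' @param path Output file.
#' @export
write_network_json <- function(net, path) {
  if (is.null(net$cycles)) net <- classify_network_edges(net)
  obj <- list(
    toepad_length = net$toepad_length,
    nodes = net$nodes,
    edges = lapply(net$edges, function(e)
      list(from = e$from, to = e$to, length = e$length, path = e$path)),
    cycles = net$cycles,
    incomplete = net$incomplete)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fold network from JSON
#' @param path File written by [write_network_json()].
#' @return A classified [fold_network()].
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- lapply(seq_len(length(obj$edges$from)), function(i)
    list(from = obj$edges$from[i], to = obj$edges$to[i],
         length = obj$edges$length[i],
         path = matrix(unlist(obj$edges$path[[i]]), ncol = 2)))
  if (is.data.frame(obj$edges)) {
    edges <- lapply(seq_len(nrow(obj$edges)), function(i)
      list(from = obj$edges$from[i], to = obj$edges$to[i],
           length = obj$edges$length[i],
           path = matrix(unlist(obj$edges$path[[i]]), ncol = 2)))
  }
  net <- fold_network(matrix(unlist(obj$nodes), ncol = 2), edges,
                      obj$toepad_length)
  classify_network_edges(net)
}

#' Export a fold network to GraphML
#'
#' Node coordinates and edge lengths are stored as attributes; polyline
#' geometry is not representable in GraphML and is dropped.
#'
#' @param net A [fold_network()].
#' @param path Output file.
#' @export
write_network_graphml <- function(net, path) {
  g <- net_igraph(net)
  igraph::V(g)$x <- net$nodes[seq_len(igraph::vcount(g)), 1]
  igraph::V(g)$y <- net$nodes[seq_len(igraph::vcount(g)), 2]
  igraph::E(g)$length <- vapply(net$edges, function(e) e$length, 0)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a 3D volume as multi-page TIFF
#'
#' One 32-bit float page per z-slice (requires the `tiff` package).
#'
#' @param vol 3D numeric array.
#' @param path Output file.
#' @param labels If `TRUE`, write an 8-bit label volume (integer ids
#'   0-255); otherwise 32-bit float intensities, affinely rescaled to
#'   `[0, 1]` with the transform recorded in a `<path>.json` sidecar
#'   (the TIFF writer clips values outside that range).
#' @export
write_volume_tiff <- function(vol, path, labels = FALSE) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to write TIFF volumes")
  if (labels) {
    if (any(vol < 0 | vol > 255)) stop("label ids must be in 0..255")
    pages <- lapply(seq_len(dim(vol)[3]), function(z) t(vol[, , z]) / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  } else {
    # the tiff package clips samples to [0, 1]; rescale affinely and store
    # the transform in a sidecar so intensities round-trip exactly
    vmin <- min(vol); vmax <- max(vol)
    span <- if (vmax > vmin) vmax - vmin else 1
    pages <- lapply(seq_len(dim(vol)[3]),
                    function(z) (t(vol[, , z]) - vmin) / span)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(offset = vmin, span = span),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a multi-page TIFF volume written by [write_volume_tiff()]
#' @param path TIFF file.
#' @param labels If `TRUE`, decode an 8-bit label volume back to integer
#'   ids.
#' @return 3D numeric (or integer, for labels) array.
#' @export
read_volume_tiff <- function(path, labels = FALSE) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to read TIFF volumes")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
  if (labels) {
    arr <- round(arr * 255)
    storage.mode(arr) <- "integer"
    return(arr)
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    tf <- jsonlite::read_json(side, simplifyVector = TRUE)
    arr <- arr * tf$span + tf$offset
  }
  arr
}

#' Write detected centroids as CSV (0-based voxel coordinates)
#' @param cells A `cell_centroids` tibble (1-based coordinates).
#' @param path Output file.
#' @export
write_centroids_csv <- function(cells, path) {
  out <- as.data.frame(cells)
  out$x <- out$x - 1; out$y <- out$y - 1; out$z <- out$z - 1
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read layer material/growth parameters from YAML
#'
#' Expected structure: a mapping with `epidermis` and `dermis`, each with
#' `E`, `nu`, `lambda_T` and optional `lambda_N` (default 0) and `beta`
#' (default 1).
#'
#' @param path YAML file.
#' @return List with `materials` and `growth` ready for
#'   [relax_to_steady_state()].
#' @export
read_params_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  parse1 <- function(l) {
    stopifnot(!is.null(l$E), !is.null(l$nu), !is.null(l$lambda_T))
    list(mat = elastic_constants(l$E, l$nu),
         g = growth_law(lambda_N = l$lambda_N %||% 0,
                        lambda_T = l$lambda_T, beta = l$beta %||% 1))
  }
  e <- parse1(y$epidermis); d <- parse1(y$dermis)
  list(materials = list(epidermis = e$mat, dermis = d$mat),
       growth = list(epidermis = e$g, dermis = d$g))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an optimization result as JSON plus a history CSV
#'
#' `<basename>.json` holds the best parameters, best objective, stopping
#' reason and seed; `<basename>_history.csv` holds the full evaluation
#' history (parameters, objective, failure flag, iteration).
#'
#' @param result An `opt_result` from [bayes_optimize()].
#' @param basename Path prefix (without extension).
#' @export
write_opt_result <- function(result, basename) {
  stopifnot(inherits(result, "opt_result"))
  jsonlite::write_json(
    list(best_params = result$best_params,
         best_objective = result$best_objective,
         evaluations = nrow(result$history),
         stopped_because = result$stopped_because,
         seed = result$seed),
    paste0(basename, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(result$history),
                   paste0(basename, "_history.csv"), row.names = FALSE)
  invisible(basename)
}

#' Write a convergence log as CSV
#' @param state A `sim_state`.
#' @param path Output file.
#' @export
write_convergence_csv <- function(state, path) {
  utils::write.csv(as.data.frame(state$log), path, row.names = FALSE)
  invisible(path)
}
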