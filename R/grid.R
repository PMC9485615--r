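#' Three-layer spherical source grid
#'
#' Builds the source space: a geodesic icosphere tessellation per layer,
#' scaled to the layer radii (default 63, 73, 83 mm, i.e. 10 mm between
#' layers), with points below the cut plane removed and an orthonormal
#' tangential dipole basis at every retained point. In a homogeneous
#' spherical conductor a radial moment produces no external magnetic field,
#' so no radial basis vector is defined.
#'
#' The tangential basis is deterministic: \code{e1 = normalize(z x rhat)}
#' (falling back to \code{x x rhat} near the poles) and \code{e2 = rhat x e1}.
#'
#' @param head A \code{head_model}.
#' @param layer_radii Strictly increasing radii in mm, all inside the head.
#' @param cut_plane_z Points with z below this plane (mm) are excluded;
#'   default -10 mm approximates exclusion of points below the ears.
#' @param subdivisions Icosphere refinement per layer (default 3, giving 642
#'   points per layer before exclusion).
#' @return An object of class \code{source_grid} with fields \code{points}
#'   (P x 3 mm), \code{layer_index}, \code{basis_e1}, \code{basis_e2}
#'   (P x 3), and \code{neighbors} (list of integer vectors, see
#'   \code{\link{neighbor_sets}}).
#' @export
build_grid <- function(head = head_model(), layer_radii = c(63, 73, 83),
                       cut_plane_z = -10, subdivisions = 3L) {
  stopifnot(inherits(head, "head_model"))
  layer_radii <- as.numeric(layer_radii)
  if (any(diff(layer_radii) <= 0))
    stop("'layer_radii' must be strictly increasing")
  if (any(layer_radii >= head$radius))
    stop("layer radii must be strictly inside the head sphere")
  ico <- icosphere(subdivisions)
  edges <- faces_to_edges(ico$faces)
  pts <- list(); layer <- list(); ledges <- list(); offset <- 0L
  for (l in seq_along(layer_radii)) {
    p <- ico$vertices * layer_radii[l]
    keep <- which(p[, 3] >= cut_plane_z)
    remap <- integer(nrow(p)); remap[keep] <- seq_along(keep)
    ekeep <- edges[p[edges[, 1], 3] >= cut_plane_z &
                   p[edges[, 2], 3] >= cut_plane_z, , drop = FALSE]
    pts[[l]] <- p[keep, , drop = FALSE]
    layer[[l]] <- rep(l, length(keep))
    ledges[[l]] <- cbind(remap[ekeep[, 1]], remap[ekeep[, 2]]) + offset
    offset <- offset + length(keep)
  }
  points <- do.call(rbind, pts)
  layer_index <- unlist(layer)
  edges_all <- do.call(rbind, ledges)
  basis <- tangential_basis(points)
  grid <- structure(list(points = points, layer_index = layer_index,
                         layer_radii = layer_radii,
                         basis_e1 = basis$e1, basis_e2 = basis$e2,
                         edges = edges_all, neighbors = NULL,
                         cut_plane_z = cut_plane_z,
                         subdivisions = as.integer(subdivisions)),
                    class = "source_grid")
  grid$neighbors <- neighbor_sets(grid)
  grid
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("Source grid: %d points on %d layers (radii %s mm), cut plane z >= %g mm\n",
              nrow(x$points), length(x$layer_radii),
              paste(x$layer_radii, collapse = ", "), x$cut_plane_z))
  invisible(x)
}

#' Number of points in a source grid
#' @param grid A \code{source_grid}.
#' @return Integer.
#' @export
n_points <- function(grid) nrow(grid$points)

# deterministic orthonormal tangent pair at each point
tangential_basis <- function(points) {
  rhat <- points / sqrt(rowSums(points^2))
  zx <- cbind(-rhat[, 2], rhat[, 1], 0)      # z x rhat
  polar <- sqrt(rowSums(zx^2)) < 1e-8
  if (any(polar))                            # x x rhat fallback
    zx[polar, ] <- cbind(0, -rhat[polar, 3], rhat[polar, 2])
  e1 <- zx / sqrt(rowSums(zx^2))
  e2 <- cbind(rhat[, 2] * e1[, 3] - rhat[, 3] * e1[, 2],
              rhat[, 3] * e1[, 1] - rhat[, 1] * e1[, 3],
              rhat[, 1] * e1[, 2] - rhat[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}

#' Neighbor sets of the source grid
#'
#' For every grid point: its in-layer tessellation neighbors (first ring),
#' those neighbors' neighbors (second ring), plus the single nearest point
#' from each other layer; self and duplicates removed. Interior points
#' accumulate up to 20 neighbors, points at the cut boundary fewer.
#'
#' @param grid A \code{source_grid}.
#' @return List of integer vectors, one per grid point.
#' @export
neighbor_sets <- function(grid) {
  stopifnot(inherits(grid, "source_grid"))
  P <- nrow(grid$points)
  ring1 <- vector("list", P)
  for (k in seq_len(nrow(grid$edges))) {
    i <- grid$edges[k, 1]; j <- grid$edges[k, 2]
    ring1[[i]] <- c(ring1[[i]], j)
    ring1[[j]] <- c(ring1[[j]], i)
  }
  layers <- sort(unique(grid$layer_index))
  by_layer <- lapply(layers, function(l) which(grid$layer_index == l))
  out <- vector("list", P)
  for (i in seq_len(P)) {
    r1 <- ring1[[i]]
    r2 <- unlist(ring1[r1], use.names = FALSE)
    nb <- c(r1, r2)
    for (l in layers) {
      if (l == grid$layer_index[i]) next
      cand <- by_layer[[l]]
      d2 <- rowSums((grid$points[cand, , drop = FALSE] -
                     matrix(grid$points[i, ], length(cand), 3,
                            byrow = TRUE))^2)
      nb <- c(nb, cand[which.min(d2)])
    }
    nb <- unique(nb)
    out[[i]] <- sort(nb[nb != i])
  }
  out
}

#' Export a grid as a tab-separated table
#'
#' Columns: index, layer, x, y, z (mm).
#'
#' @param grid A \code{source_grid}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  df <- data.frame(index = seq_len(n_points(grid)), layer = grid$layer_index,
                   x = grid$points[, 1], y = grid$points[, 2],
                   z = grid$points[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export neighbor lists as JSON
#'
#' @param grid A \code{source_grid}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_neighbors_json <- function(grid, path) {
  jsonlite::write_json(grid$neighbors, path)
  invisible(path)
}
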