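#' Geodesic icosphere tessellation
#'
#' Vertices of an icosahedron subdivided \code{subdivisions} times, each new
#' edge midpoint projected back to the unit sphere. Vertex count is
#' \code{10 * 4^s + 2} (12, 42, 162, 642, ...).
#'
#' @param subdivisions Non-negative integer subdivision level.
#' @return A list with \code{vertices} (n x 3, unit norm) and \code{faces}
#'   (m x 3 vertex indices).
#' @export
icosphere <- function(subdivisions = 3L) {
  if (!is.numeric(subdivisions) || length(subdivisions) != 1L ||
      subdivisions < 0 || subdivisions != round(subdivisions))
    stop("'subdivisions' must be a non-negative integer")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    midkey <- new.env(hash = TRUE, parent = emptyenv())
    verts <- vector("list", 0L)
    midpoint <- function(i, j) {
      key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
      idx <- midkey[[key]]
      if (!is.null(idx)) return(idx)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      verts[[length(verts) + 1L]] <<- m
      idx <- nv + length(verts)
      midkey[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(k - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, verts))
    f <- newf
  }
  list(vertices = v, faces = f)
}

# unique undirected edges of a face matrix, as a 2-column index matrix
faces_to_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}
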