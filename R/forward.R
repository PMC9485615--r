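#' Magnetic field of a current dipole in a spherical conductor
#'
#' Closed-form external magnetic field of a current dipole inside a
#' homogeneous conducting sphere centered at the origin, projected onto each
#' sensor's orientation. The physical constant mu0/(4 pi) is folded into a
#' global scale: every quantity the pipeline compares (correlations, ratios,
#' ranks) is scale-invariant, so field units are arbitrary but consistent.
#' A purely radial moment produces an identically zero external field.
#'
#' @param location Dipole location, length-3 mm vector strictly inside the
#'   head sphere.
#' @param moment Dipole moment, length-3 vector (arbitrary units).
#' @param sensors A \code{sensor_array} whose positions lie outside the head.
#' @param head A \code{head_model}.
#' @return Numeric field vector, one value per channel.
#' @export
dipole_field <- function(location, moment, sensors, head = head_model()) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(head, "head_model"))
  location <- as.numeric(location); moment <- as.numeric(moment)
  if (length(location) != 3L || any(!is.finite(location)))
    stop("'location' must be a finite 3-vector")
  if (length(moment) != 3L || any(!is.finite(moment)))
    stop("'moment' must be a finite 3-vector")
  if (sqrt(sum(location^2)) >= head$radius)
    stop("dipole location must lie strictly inside the head sphere")
  r <- sensors$positions                       # m x 3, sensor positions
  if (any(rowSums(sweep(r, 2, location)^2) == 0))
    stop("dipole location coincides with a sensor")
  rn <- sqrt(rowSums(r^2))
  a <- sweep(r, 2, location)                   # r - r0
  an <- sqrt(rowSums(a^2))
  r0_dot_r <- as.numeric(r %*% location)
  a_dot_r <- rowSums(a * r)
  F <- an * (rn * an + rn^2 - r0_dot_r)
  gF_r <- an^2 / rn + a_dot_r / an + 2 * an + 2 * rn   # coefficient of r
  gF_r0 <- an + 2 * rn + a_dot_r / an                  # coefficient of r0
  q_x_r0 <- c(moment[2] * location[3] - moment[3] * location[2],
              moment[3] * location[1] - moment[1] * location[3],
              moment[1] * location[2] - moment[2] * location[1])
  qxr0_dot_r <- as.numeric(r %*% q_x_r0)
  # B = (F * (Q x r0) - (Q x r0 . r) * grad F) / F^2, per component
  B <- (outer(F, q_x_r0) -
        qxr0_dot_r * (gF_r * r - outer(gF_r0, location))) / F^2
  rowSums(B * sensors$orientations)
}

# gain blocks for one sensor array: fields of the unit-e1 and unit-e2 moments
# at every grid point, fully vectorized over (sensor, point) pairs
gain_block <- function(sensors, grid) {
  r <- sensors$positions                       # m x 3
  m <- nrow(r); P <- nrow(grid$points)
  rn <- sqrt(rowSums(r^2))                     # m
  # (m x P) pairwise geometry
  rx <- matrix(r[, 1], m, P); ry <- matrix(r[, 2], m, P)
  rz <- matrix(r[, 3], m, P)
  px <- matrix(grid$points[, 1], m, P, byrow = TRUE)
  py <- matrix(grid$points[, 2], m, P, byrow = TRUE)
  pz <- matrix(grid$points[, 3], m, P, byrow = TRUE)
  ax <- rx - px; ay <- ry - py; az <- rz - pz
  an <- sqrt(ax^2 + ay^2 + az^2)
  rnm <- matrix(rn, m, P)
  r0_dot_r <- rx * px + ry * py + rz * pz
  a_dot_r <- ax * rx + ay * ry + az * rz
  F <- an * (rnm * an + rnm^2 - r0_dot_r)
  gF_r <- an^2 / rnm + a_dot_r / an + 2 * an + 2 * rnm
  gF_r0 <- an + 2 * rnm + a_dot_r / an
  gx <- gF_r * rx - gF_r0 * px
  gy <- gF_r * ry - gF_r0 * py
  gz <- gF_r * rz - gF_r0 * pz
  ox <- matrix(sensors$orientations[, 1], m, P)
  oy <- matrix(sensors$orientations[, 2], m, P)
  oz <- matrix(sensors$orientations[, 3], m, P)
  one_moment <- function(e) {
    qx <- matrix(e[, 2] * grid$points[, 3] - e[, 3] * grid$points[, 2],
                 m, P, byrow = TRUE)
    qy <- matrix(e[, 3] * grid$points[, 1] - e[, 1] * grid$points[, 3],
                 m, P, byrow = TRUE)
    qz <- matrix(e[, 1] * grid$points[, 2] - e[, 2] * grid$points[, 1],
                 m, P, byrow = TRUE)
    qdr <- qx * rx + qy * ry + qz * rz
    ((F * qx - qdr * gx) * ox + (F * qy - qdr * gy) * oy +
     (F * qz - qdr * gz) * oz) / F^2
  }
  list(B1 = one_moment(grid$basis_e1), B2 = one_moment(grid$basis_e2))
}

#' Gain (leadfield) matrix of a helmet over a source grid
#'
#' Channels x (2 P) forward operator: column pair (2i-1, 2i) holds the fields
#' of the unit moments along the tangential basis vectors (e1, e2) of grid
#' point i. Rows are array-major in the helmet's channel order.
#'
#' @param helmet A \code{virtual_helmet}.
#' @param grid A \code{source_grid}.
#' @param head A \code{head_model}.
#' @return An object of class \code{gain_matrix}: \code{values} plus cached
#'   per-point summaries used by the inverse solver.
#' @export
gain_matrix <- function(helmet, grid, head = head_model()) {
  stopifnot(inherits(helmet, "virtual_helmet"), inherits(grid, "source_grid"))
  for (arr in helmet$arrays)
    if (any(sqrt(rowSums(arr$positions^2)) <= head$radius))
      stop("helmet has sensors inside the head sphere")
  if (any(sqrt(rowSums(grid$points^2)) >= head$radius))
    stop("grid has points outside the head sphere")
  P <- n_points(grid)
  blocks <- lapply(helmet$arrays, gain_block, grid = grid)
  G <- matrix(0, n_channels(helmet), 2L * P)
  row0 <- 0L
  for (b in blocks) {
    m <- nrow(b$B1)
    G[row0 + seq_len(m), seq(1L, 2L * P, by = 2L)] <- b$B1
    G[row0 + seq_len(m), seq(2L, 2L * P, by = 2L)] <- b$B2
    row0 <- row0 + m
  }
  e1_cols <- seq(1L, 2L * P, by = 2L)
  e2_cols <- seq(2L, 2L * P, by = 2L)
  structure(list(values = G,
                 n_arrays = n_arrays(helmet),
                 channels = n_channels(helmet),
                 serial = helmet$serial,
                 helmet_name = helmet$name,
                 n_points = P,
                 # per-point 2x2 Gram entries and column sums, cached for the
                 # vectorized per-location least-squares scan
                 gtg11 = colSums(G[, e1_cols, drop = FALSE]^2),
                 gtg22 = colSums(G[, e2_cols, drop = FALSE]^2),
                 gtg12 = colSums(G[, e1_cols, drop = FALSE] *
                                 G[, e2_cols, drop = FALSE]),
                 gsum1 = colSums(G[, e1_cols, drop = FALSE]),
                 gsum2 = colSums(G[, e2_cols, drop = FALSE])),
            class = "gain_matrix")
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat(sprintf("Gain matrix: %d channels x %d columns (%d grid points x 2), helmet '%s'\n",
              x$channels, 2L * x$n_points, x$n_points, x$helmet_name))
  invisible(x)
}

#' @export
dim.gain_matrix <- function(x) dim(x$values)

#' Forward-project a dipole set through a gain matrix
#'
#' @param gain A \code{gain_matrix}.
#' @param dipoles A \code{dipole_set} (may be empty).
#' @return Numeric field vector (one value per channel).
#' @export
forward_project <- function(gain, dipoles) {
  stopifnot(inherits(gain, "gain_matrix"), inherits(dipoles, "dipole_set"))
  field <- numeric(gain$channels)
  if (length(dipoles$indices) == 0L) return(field)
  if (any(dipoles$indices < 1L | dipoles$indices > gain$n_points))
    stop("dipole index out of range for this gain matrix")
  for (j in seq_along(dipoles$indices)) {
    i <- dipoles$indices[j]
    field <- field + gain$values[, 2L * i - 1L] * dipoles$coefficients[j, 1] +
                     gain$values[, 2L * i] * dipoles$coefficients[j, 2]
  }
  field
}

#' Effective rank of a gain matrix
#'
#' Number of singular values strictly greater than
#' \code{tolerance_fraction} times the largest singular value: the number of
#' effectively independent channels (leadfields) the helmet provides.
#'
#' @param gain A \code{gain_matrix} or a plain numeric matrix.
#' @param tolerance_fraction Relative tolerance in (0, 1); default 1e-3
#'   (0.1 percent of the maximal singular value).
#' @return Integer effective rank.
#' @export
effective_rank <- function(gain, tolerance_fraction = 1e-3) {
  G <- if (inherits(gain, "gain_matrix")) gain$values else as.matrix(gain)
  if (length(G) == 0L || any(!is.finite(G))) stop("gain must be finite and non-empty")
  if (tolerance_fraction <= 0 || tolerance_fraction >= 1)
    stop("'tolerance_fraction' must be in (0, 1)")
  if (all(G == 0)) return(0L)
  sv <- svd(G, nu = 0, nv = 0)$d
  sum(sv > tolerance_fraction * sv[1])
}
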