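#' Magnetometer sensor array
#'
#' A set of point magnetometers in head coordinates: positions in mm and unit
#' orientation vectors giving each sensor's measurement direction.
#'
#' @param positions Numeric n x 3 matrix of sensor positions (mm).
#' @param orientations Numeric n x 3 matrix of unit orientation vectors.
#' @param labels Character vector of channel labels (default \code{A1..An}).
#' @return An object of class \code{sensor_array}.
#' @export
sensor_array <- function(positions, orientations, labels = NULL) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  if (ncol(positions) != 3L || ncol(orientations) != 3L ||
      nrow(positions) != nrow(orientations))
    stop("'positions' and 'orientations' must be n x 3 matrices of equal n")
  if (any(!is.finite(positions)) || any(!is.finite(orientations)))
    stop("sensor coordinates must be finite")
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("orientation vectors must have unit norm (tol 1e-9)")
  n <- nrow(positions)
  if (is.null(labels)) labels <- paste0("A", seq_len(n))
  if (length(labels) != n) stop("'labels' length must match sensor count")
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  dimnames(orientations) <- list(NULL, c("ox", "oy", "oz"))
  structure(list(labels = as.character(labels), positions = positions,
                 orientations = orientations),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  r <- sqrt(rowSums(x$positions^2))
  cat(sprintf("Sensor array: %d magnetometers, radial distance %.1f-%.1f mm\n",
              nrow(x$positions), min(r), max(r)))
  invisible(x)
}

#' Number of channels of an array or helmet
#' @param x A \code{sensor_array} or \code{virtual_helmet}.
#' @return Integer channel count.
#' @export
n_channels <- function(x) UseMethod("n_channels")

#' @export
n_channels.sensor_array <- function(x) nrow(x$positions)

#' Synthetic whole-head 248-channel magnetometer helmet
#'
#' Places \code{n} point magnetometers quasi-uniformly (Fibonacci lattice) on
#' a spherical cap and orients them radially inward, toward the head center.
#' The cap extends from the helmet vertex down to \code{z_min} below the
#' origin plane, reproducing whole-head coverage with a realistic
#' scalp-to-sensor standoff.
#'
#' @param n Number of magnetometers (default 248).
#' @param radius Cap sphere radius in mm (default 120).
#' @param z_min Lower cap edge in mm (default -15).
#' @return A \code{sensor_array}.
#' @export
synthetic_helmet_array <- function(n = 248, radius = 120, z_min = -15) {
  if (n < 1 || radius <= 0 || z_min <= -radius || z_min >= radius)
    stop("invalid helmet parameters")
  i <- seq_len(n)
  # even spacing in z gives an equal-area (uniform) lattice on the cap
  z <- radius - (i - 0.5) / n * (radius - z_min)
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  rho <- sqrt(radius^2 - z^2)
  pos <- cbind(rho * cos(phi), rho * sin(phi), z)
  ori <- -pos / radius
  sensor_array(pos, ori)
}

#' Apply a rigid transform to a sensor array
#'
#' Positions are rotated about the origin and then translated; orientation
#' vectors are rotated only (a translation does not change a measurement
#' direction).
#'
#' @param array A \code{sensor_array}.
#' @param t A \code{rigid_transform}.
#' @param label_suffix Optional string appended to every channel label (used
#'   by \code{\link{build_vmh}} to mark the array position).
#' @return The transformed \code{sensor_array}.
#' @export
apply_transform <- function(array, t, label_suffix = NULL) {
  stopifnot(inherits(array, "sensor_array"), inherits(t, "rigid_transform"))
  R <- rotation_matrix(t)
  pos <- array$positions %*% t(R)
  pos <- sweep(pos, 2, t$translation_mm, "+")
  ori <- array$orientations %*% t(R)
  labels <- array$labels
  if (!is.null(label_suffix)) labels <- paste0(labels, label_suffix)
  sensor_array(pos, ori, labels)
}

#' Read / write a sensor layout file
#'
#' Tab-separated text, one row per channel:
#' \code{label  x_mm  y_mm  z_mm  ox  oy  oz}. The round trip is lossless to
#' six decimals.
#'
#' @param array A \code{sensor_array}.
#' @param path File path.
#' @return \code{read_sensor_layout} returns a \code{sensor_array};
#'   \code{write_sensor_layout} returns \code{path} invisibly.
#' @export
write_sensor_layout <- function(array, path) {
  stopifnot(inherits(array, "sensor_array"))
  df <- data.frame(label = array$labels,
                   x_mm = sprintf("%.6f", array$positions[, 1]),
                   y_mm = sprintf("%.6f", array$positions[, 2]),
                   z_mm = sprintf("%.6f", array$positions[, 3]),
                   ox = sprintf("%.6f", array$orientations[, 1]),
                   oy = sprintf("%.6f", array$orientations[, 2]),
                   oz = sprintf("%.6f", array$orientations[, 3]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_layout
#' @export
read_sensor_layout <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", rep("numeric", 6)))
  ori <- as.matrix(df[, c("ox", "oy", "oz")])
  # renormalize: 6-decimal serialization may leave norms off by ~1e-7
  ori <- ori / sqrt(rowSums(ori^2))
  sensor_array(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), ori, df$label)
}
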