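#' Spherical head model
#'
#' Homogeneous single-sphere head model centered at the origin of the head
#' coordinate system. All geometry in this package lives in head coordinates
#' with distances in millimetres.
#'
#' @param radius Sphere radius in mm. Default 95.5 mm, a typical adult fit.
#' @return An object of class \code{head_model}.
#' @export
head_model <- function(radius = 95.5) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("'radius' must be a single positive finite number")
  structure(list(center = c(0, 0, 0), radius = radius), class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("Spherical head model: radius %.1f mm, centered at origin\n",
              x$radius))
  invisible(x)
}

#' Rigid transform (rotation about the origin, then translation)
#'
#' Rotations are about the fixed head-frame axes through the origin and are
#' always applied before the translation. The composition order of the three
#' axis rotations is configurable; the default \code{"zyx"} means
#' \code{R = Rz \%*\% Ry \%*\% Rx}, i.e. the x rotation is applied first.
#'
#' @param rotation_deg Numeric length-3: rotation angles (degrees) about the
#'   head-frame x, y and z axes.
#' @param translation_mm Numeric length-3 translation in mm.
#' @param rot_order Single string, a permutation of \code{"xyz"} read as the
#'   left-to-right matrix product (default \code{"zyx"}).
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            rot_order = "zyx") {
  rotation_deg <- as.numeric(rotation_deg)
  translation_mm <- as.numeric(translation_mm)
  if (length(rotation_deg) != 3L || any(!is.finite(rotation_deg)))
    stop("'rotation_deg' must be 3 finite angles in degrees")
  if (length(translation_mm) != 3L || any(!is.finite(translation_mm)))
    stop("'translation_mm' must be 3 finite lengths in mm")
  if (!is.character(rot_order) || length(rot_order) != 1L ||
      !identical(sort(strsplit(rot_order, "")[[1L]]), c("x", "y", "z")))
    stop("'rot_order' must be a permutation of \"xyz\"")
  structure(list(rotation_deg = rotation_deg,
                 translation_mm = translation_mm,
                 rot_order = rot_order),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: rotate (%g, %g, %g) deg [order %s], then translate (%g, %g, %g) mm\n",
              x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3],
              x$rot_order,
              x$translation_mm[1], x$translation_mm[2], x$translation_mm[3]))
  invisible(x)
}

axis_rotation <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3),
         y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3),
         z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3))
}

#' Rotation matrix of a rigid transform
#'
#' @param t A \code{rigid_transform}.
#' @return A 3x3 rotation matrix acting on column vectors.
#' @export
rotation_matrix <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  axes <- strsplit(t$rot_order, "")[[1L]]
  ang <- c(x = t$rotation_deg[1], y = t$rotation_deg[2], z = t$rotation_deg[3])
  R <- diag(3)
  for (ax in axes) R <- R %*% axis_rotation(ax, ang[[ax]])
  R
}

#' Invert a rigid transform
#'
#' The inverse reverses the translation and applies the negated angles in the
#' reversed axis order, so that composing a transform with its inverse is the
#' identity.
#'
#' @param t A \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  R <- rotation_matrix(t)
  rigid_transform(rotation_deg = -t$rotation_deg,
                  translation_mm = as.numeric(-crossprod(R, t$translation_mm)),
                  rot_order = paste(rev(strsplit(t$rot_order, "")[[1L]]),
                                    collapse = ""))
}

#' Convert a head movement to its sensor counter-transform
#'
#' A recording with the head moved by \code{t} (relative to the helmet) is
#' equivalent, in a fixed head frame, to moving the sensor array by the
#' inverse transform. This helper expresses that counter-movement.
#'
#' @param t The head movement as a \code{rigid_transform}.
#' @return The \code{rigid_transform} to apply to the sensor array.
#' @export
head_to_sensor_transform <- function(t) invert_transform(t)

is_identity_transform <- function(t) {
  all(t$rotation_deg == 0) && all(t$translation_mm == 0)
}
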