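#' Assemble a virtual MEG helmet
#'
#' A virtual MEG helmet (VMH) combines recordings of the same activity made at
#' several head positions: in a fixed head frame it is equivalent to one
#' helmet whose sensor array is replicated under the counter-movement of each
#' head position. The first constituent array is always the untransformed
#' base; each transform adds one more array. Channel ordering is array-major
#' and stable.
#'
#' @param base The standard \code{sensor_array}.
#' @param transforms List of \code{rigid_transform}s (possibly empty, giving
#'   the standard single-array helmet).
#' @param serial Optional catalog identifier.
#' @param name Optional display name.
#' @return An object of class \code{virtual_helmet}.
#' @export
build_vmh <- function(base, transforms = list(), serial = NA_integer_,
                      name = NULL) {
  stopifnot(inherits(base, "sensor_array"))
  if (inherits(transforms, "rigid_transform")) transforms <- list(transforms)
  stopifnot(all(vapply(transforms, inherits, TRUE, "rigid_transform")))
  identity <- rigid_transform()
  arrays <- vector("list", 1L + length(transforms))
  arrays[[1L]] <- apply_transform(base, identity, label_suffix = "_p1")
  for (j in seq_along(transforms))
    arrays[[j + 1L]] <- apply_transform(base, transforms[[j]],
                                        label_suffix = paste0("_p", j + 1L))
  structure(list(arrays = arrays,
                 transforms = c(list(identity), transforms),
                 serial = serial,
                 name = if (is.null(name)) paste0("helmet-", serial) else name),
            class = "virtual_helmet")
}

#' @export
n_channels.virtual_helmet <- function(x) {
  sum(vapply(x$arrays, n_channels, integer(1)))
}

#' Number of constituent arrays of a helmet
#' @param helmet A \code{virtual_helmet}.
#' @return Integer.
#' @export
n_arrays <- function(helmet) {
  stopifnot(inherits(helmet, "virtual_helmet"))
  length(helmet$arrays)
}

#' @export
print.virtual_helmet <- function(x, ...) {
  cat(sprintf("Virtual MEG helmet '%s' (serial %s): %d array(s), %d channels\n",
              x$name, as.character(x$serial), n_arrays(x), n_channels(x)))
  invisible(x)
}

#' Stack all sensors of a helmet into one array
#'
#' @param helmet A \code{virtual_helmet}.
#' @return A \code{sensor_array} with array-major channel order.
#' @export
helmet_sensors <- function(helmet) {
  stopifnot(inherits(helmet, "virtual_helmet"))
  sensor_array(do.call(rbind, lapply(helmet$arrays, `[[`, "positions")),
               do.call(rbind, lapply(helmet$arrays, `[[`, "orientations")),
               unlist(lapply(helmet$arrays, `[[`, "labels")))
}

#' Does a helmet clash with the head sphere?
#'
#' A helmet clashes when any of its sensors lies within
#' \code{head$radius + margin} of the head center; such helmets are excluded
#' from catalogs because the corresponding head position is physically
#' impossible.
#'
#' @param helmet A \code{virtual_helmet}.
#' @param head A \code{head_model}.
#' @param margin Extra clearance in mm (default 0).
#' @return \code{TRUE} if any sensor is inside the inflated sphere.
#' @export
check_clash <- function(helmet, head, margin = 0) {
  stopifnot(inherits(helmet, "virtual_helmet"), inherits(head, "head_model"),
            margin >= 0)
  s <- helmet_sensors(helmet)
  any(sqrt(rowSums(s$positions^2)) < head$radius + margin)
}

# serial, name, list of (rotation, translation) per extra array
vmh_catalog_spec <- function() {
  tr <- function(rot, tra) list(rot = rot, tra = tra)
  list(
    list(serial = 1L,  name = "standard", extra = list()),
    list(serial = 2L,  name = "vmh-2",  extra = list(tr(c(20, 0, 0),  c(-15, 15, 0)))),
    list(serial = 3L,  name = "vmh-3",  extra = list(tr(c(0, 20, 0),  c(-15, 15, 0)))),
    list(serial = 4L,  name = "vmh-4",  extra = list(tr(c(0, 20, 0),  c(-15, -15, 0)))),
    list(serial = 5L,  name = "vmh-5",  extra = list(tr(c(0, 0, 20),  c(-15, -15, 0)))),
    list(serial = 6L,  name = "vmh-6",  extra = list(tr(c(-20, 0, 0), c(-15, -15, 0)))),
    list(serial = 7L,  name = "vmh-7",  extra = list(tr(c(0, -20, 0), c(-15, 15, 0)))),
    list(serial = 8L,  name = "vmh-8",  extra = list(tr(c(0, -20, 0), c(-15, -15, 0)))),
    list(serial = 9L,  name = "vmh-9",  extra = list(tr(c(0, 0, -20), c(-15, 15, 0)))),
    list(serial = 10L, name = "vmh-10", extra = list(tr(c(0, 0, -20), c(-15, -15, 0)))),
    list(serial = 11L, name = "VMHa",   extra = list(tr(c(20, 20, 20), c(15, 15, 15)))),
    list(serial = 12L, name = "vmh-12", extra = list(tr(c(20, 20, 20), c(-15, -15, 0)))),
    list(serial = 13L, name = "vmh-13", extra = list(tr(c(-20, -20, -20), c(-15, -15, 0)))),
    list(serial = 14L, name = "VMHb",   extra = list(tr(c(20, 20, 20), c(15, 15, 15)),
                                                     tr(c(-20, -20, -20), c(-15, -15, 0))))
  )
}

#' The catalog of examined helmets
#'
#' The standard single-array helmet plus 13 virtual helmet constructions:
#' each combines the standard array with one or two counterparts
#' rotated by +/-20 degrees about one or all axes and translated by +/-15 mm.
#' Serials 11 and 14 are the two helmets (VMHa, VMHb) used in the
#' helmet-comparison driver.
#'
#' @param base Base \code{sensor_array} (default the synthetic 248-channel
#'   helmet).
#' @param serials Optional subset of serials 1..14.
#' @return A named list of \code{virtual_helmet}s.
#' @export
helmet_catalog <- function(base = synthetic_helmet_array(), serials = NULL) {
  spec <- vmh_catalog_spec()
  if (!is.null(serials)) {
    keep <- vapply(spec, function(s) s$serial %in% serials, TRUE)
    if (!all(serials %in% vapply(spec, `[[`, integer(1), "serial")))
      stop("unknown helmet serial(s)")
    spec <- spec[keep]
  }
  out <- lapply(spec, function(s) {
    tf <- lapply(s$extra, function(e) rigid_transform(e$rot, e$tra))
    build_vmh(base, tf, serial = s$serial, name = s$name)
  })
  names(out) <- vapply(spec, function(s) as.character(s$serial), "")
  out
}

#' Catalog transforms as a table
#'
#' @param catalog A list of helmets from \code{\link{helmet_catalog}}.
#' @return A data.frame with one row per constituent array: serial, name,
#'   array position, rotation angles and translations.
#' @export
catalog_table <- function(catalog = helmet_catalog()) {
  rows <- lapply(catalog, function(h) {
    do.call(rbind, lapply(seq_along(h$transforms), function(j) {
      t <- h$transforms[[j]]
      data.frame(serial = h$serial, name = h$name, n_arrays = n_arrays(h),
                 array = j,
                 rx_deg = t$rotation_deg[1], ry_deg = t$rotation_deg[2],
                 rz_deg = t$rotation_deg[3],
                 tx_mm = t$translation_mm[1], ty_mm = t$translation_mm[2],
                 tz_mm = t$translation_mm[3],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
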