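#' Dipole set on the source grid
#'
#' A set of equivalent current dipoles at grid points, each described by two
#' coefficients (q1, q2) on the point's local tangential basis; the moment is
#' \code{q1 * e1 + q2 * e2}.
#'
#' @param indices Integer grid-point indices.
#' @param coefficients Numeric k x 2 matrix of tangential coefficients.
#' @return An object of class \code{dipole_set}.
#' @export
dipole_set <- function(indices, coefficients) {
  indices <- as.integer(indices)
  coefficients <- matrix(as.numeric(coefficients), length(indices), 2)
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  colnames(coefficients) <- c("q1", "q2")
  structure(list(indices = indices, coefficients = coefficients),
            class = "dipole_set")
}

#' @export
print.dipole_set <- function(x, ...) {
  cat(sprintf("Dipole set: %d dipole(s) at grid indices %s\n",
              length(x$indices), paste(x$indices, collapse = ", ")))
  invisible(x)
}

#' Randomly placed dipoles
#'
#' Draws \code{k} distinct grid points uniformly and, for each dipole, two
#' tangential coefficients uniform on [0.5, 1] (amplitudes between half and a
#' unit vector). Uses the global RNG; set a seed for reproducibility.
#'
#' @param grid A \code{source_grid}.
#' @param k Number of dipoles (1 to grid size).
#' @param coef_range Length-2 amplitude range (default \code{c(0.5, 1)}).
#' @return A \code{dipole_set}.
#' @export
random_dipoles <- function(grid, k, coef_range = c(0.5, 1)) {
  stopifnot(inherits(grid, "source_grid"))
  P <- n_points(grid)
  if (k < 1 || k > P) stop("'k' must be between 1 and the grid size")
  idx <- sample.int(P, k)
  q <- matrix(stats::runif(2 * k, coef_range[1], coef_range[2]), k, 2)
  dipole_set(idx, q)
}

#' Neighbor dipole sets with jittered amplitudes
#'
#' For robustness assessment, dipoles are re-placed at neighboring grid
#' locations with each tangential coefficient independently rescaled by a
#' factor uniform in \code{jitter_range} (default -20 to +20 percent). Each
#' returned case pairs one neighbor per original dipole; with \code{n_cases}
#' set, that many distinct combinations are sampled (seeded by the caller's
#' RNG state), otherwise all combinations are enumerated.
#'
#' @param dipoles A \code{dipole_set}.
#' @param grid A \code{source_grid}.
#' @param n_cases Optional number of neighbor combinations to sample.
#' @param jitter_range Length-2 multiplicative jitter range
#'   (default \code{c(0.8, 1.2)}; \code{c(1, 1)} moves locations only).
#' @return List of \code{dipole_set}s.
#' @export
jitter_dipoles <- function(dipoles, grid, n_cases = NULL,
                           jitter_range = c(0.8, 1.2)) {
  stopifnot(inherits(dipoles, "dipole_set"), inherits(grid, "source_grid"))
  nb <- lapply(dipoles$indices, function(i) grid$neighbors[[i]])
  if (any(lengths(nb) == 0L)) stop("a dipole has no grid neighbors")
  total <- prod(lengths(nb))
  k <- length(dipoles$indices)
  if (is.null(n_cases) || n_cases >= total) {
    if (total > 10000)
      stop("too many neighbor combinations to enumerate; set 'n_cases'")
    combos <- as.matrix(expand.grid(nb, KEEP.OUT.ATTRS = FALSE))
  } else {
    # sample distinct combinations without enumerating the product set
    seen <- new.env(hash = TRUE, parent = emptyenv())
    combos <- matrix(0L, n_cases, k)
    got <- 0L
    while (got < n_cases) {
      cand <- vapply(nb, function(v) v[sample.int(length(v), 1L)], integer(1))
      key <- paste(cand, collapse = "_")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        combos[got, ] <- cand
      }
    }
  }
  lapply(seq_len(nrow(combos)), function(r) {
    fac <- matrix(stats::runif(2 * k, jitter_range[1], jitter_range[2]), k, 2)
    dipole_set(combos[r, ], dipoles$coefficients * fac)
  })
}
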