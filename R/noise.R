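#' Monte-Carlo calibration of the noise model
#'
#' Two noise components are added to simulated fields: technical noise (TN),
#' i.i.d. Gaussian per sensor with scale k, and brain noise (BN), Gaussian
#' source noise of scale c projected through the gain matrix. Both scales are
#' calibrated against the standard (single-array) helmet:
#' \deqn{k = f \cdot (1/3) \cdot 0.75 \cdot \overline{std(signal)}}
#' where f is the noise-level fraction, 1/3 is the additive-std bookkeeping
#' weight of TN within the overall noise (std(TN) = std(ON)/3), 0.75 is the
#' mean of the Uniform(0.5, 1) amplitude draw, and the mean signal std comes
#' from \code{n_iter} draws of three simultaneously active unit dipoles
#' (unit coefficients on both tangential basis vectors); and
#' \deqn{c = 2 \, std(TN) / \overline{std(BN)}}
#' with the mean BN std from \code{n_iter} standard-normal grid vectors
#' projected on the standard helmet, enforcing std(BN) = 2 std(TN).
#'
#' @param standard_gain The \code{gain_matrix} of the standard helmet
#'   (n_arrays must be 1).
#' @param f Noise-level fraction (e.g. 0.1 or 0.3).
#' @param n_iter Calibration replications (default 1000, minimum 2).
#' @param seed Optional integer seed; if given, calibration is bit
#'   reproducible regardless of the surrounding RNG state.
#' @return An object of class \code{noise_calibration}.
#' @export
calibrate_noise <- function(standard_gain, f, n_iter = 1000L, seed = NULL) {
  stopifnot(inherits(standard_gain, "gain_matrix"))
  if (standard_gain$n_arrays != 1L)
    stop("calibration must use the standard (single-array) gain")
  if (!is.numeric(f) || f < 0) stop("'f' must be a non-negative number")
  if (n_iter < 2) stop("'n_iter' must be at least 2")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  G <- standard_gain$values
  P <- standard_gain$n_points
  sig_std <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(P, 3L)
    cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    sig_std[it] <- stats::sd(rowSums(G[, cols, drop = FALSE]))
  }
  bn_std <- numeric(n_iter)
  for (it in seq_len(n_iter))
    bn_std[it] <- stats::sd(as.numeric(G %*% stats::rnorm(2L * P)))
  mean_signal_std <- mean(sig_std)
  mean_bn_std <- mean(bn_std)
  k <- f * (1 / 3) * 0.75 * mean_signal_std
  c <- 2 * k / mean_bn_std
  structure(list(f = f, k = k, c = c,
                 mean_signal_std = mean_signal_std,
                 mean_bn_std = mean_bn_std,
                 n_iter = as.integer(n_iter), seed = seed),
            class = "noise_calibration")
}

#' @export
print.noise_calibration <- function(x, ...) {
  cat(sprintf("Noise calibration: f = %g, k = %.4g, c = %.4g (%d iterations)\n",
              x$f, x$k, x$c, x$n_iter))
  invisible(x)
}

#' Technical (sensor) noise
#'
#' Uncorrelated Gaussian noise, i.i.d. across channels with the calibrated
#' scale k. The scale is identical for every constituent array of a virtual
#' helmet: technical noise does not depend on head position.
#'
#' @param cal A \code{noise_calibration}.
#' @param n_channels Number of channels to draw.
#' @return Numeric noise vector.
#' @export
technical_noise <- function(cal, n_channels) {
  stopifnot(inherits(cal, "noise_calibration"))
  cal$k * stats::rnorm(n_channels)
}

#' Brain (projected source) noise
#'
#' Spatially correlated noise: a standard-normal source vector scaled by the
#' calibrated c and forward-projected through the helmet's gain. With
#' \code{mode = "single"} (default) one shared grid draw is projected through
#' the full gain, so the noise is coherent across the constituent arrays of a
#' virtual helmet, exactly like a real background source configuration.
#' \code{mode = "per-array"} draws an independent source vector per
#' constituent array (arrays standing for separate recording sessions);
#' the calibration target (std(BN) = 2 std(TN) on the standard helmet) is
#' identical in both modes, but per-array noise can be partially averaged
#' out by a multi-array helmet.
#'
#' @param cal A \code{noise_calibration}.
#' @param helmet_gain \code{gain_matrix} of the helmet under test.
#' @param mode \code{"single"} or \code{"per-array"}.
#' @return Numeric noise vector of length \code{helmet_gain$channels}.
#' @export
brain_noise <- function(cal, helmet_gain, mode = c("single", "per-array")) {
  stopifnot(inherits(cal, "noise_calibration"),
            inherits(helmet_gain, "gain_matrix"))
  mode <- match.arg(mode)
  G <- helmet_gain$values
  P <- helmet_gain$n_points
  if (mode == "single")
    return(as.numeric(G %*% (cal$c * stats::rnorm(2L * P))))
  n <- helmet_gain$n_arrays
  m <- helmet_gain$channels / n
  out <- numeric(helmet_gain$channels)
  for (a in seq_len(n)) {
    rows <- (a - 1L) * m + seq_len(m)
    out[rows] <- as.numeric(G[rows, , drop = FALSE] %*%
                            (cal$c * stats::rnorm(2L * P)))
  }
  out
}

#' Overall noise
#'
#' Combines technical and brain noise and scales by sqrt(n): with n head
#' positions the recording time per position, and hence the number of
#' averaged events, drops by a factor n, weakening noise suppression by
#' sqrt(n).
#'
#' @param tn Technical-noise vector.
#' @param bn Brain-noise vector (same length).
#' @param n_arrays Number of constituent arrays n.
#' @return \code{sqrt(n_arrays) * (tn + bn)}.
#' @export
overall_noise <- function(tn, bn, n_arrays) {
  if (length(tn) != length(bn)) stop("'tn' and 'bn' lengths differ")
  sqrt(n_arrays) * (tn + bn)
}

#' Simulate a noisy measurement
#'
#' Forward-projects a dipole set and adds the overall noise for the helmet's
#' number of arrays. With \code{cal = NULL} (or f = 0) the noiseless forward
#' projection is returned.
#'
#' @param gain A \code{gain_matrix}.
#' @param dipoles A \code{dipole_set}.
#' @param cal A \code{noise_calibration} or \code{NULL}.
#' @param bn_mode Brain-noise mode, see \code{\link{brain_noise}}.
#' @return Numeric measurement vector.
#' @export
simulate_measurement <- function(gain, dipoles, cal = NULL,
                                 bn_mode = c("single", "per-array")) {
  signal <- forward_project(gain, dipoles)
  if (is.null(cal) || cal$f == 0) return(signal)
  bn_mode <- match.arg(bn_mode)
  tn <- technical_noise(cal, gain$channels)
  bn <- brain_noise(cal, gain, mode = bn_mode)
  signal + overall_noise(tn, bn, gain$n_arrays)
}

#' Serialize / restore a noise calibration
#'
#' @param cal A \code{noise_calibration}.
#' @param path JSON file path.
#' @return \code{write_calibration_json} returns \code{path} invisibly;
#'   \code{read_calibration_json} returns a \code{noise_calibration}.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "noise_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(f = x$f, k = x$k, c = x$c,
                 mean_signal_std = x$mean_signal_std,
                 mean_bn_std = x$mean_bn_std,
                 n_iter = as.integer(x$n_iter),
                 seed = x$seed),
            class = "noise_calibration")
}
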