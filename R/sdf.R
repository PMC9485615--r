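# candidates weaker than threshold x the strongest magnitude are discarded
prune_keep <- function(magnitude, threshold) {
  magnitude >= threshold * max(magnitude, 0)
}

# Vectorized single-ECD scan: for every grid point solve the 2-column
# least-squares problem via its (cached) 2x2 normal equations and score the
# squared Pearson correlation between the measured and estimated fields.
ecd_scan <- function(gain, field) {
  G <- gain$values
  m <- gain$channels
  gtm <- as.numeric(crossprod(G, field))
  m1 <- gtm[seq(1L, length(gtm), by = 2L)]
  m2 <- gtm[seq(2L, length(gtm), by = 2L)]
  a <- gain$gtg11; b <- gain$gtg12; d <- gain$gtg22
  det <- a * d - b^2
  ok <- det > .Machine$double.eps * (a * d + .Machine$double.xmin)
  q1 <- ifelse(ok, (d * m1 - b * m2) / det, 0)
  q2 <- ifelse(ok, (a * m2 - b * m1) / det, 0)
  # Pearson correlation of field with est = q1 g1 + q2 g2, via cached sums
  est_dot_m <- q1 * m1 + q2 * m2
  est_sum <- q1 * gain$gsum1 + q2 * gain$gsum2
  est_ss <- q1^2 * a + 2 * q1 * q2 * b + q2^2 * d
  f_sum <- sum(field)
  f_ss <- sum(field^2)
  var_f <- f_ss - f_sum^2 / m
  var_e <- est_ss - est_sum^2 / m
  cov_fe <- est_dot_m - f_sum * est_sum / m
  r2 <- ifelse(var_e > 0, cov_fe^2 / (var_f * var_e), 0)
  r2[!is.finite(r2)] <- 0
  i <- which.max(r2)                      # ties broken at the lowest index
  list(index = i, q = c(q1[i], q2[i]), r_squared = min(r2[i], 1))
}

#' Fit a single equivalent current dipole
#'
#' Scans every grid location: solves the overdetermined channels-by-2
#' least-squares problem for the two tangential coefficients, estimates the
#' field of that solution, and selects the location whose estimated field has
#' the highest squared Pearson (spatial) correlation with the measured field.
#' Ties are broken deterministically at the lowest grid index.
#'
#' @param gain A \code{gain_matrix}.
#' @param field Measured field vector in the gain's channel order.
#' @return A list: \code{grid_index}, \code{coefficients} (q1, q2),
#'   \code{magnitude} (Euclidean norm of the coefficients) and
#'   \code{r_squared}.
#' @export
fit_single_ecd <- function(gain, field) {
  stopifnot(inherits(gain, "gain_matrix"))
  field <- as.numeric(field)
  if (length(field) != gain$channels)
    stop("field length does not match the gain's channel count")
  if (gain$channels < 3L) stop("need at least 3 channels")
  if (stats::sd(field) == 0)
    stop("degenerate input: field has zero variance")
  s <- ecd_scan(gain, field)
  list(grid_index = s$index, coefficients = s$q,
       magnitude = sqrt(sum(s$q^2)), r_squared = s$r_squared)
}

#' Sequential dipole fit (SDF)
#'
#' The pipeline's inverse model: a single equivalent current dipole is fitted to
#' the field (\code{\link{fit_single_ecd}}), its estimated field is
#' subtracted, and the next dipole is fitted to the residual; the cycle runs
#' \code{max_iter} times (default 6). Candidates whose coefficient magnitude
#' falls below \code{prune_threshold} times the strongest candidate's
#' magnitude are then discarded. No channels are pre-selected: every fit uses
#' the whole array.
#'
#' @param gain A \code{gain_matrix}.
#' @param field Measured field vector.
#' @param max_iter Maximum number of sequential fits (default 6).
#' @param prune_threshold Relative magnitude threshold (default 0.3).
#' @return An object of class \code{sdf}: \code{dipoles} (surviving
#'   candidates, a data.frame), \code{all_candidates},
#'   \code{residual_norm_history}, \code{early_stop}, and the inputs needed
#'   by its methods.
#' @export
sdf <- function(gain, field, max_iter = 6L, prune_threshold = 0.3) {
  stopifnot(inherits(gain, "gain_matrix"), max_iter >= 1, prune_threshold >= 0)
  field <- as.numeric(field)
  if (length(field) != gain$channels)
    stop("field length does not match the gain's channel count")
  if (stats::sd(field) == 0)
    stop("degenerate input: field has zero variance")
  norm0 <- sqrt(sum(field^2))
  residual <- field
  cand <- vector("list", max_iter)
  res_hist <- numeric(0)
  early_stop <- FALSE
  n_cand <- 0L
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(residual^2)) < 1e-12 * norm0) {
      early_stop <- TRUE
      break
    }
    s <- ecd_scan(gain, residual)
    est <- gain$values[, 2L * s$index - 1L] * s$q[1] +
           gain$values[, 2L * s$index] * s$q[2]
    residual <- residual - est
    n_cand <- it
    cand[[it]] <- data.frame(grid_index = s$index, q1 = s$q[1], q2 = s$q[2],
                             magnitude = sqrt(sum(s$q^2)),
                             r_squared = s$r_squared, iteration = it)
    res_hist <- c(res_hist, sqrt(sum(residual^2)))
  }
  all_candidates <- if (n_cand > 0L) do.call(rbind, cand[seq_len(n_cand)])
                    else data.frame(grid_index = integer(0), q1 = numeric(0),
                                    q2 = numeric(0), magnitude = numeric(0),
                                    r_squared = numeric(0),
                                    iteration = integer(0))
  keep <- prune_keep(all_candidates$magnitude, prune_threshold)
  dipoles <- all_candidates[keep, , drop = FALSE]
  rownames(dipoles) <- NULL
  structure(list(dipoles = dipoles, all_candidates = all_candidates,
                 residual_norm_history = res_hist,
                 early_stop = early_stop,
                 field_norm = norm0,
                 max_iter = as.integer(max_iter),
                 prune_threshold = prune_threshold,
                 gain = gain, field = field,
                 call = match.call()),
            class = "sdf")
}

#' @export
print.sdf <- function(x, ...) {
  cat(sprintf("Sequential dipole fit: %d surviving dipole(s) of %d candidate(s)\n",
              nrow(x$dipoles), nrow(x$all_candidates)))
  if (nrow(x$dipoles) > 0) {
    df <- x$dipoles
    df$q1 <- signif(df$q1, 4); df$q2 <- signif(df$q2, 4)
    df$magnitude <- signif(df$magnitude, 4)
    df$r_squared <- signif(df$r_squared, 4)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.sdf <- function(object, ...) {
  res <- list(n_dipoles = nrow(object$dipoles),
              n_candidates = nrow(object$all_candidates),
              dipoles = object$dipoles,
              residual_norm_history = object$residual_norm_history,
              relative_residual = if (length(object$residual_norm_history))
                utils::tail(object$residual_norm_history, 1) / object$field_norm
                else NA_real_,
              early_stop = object$early_stop)
  class(res) <- "summary.sdf"
  res
}

#' @export
print.summary.sdf <- function(x, ...) {
  cat(sprintf("Sequential dipole fit: %d of %d candidates survive pruning\n",
              x$n_dipoles, x$n_candidates))
  cat(sprintf("Relative residual norm after the last iteration: %.3g\n",
              x$relative_residual))
  if (x$early_stop) cat("Residual reached numerical zero before the cap.\n")
  if (x$n_dipoles > 0) print(x$dipoles, row.names = FALSE)
  invisible(x)
}

#' @export
coef.sdf <- function(object, ...) {
  out <- as.matrix(object$dipoles[, c("q1", "q2")])
  rownames(out) <- object$dipoles$grid_index
  out
}

#' @export
fitted.sdf <- function(object, ...) {
  forward_project(object$gain, as_dipole_set(object))
}

#' @export
residuals.sdf <- function(object, ...) object$field - fitted(object)

#' Surviving dipoles of a fit as a dipole set
#'
#' @param fit An \code{sdf} object.
#' @return A \code{dipole_set} of the surviving dipoles.
#' @export
as_dipole_set <- function(fit) {
  stopifnot(inherits(fit, "sdf"))
  dipole_set(fit$dipoles$grid_index,
             cbind(fit$dipoles$q1, fit$dipoles$q2))
}

#' Serialize a fit result to JSON
#'
#' @param fit An \code{sdf} object.
#' @param path JSON file path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "sdf"))
  jsonlite::write_json(list(dipoles = fit$dipoles,
                            all_candidates = fit$all_candidates,
                            residual_norm_history = fit$residual_norm_history,
                            early_stop = fit$early_stop),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
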