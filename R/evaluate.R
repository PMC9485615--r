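# all injections of 1..r into 1..n (r <= n), one per row; row count n!/(n-r)!
all_injections <- function(r, n) {
  if (r == 0L) return(matrix(integer(0), 1, 0))
  out <- matrix(seq_len(n), ncol = 1)
  for (j in seq_len(r - 1L)) {
    rows <- lapply(seq_len(nrow(out)), function(i) {
      rest <- setdiff(seq_len(n), out[i, ])
      cbind(matrix(out[i, ], length(rest), j, byrow = TRUE), rest)
    })
    out <- do.call(rbind, rows)
  }
  out
}

#' Match solved dipoles to placed dipoles
#'
#' One-to-one assignment of \code{min(n_placed, n_solved)} pairs minimizing
#' the total Euclidean distance between grid locations (exact enumeration;
#' set sizes never exceed the sequential-fit cap of 6). Placed dipoles
#' without a match and superfluous solved dipoles do not contribute to the
#' mean distance. A \code{"greedy"} mode (closest pair first) is available
#' for sensitivity analysis.
#'
#' @param placed A \code{dipole_set} (or integer indices).
#' @param solved An \code{sdf} fit, a \code{dipole_set}, or integer indices.
#' @param grid The common \code{source_grid}.
#' @param method \code{"optimal"} (default) or \code{"greedy"}.
#' @return An object of class \code{match_result}: \code{pairs} (data.frame
#'   with placed index, solved index, distance in mm), \code{n_placed},
#'   \code{n_solved}, \code{mean_distance_mm} (NA when no pair exists).
#' @export
match_dipoles <- function(placed, solved, grid,
                          method = c("optimal", "greedy")) {
  stopifnot(inherits(grid, "source_grid"))
  method <- match.arg(method)
  p_idx <- if (inherits(placed, "dipole_set")) placed$indices
           else as.integer(placed)
  s_idx <- if (inherits(solved, "sdf")) solved$dipoles$grid_index
           else if (inherits(solved, "dipole_set")) solved$indices
           else as.integer(solved)
  np <- length(p_idx); ns <- length(s_idx)
  r <- min(np, ns)
  if (r == 0L) {
    return(structure(list(pairs = data.frame(placed = integer(0),
                                             solved = integer(0),
                                             distance_mm = numeric(0)),
                          n_placed = np, n_solved = ns,
                          mean_distance_mm = NA_real_),
                     class = "match_result"))
  }
  D <- matrix(0, np, ns)
  for (i in seq_len(np))
    D[i, ] <- sqrt(rowSums((grid$points[s_idx, , drop = FALSE] -
                            matrix(grid$points[p_idx[i], ], ns, 3,
                                   byrow = TRUE))^2))
  if (method == "greedy") {
    pairs <- matrix(0L, r, 2)
    Dw <- D
    for (k in seq_len(r)) {
      ij <- arrayInd(which.min(Dw), dim(Dw))
      pairs[k, ] <- ij
      Dw[ij[1], ] <- Inf; Dw[, ij[2]] <- Inf
    }
    dist <- D[pairs]
  } else if (np <= ns) {
    inj <- all_injections(np, ns)
    tot <- vapply(seq_len(nrow(inj)),
                  function(t) sum(D[cbind(seq_len(np), inj[t, ])]), 0)
    best <- which.min(tot)
    pairs <- cbind(seq_len(np), inj[best, ])
    dist <- D[pairs]
  } else {
    inj <- all_injections(ns, np)
    tot <- vapply(seq_len(nrow(inj)),
                  function(t) sum(D[cbind(inj[t, ], seq_len(ns))]), 0)
    best <- which.min(tot)
    pairs <- cbind(inj[best, ], seq_len(ns))
    dist <- D[pairs]
  }
  structure(list(pairs = data.frame(placed = p_idx[pairs[, 1]],
                                    solved = s_idx[pairs[, 2]],
                                    distance_mm = dist),
                 n_placed = np, n_solved = ns,
                 mean_distance_mm = mean(dist)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Dipole matching: %d placed, %d solved, %d pair(s), mean distance %s mm\n",
              x$n_placed, x$n_solved, nrow(x$pairs),
              if (is.na(x$mean_distance_mm)) "NA"
              else sprintf("%.2f", x$mean_distance_mm)))
  invisible(x)
}

# ranking key: (|count deviation|, superfluous flag, mean distance).
# Missing dipoles are preferred over superfluous at equal deviation; the
# count class dominates distance accuracy.
verdict_key <- function(m) {
  c(abs(m$n_solved - m$n_placed),
    as.numeric(m$n_solved > m$n_placed),
    if (is.na(m$mean_distance_mm)) Inf else m$mean_distance_mm)
}

#' Select the best helmet(s) for one placed set
#'
#' Ranks helmets evaluated on the identical placed dipole set: precedence
#' goes to the solved-dipole count (smallest absolute deviation from the
#' placed count, with missing preferred over superfluous at equal deviation)
#' and, within the winning count class, to the lowest mean distance. Exact
#' ties put every tied helmet in the best set.
#'
#' @param verdicts Named list of \code{match_result}s (names identify the
#'   helmets), all for the same placed set.
#' @param tol Numeric tolerance for distance ties (default 1e-9 mm).
#' @return Character vector of best helmet names.
#' @export
best_helmet <- function(verdicts, tol = 1e-9) {
  stopifnot(length(verdicts) >= 1,
            all(vapply(verdicts, inherits, TRUE, "match_result")))
  if (is.null(names(verdicts)) || any(names(verdicts) == ""))
    stop("'verdicts' must be a named list")
  np <- vapply(verdicts, `[[`, 0, "n_placed")
  if (length(unique(np)) != 1L)
    stop("all verdicts must share the same placed set")
  keys <- t(vapply(verdicts, verdict_key, numeric(3)))
  ord <- order(keys[, 1], keys[, 2], keys[, 3])
  top <- keys[ord[1], ]
  tied <- keys[, 1] == top[1] & keys[, 2] == top[2] &
    (abs(keys[, 3] - top[3]) <= tol | (is.infinite(keys[, 3]) & is.infinite(top[3])))
  names(verdicts)[tied]
}

#' Robustness of a helmet over neighbor cases
#'
#' The percentage of neighbor cases for which the helmet is in the best set
#' out of all examined helmets.
#'
#' @param helmet Helmet name (as used in the best sets).
#' @param neighbor_best_sets List of character vectors, the best set per
#'   neighbor case.
#' @return Percentage in [0, 100]; NA with a warning when there are no
#'   neighbor cases.
#' @export
robustness <- function(helmet, neighbor_best_sets) {
  if (length(neighbor_best_sets) == 0L) {
    warning("no neighbor cases: robustness undefined")
    return(NA_real_)
  }
  100 * mean(vapply(neighbor_best_sets, function(b) helmet %in% b, TRUE))
}

#' Binary best-solution matrix over cases
#'
#' Arranges per-case best sets as a logical (helmet x case) matrix: entry
#' (h, c) is TRUE when helmet h offered the best solution for case c. The
#' row-wise means are the helmets' robustness percentages.
#'
#' @param best_sets List of character vectors (the best set per case).
#' @param helmets Character vector of helmet names defining the row order.
#' @return A logical matrix with one row per helmet and one column per case.
#' @export
best_matrix <- function(best_sets, helmets) {
  out <- vapply(best_sets, function(b) helmets %in% b,
                logical(length(helmets)))
  out <- matrix(out, nrow = length(helmets),
                dimnames = list(helmets, NULL))
  out
}

#' Permutation test for a difference of means
#'
#' Label-permutation test with add-one correction:
#' \code{p = (1 + #extreme) / (1 + n_perm)}. With \code{paired = TRUE} the
#' samples must be equal-length per-case measurements of the same units and
#' the null is imposed by random sign flips of the per-case differences,
#' which is the appropriate (and more powerful) exchangeability argument when
#' both conditions are evaluated on identical simulated cases.
#'
#' @param sample_a,sample_b Numeric samples.
#' @param n_perm Number of permutations (default 10000; below 100 a warning
#'   is issued).
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (mean(a) > mean(b)) or \code{"less"}.
#' @param paired Use the sign-flip test for paired samples (default FALSE).
#' @return List with \code{p_value}, \code{observed} (mean(a) - mean(b)) and
#'   \code{n_perm}.
#' @export
permutation_test <- function(sample_a, sample_b, n_perm = 10000L,
                             alternative = c("two.sided", "greater", "less"),
                             paired = FALSE) {
  alternative <- match.arg(alternative)
  if (paired) {
    if (length(sample_a) != length(sample_b))
      stop("paired samples must have equal length")
    keep <- is.finite(sample_a) & is.finite(sample_b)
    sample_a <- sample_a[keep]; sample_b <- sample_b[keep]
  } else {
    sample_a <- sample_a[is.finite(sample_a)]
    sample_b <- sample_b[is.finite(sample_b)]
  }
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("samples must be non-empty")
  if (n_perm < 100) warning("n_perm < 100: the p-value is very coarse")
  obs <- mean(sample_a) - mean(sample_b)
  stat <- numeric(n_perm)
  if (paired) {
    d <- sample_a - sample_b
    for (i in seq_len(n_perm))
      stat[i] <- mean(d * sample(c(-1, 1), length(d), replace = TRUE))
  } else {
    pool <- c(sample_a, sample_b)
    na <- length(sample_a)
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      stat[i] <- mean(pool[idx]) - mean(pool[-idx])
    }
  }
  extreme <- switch(alternative,
                    two.sided = sum(abs(stat) >= abs(obs)),
                    greater = sum(stat >= obs),
                    less = sum(stat <= obs))
  list(p_value = (1 + extreme) / (1 + n_perm), observed = obs,
       n_perm = as.integer(n_perm))
}
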