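# Shared fixtures and independent oracles for the test suite.
# Fixtures are built lazily and memoized so each is constructed once per run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

small_grid <- function() fixture("small_grid", function()
  build_grid(head_model(), layer_radii = c(63, 73, 83), subdivisions = 2L))

toy_grid <- function() fixture("toy_grid", function()
  build_grid(head_model(), layer_radii = c(60, 80), subdivisions = 1L))

std_helmet <- function() fixture("std_helmet", function()
  helmet_catalog(serials = 1L)[[1L]])

small_gain <- function() fixture("small_gain", function()
  gain_matrix(std_helmet(), small_grid()))

toy_gain <- function() fixture("toy_gain", function()
  gain_matrix(std_helmet(), toy_grid()))

full_grid <- function() fixture("full_grid", function() build_grid())

full_gain <- function() fixture("full_gain", function()
  gain_matrix(std_helmet(), full_grid()))

# Independent, literal transcription of the closed-form spherical-conductor
# field (scalar arithmetic, one sensor at a time), kept deliberately separate
# from the vectorized implementation it checks.
cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

sarvas_oracle <- function(location, moment, positions, orientations) {
  out <- numeric(nrow(positions))
  for (s in seq_len(nrow(positions))) {
    r <- positions[s, ]
    rn <- sqrt(sum(r^2))
    a <- r - location
    an <- sqrt(sum(a^2))
    F <- an * (rn * an + rn^2 - sum(location * r))
    gradF <- (an^2 / rn + sum(a * r) / an + 2 * an + 2 * rn) * r -
             (an + 2 * rn + sum(a * r) / an) * location
    qxr0 <- cross3(moment, location)
    B <- (F * qxr0 - sum(qxr0 * r) * gradF) / F^2
    out[s] <- sum(B * orientations[s, ])
  }
  out
}

# Exhaustive per-location normal-equations single-dipole fit: the brute-force
# oracle for the vectorized scan inside the sequential fit.
brute_force_ecd <- function(gain, field) {
  P <- gain$n_points
  best <- list(r2 = -Inf, index = NA_integer_, q = c(NA, NA))
  for (i in seq_len(P)) {
    Gi <- gain$values[, c(2L * i - 1L, 2L * i)]
    L <- solve(crossprod(Gi), crossprod(Gi, field))
    est <- as.numeric(Gi %*% L)
    r2 <- if (stats::sd(est) == 0) 0 else stats::cor(field, est)^2
    if (r2 > best$r2 + 1e-15) best <- list(r2 = r2, index = i, q = as.numeric(L))
  }
  best
}

# exhaustive minimum-total-distance assignment over all permutations
brute_force_match_total <- function(p_idx, s_idx, grid) {
  stopifnot(length(p_idx) == length(s_idx))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  d <- function(i, j) sqrt(sum((grid$points[i, ] - grid$points[j, ])^2))
  min(vapply(perms(seq_along(s_idx)), function(pm)
    sum(vapply(seq_along(p_idx),
               function(k) d(p_idx[k], s_idx[pm[k]]), 0)), 0))
}
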