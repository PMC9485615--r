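test_that("noiseless single dipoles are recovered exactly (inverse crime)", {
  g <- small_grid(); G <- small_gain()
  set.seed(21)
  for (rep in 1:25) {
    d <- random_dipoles(g, 1)
    fit <- sdf(G, forward_project(G, d))
    expect_equal(nrow(fit$dipoles), 1L)
    expect_equal(fit$dipoles$grid_index, d$indices)
    expect_gt(fit$dipoles$r_squared, 1 - 1e-9)
    expect_equal(c(fit$dipoles$q1, fit$dipoles$q2),
                 as.numeric(d$coefficients),
                 tolerance = 1e-8)
    expect_true(fit$early_stop)
  }
})

test_that("fit selection and correlation are scale invariant", {
  g <- small_grid(); G <- small_gain()
  set.seed(22)
  d <- random_dipoles(g, 2)
  field <- forward_project(G, d) + 0.05 * max(abs(forward_project(G, d))) *
    stats::rnorm(248)
  f1 <- fit_single_ecd(G, field)
  f2 <- fit_single_ecd(G, 37.5 * field)
  expect_equal(f2$grid_index, f1$grid_index)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-10)
  expect_equal(f2$coefficients, 37.5 * f1$coefficients, tolerance = 1e-8)
  # pruning is scale invariant too
  s1 <- sdf(G, field); s2 <- sdf(G, 37.5 * field)
  expect_equal(s2$dipoles$grid_index, s1$dipoles$grid_index)
})

test_that("the vectorized scan agrees with a brute-force per-location solve", {
  g <- toy_grid(); G <- toy_gain()
  expect_lt(n_points(g), 60L)   # a ~50-point toy grid
  set.seed(23)
  for (rep in 1:12) {
    d <- random_dipoles(g, sample(1:2, 1))
    field <- forward_project(G, d)
    if (rep > 6) field <- field + 0.1 * stats::sd(field) * stats::rnorm(248)
    got <- fit_single_ecd(G, field)
    want <- brute_force_ecd(G, field)
    expect_equal(got$grid_index, want$index)
    expect_equal(got$coefficients, want$q, tolerance = 1e-8)
    expect_equal(got$r_squared, want$r2, tolerance = 1e-10)
  }
})

test_that("two well-separated dipoles are both recovered noiselessly", {
  # a constructed instance: two comparable-strength outer-layer dipoles,
  # 160 mm apart, on the toy grid
  g <- toy_grid(); G <- toy_gain()
  d <- dipole_set(c(26L, 29L), rbind(c(0.9, 0.7), c(0.8, 0.6)))
  expect_gt(sqrt(sum((g$points[26, ] - g$points[29, ])^2)), 100)
  field <- forward_project(G, d)
  fit <- sdf(G, field)
  expect_setequal(fit$dipoles$grid_index, d$indices)
  # sequential coefficients absorb slight field overlap; a joint 4-column
  # least-squares refit at the recovered locations is exact
  Gj <- G$values[, c(2L * 26L - 1L, 2L * 26L, 2L * 29L - 1L, 2L * 29L)]
  joint <- as.numeric(qr.solve(Gj, field))
  expect_equal(joint, as.numeric(t(d$coefficients)), tolerance = 1e-8)
  # cross-check against the exhaustive 2-dipole search over all index pairs
  P <- n_points(g)
  best <- NULL; best_r2 <- -Inf
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    Gi <- G$values[, c(2L * i - 1L, 2L * i, 2L * j - 1L, 2L * j)]
    est <- Gi %*% qr.solve(Gi, field)
    r2 <- stats::cor(field, est)^2
    if (r2 > best_r2) { best_r2 <- r2; best <- c(i, j) }
  }
  expect_equal(best, c(26L, 29L))
})

test_that("pruning discards candidates below 0.3 of the strongest magnitude", {
  # the rule itself on the canonical magnitudes
  expect_identical(vmhsim:::prune_keep(c(1.0, 0.6, 0.2), 0.3),
                   c(TRUE, TRUE, FALSE))
  expect_identical(vmhsim:::prune_keep(c(0.3, 1.0), 0.3), c(TRUE, TRUE))
  expect_identical(vmhsim:::prune_keep(c(0.29, 1.0), 0.3), c(FALSE, TRUE))
  # and through the fit: survivors always clear the threshold
  g <- small_grid(); G <- small_gain()
  cal <- calibrate_noise(G, f = 0.3, n_iter = 100, seed = 30)
  set.seed(31)
  for (rep in 1:5) {
    d <- random_dipoles(g, 3)
    fit <- sdf(G, simulate_measurement(G, d, cal))
    expect_true(all(fit$dipoles$magnitude >=
                    0.3 * max(fit$all_candidates$magnitude)))
    expect_true(all(fit$all_candidates$magnitude[
      !vmhsim:::prune_keep(fit$all_candidates$magnitude, 0.3)] <
      0.3 * max(fit$all_candidates$magnitude)))
  }
})

test_that("at most six candidates are ever produced", {
  g <- small_grid(); G <- small_gain()
  set.seed(25)
  d <- random_dipoles(g, 8)
  cal <- calibrate_noise(G, f = 0.1, n_iter = 100, seed = 26)
  field <- simulate_measurement(G, d, cal)
  fit <- sdf(G, field)
  expect_lte(nrow(fit$all_candidates), 6L)
  expect_lte(nrow(fit$dipoles), nrow(fit$all_candidates))
  expect_true(all(fit$all_candidates$iteration <= 6L))
})

test_that("the residual norm never increases across iterations", {
  g <- small_grid(); G <- small_gain()
  cal <- calibrate_noise(G, f = 0.3, n_iter = 100, seed = 27)
  set.seed(28)
  for (rep in 1:5) {
    d <- random_dipoles(g, 3)
    fit <- sdf(G, simulate_measurement(G, d, cal))
    hist <- c(fit$field_norm, fit$residual_norm_history)
    expect_true(all(diff(hist) <= 1e-9 * fit$field_norm))
  }
})

test_that("degenerate fields are rejected", {
  G <- small_gain()
  expect_error(sdf(G, rep(1, 248)), "zero variance")
  expect_error(fit_single_ecd(G, rep(0, 248)), "zero variance")
  expect_error(sdf(G, rep(0.5, 100)), "channel count")
})

test_that("fit objects expose the standard modelling methods", {
  g <- small_grid(); G <- small_gain()
  set.seed(29)
  d <- random_dipoles(g, 1)
  field <- forward_project(G, d)
  fit <- sdf(G, field)
  expect_s3_class(fit, "sdf")
  cf <- coef(fit)
  expect_equal(dim(cf), c(nrow(fit$dipoles), 2L))
  expect_equal(fitted(fit) + residuals(fit), field, tolerance = 1e-12)
  # a single noiseless dipole is fitted exactly, so the residual vanishes
  expect_lt(sqrt(sum(residuals(fit)^2)), 1e-8 * sqrt(sum(field^2)))
  s <- summary(fit)
  expect_s3_class(s, "summary.sdf")
  expect_equal(s$n_dipoles, nrow(fit$dipoles))
  expect_output(print(fit), "Sequential dipole fit")
  ds <- as_dipole_set(fit)
  expect_s3_class(ds, "dipole_set")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})
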