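test_that("a radial moment produces no external field", {
  arr <- synthetic_helmet_array()
  loc <- c(10, -20, 50)
  f <- dipole_field(loc, loc / sqrt(sum(loc^2)), arr)
  tang <- dipole_field(loc, c(-loc[2], loc[1], 0) / sqrt(sum(loc[1:2]^2)), arr)
  expect_lt(max(abs(f)), 1e-12 * max(abs(tang)))
})

test_that("the field is linear in the moment", {
  arr <- synthetic_helmet_array()
  f1 <- dipole_field(c(0, 0, 50), c(1, 0, 0), arr)
  f2 <- dipole_field(c(0, 0, 50), c(2, 0, 0), arr)
  expect_identical(f2, 2 * f1)
  fa <- dipole_field(c(20, 10, 40), c(1, 1, 0) / sqrt(2), arr)
  fb <- dipole_field(c(20, 10, 40), c(0, 0.5, 0.5), arr)
  fab <- dipole_field(c(20, 10, 40), c(1, 1, 0) / sqrt(2) + c(0, 0.5, 0.5), arr)
  expect_equal(fab, fa + fb, tolerance = 1e-12)
})

test_that("fields match an independent closed-form transcription to 1e-10", {
  # a ring of sensors at 120 mm plus the full synthetic helmet
  theta <- seq(0, 2 * pi, length.out = 25)[-25]
  ring <- sensor_array(cbind(120 * cos(theta), 120 * sin(theta), 0),
                       -cbind(cos(theta), sin(theta), 0))
  for (sensors in list(ring, synthetic_helmet_array())) {
    f <- dipole_field(c(0, 0, 50), c(1, 0, 0), sensors)
    o <- sarvas_oracle(c(0, 0, 50), c(1, 0, 0),
                       sensors$positions, sensors$orientations)
    expect_equal(f, o, tolerance = 1e-10)
    f2 <- dipole_field(c(15, -25, 40), c(0.3, 0.7, -0.2), sensors)
    o2 <- sarvas_oracle(c(15, -25, 40), c(0.3, 0.7, -0.2),
                        sensors$positions, sensors$orientations)
    expect_equal(f2, o2, tolerance = 1e-10)
  }
})

test_that("invalid dipole locations are rejected", {
  arr <- synthetic_helmet_array()
  expect_error(dipole_field(c(0, 0, 96), c(1, 0, 0), arr), "inside")
  expect_error(dipole_field(c(0, 0, NA), c(1, 0, 0), arr), "finite")
})

test_that("gain matrices have the array-major channels x 2P contract", {
  g <- small_grid()
  G1 <- small_gain()
  expect_equal(dim(G1), c(248L, 2L * n_points(g)))
  Gb <- gain_matrix(helmet_catalog(serials = 14L)[[1L]], g)
  expect_equal(nrow(Gb$values), 744L)
  # column (2i-1) is the field of the unit-e1 moment at point i
  i <- 37L
  f <- dipole_field(g$points[i, ], g$basis_e1[i, ],
                    helmet_sensors(std_helmet()))
  expect_equal(G1$values[, 2L * i - 1L], f, tolerance = 1e-10)
  f2 <- dipole_field(g$points[i, ], g$basis_e2[i, ],
                     helmet_sensors(std_helmet()))
  expect_equal(G1$values[, 2L * i], f2, tolerance = 1e-10)
})

test_that("forward projection superposes per-dipole fields", {
  g <- small_grid(); G <- small_gain()
  expect_identical(forward_project(G, dipole_set(integer(0), numeric(0))),
                   numeric(248))
  one <- forward_project(G, dipole_set(5L, c(1, 0)))
  expect_identical(one, G$values[, 9L])
  set.seed(4)
  d <- random_dipoles(g, 2)
  f12 <- forward_project(G, d)
  f1 <- forward_project(G, dipole_set(d$indices[1], d$coefficients[1, ]))
  f2 <- forward_project(G, dipole_set(d$indices[2], d$coefficients[2, ]))
  expect_equal(f12, f1 + f2, tolerance = 1e-12)
  byhand <- dipole_field(g$points[d$indices[1], ],
                         d$coefficients[1, 1] * g$basis_e1[d$indices[1], ] +
                         d$coefficients[1, 2] * g$basis_e2[d$indices[1], ],
                         helmet_sensors(std_helmet()))
  expect_equal(f1, byhand, tolerance = 1e-10)
  expect_error(forward_project(G, dipole_set(n_points(g) + 1L, c(1, 0))),
               "out of range")
})

test_that("effective rank counts singular values above the tolerance", {
  A <- diag(c(1, 0.5, 5e-4))   # singular values by construction
  expect_equal(effective_rank(A, 1e-3), 2L)
  expect_equal(effective_rank(A, 1e-4), 3L)
  expect_equal(effective_rank(matrix(0, 4, 4)), 0L)
  G <- toy_gain()
  r <- effective_rank(G)
  expect_lte(r, min(dim(G)))
  # duplicating every row scales all singular values by sqrt(2)
  expect_equal(effective_rank(rbind(G$values, G$values)), r)
  # monotone non-increasing in the tolerance
  tols <- c(1e-6, 1e-4, 1e-3, 1e-2, 1e-1)
  ranks <- vapply(tols, function(t) effective_rank(G, t), integer(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("adding a second array raises the effective rank", {
  g <- small_grid()
  r1 <- effective_rank(small_gain())
  for (s in c(3L, 11L)) {
    G2 <- gain_matrix(helmet_catalog(serials = s)[[1L]], g)
    expect_gt(effective_rank(G2), r1)
  }
})

test_that("fields are equivariant under joint rotation of the geometry", {
  t <- rigid_transform(c(20, -10, 35), c(0, 0, 0))
  R <- rotation_matrix(t)
  arr <- synthetic_helmet_array(50)
  arr_rot <- apply_transform(arr, t)
  loc <- c(25, 5, 45); mom <- c(0.4, -0.8, 0.2)
  f <- dipole_field(loc, mom, arr)
  f_rot <- dipole_field(as.numeric(R %*% loc), as.numeric(R %*% mom), arr_rot)
  expect_equal(f, f_rot, tolerance = 1e-9)
})

test_that("field magnitude falls as the source moves inward", {
  arr <- synthetic_helmet_array()
  depths <- seq(80, 20, by = -10)
  mags <- vapply(depths, function(z)
    max(abs(dipole_field(c(0, 0, z), c(1, 0, 0), arr))), 0)
  expect_true(all(diff(mags) < 0))
})
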