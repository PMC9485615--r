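# Drivers are exercised on a reduced geometry (subdivision-2 grid) and a few
# trials: these tests check plumbing contracts (determinism, shared placed
# sets, structural invariants), not the scientific effects, which live in the
# acceptance suite.

tiny_config <- function(...) {
  args <- list(seed = 77L, n_sims = 3L, dipole_counts = 2L,
               noise_levels = c(0, 0.1), n_pairs = 2L,
               max_neighbor_cases = 3L, calibration_iter = 60L,
               subdivisions = 2L, n_perm = 300L,
               helmet_serials = c(1L, 3L, 11L), report_rank = FALSE)
  do.call(vmh_config, utils::modifyList(args, list(...)))
}

test_that("part 1 is deterministic and shares placed sets across helmets", {
  cfg <- tiny_config()
  r1 <- run_part1(cfg)
  r2 <- run_part1(cfg)
  expect_identical(r1$raw, r2$raw)
  expect_identical(r1$summary, r2$summary)
  # identical placed dipole sets for every helmet within a trial
  key <- interaction(r1$raw$noise, r1$raw$n_placed, r1$raw$trial)
  per_trial <- split(r1$raw$placed_indices, key)
  expect_true(all(vapply(per_trial,
                         function(v) length(unique(v)) == 1L, TRUE)))
  expect_equal(nrow(r1$raw), 3L * 2L * 3L)   # trials x noise x helmets
})

test_that("noiseless single dipoles are solved perfectly by every helmet", {
  cfg <- vmh_config(seed = 78L, n_sims = 5L, dipole_counts = 1L,
                    noise_levels = 0, subdivisions = 2L,
                    calibration_iter = 60L)
  r <- run_part1(cfg)
  expect_true(all(r$raw$n_solved == 1L))
  expect_true(all(r$raw$mean_distance_mm == 0))
  s <- r$summary
  expect_true(all(s$n_solved_mean == 1))
  expect_true(all(s$distance_mean_mm == 0))
})

test_that("part 2 produces valid best sets and robustness percentages", {
  cfg <- tiny_config()
  r <- run_part2(cfg)
  expect_equal(nrow(r$pairs), 2L)
  expect_true(all(r$pairs$n_best >= 1))
  expect_true(all(r$robustness$robustness_pct >= 0 &
                  r$robustness$robustness_pct <= 100))
  expect_equal(nrow(r$robustness), 2L * 3L)    # pairs x helmets
  expect_true(all(r$best_pct >= 0 & r$best_pct <= 100))
  r2 <- run_part2(cfg)
  expect_identical(r$robustness, r2$robustness)
  expect_identical(r$pairs, r2$pairs)
  # per-pair binary (helmet x neighbor) best-solution matrices
  bm <- best_matrix(r$neighbor_best[[1]], c("1", "3", "11"))
  expect_type(bm, "logical")
  expect_equal(dim(bm), c(3L, cfg$max_neighbor_cases))
  expect_true(all(colSums(bm) >= 1))
  expect_equal(100 * rowMeans(bm)[["3"]],
               r$robustness$robustness_pct[r$robustness$pair == 1 &
                                           r$robustness$serial == 3])
  # effective ranks are reported when requested
  cfg_rank <- tiny_config(report_rank = TRUE)
  cfg_rank$n_pairs <- 1L
  rr <- run_part2(cfg_rank)
  expect_named(rr$effective_ranks, c("1", "3", "11"))
  expect_true(all(rr$effective_ranks > 0))
})

test_that("part 3 selection, oracle bound and flags are coherent", {
  cfg <- tiny_config()
  cfg$n_pairs <- 4L
  r <- run_part3(cfg)
  cand <- setdiff(cfg$helmet_serials, 1L)
  expect_true(all(is.na(r$cases$selected_serial) |
                  r$cases$selected_serial %in% as.character(cand)))
  # the oracle (theoretical) error never exceeds the personalized error
  ok <- !is.na(r$cases$personalized_error_mm)
  expect_true(all(r$cases$theoretical_error_mm[ok] <=
                  r$cases$personalized_error_mm[ok] + 1e-9))
  expect_equal(r$n_no_preference, sum(r$cases$no_preference))
  expect_true(r$best_single_serial %in% cand)
  r2 <- run_part3(cfg)
  expect_identical(r$cases, r2$cases)
  expect_identical(r$means, r2$means)
  # the standard helmet joins stage 2 only when asked
  cfg_std <- tiny_config(include_standard_in_stage2 = TRUE)
  cfg_std$n_pairs <- 2L
  r3 <- run_part3(cfg_std)
  expect_true(all(colnames(r3$candidate_errors) == c("1", "3", "11")))
  # tie sweep reports one personalized mean per extra selection
  cfg_sweep <- tiny_config(tie_sweep = 3L)
  cfg_sweep$n_pairs <- 2L
  r4 <- run_part3(cfg_sweep)
  expect_length(r4$tie_sweep_means, 3L)
})

test_that("configs validate and round-trip through YAML", {
  expect_error(vmh_config(helmet_serials = c(1, 99)), "catalog")
  expect_error(vmh_config(n_sims = 0), ">= 1")
  cfg <- vmh_config(seed = 9L, n_sims = 12L, layer_radii = c(60, 70, 80),
                    bn_mode = "per-array")
  path <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(seed = 9L, n_sims = 12L, bn_mode = "per-array",
                        grid = list(layer_radii = c(60, 70, 80))), path)
  back <- read_config_yaml(path)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$n_sims, cfg$n_sims)
  expect_equal(back$layer_radii, cfg$layer_radii)
  expect_equal(back$bn_mode, "per-array")
  yaml::write_yaml(list(bogus_key = 1), path)
  expect_error(read_config_yaml(path), "unknown config key")
})

test_that("derived seeds give stable, distinct substreams", {
  expect_identical(derive_seed(1L, 2L, 3L), derive_seed(1L, 2L, 3L))
  seeds <- vapply(1:500, function(i) derive_seed(42L, 1L, i), integer(1))
  expect_equal(length(unique(seeds)), 500L)
  expect_true(all(seeds >= 1 & seeds < 2^31))
  expect_false(derive_seed(1L, 2L, 3L) == derive_seed(1L, 3L, 2L))
})

test_that("the CLI writes catalogs, ranks and manifests", {
  out <- withr::local_tempdir()
  expect_output(status <- run_cli(c("catalog", "--out", out)))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "catalog.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  tab <- utils::read.csv(file.path(out, "catalog.csv"))
  expect_setequal(unique(tab$serial), 1:14)
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$command, "catalog")
  expect_equal(manifest$config$seed, 1L)
  # rank subcommand on a reduced grid
  cfgfile <- file.path(out, "cfg.yml")
  yaml::write_yaml(list(subdivisions = 1L), cfgfile)
  suppressMessages(status <- run_cli(c("rank", "--helmet", "3",
                                       "--config", cfgfile, "--out", out)))
  expect_identical(status, 0L)
  rank <- jsonlite::read_json(file.path(out, "rank.json"))
  expect_equal(rank$serial, 3L)
  expect_gt(rank$effective_rank, 0)
  # bad inputs exit nonzero without raising
  expect_message(bad <- run_cli(c("nonsense")), "usage")
  expect_identical(bad, 1L)
})
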