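test_that("ensemble specifications validate their invariants", {
  s <- structure_from_open_set(30, 1:10)
  expect_error(ensemble_spec(list(s), weights = c(0.7, 0.3)),
               class = "smstruct_value_error")
  expect_error(ensemble_spec(s, p_open = 0.2, p_closed = 0.4),
               class = "smstruct_value_error")
  expect_error(ensemble_spec(s, p_open = 1.4), class = "smstruct_value_error")
  expect_error(ensemble_spec(s, missing_tail = 30),
               class = "smstruct_value_error")
  expect_error(ensemble_spec(list(s, structure_from_open_set(20, 1:10))),
               class = "smstruct_value_error")
})

test_that("simulation is deterministic under a fixed seed", {
  hp <- fixture_hairpin()
  a <- simulate_mods(hp, 50, seed = 12)
  b <- simulate_mods(hp, 50, seed = 12)
  expect_identical(unclass(a$mods), unclass(b$mods))
  expect_identical(a$truth, b$truth)
  sa <- simulate_stats(a$mods, hp, seed = 13)
  sb <- simulate_stats(b$mods, hp, seed = 13)
  expect_identical(unclass(sa), unclass(sb))
  expect_false(identical(unclass(simulate_mods(hp, 50, seed = 14)$mods),
                         unclass(a$mods)))
})

test_that("noise-free limits and the missing tail are honored", {
  hp <- fixture_hairpin(p_open = 1, p_closed = 0)
  ref <- hp$structures[[1]]
  sim <- simulate_mods(hp, 20, seed = 3)
  x <- unclass(sim$mods)
  L <- hp$length
  expect_true(all(is.na(x[, (L - 12):L])))
  covered <- seq_len(L - 13)
  expected_mod <- intersect(intersect(hp$probed, ref$open_set), covered)
  for (r in 1:20) {
    expect_setequal(which(x[r, covered] == 1), expected_mod)
  }
  expect_equal(sim$truth, rep(1L, 20))
})

test_that("per-position modification frequencies match the generator", {
  hp <- fixture_hairpin(p_open = 0.5, p_closed = 0.15)
  sim <- simulate_mods(hp, 2000, seed = 17)
  x <- unclass(sim$mods)
  ref <- hp$structures[[1]]
  open_probed <- setdiff(intersect(hp$probed, ref$open_set), 48:60)
  freq <- colMeans(x[, open_probed, drop = FALSE])
  tol <- 3 * sqrt(0.25 / 2000)
  expect_true(all(abs(freq - 0.5) < tol))
  paired_probed <- setdiff(setdiff(hp$probed, ref$open_set), 48:60)
  freq_p <- colMeans(x[, paired_probed, drop = FALSE])
  expect_true(all(abs(freq_p - 0.15) < 3 * sqrt(0.15 * 0.85 / 2000)))
})

test_that("statistic emission matches the configured distributions", {
  d <- stat_distribution(0.15)
  expect_equal(d$cdf(0.2), 0.15)
  expect_equal(d$cdf(1), 1)
  set.seed(19)
  draws <- d$sample(20000)
  expect_lt(abs(mean(draws < 0.2) - 0.15), 3 * sqrt(0.15 * 0.85 / 20000))
  # point-mass-like alternative makes calling exact on modified cells
  hp <- fixture_hairpin()
  sim <- simulate_mods(hp, 100, seed = 23)
  spec_sharp <- ensemble_spec(hp$structures, p_open = hp$p_open[1],
                              p_closed = hp$p_closed[1],
                              stat_alt = stat_distribution(1 - 1e-12),
                              stat_null = stat_distribution(0))
  stats <- simulate_stats(sim$mods, spec_sharp, seed = 24)
  called <- call_modifications(stats, 0.2)
  expect_identical(unclass(called) == 1, unclass(sim$mods) == 1)
})

test_that("full pipeline calibration recovers the configured operating point", {
  hp <- fixture_hairpin()
  null_spec <- ensemble_spec(hp$structures, p_open = 0, p_closed = 0,
                             probed = hp$probed)
  ctrl <- simulate_stats(simulate_mods(null_spec, 400, seed = 5)$mods,
                         null_spec, seed = 6)
  curve <- fdr_curve(ctrl, seq(0.05, 0.5, by = 0.05))
  thr <- select_threshold(curve, target_fdr = 0.15)
  sim <- simulate_mods(hp, 800, seed = 7)
  stats <- simulate_stats(sim$mods, hp, seed = 8)
  called <- call_modifications(stats, thr)
  truth_mod <- unclass(sim$mods) == 1
  called_mod <- unclass(called) == 1
  probed_cov <- intersect(hp$probed, seq_len(hp$length - hp$missing_tail))
  tm <- truth_mod[, probed_cov]; cm <- called_mod[, probed_cov]
  sens <- mean(cm[tm]); spec <- mean(!cm[!tm])
  p_sens <- hp$stat_alt$cdf(thr)
  p_spec <- 1 - hp$stat_null$cdf(thr)
  expect_lt(abs(sens - p_sens), 3 * sqrt(p_sens * (1 - p_sens) / sum(tm)))
  expect_lt(abs(spec - p_spec), 3 * sqrt(p_spec * (1 - p_spec) / sum(!tm)))
})

test_that("bundled fixtures are internally consistent and reproducible", {
  hp <- fixture_hairpin()
  ref <- hp$structures[[1]]
  expect_equal(ref$open_set, c(13:20, 33:60))
  expect_equal(constrained_fold(ref$sequence)$dotbracket, ref$dotbracket)

  td <- fixture_two_domain()
  dbs <- vapply(td$structures, function(s) s$dotbracket, "")
  diffpos <- which(strsplit(dbs[1], "")[[1]] != strsplit(dbs[2], "")[[1]])
  expect_true(all(diffpos >= 25 & diffpos <= 44))
  expect_length(attr(td, "aptamer_positions"), 10L)
  tb <- fixture_two_domain(bound = TRUE)
  expect_equal(tb$p_open[attr(tb, "aptamer_positions")], rep(0.1, 10))

  t1 <- fixture_transcriptome(5, seed = 1)
  t2 <- fixture_transcriptome(5, seed = 1)
  expect_identical(
    lapply(t1$specs, function(s) s$structures[[1]]$dotbracket),
    lapply(t2$specs, function(s) s$structures[[1]]$dotbracket)
  )
  sim1 <- simulate_mods(t1$specs[[1]], 30)
  sim2 <- simulate_mods(t2$specs[[1]], 30)
  expect_identical(unclass(sim1$mods), unclass(sim2$mods))
})

test_that("ensemble specs load from YAML configs", {
  dir <- withr::local_tempdir()
  db <- file.path(dir, "structures.db")
  hp <- fixture_hairpin()
  write_structures(hp$structures, db)
  cfg <- file.path(dir, "spec.yaml")
  writeLines(c(
    "structures: structures.db",
    "p_open: 0.6",
    "p_closed: 0.1",
    "missing_tail: 5",
    "seed: 3",
    "stat_null_p_below: 0.2"
  ), cfg)
  spec <- read_ensemble_spec(cfg)
  expect_s3_class(spec, "sms_ensemble_spec")
  expect_equal(spec$p_open[1], 0.6)
  expect_equal(spec$missing_tail, 5L)
  expect_equal(spec$stat_null$p_below, 0.2)
  expect_equal(spec$structures[[1]]$dotbracket, hp$structures[[1]]$dotbracket)
  # inline structures
  cfg2 <- file.path(dir, "spec2.yaml")
  writeLines(c(
    "structures:",
    "  - dotbracket: '((((....))))'",
    "    sequence: GGGGAAAACCCC",
    "weights: [1.0]",
    "missing_tail: 0"
  ), cfg2)
  spec2 <- read_ensemble_spec(cfg2)
  expect_equal(spec2$length, 12L)
  expect_error(read_ensemble_spec(textConnection("p_open: 0.5")),
               class = "smstruct_format_error")
})
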