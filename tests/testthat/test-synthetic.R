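test_that("synthetic connectomes are valid, bilateral and reproducible", {
  spec <- synthetic_spec(rng_seed = 1)
  co <- synth_connectome(spec)
  expect_s3_class(co, "ndm_connectome")
  expect_equal(nrow(co$weights), 82)
  expect_equal(nrow(homologue_pairs(co)), 41)
  expect_true(all(co$weights >= 0))
  expect_equal(co$weights, t(co$weights))
  # homotopic edges always present
  pairs <- homologue_pairs(co)
  expect_true(all(co$weights[cbind(pairs$left, pairs$right)] > 0))
  # determinism
  co2 <- synth_connectome(synthetic_spec(rng_seed = 1))
  expect_identical(co$weights, co2$weights)
  expect_false(identical(
    synth_connectome(synthetic_spec(rng_seed = 2))$weights, co$weights))
})

test_that("spec validation catches inconsistent worlds", {
  expect_error(synthetic_spec(n_regions = 81), "even")
  expect_error(synthetic_spec(sigma = -0.1), "nonnegative")
  expect_error(synthetic_spec(t_star = 7.5), "grid")
  expect_error(synthetic_spec(shortcut_density = 0), "in \\(0, 1\\]")
  expect_error(synthetic_spec(seed_pair = 42), "out of range")
})

test_that("noise-free planted atrophy correlates perfectly at the truth", {
  spec <- synthetic_spec(n_regions = 30, sigma = 0, rng_seed = 5)
  co <- synth_connectome(spec)
  sa <- synth_atrophy(spec, co)
  dec <- build_laplacian(co)
  ex <- which(bilateral_seed_vector(co$regions, sa$truth$pair_label) == 1)
  f0 <- numeric(30); f0[ex] <- 1
  traj <- propagate(dec, f0, times = spec$times)
  r <- correlation_trace(traj, sa$atrophy, exclude = ex)
  expect_equal(r[spec$times == sa$truth$t_star], 1.0, tolerance = 1e-12)
})

test_that("planted seeds are recovered at low noise, not at extreme noise", {
  # scaled-down version of the recovery property (full 100-rep version in
  # the acceptance suite)
  rec <- 0
  for (i in 1:20) {
    set.seed(200 + i)
    spec <- synthetic_spec(seed_pair = sample(41, 1),
                           t_star = sample(5:30, 1), rng_seed = 200 + i)
    co <- synth_connectome(spec)
    sa <- synth_atrophy(spec, co)
    scan <- repeated_seed_scan(co, sa$atrophy)
    rec <- rec + (scan$seeds$seed_label[1] == sa$truth$pair_label)
  }
  expect_gte(rec, 18)

  # sigma -> infinity degrades recovery to chance
  rec_noise <- 0
  for (i in 1:15) {
    set.seed(300 + i)
    spec <- synthetic_spec(sigma = 100, seed_pair = sample(41, 1),
                           t_star = 15, rng_seed = 300 + i)
    co <- synth_connectome(spec)
    sa <- synth_atrophy(spec, co)
    scan <- repeated_seed_scan(co, sa$atrophy)
    rec_noise <- rec_noise + (scan$seeds$seed_label[1] == sa$truth$pair_label)
  }
  expect_lte(rec_noise, 5)   # chance is ~1/41; 6+/15 would be wildly above
})

test_that("volume tables carry the planted group difference", {
  spec <- synthetic_spec(rng_seed = 31)
  co <- synth_connectome(spec)
  vt <- synth_volume_tables(spec, co)
  expect_equal(nrow(as.data.frame(vt$patients)), 14)
  expect_equal(nrow(as.data.frame(vt$controls)), 12)
  am <- t_map_two_sample(vt$patients, vt$controls)
  f <- ndmscan:::planted_pattern(spec, co)$f
  expect_gt(cor(am$t, f), 0.5)

  # no effect -> t-map centred on zero
  null_spec <- synthetic_spec(effect = 0, rng_seed = 32)
  co0 <- synth_connectome(null_spec)
  vt0 <- synth_volume_tables(null_spec, co0)
  am0 <- t_map_two_sample(vt0$patients, vt0$controls)
  expect_lt(abs(mean(am0$t)), 3 / sqrt(82))
})

test_that("end-to-end study recovers the planted pair from volumes", {
  # detectable-atrophy regime (effect 15% >= the 5% floor, CV 2%, n 14 v 12)
  rec <- 0
  for (i in 1:15) {
    set.seed(400 + i)
    spec <- synthetic_spec(effect = 0.15, seed_pair = sample(41, 1),
                           t_star = sample(5:30, 1), rng_seed = 400 + i)
    co <- synth_connectome(spec)
    vt <- synth_volume_tables(spec, co)
    am <- t_map_two_sample(vt$patients, vt$controls)
    scan <- repeated_seed_scan(co, am)
    rec <- rec + (scan$seeds$seed_label[1] == vt$truth$pair_label)
  }
  expect_gte(rec, 13)   # full 50-rep version in the acceptance suite
})

test_that("a written study directory is complete and self-consistent", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_regions = 20, rng_seed = 17)
  write_synthetic_study(spec, dir)
  files <- c("connectome.txt", "regions.tsv", "volumes_patients.tsv",
             "volumes_controls.tsv", "atrophy.tsv", "truth.tsv")
  expect_true(all(file.exists(file.path(dir, files))))
  co <- load_connectome(file.path(dir, "connectome.txt"),
                        file.path(dir, "regions.tsv"))
  at <- read_atrophy_map(file.path(dir, "atrophy.tsv"))
  expect_identical(at$region_label, co$regions$label)
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_true(truth$pair_index %in% 1:10)
  # atrophy file must not leak the ground truth
  expect_false(any(grepl("t_star", readLines(file.path(dir, "atrophy.tsv")))))
})
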