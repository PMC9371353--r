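test_that("bilateral seed vectors have two ones at the homologue pair", {
  regs <- bilateral_regions(82)
  f0 <- bilateral_seed_vector(regs, "lh_r07")
  expect_equal(sum(f0), 2)
  expect_equal(which(f0 == 1), c(7L, 48L))
  expect_equal(bilateral_seed_vector(regs, 48L), f0)   # via either member
  expect_error(bilateral_seed_vector(regs, "nowhere"), "unknown region")

  pairs <- homologue_pairs(regs)
  expect_equal(nrow(pairs), 41)   # 41 distinct initial conditions
  seeds <- vapply(pairs$pair_label,
                  function(s) bilateral_seed_vector(regs, s), numeric(82))
  expect_equal(unname(colSums(seeds)), rep(2, 41))
  expect_equal(nrow(unique(t(seeds))), 41)

  expect_message(f0m <- bilateral_seed_vector(midline_regions(3), "m02"),
                 "midline")
  expect_equal(sum(f0m), 1)
})

test_that("correlation traces hit +/-1 on planted patterns, NA at t = 0", {
  co <- random_connectome(10, seed = 11)
  dec <- build_laplacian(co)
  ex <- c(1L, 6L)
  f0 <- numeric(10); f0[ex] <- 1
  traj <- propagate(dec, f0, times = 0:10)
  target <- atrophy_map(traj$values[6, ], labels = co$regions$label)

  r <- correlation_trace(traj, target, exclude = ex)
  expect_true(is.na(r[1]))            # zero variance at t = 0 is missing
  expect_equal(r[6], 1.0, tolerance = 1e-12)
  anti <- atrophy_map(-traj$values[6, ], labels = co$regions$label)
  expect_equal(correlation_trace(traj, anti, exclude = ex)[6], -1.0,
               tolerance = 1e-12)
  expect_true(all(abs(r[-1]) <= 1 + 1e-12))
  flat <- atrophy_map(rep(2, 10), labels = co$regions$label)
  expect_true(all(is.na(correlation_trace(traj, flat, exclude = ex))))
})

test_that("the scan has the stated dimensions and recovers a planted seed", {
  spec <- synthetic_spec(rng_seed = 5)
  co <- synth_connectome(spec)
  dec <- build_laplacian(co)
  pairs <- homologue_pairs(co)
  ex <- c(pairs$left[12], pairs$right[12])
  f0 <- numeric(82); f0[ex] <- 1
  noise_free <- atrophy_map(propagate(dec, f0, times = 20)$values[1, ],
                            labels = co$regions$label)
  scan <- repeated_seed_scan(co, noise_free, dec = dec)

  expect_identical(dim(scan$corr_matrix), c(41L, 51L))
  expect_equal(unique(scan$n_used), 80L)
  expect_identical(scan$seeds$seed_label[1], pairs$pair_label[12])
  expect_equal(scan$seeds$max_r[1], 1.0, tolerance = 1e-9)
  expect_equal(scan$seeds$t_star[1], 20)
  # row maxima are exact and NA-free times only
  for (k in c(1, 12, 41)) {
    row <- scan$corr_matrix[pairs$pair_label[k] == rownames(scan$corr_matrix), ]
    expect_equal(scan$seeds$max_r[scan$seeds$seed_label == pairs$pair_label[k]],
                 max(row, na.rm = TRUE))
  }
  expect_true(all(is.na(scan$corr_matrix[, 1])))   # t = 0 column
  expect_true(all(scan$seeds$p_fwe >= scan$seeds$p))
  expect_true(all(scan$seeds$p > 0 & scan$seeds$p_fwe <= 1))
})

test_that("scan errors on degenerate atrophy and mismatched regions", {
  spec <- synthetic_spec(n_regions = 10, seed_pair = 3, rng_seed = 2)
  co <- synth_connectome(spec)
  flat <- atrophy_map(rep(1, 10), labels = co$regions$label)
  expect_error(repeated_seed_scan(co, flat), "degenerate atrophy")
  wrong <- atrophy_map(rnorm(10), labels = rev(co$regions$label))
  expect_error(repeated_seed_scan(co, wrong), "do not match")
})

test_that("the correlation surface is scale invariant", {
  spec <- synthetic_spec(n_regions = 20, rng_seed = 8)
  co <- synth_connectome(spec)
  at <- synth_atrophy(spec, co)$atrophy
  s1 <- repeated_seed_scan(co, at)
  scaled <- atrophy_map(at$t * 37.5, labels = at$region_label)
  s2 <- repeated_seed_scan(co, scaled)
  expect_equal(s1$corr_matrix, s2$corr_matrix, tolerance = 1e-12)
})

test_that("max_r is monotone when the time grid is extended", {
  spec <- synthetic_spec(n_regions = 20, rng_seed = 13)
  co <- synth_connectome(spec)
  at <- synth_atrophy(spec, co)$atrophy
  short <- repeated_seed_scan(co, at, times = 0:20)
  long <- repeated_seed_scan(co, at, times = 0:50)
  short_r <- short$seeds$max_r[order(short$seeds$seed_label)]
  long_r <- long$seeds$max_r[order(long$seeds$seed_label)]
  expect_true(all(long_r >= short_r - 1e-12))
})

test_that("FWE correction is Bonferroni with Holm as alternative", {
  p <- c(0.001, 0.5, 0.04)
  expect_equal(ndmscan:::fwe_adjust(rep(0.001, 41))[1], 0.041)
  expect_equal(ndmscan:::fwe_adjust(p)[2], 1.0)            # clamped at 1
  expect_equal(ndmscan:::fwe_adjust(0.37), 0.37)           # S = 1 identity
  expect_equal(ndmscan:::fwe_adjust(p, "holm"), p.adjust(p, "holm"))

  spec <- synthetic_spec(n_regions = 20, rng_seed = 3)
  co <- synth_connectome(spec)
  at <- synth_atrophy(spec, co)$atrophy
  scan <- repeated_seed_scan(co, at)
  holm <- fwe_correct(scan, "holm")
  expect_true(all(holm$seeds$p_fwe <= scan$seeds$p_fwe + 1e-15))
  expect_identical(holm$correction, "holm")
})

test_that("seed-scan output writes summary and surface TSVs", {
  spec <- synthetic_spec(n_regions = 10, seed_pair = 3, rng_seed = 21)
  co <- synth_connectome(spec)
  at <- synth_atrophy(spec, co)$atrophy
  scan <- repeated_seed_scan(co, at)
  sp <- withr::local_tempfile(fileext = ".tsv")
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_seed_scan(scan, sp, surface_path = fp)
  summ <- read.table(sp, header = TRUE, sep = "\t")
  expect_identical(names(summ), c("seed_label", "max_r", "t_star", "p", "p_fwe"))
  expect_equal(nrow(summ), 5)
  surf <- read.table(fp, header = TRUE, sep = "\t")
  expect_equal(nrow(surf), 5 * 51)
})
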