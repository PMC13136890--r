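test_that("closed-form energy distances are reproduced", {
  # identical multisets
  x <- matrix(rnorm(30), ncol = 3)
  expect_equal(energy_distance(x, x), 0, tolerance = 1e-12)
  # 1-D singletons {0} vs {1}: 2*1 - 0 - 0
  expect_equal(energy_distance(matrix(0), matrix(1), min_vectors = 1), 2)
  # 1-D {0,0} vs {1,3}: 2/4*(1+3+1+3) - 0 - 1/4*(2+2)
  expect_equal(energy_distance(matrix(c(0, 0)), matrix(c(1, 3))), 3)
})

test_that("energy distance agrees with the brute-force oracle", {
  set.seed(2024)
  for (rep in 1:40) {
    n <- sample(2:60, 1)
    m <- sample(2:60, 1)
    x <- matrix(rnorm(n * 9), ncol = 9)
    y <- matrix(rnorm(m * 9, mean = 0.3), ncol = 9)
    expect_equal(energy_distance(x, y), energy_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("energy distance is symmetric and scale-equivariant", {
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(rnorm(40 * 9), ncol = 9)
    y <- matrix(rnorm(30 * 9, sd = 2), ncol = 9)
    e <- energy_distance(x, y)
    expect_equal(e, energy_distance(y, x), tolerance = 1e-12)
    c0 <- runif(1, 0.1, 10)
    expect_equal(energy_distance(c0 * x, c0 * y), c0 * e,
                 tolerance = 1e-10)
    expect_gt(e, -1e-12)
  }
})

test_that("small or undefined feature sets yield NA, not errors", {
  x <- matrix(rnorm(90), ncol = 9)
  expect_true(is.na(energy_distance(x[1, , drop = FALSE], x)))
  expect_true(is.na(energy_distance(x, x, min_vectors = 100)))
  sm <- signal_matrix(data.frame(read_id = "r", position = 1, dwell = 1,
                                 mean = 0, sd = 0), ref_length = 5)
  expect_true(is.na(energy_distance(window_features(sm, 1),
                                    window_features(sm, 2))))
  expect_error(energy_distance(x, x[, 1:3]), "dimension")
})

test_that("profiles localize a mean-shift effect at the perturbed site", {
  cfg <- sim_config(seed = 21, modified_positions = 60L,
                    modified_error = c(mismatch = 0.02, deletion = 0.01,
                                       insertion = 0.005),
                    mod_mean_shift = 0.5, mod_sd_inflation = 1,
                    dwell_shift_logmean = 0)
  sim <- simulate_dataset(cfg)
  sc <- pipeline_scores(sim, max_vectors = 100)
  prof <- sc$profile
  amax <- prof$position[prof$defined][
    which.max(prof$energy_distance[prof$defined])]
  # 3-nt window smearing bounds the argmax to site +/- 1
  expect_true(amax %in% 59:61)
  # a replicate-control comparison stays low everywhere the effect is strong
  simn <- simulate_dataset(null_sim_config(seed = 21,
                                           modified_positions = 60L))
  pren <- preprocess_signals(coverage_filter(simn$signal$modified),
                             coverage_filter(simn$signal$control))
  profn <- energy_profile(pren$modified, pren$control, max_vectors = 100)
  null95 <- quantile(profn$energy_distance[profn$defined], 0.95)
  expect_gt(prof$energy_distance[60], null95)
})

test_that("subsampling is a seeded no-op when windows fit the cap", {
  sim <- simulate_dataset(tiny_sim_config(seed = 6))
  pre <- preprocess_signals(coverage_filter(sim$signal$modified),
                            coverage_filter(sim$signal$control))
  p1 <- energy_profile(pre$modified, pre$control, max_vectors = 10000)
  p2 <- energy_profile(pre$modified, pre$control, max_vectors = 10000,
                       subsample_seed = 99)
  expect_identical(p1, p2)
  # with an active cap, a fixed subsample seed reproduces the profile
  p3 <- energy_profile(pre$modified, pre$control, max_vectors = 20,
                       subsample_seed = 5)
  p4 <- energy_profile(pre$modified, pre$control, max_vectors = 20,
                       subsample_seed = 5)
  expect_identical(p3, p4)
  expect_true(all(p3$n[p3$defined] <= 20))
})

test_that("profile marks edges and low-coverage centers undefined", {
  sim <- simulate_dataset(tiny_sim_config(seed = 13))
  pre <- preprocess_signals(coverage_filter(sim$signal$modified),
                            coverage_filter(sim$signal$control))
  prof <- energy_profile(pre$modified, pre$control, min_vectors = 10)
  expect_false(prof$defined[1])
  expect_false(prof$defined[120])
  expect_true(all(is.na(prof$energy_distance[!prof$defined])))
  expect_true(all(prof$n[prof$defined] >= 10 & prof$m[prof$defined] >= 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  expect_equal(strip_attrs(read_profile_csv(path)), strip_attrs(prof),
               tolerance = 1e-12)
})
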