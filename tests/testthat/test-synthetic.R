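test_that("weighing schedule follows the twice-weekly then weekly design", {
  grid <- build_schedule(cohort_config())
  expect_identical(grid[1:7], c(0, 3, 7, 10, 14, 17, 21))
  expect_true(all(grid >= 0 & grid <= 72))   # age cap 100 d, weaning at 28 d
  expect_true(all(diff(grid) > 0))
  expect_identical(anyDuplicated(grid), 0L)
  # weekly phase has 7-day gaps
  expect_true(all(diff(grid[grid >= 21]) == 7))
})

test_that("parameter draws are reproducible and respect the invariants", {
  cfg <- cohort_config()
  set.seed(99); a <- sample_animal_params(cfg)
  set.seed(99); b <- sample_animal_params(cfg)
  expect_identical(a, b)
  set.seed(100)
  draws <- replicate(500, {
    p <- sample_animal_params(cfg)
    c(p$W0, p$mu0, p$D, p$C, p$ts)
  })
  expect_true(all(draws[1, ] > 0))                  # W0
  expect_true(all(draws[2, ] > 0 & draws[3, ] > 0)) # mu0, D
  expect_true(all(draws[4, ] >= 0 & draws[4, ] <= 0.12))
  expect_true(all(draws[5, ] > 2 & draws[5, ] < 30))
  # log(mu0) and log(D) are strongly correlated by design
  expect_gt(cor(log(draws[2, ]), log(draws[3, ])), 0.8)
})

test_that("mean recovery switch of many draws matches the configured 9 d", {
  cfg <- cohort_config()
  set.seed(7)
  ts <- replicate(1e4, sample_animal_params(cfg)$ts)
  se <- sd(ts) / sqrt(length(ts))
  expect_lt(abs(mean(ts) - 9), 2 * se + 0.1)  # small truncation bias allowed
})

test_that("zero-perturbation configuration yields C = 0 exactly", {
  cfg <- cohort_config(c_prob_zero = 1)
  set.seed(12)
  expect_true(all(replicate(20, sample_animal_params(cfg)$C) == 0))
})

test_that("trajectory simulation is exact without noise, positive with noise", {
  p <- ref_pert()
  grid <- paper_schedule()
  tr <- simulate_trajectory(p, grid, noise_cv = 0, animal_id = "T")
  expect_identical(tr$weights, perturbed_weight(p, grid))
  # strong perturbation: day-1 weighing below the weaning weighing
  expect_lt(tr$weights[2], tr$weights[1])
  set.seed(33)
  tr2 <- simulate_trajectory(p, grid, noise_cv = 0.5, animal_id = "T")
  expect_true(all(tr2$weights > 0))   # lognormal noise keeps positivity
})

test_that("faecal scores sit on the panel days and track C when linked", {
  cfg <- cohort_config()
  expect_identical(cfg$fs_days, c(0, 2, 6, 8, 12, 15, 20, 27, 34))
  set.seed(41)
  s <- simulate_faecal_scores(ref_pert(), cfg)
  expect_identical(length(s), 9L)
  expect_true(all(s %in% 0:2))
  # null linkage: cohort-level correlation of C with FS_sum is ~0
  cfg0 <- cohort_config(fs_c_slope = 0, fs_recovery_decay = 0)
  set.seed(42)
  cs <- numeric(300); fs <- numeric(300)
  for (i in 1:300) {
    p <- sample_animal_params(cfg0)
    cs[i] <- p$C
    fs[i] <- aggregate_faecal_scores(simulate_faecal_scores(p, cfg0))$FS_sum
  }
  expect_gt(correlate(cs, fs)$p, 0.01)
})

test_that("haemograms are reproducible and decouple under zero loadings", {
  cfg <- cohort_config()
  p <- ref_pert()
  set.seed(50); h1 <- simulate_haemogram(p, cfg, 28)
  set.seed(50); h2 <- simulate_haemogram(p, cfg, 28)
  expect_identical(h1, h2)
  expect_identical(names(h1), default_haem_loadings()$trait)
  expect_true(all(h1 >= 0))
  # zero loadings: trait distribution independent of C
  L0 <- default_haem_loadings()
  L0$rho_C <- 0; L0$rho_ts <- 0
  cfg0 <- cohort_config(haem_loadings = L0)
  set.seed(51)
  hct <- sapply(1:300, function(i) {
    p <- sample_animal_params(cfg0)
    c(p$C, simulate_haemogram(p, cfg0, 28)[["Hct"]])
  })
  expect_gt(correlate(hct[1, ], hct[2, ])$p, 0.01)
})

test_that("cohort generation is reproducible and internally consistent", {
  cfg <- cohort_config(n_animals = 5, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$weights, c2$weights)
  expect_identical(c1$haemogram, c2$haemogram)
  # truth joins 1:1 with the trajectories
  expect_setequal(c1$truth$animal_id, names(c1$trajectories))
  expect_identical(anyDuplicated(c1$truth$animal_id), 0L)
  # first weighing is the (noisy) weaning weight; truth W0 is the noiseless one
  expect_equal(c1$weights$weight_kg[c1$weights$time_days == 0],
               c1$truth$W0, tolerance = 0.1)
  # write-out is byte-identical across runs
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("noiseless end-to-end recovery reproduces the truth table", {
  cfg <- cohort_config(n_animals = 8, seed = 15, noise_cv = 0)
  coh <- generate_cohort(cfg)
  for (i in seq_len(8)) {
    f <- fit_perturbed(coh$trajectories[[i]])
    tru <- coh$truth[i, ]
    expect_lt(abs(f$params$mu0 - tru$mu0) / tru$mu0, 0.02)
    expect_lt(abs(f$params$D - tru$D) / tru$D, 0.02)
    expect_lt(abs(f$params$C - tru$C) / tru$C, 0.02)
    expect_lt(abs(f$params$ts - tru$ts), 0.5)
  }
})
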