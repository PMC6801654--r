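test_that("calibration objective is a (weighted) sum of squares", {
  obs <- c(9, 10, 11); pred <- c(8, 11, 9)
  expect_identical(objective_J(obs, obs), 0)
  expect_identical(objective_J(obs, obs, weighted = TRUE), 0)
  expect_identical(objective_J(obs, pred), 6)
  expect_identical(objective_J(obs, pred, weighted = TRUE), 2)
  # quadratic homogeneity: doubling residuals quadruples J
  expect_identical(objective_J(obs, obs + 2 * (pred - obs)), 4 * 6)
  expect_error(objective_J(obs, pred[1:2]), "length")
})

test_that("Gompertz fit recovers generating parameters on noiseless data", {
  tr <- simulate_trajectory(ref_pert(C = 0, ts = 9), paper_schedule(),
                            noise_cv = 0, animal_id = "G1")
  f <- fit_gompertz(tr)
  expect_identical(f$model_name, "gompertz")
  expect_identical(f$n_p, 2L)
  expect_identical(f$params$W0, 8.91)
  expect_lt(abs(f$params$mu0 - 0.05) / 0.05, 0.001)
  expect_lt(abs(f$params$D - 0.02) / 0.02, 0.001)
  # optimality: fitted J no worse than J at the generating truth
  expect_lte(f$J, objective_J(tr$weights, gompertz_weight(ref_gomp(), tr$times),
                              weighted = TRUE) + 1e-12)
})

test_that("a constant-weight animal is fitted with essentially zero mu0", {
  tr <- weight_trajectory("flat", paper_schedule(),
                          rep(8.91, length(paper_schedule())))
  f <- fit_gompertz(tr)
  expect_lte(f$params$mu0, 1e-4)
})

test_that("perturbed fit recovers all four parameters on noiseless data", {
  tr <- simulate_trajectory(ref_pert(), paper_schedule(), noise_cv = 0,
                            animal_id = "P1")
  f <- fit_perturbed(tr)
  expect_identical(f$n_p, 4L)
  expect_lt(abs(f$params$mu0 - 0.05) / 0.05, 0.02)
  expect_lt(abs(f$params$D - 0.02) / 0.02, 0.02)
  expect_lt(abs(f$params$C - 0.08) / 0.08, 0.02)
  expect_lt(abs(f$params$ts - 9), 0.5)
  expect_true(f$converged)
})

test_that("fits are deterministic for fixed data and configuration", {
  tr <- simulate_trajectory(ref_pert(), paper_schedule(), noise_cv = 0,
                            animal_id = "P1")
  f1 <- fit_perturbed(tr)
  f2 <- fit_perturbed(tr)
  expect_identical(f1, f2)
})

test_that("model nesting: C = 0 data give a tiny fitted C and no J penalty", {
  tr <- simulate_trajectory(ref_pert(C = 0, ts = 9), paper_schedule(),
                            noise_cv = 0, animal_id = "N1")
  fp <- fit_perturbed(tr)
  fg <- fit_gompertz(tr)
  expect_lte(fp$params$C, 1e-4)
  expect_lte(fp$J, fg$J + 1e-10)
})

test_that("nesting holds on noisy trajectories too", {
  set.seed(71)
  for (i in 1:5) {
    tr <- simulate_trajectory(ref_pert(C = runif(1, 0, 0.1), ts = runif(1, 3, 20)),
                              paper_schedule(), noise_cv = 0.015,
                              animal_id = "N")
    expect_lte(fit_perturbed(tr)$J, fit_gompertz(tr)$J * (1 + 1e-9))
  }
})

test_that("too few observations raises a skip condition, not a crash", {
  tr <- weight_trajectory("S1", c(0, 7, 14), c(8.9, 9.5, 10.4))
  expect_error(fit_gompertz(tr), class = "weanres_skip")
  tr5 <- weight_trajectory("S2", c(0, 7, 14, 21, 28),
                           c(8.9, 9.5, 10.4, 11.6, 12.5))
  expect_error(fit_perturbed(tr5), class = "weanres_skip")
})

test_that("unperturbed subset is the weaning record plus the last four in window", {
  tr <- weight_trajectory("U1", c(0, 3, 7, 14, 21, 28, 35, 42, 49, 56, 63, 70, 77),
                          seq(8.9, by = 1, length.out = 13))
  sub <- select_unperturbed_subset(tr)
  expect_identical(sub$times, c(0, 49, 56, 63, 70))   # 77 > 75 excluded
  expect_identical(length(sub$times), 5L)
  # exactly five records in window: all retained
  tr2 <- weight_trajectory("U2", c(0, 70, 71, 72, 73), c(9, 30, 30.4, 30.8, 31.2))
  expect_identical(select_unperturbed_subset(tr2)$times, c(0, 70, 71, 72, 73))
  # property: output size is always 5 on random trajectories
  set.seed(5)
  for (i in 1:20) {
    times <- sort(sample(1:90, sample(5:15, 1)))
    tr3 <- weight_trajectory("U3", c(0, times), seq(9, by = 0.5,
                                                    length.out = length(times) + 1))
    if (sum(times <= 75) >= 4) {
      expect_identical(length(select_unperturbed_subset(tr3)$times), 5L)
    }
  }
  expect_error(select_unperturbed_subset(
    weight_trajectory("U4", c(0, 10, 20, 80), c(9, 10, 11, 20))),
    class = "weanres_skip")
})

test_that("unperturbed reference equals the full fit when nothing is perturbed", {
  tr <- simulate_trajectory(ref_pert(C = 0, ts = 9), paper_schedule(),
                            noise_cv = 0, animal_id = "R1")
  full <- fit_gompertz(tr)
  ref <- fit_unperturbed_reference(tr)
  expect_identical(ref$model_name, "unperturbed_reference")
  tt <- seq(0, 75, by = 1)
  expect_rel_equal(gompertz_weight(ref$params, tt),
                   gompertz_weight(full$params, tt), 0.005)
})

test_that("under strong perturbation the reference runs above the perturbed fit", {
  tr <- simulate_trajectory(ref_pert(C = 0.08, ts = 9), paper_schedule(),
                            noise_cv = 0, animal_id = "R2")
  ref <- fit_unperturbed_reference(tr)
  prt <- fit_perturbed(tr)
  tt <- seq(0.5, 9, by = 0.5)
  expect_true(all(gompertz_weight(ref$params, tt) >
                    perturbed_weight(prt$params, tt)))
  # and it reproduces its own five calibration points closely
  sub <- select_unperturbed_subset(tr)
  expect_rel_equal(gompertz_weight(ref$params, sub$times[-1]),
                   sub$weights[-1], 0.02)
})

test_that("goodness of fit has the right identities and CCC <= |r|", {
  obs <- c(9.1, 10.4, 12.2, 13.8, 15.1, 16.9)
  g <- goodness_of_fit(obs, obs)
  expect_identical(g$r2, 1)
  expect_identical(g$ccc, 1)
  g0 <- goodness_of_fit(obs, rep(mean(obs), length(obs)))
  expect_equal(g0$r2, 0)
  gs <- goodness_of_fit(obs, obs + 5)
  expect_equal(gs$pearson_r, 1)
  expect_lt(gs$ccc, 1)
  set.seed(9)
  for (i in 1:25) {
    x <- rnorm(10); y <- rnorm(10, x)
    gg <- goodness_of_fit(x, y)
    expect_lte(gg$ccc, abs(gg$pearson_r) + 1e-12)
  }
  expect_true(is.na(goodness_of_fit(rep(1, 5), rnorm(5))$r2))
})

test_that("AIC penalises complexity and rewards fit", {
  expect_lt(compute_aic(0.5, 14, 2), compute_aic(0.5, 14, 4))
  expect_lt(compute_aic(0.1, 14, 4), compute_aic(0.5, 14, 4))
  expect_identical(as.numeric(compute_aic(0, 14, 2)), -Inf)
  expect_true(attr(compute_aic(0, 14, 2), "perfect_fit"))
  # uncorrected form matches the plain least-squares definition
  expect_equal(compute_aic(0.5, 14, 2, corrected = FALSE),
               14 * log(0.5) + 2 * 3)
  expect_equal(compute_aic(0.5, 14, 2),
               14 * log(0.5) + 2 * 3 + 2 * 3 * 4 / 12)
})

test_that("J ranking sorts descending, densely, and ignores input order", {
  df <- data.frame(animal_id = c("a", "b", "c"), J = c(0.9, 0.1, 0.5))
  r <- rank_by_J(df)
  expect_identical(r$animal_id, c("a", "c", "b"))
  expect_identical(r$J_rank, c(1L, 2L, 3L))
  r2 <- rank_by_J(df[c(3, 1, 2), ])
  expect_identical(r, r2)
  # dense ranks on ties, deterministic id tie-break
  df3 <- data.frame(animal_id = c("b", "a", "c"), J = c(0.5, 0.5, 0.1))
  r3 <- rank_by_J(df3)
  expect_identical(r3$animal_id, c("a", "b", "c"))
  expect_identical(r3$J_rank, c(1L, 1L, 2L))
})

test_that("J rank tracks the true perturbation coefficient across a cohort", {
  cfg <- cohort_config(n_animals = 30, seed = 88, noise_cv = 0.015,
                       c_min = 0.01, c_max = 0.12)
  coh <- generate_cohort(cfg)
  fits <- lapply(coh$trajectories, fit_gompertz)
  r <- rank_by_J(fits)
  merged <- merge(r, coh$truth, by = "animal_id")
  rho <- cor(merged$J, merged$C, method = "spearman")
  expect_gte(rho, 0.8)
})
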