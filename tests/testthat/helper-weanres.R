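# shared fixtures: canonical piglet-scale parameters and the weighing grid

ref_gomp <- function() gompertz_params(W0 = 8.91, mu0 = 0.05, D = 0.02)

ref_pert <- function(C = 0.08, ts = 9) {
  perturbed_params(W0 = 8.91, mu0 = 0.05, D = 0.02, C = C, ts = ts)
}

paper_schedule <- function() build_schedule(cohort_config())

# random perturbed-parameter draws from the documented piglet-scale ranges
draw_random_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    perturbed_params(W0 = runif(1, 7, 11),
                     mu0 = runif(1, 0.02, 0.09),
                     D = runif(1, 0.008, 0.05),
                     C = runif(1, 0, 0.12),
                     ts = runif(1, 2, 30))
  })
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * pmax(abs(expected), 1e-300)),
              label = sprintf("max relative error %.3g <= %g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), 1e-300)), rel_tol))
}
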