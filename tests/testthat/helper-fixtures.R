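# Shared fixtures: reference ground truths, small designs, and a study-scale
# synthetic replica memoised across tests.

ref <- list(
  MA = reference_params("MA"),
  Sat = reference_params("Sat"),
  Power = reference_params("Power"),
  SiGMA = reference_params("SiGMA")
)

# a compact but informative design: 3 tumor x 4 CTL levels x 4 times
small_design <- design_spec("small", desired_conc = 10^(4:6),
                            ctl_conc = c(0, 1e5, 1e6, 1e7),
                            time_points_h = c(0, 24, 48, 72),
                            replicates = 2)

# fine time course without CTLs, for the early-growth models
growth_design <- design_spec("growth", desired_conc = 1e5, ctl_conc = 0,
                             time_points_h = c(0, 4, 8, 12, 16, 20, 24),
                             replicates = 3)

noiseless <- noise_model("none")
study_noise <- noise_model("gaussian", sigma = 0.51)

# study-scale replica shared by the acceptance tests (generated once)
study_replica <- local({
  cache <- NULL
  function(seed = 101L) {
    if (is.null(cache)) cache <<- simulate_study_data(seed = seed)
    cache
  }
})

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
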