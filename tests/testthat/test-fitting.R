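make_stub_fit <- function(ssr, n_obs, n_params) {
  # minimal gel_fit for the F/chi-square arithmetic
  structure(list(ssr = ssr, n_obs = n_obs, n_params = n_params),
            class = "gel_fit")
}

test_that("noiseless data return the generating parameters to 1e-6", {
  cases <- list(
    list(truth = ref$MA, design = small_design),
    list(truth = ref$Sat, design = small_design),
    list(truth = ref$Power, design = small_design),
    list(truth = ref$SiGMA, design = small_design),
    list(truth = list(spec = model_spec("EG"),
                      params = model_params(model_spec("EG"),
                                            alpha = 2.6, r = 0.74)),
         design = growth_design),
    list(truth = list(spec = model_spec("Alt1"),
                      params = model_params(model_spec("Alt1"), alpha = 2.5,
                                            r = 0.7, tprime = 0.3)),
         design = growth_design),
    list(truth = list(spec = model_spec("Alt2"),
                      params = model_params(model_spec("Alt2"), alpha = 2.5,
                                            fd = 0.4, d = 2.5, r = 0.9)),
         design = growth_design)
  )
  for (cs in cases) {
    dat <- generate_dataset(cs$design, cs$truth$spec, cs$truth$params,
                            noiseless, seed = 1)
    fit <- suppressWarnings(fit_model(dat, cs$truth$spec, n_starts = 30,
                                      seed = 2))
    expect_lt(fit$ssr, 1e-12)
    expect_rel_equal(unlist(fit$par), unlist(cs$truth$params), 1e-6)
  }
})

test_that("grouped-parameter variants recover per-group truths", {
  d1 <- builtin_designs()$dataset1
  sp_vr <- model_spec("EG_vr", groups = 10^(3:5))
  truth <- model_params(sp_vr, alpha = 2.6, r = c(0.5, 0.7, 0.9))
  dat <- generate_dataset(d1, sp_vr, truth, noiseless, seed = 1)
  fit <- suppressWarnings(fit_model(dat, sp_vr, n_starts = 20, seed = 3))
  expect_rel_equal(unlist(fit$par), unlist(truth), 1e-6)

  sp_va <- model_spec("EG", var_alpha = TRUE, groups = 10^(3:5))
  truth_va <- model_params(sp_va, alpha = c(2.2, 2.6, 3.1), r = 0.7)
  dat2 <- generate_dataset(d1, sp_va, truth_va, noiseless, seed = 1)
  fit2 <- suppressWarnings(fit_model(dat2, sp_va, n_starts = 20, seed = 3))
  expect_rel_equal(unlist(fit2$par), unlist(truth_va), 1e-6)
})

test_that("tying all group alphas together reproduces the single-alpha model", {
  sp_va <- model_spec("MA", var_alpha = TRUE, groups = 10^(4:6))
  tied <- model_params(sp_va, alpha = c(2.77, 2.77, 2.77), r = 0.576,
                       k = 3.79e-7)
  Ta <- rep(10^(4:6), each = 3); E <- rep(c(0, 1e5, 1e6), 3)
  expect_equal(log_prediction(sp_va, tied, Ta, E, 1),
               log_prediction(ref$MA$spec, ref$MA$params, Ta, E, 1))
})

test_that("fitting is deterministic given the seed", {
  dat <- generate_dataset(small_design, ref$Sat$spec, ref$Sat$params,
                          study_noise, seed = 9)
  f1 <- suppressWarnings(fit_model(dat, ref$Sat$spec, n_starts = 10, seed = 4))
  f2 <- suppressWarnings(fit_model(dat, ref$Sat$spec, n_starts = 10, seed = 4))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$ssr, f2$ssr)
})

test_that("fit preconditions and boundary pinning are reported", {
  dat <- generate_dataset(growth_design, model_spec("EG"),
                          model_params(model_spec("EG"), alpha = 2.5, r = 0.7),
                          noiseless, seed = 1)
  expect_error(fit_model(dat[1:2, ], ref$SiGMA$spec), "at least")
  zero_dat <- dat
  zero_dat$b16_measured[1] <- 0
  expect_error(fit_model(zero_dat, model_spec("EG")), "non-positive")
  expect_warning(
    fit_model(dat, model_spec("EG"), n_starts = 5, upper = list(r = 0.3)),
    "pinned"
  )
})

test_that("the AIC follows the Gaussian least-squares convention", {
  # halving the SSR at fixed n and K drops the AIC by n log 2
  expect_equal(compute_aic(10, 100, 3) - compute_aic(5, 100, 3),
               100 * log(2))
  # convention-free Delta between two models on the same data:
  # n log(SSR1/SSR2) + 2 (K1 - K2); at the study scale this is ~160
  delta <- compute_aic(164, 431, 3) - compute_aic(112, 431, 5)
  expect_equal(delta, 431 * log(164 / 112) - 4)
  expect_equal(round(delta), 160)
  # and the saturating-model gap is ~23
  expect_equal(round(compute_aic(118.5, 431, 4) - compute_aic(112, 431, 5)),
               22)
  expect_warning(expect_equal(compute_aic(0, 10, 2), -Inf), "zero")
  expect_error(compute_aic(5, 3, 3))
})

test_that("Akaike weights follow the exponential-difference formula", {
  w <- akaike_weights(c(10, 10, 10))
  expect_equal(w$weights, rep(1 / 3, 3))
  expect_equal(min(w$delta), 0)
  w2 <- akaike_weights(c(100, 102))
  expect_equal(w2$weights, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(round(w2$weights, 4), c(0.7311, 0.2689))
  # the study-scale Delta vector gives weights (0, 0, 0.001, 0.999) at 2 sf
  w3 <- akaike_weights(c(160, 23, 14, 0))
  expect_equal(round(w3$weights, 3), c(0, 0, 0.001, 0.999))
  expect_equal(sum(w3$weights), 1, tolerance = 1e-12)
  # invariance to a constant shift
  w4 <- akaike_weights(c(160, 23, 14, 0) + 57.3)
  expect_equal(w4$weights, w3$weights)
  expect_equal(w4$delta, w3$delta)
})

test_that("nested tests reproduce hand arithmetic and degenerate cases", {
  red <- make_stub_fit(10, 20, 2)
  full <- make_stub_fit(8, 20, 3)
  ft <- nested_f_test(red, full)
  expect_equal(ft$statistic, (2 / 1) / (8 / 17))
  expect_equal(unname(ft$df), c(1, 17))
  expect_equal(ft$p_value, pf(4.25, 1, 17, lower.tail = FALSE))
  # identical fits: F = 0, p = 1
  same <- nested_f_test(make_stub_fit(8, 20, 2), make_stub_fit(8, 20, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # misordered SSRs signal an optimizer failure upstream
  expect_error(nested_f_test(make_stub_fit(5, 20, 2), make_stub_fit(8, 20, 3)),
               "converged")
  # likelihood-ratio version of the same comparison
  lr <- lr_chisq_test(red, full)
  expect_equal(lr$statistic, 20 * log(10 / 8))
  expect_equal(lr$df, 1)
})

test_that("lack-of-fit decomposition matches a brute-force ANOVA oracle", {
  # symmetric replicate deviations: the model passes through every group
  # mean, so the lack-of-fit component vanishes
  eg <- model_params(model_spec("EG"), alpha = 2.5, r = 0.7)
  dat <- generate_dataset(
    design_spec("dup", desired_conc = 1e5, ctl_conc = 0,
                time_points_h = c(0, 8, 16, 24), replicates = 2),
    model_spec("EG"), eg, noiseless, seed = 1)
  dat$b16_measured <- dat$b16_measured * exp(c(-0.2, 0.2))
  fit <- suppressWarnings(fit_model(dat, model_spec("EG"), n_starts = 5))
  lof0 <- lack_of_fit_test(fit)
  expect_lt(abs(lof0$ss_lof), 1e-8)
  expect_lt(abs(lof0$statistic), 1e-6)

  # noisy case against an independent decomposition
  dat2 <- generate_dataset(
    design_spec("toy", desired_conc = c(1e4, 1e5), ctl_conc = c(0, 1e6),
                time_points_h = c(0, 24, 48), replicates = 3),
    ref$MA$spec, ref$MA$params, study_noise, seed = 8)
  fit2 <- suppressWarnings(fit_model(dat2, ref$MA$spec, n_starts = 10))
  lof <- lack_of_fit_test(fit2)
  key <- paste(dat2$b16_desired, dat2$otl_conc, dat2$time_h)
  lnT <- log(dat2$b16_measured)
  ss_pe <- sum(unlist(lapply(split(lnT, key), function(v) (v - mean(v))^2)))
  G <- length(unique(key))
  F_oracle <- ((fit2$ssr - ss_pe) / (G - fit2$n_params)) /
    (ss_pe / (length(lnT) - G))
  expect_equal(lof$statistic, F_oracle, tolerance = 1e-10)
  expect_equal(unname(lof$df), c(G - 3, length(lnT) - G))
})

test_that("residual diagnostics flag non-normality and degeneracy", {
  bimodal <- rep(c(-1, 1), each = 50)
  expect_lt(residual_diagnostics(bimodal)$shapiro_p, 1e-3)
  expect_true(residual_diagnostics(rep(0.3, 10))$degenerate)
  expect_error(residual_diagnostics(c(0.1, 0.2)), "at least 3")
  normal <- withr::with_seed(5, rnorm(200))
  expect_gt(residual_diagnostics(normal)$shapiro_p, 0.01)
  # fit-level diagnostics carry condition summaries
  dat <- generate_dataset(small_design, ref$MA$spec, ref$MA$params,
                          study_noise, seed = 2)
  fit <- suppressWarnings(fit_model(dat, ref$MA$spec, n_starts = 10))
  dg <- residual_diagnostics(fit)
  expect_true(all(c("by_time", "by_condition") %in% names(dg)))
  expect_equal(nrow(dg$by_time), length(unique(dat$time_h)))
})

test_that("linearized intervals match the closed-form linear-regression oracle", {
  eg <- model_spec("EG")
  dat <- generate_dataset(growth_design, eg,
                          model_params(eg, alpha = 2.6, r = 0.74),
                          noise_model("gaussian", sigma = 0.4), seed = 6)
  fit <- fit_model(dat, eg, n_starts = 10)
  # the EG model is linear in (ln alpha, r): lnT - lnTa = -ln(alpha) + r t
  olm <- lm(I(log(b16_measured) - log(b16_desired)) ~ I(time_h / 24),
            data = dat)
  expect_equal(fit$par$r, unname(coef(olm)[2]), tolerance = 1e-7)
  expect_equal(fit$par$alpha, exp(-unname(coef(olm)[1])), tolerance = 1e-7)
  ci_lm <- confint(olm)
  ci <- confidence_intervals(fit)
  expect_equal(unname(ci["r", ]), unname(ci_lm[2, ]), tolerance = 1e-6)
  # alpha standard error transforms by the chain rule through alpha=exp(-b0)
  se_b0 <- sqrt(diag(vcov(olm)))[1]
  expect_equal(fit$se_theta[1], unname(fit$par$alpha * se_b0),
               tolerance = 1e-6)
  # bootstrap intervals bracket the same estimates
  cib <- confidence_intervals(fit, method = "bootstrap", n_boot = 60,
                              seed = 2)
  expect_true(cib["r", 1] < fit$par$r && fit$par$r < cib["r", 2])
  # zero-noise intervals collapse
  dat0 <- generate_dataset(growth_design, eg,
                           model_params(eg, alpha = 2.6, r = 0.74),
                           noiseless, seed = 1)
  fit0 <- suppressWarnings(fit_model(dat0, eg, n_starts = 5))
  ci0 <- confidence_intervals(fit0)
  expect_lt(ci0["r", 2] - ci0["r", 1], 1e-5)
})

test_that("zero-noise model selection identifies the generating model", {
  dat <- generate_dataset(small_design, ref$SiGMA$spec, ref$SiGMA$params,
                          noiseless, seed = 1)
  fits <- suppressWarnings(lapply(
    list(ref$MA, ref$Sat, ref$Power, ref$SiGMA),
    function(g) fit_model(dat, g$spec, n_starts = 15, seed = 2)
  ))
  cmp <- suppressWarnings(compare_models(fits))
  expect_equal(cmp$best, "SiGMA")
  expect_error(compare_models(fits[1:2][c(1, 1)]), NA) # same data accepted
  other <- generate_dataset(small_design, ref$SiGMA$spec, ref$SiGMA$params,
                            study_noise, seed = 2)
  fit_other <- suppressWarnings(fit_model(other, ref$MA$spec, n_starts = 5))
  expect_error(compare_models(list(fits[[4]], fit_other)), "identical data")
})
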