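# End-to-end workflows chaining the other modules, plus file output with a
# reproducibility manifest. These functions are the programmatic interface;
# inst/cli/ctlgels.R wraps them for shell use.

write_manifest <- function(out_dir, config) {
  manifest <- c(list(package = "ctlgels",
                     version = as.character(utils::packageVersion("ctlgels")),
                     timestamp = format(Sys.time(), tz = "UTC")),
                config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Fit-and-compare pipeline
#'
#' Applies a filter, fits each requested model, compares them by AIC and
#' Akaike weight, and runs residual diagnostics on the best fit. With
#' `out_dir`, writes `fit_summary.json`, `residuals.csv`, and a
#' `manifest.json` sufficient to re-run bit-identically.
#'
#' @param data A `gel_data` frame or a CSV path readable by
#'   [read_gel_csv()].
#' @param models Character vector of model names (see [model_spec()]).
#' @param filter A [gel_filter()]; default excludes zero-count gels and
#'   CTL concentrations above 1e7 cell/mL.
#' @param n_starts,seed Passed to [fit_model()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `data` (filtered), `comparison`
#'   ([compare_models()] result), and `diagnostics` of the best fit.
#' @export
run_fit_pipeline <- function(data, models = c("MA", "Sat", "Power", "SiGMA"),
                             filter = gel_filter(max_ctl_conc = 1e7),
                             n_starts = 50, seed = 1L, out_dir = NULL) {
  if (is.character(data)) data <- read_gel_csv(data)
  filtered <- apply_filter(data, filter)
  fits <- lapply(models, function(m) {
    fit_model(filtered, model_spec(m), n_starts = n_starts, seed = seed)
  })
  names(fits) <- models
  comparison <- if (length(fits) >= 2) compare_models(fits) else
    structure(list(table = data.frame(model = models,
                                      n_params = fits[[1]]$n_params,
                                      ssr = fits[[1]]$ssr,
                                      aic = fits[[1]]$aic,
                                      delta = 0, weight = 1),
                   best = models[1], fits = fits),
              class = "model_comparison")
  diagnostics <- residual_diagnostics(comparison$fits[[comparison$best]])
  out <- list(data = filtered, comparison = comparison,
              diagnostics = diagnostics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    summary_list <- list(
      n_obs = nrow(filtered),
      filter_report = as.list(attr(filtered, "filter_report")),
      table = comparison$table, best = comparison$best,
      estimates = lapply(comparison$fits, function(f) unlist(f$par)),
      shapiro_p = diagnostics$shapiro_p
    )
    jsonlite::write_json(summary_list, file.path(out_dir, "fit_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    resid_tab <- do.call(rbind, lapply(names(comparison$fits), function(nm) {
      f <- comparison$fits[[nm]]
      cbind(model = nm, f$frame, residual = f$residuals)
    }))
    write.csv(resid_tab, file.path(out_dir, "residuals.csv"),
              row.names = FALSE)
    write_manifest(out_dir, list(command = "fit", models = models,
                                 n_starts = n_starts, seed = seed))
  }
  out
}

#' Growth-rate and death-rate regression pipeline
#'
#' Net growth rates per CTL concentration, the CTL-attributable death rate
#' K = r0 - r_net, and its power-law scaling with CTL concentration. With
#' `out_dir`, writes a tidy `rates.csv` and `growth_summary.json`.
#'
#' @inheritParams run_fit_pipeline
#' @param pool_desired Passed to [net_growth_rates()].
#' @return List with `rates` and `death_curve`.
#' @export
run_growth_pipeline <- function(data,
                                filter = gel_filter(max_ctl_conc = 1e7),
                                pool_desired = TRUE, out_dir = NULL) {
  if (is.character(data)) data <- read_gel_csv(data)
  filtered <- apply_filter(data, filter)
  rates <- net_growth_rates(filtered, pool_desired = pool_desired)
  death_curve <- death_rate_power_fit(rates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(death_curve$points, file.path(out_dir, "rates.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(r0 = death_curve$r0, exponent = death_curve$exponent,
           coefficient = death_curve$coefficient,
           n_excluded = death_curve$n_excluded),
      file.path(out_dir, "growth_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(out_dir, list(command = "growth",
                                 pool_desired = pool_desired))
  }
  list(rates = rates, death_curve = death_curve)
}

#' Reproduce a quantitative analysis end to end
#'
#' Regenerates one of the package's headline analyses:
#' \describe{
#'   \item{`"table1"`}{the four-model comparison table on supplied gel data
#'     (CTL <= 1e7 cell/mL, zero gels excluded).}
#'   \item{`"fig3"`}{t90-versus-E curves and the control concentration Ec
#'     (90% elimination within `horizon_days`) per fitted model; requires
#'     `fits` (a [compare_models()] result or list of `gel_fit`s).}
#'   \item{`"fig6"`}{CTL-efficacy metric grids per fitted model; requires
#'     `fits`.}
#'   \item{`"power"`}{the three design comparisons (D1/D2/D3, A vs B) with
#'     recovery matrices, |delta D| and both p-values; needs no data
#'     (gaussian surrogate noise, or pass `noise`).}
#' }
#'
#' @param target One of `"table1"`, `"fig3"`, `"fig6"`, `"power"`.
#' @param data Gel data (frame or CSV path) for `"table1"`.
#' @param fits Fitted models for `"fig3"`/`"fig6"`.
#' @param horizon_days Elimination horizon for `"fig3"` (default 100 days).
#' @param n_replicates,n_null_draws,noise,n_starts Power-analysis settings.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return Target-specific result list.
#' @export
run_reproduce <- function(target = c("table1", "fig3", "fig6", "power"),
                          data = NULL, fits = NULL, horizon_days = 100,
                          n_replicates = 100, n_null_draws = 1e5,
                          noise = noise_model("gaussian", sigma = 0.51),
                          n_starts = 10, seed = 1L, out_dir = NULL) {
  target <- match.arg(target)
  get_fits <- function() {
    if (is.null(fits)) {
      stop("target '", target, "' needs `fits`: run run_fit_pipeline() on ",
           "the gel data first (public source: the study's data deposit) ",
           "and pass its $comparison")
    }
    if (inherits(fits, "model_comparison")) fits$fits else fits
  }
  res <- switch(target,
    table1 = {
      if (is.null(data)) {
        stop("target 'table1' needs `data`: a gel-measurement CSV in the ",
             "gel_schema() layout (the study's public data deposit, or ",
             "simulate_study_data())")
      }
      run_fit_pipeline(data, n_starts = max(n_starts, 50), seed = seed,
                       out_dir = out_dir)
    },
    fig3 = {
      fl <- get_fits()
      E_grid <- 10^seq(4, 8, length.out = 81)
      list(
        t90_curves = lapply(fl, function(f) {
          data.frame(E = E_grid, t90_days = t90(f$spec, f$par, E_grid))
        }),
        Ec = vapply(fl, function(f) {
          control_concentration(f$spec, f$par, horizon_days = horizon_days)
        }, 0)
      )
    },
    fig6 = {
      fl <- get_fits()
      lapply(fl, function(f) {
        efficacy_metrics(f$spec, f$par, E = 10^seq(4, 7, length.out = 31),
                         Ta = c(1e4, 1e5, 1e6))
      })
    },
    power = {
      d <- builtin_designs()
      pairs <- list(D1 = c("D1-A", "D1-B"), D2 = c("D2-A", "D2-B"),
                    D3 = c("D3-A", "D3-B"))
      seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1, 3))
      out <- lapply(seq_along(pairs), function(i) {
        compare_designs(d[[pairs[[i]][1]]], d[[pairs[[i]][2]]],
                        noise = noise, n_replicates = n_replicates,
                        n_null_draws = n_null_draws, seed = seeds[i],
                        n_starts = n_starts)
      })
      names(out) <- names(pairs)
      out
    }
  )
  if (!is.null(out_dir) && target != "table1") {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ser <- switch(target,
      fig3 = list(Ec = as.list(res$Ec)),
      fig6 = res,
      power = lapply(res, function(x) {
        list(det_A = x$det_A, det_B = x$det_B, delta_D = x$delta_D_obs,
             p_null = x$p_null, p_perm = x$p_perm, better = x$better,
             matrix_A = unclass(x$matrix_A), matrix_B = unclass(x$matrix_B))
      })
    )
    jsonlite::write_json(ser, file.path(out_dir, paste0(target, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(out_dir, list(command = "reproduce", target = target,
                                 seed = seed, n_replicates = n_replicates,
                                 n_null_draws = n_null_draws))
  }
  res
}
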