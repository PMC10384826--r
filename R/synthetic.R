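# Synthetic gel experiments: a design grid, a ground-truth model, a recovery
# fraction 1/alpha, and ln-scale measurement noise (gaussian or resampled
# from residual pools). Every downstream module is testable on these without
# any external data.

#' Define an experimental design for simulated gel assays
#'
#' A design is a grid of (desired tumor concentration, CTL concentration)
#' conditions crossed with measurement time points and a replicate count.
#' `drop_last` removes that many records from the end of the expanded grid,
#' mirroring real designs whose totals fall short of a full crossing.
#'
#' @param name Design label.
#' @param desired_conc,ctl_conc Vectors crossed to form the conditions
#'   (cell/mL); alternatively supply `conditions` directly.
#' @param time_points_h Measurement times, hours.
#' @param replicates Gels per condition-time cell.
#' @param drop_last Records trimmed from the end of the expanded design.
#' @param conditions Optional data frame with columns `Ta`, `E` overriding
#'   the crossing.
#' @return Object of class `design_spec` with derived `n_obs`.
#' @export
design_spec <- function(name, desired_conc = NULL, ctl_conc = NULL,
                        time_points_h, replicates = 1, drop_last = 0,
                        conditions = NULL) {
  if (is.null(conditions)) {
    stopifnot(!is.null(desired_conc), !is.null(ctl_conc))
    conditions <- expand.grid(Ta = desired_conc, E = ctl_conc)
  }
  stopifnot(all(c("Ta", "E") %in% names(conditions)),
            all(conditions$Ta > 0), all(conditions$E >= 0),
            all(time_points_h >= 0), replicates >= 1)
  n_obs <- nrow(conditions) * length(time_points_h) * replicates - drop_last
  structure(
    list(name = name, conditions = conditions,
         time_points_h = sort(time_points_h), replicates = replicates,
         drop_last = drop_last, n_obs = n_obs),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design ", x$name, ": ", nrow(x$conditions), " conditions x ",
      length(x$time_points_h), " times x ", x$replicates,
      " replicates", if (x$drop_last > 0) paste0(" - ", x$drop_last),
      " = ", x$n_obs, " observations\n", sep = "")
  invisible(x)
}

#' Built-in experimental designs
#'
#' The six candidate designs of the power analysis and replicas of the five
#' gel-assay dataset designs:
#' \itemize{
#'   \item `D1-A`/`D1-B`: two- vs four-time-point experiments, 48
#'     observations each.
#'   \item `D2-A`/`D2-B`: short (0-24 h) vs long (0-72 h) time scale, 48
#'     observations each.
#'   \item `D3-A`/`D3-B`: closely vs widely spaced CTL concentrations, 40
#'     observations each.
#'   \item `dataset1`..`dataset5`: replicas of the study's design grids
#'     (growth only; short-term growth and killing; long-term; first-24 h
#'     fine time course; high-CTL check), sized so the full set holds 451
#'     gels.
#' }
#'
#' @return Named list of [design_spec()] objects.
#' @export
builtin_designs <- function() {
  list(
    `D1-A` = design_spec("D1-A", desired_conc = 10^(3:8),
                         ctl_conc = c(0, 1e5, 1e6, 1e7),
                         time_points_h = c(0, 24)),
    `D1-B` = design_spec("D1-B", desired_conc = 10^(5:7),
                         ctl_conc = c(0, 1e5, 1e6, 1e7),
                         time_points_h = c(0, 24, 48, 72)),
    `D2-A` = design_spec("D2-A", desired_conc = 10^(5:7),
                         ctl_conc = c(0, 1e5, 1e6, 1e7),
                         time_points_h = c(0, 8, 16, 24)),
    `D2-B` = design_spec("D2-B", desired_conc = 10^(5:7),
                         ctl_conc = c(0, 1e5, 1e6, 1e7),
                         time_points_h = c(0, 24, 48, 72)),
    `D3-A` = design_spec("D3-A", desired_conc = c(1e5, 1e6),
                         ctl_conc = c(0, 5e5, 1e6, 5e6, 1e7),
                         time_points_h = c(0, 24, 48, 72)),
    `D3-B` = design_spec("D3-B", desired_conc = c(1e5, 1e6),
                         ctl_conc = c(0, 1e4, 1e5, 1e6, 1e7),
                         time_points_h = c(0, 24, 48, 72)),
    dataset1 = design_spec("dataset1", desired_conc = 10^(3:5), ctl_conc = 0,
                           time_points_h = c(0, 24, 48, 72),
                           replicates = 6, drop_last = 2),
    dataset2 = design_spec("dataset2", desired_conc = 10^(4:6),
                           ctl_conc = c(0, 1e4, 1e5, 1e6, 1e7),
                           time_points_h = c(0, 24), replicates = 6),
    dataset3 = design_spec("dataset3", desired_conc = 1e6,
                           ctl_conc = c(0, 1e6, 1e7),
                           time_points_h = c(0, 24, 48, 72, 96),
                           replicates = 7, drop_last = 1),
    dataset4 = design_spec("dataset4", desired_conc = 1e5,
                           ctl_conc = c(0, 1e6, 1e7),
                           time_points_h = c(0, 4, 8, 12, 24),
                           replicates = 6),
    dataset5 = design_spec("dataset5", desired_conc = 1e5, ctl_conc = 1e8,
                           time_points_h = c(0, 24), replicates = 4,
                           drop_last = 1)
  )
}

#' Serialize experimental designs to and from YAML
#'
#' Round-trippable plain-text representation of a [design_spec()], for
#' sharing candidate designs between runs and tools.
#'
#' @param design A `design_spec`.
#' @param path Output (input) YAML file path.
#' @return `write_design_yaml` returns `path` invisibly; `read_design_yaml`
#'   returns the `design_spec`.
#' @export
write_design_yaml <- function(design, path) {
  stopifnot(inherits(design, "design_spec"))
  yaml::write_yaml(
    list(name = design$name,
         conditions = list(Ta = design$conditions$Ta,
                           E = design$conditions$E),
         time_points_h = design$time_points_h,
         replicates = design$replicates,
         drop_last = design$drop_last),
    path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  design_spec(y$name,
              conditions = data.frame(Ta = unlist(y$conditions$Ta),
                                      E = unlist(y$conditions$E)),
              time_points_h = unlist(y$time_points_h),
              replicates = y$replicates, drop_last = y$drop_last)
}

#' Reference parameter sets for the B16/OT1 gel system
#'
#' The package's reference best-fit estimates for each killing model in the
#' B16 melanoma / OT1 CTL collagen-fibrin gel system, used as simulation
#' ground truths (e.g. by the power analysis) and in examples. Units:
#' `alpha` dimensionless, rates per day, `h`/`g2` in cell/mL, `k` in the
#' model-specific units (see [model_spec()]).
#'
#' @param model One of `"MA"`, `"Sat"`, `"Power"`, `"SiGMA"`.
#' @return List with elements `spec` ([model_spec()]) and `params`
#'   ([model_params()]).
#' @export
reference_params <- function(model = c("SiGMA", "MA", "Sat", "Power")) {
  model <- match.arg(model)
  spec <- model_spec(model)
  params <- switch(model,
    MA = model_params(spec, alpha = 2.77, r = 0.576, k = 3.79e-7),
    Sat = model_params(spec, alpha = 2.81, r = 0.744, k = 6, h = 5.34e6),
    Power = model_params(spec, alpha = 2.79, r = 0.744, k = 2.23e-4,
                         n = 0.606),
    SiGMA = model_params(spec, alpha = 2.71, g0 = 0.12, g1 = 0.64,
                         g2 = 6715, k = 3.29e-7)
  )
  list(spec = spec, params = params)
}

#' Measurement-noise model for simulated gels
#'
#' Ln-scale noise added to model predictions: `"gaussian"` draws
#' `N(0, sigma^2)`; `"residual_pool"` resamples (with replacement,
#' independently per observation) from a pool of observed ln-scale
#' residuals; `"none"` is noiseless. `zero_inflation` is the probability
#' that a gel reads zero cells regardless of the model prediction,
#' emulating occasional total recovery failure (off by default).
#'
#' @param kind `"gaussian"`, `"residual_pool"`, or `"none"`.
#' @param sigma Ln-scale standard deviation (gaussian). The study-scale
#'   surrogate is sigma = 0.51, the root mean square ln-residual of the
#'   reference SiGMA fit.
#' @param pool Numeric vector of ln-scale residuals (residual_pool), e.g.
#'   from [build_residual_pool()].
#' @param zero_inflation Probability of a zero-count gel.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian", "residual_pool", "none"),
                        sigma = 0.51, pool = NULL, zero_inflation = 0) {
  kind <- match.arg(kind)
  if (kind == "gaussian") stopifnot(sigma >= 0)
  if (kind == "residual_pool" && (is.null(pool) || length(pool) == 0)) {
    stop("residual_pool noise requires a non-empty pool")
  }
  stopifnot(zero_inflation >= 0, zero_inflation <= 1)
  structure(list(kind = kind, sigma = sigma, pool = pool,
                 zero_inflation = zero_inflation),
            class = "noise_model")
}

#' Build a residual pool from gel measurements
#'
#' Residuals of ln measured concentration about the per-(condition, time)
#' group mean, pooled globally: for gels y_i in a (Ta, E, t) group with mean
#' y-bar, the pool collects y_i - y-bar. Groups with a single gel carry no
#' information about scatter and contribute nothing (with a warning).
#' Zero-count gels are omitted.
#'
#' @param data A `gel_data` frame.
#' @return Numeric vector of ln-scale residuals (mean zero by construction).
#' @export
build_residual_pool <- function(data) {
  data <- as_gel_data(data)
  data <- data[data$b16_measured > 0, , drop = FALSE]
  grp <- interaction(signif(data$b16_desired, 10), signif(data$otl_conc, 10),
                     data$time_h, drop = TRUE)
  sizes <- table(grp)
  if (any(sizes == 1)) {
    warning(sum(sizes == 1), " singleton group(s) contribute no residuals")
  }
  keep <- grp %in% names(sizes)[sizes > 1]
  lnT <- log(data$b16_measured[keep])
  g <- droplevels(grp[keep])
  unname(lnT - ave(lnT, g))
}

#' Generate a synthetic gel dataset
#'
#' For every design cell, draws ln T = model log-prediction + sampled error
#' and exponentiates to cell/mL; with probability `zero_inflation` a gel
#' reads zero instead. Deterministic given `seed`: the same seed reproduces
#' the dataset bit-for-bit, different seeds share the design cells and
#' differ only in noise.
#'
#' @param design A [design_spec()].
#' @param spec,params Ground-truth model and parameters.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param dataset_id,experiment_id Labels written into the records.
#' @return A `gel_data` frame with `design$n_obs` records.
#' @export
generate_dataset <- function(design, spec, params, noise = noise_model("none"),
                             seed = 1L, dataset_id = 1L, experiment_id = 1L) {
  stopifnot(inherits(design, "design_spec"), inherits(spec, "model_spec"),
            inherits(noise, "noise_model"))
  cells <- merge(design$conditions, data.frame(time_h = design$time_points_h))
  rows <- cells[rep(seq_len(nrow(cells)), each = design$replicates), ]
  rows$replicate <- rep(seq_len(design$replicates), nrow(cells))
  if (design$drop_last > 0) {
    rows <- rows[seq_len(nrow(rows) - design$drop_last), , drop = FALSE]
  }
  mu <- log_prediction(spec, params, rows$Ta, rows$E,
                       hours_to_days(rows$time_h))
  n <- nrow(rows)
  drawn <- with_local_seed(seed, {
    err <- switch(noise$kind,
      none = rep(0, n),
      gaussian = rnorm(n, 0, noise$sigma),
      residual_pool = sample(noise$pool, n, replace = TRUE)
    )
    zero <- if (noise$zero_inflation > 0) {
      runif(n) < noise$zero_inflation
    } else {
      rep(FALSE, n)
    }
    list(err = err, zero = zero)
  })
  measured <- exp(mu + drawn$err)
  measured[drawn$zero] <- 0
  as_gel_data(data.frame(
    dataset = dataset_id, experiment = experiment_id,
    replicate = rows$replicate, b16_desired = rows$Ta, otl_conc = rows$E,
    time_h = rows$time_h, b16_measured = measured
  ))
}

#' Simulate a full study-scale replica of the five gel datasets
#'
#' Generates the `dataset1`..`dataset5` design replicas ([builtin_designs()])
#' from one ground-truth model, yielding 451 gels, and deterministically
#' zeroes 13 of them in the high-CTL cells of datasets 2 and 3 (five gels at
#' the top CTL concentration at 24 h, eight at 72-96 h), where zero
#' recoveries occur in this assay. Excluding zeros leaves 438 records;
#' additionally restricting to CTL concentrations of at most 1e7 cell/mL
#' leaves the 431-gel analysis set.
#'
#' @param truth Ground truth as a list with `spec` and `params`, e.g. from
#'   [reference_params()] (default: the reference SiGMA fit).
#' @param noise A [noise_model()]; default gaussian with the study-scale
#'   sigma = 0.51.
#' @param seed Integer seed.
#' @return A `gel_data` frame with 451 records, 13 of them zero counts.
#' @export
simulate_study_data <- function(truth = reference_params("SiGMA"),
                                noise = noise_model("gaussian", sigma = 0.51),
                                seed = 1L) {
  designs <- builtin_designs()[paste0("dataset", 1:5)]
  parts <- lapply(seq_along(designs), function(i) {
    generate_dataset(designs[[i]], truth$spec, truth$params, noise,
                     seed = seed + i, dataset_id = i,
                     experiment_id = 1L)
  })
  out <- do.call(rbind, parts)
  # deterministic zero-count gels: 5 in dataset 2 (top CTL, 24 h),
  # 8 in dataset 3 (top CTL, 72 and 96 h)
  d2 <- which(out$dataset == 2 & out$otl_conc == 1e7 & out$time_h == 24)
  d3 <- which(out$dataset == 3 & out$otl_conc == 1e7 & out$time_h >= 72)
  out$b16_measured[d2[1:5]] <- 0
  out$b16_measured[d3[1:8]] <- 0
  rownames(out) <- NULL
  as_gel_data(out)
}
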