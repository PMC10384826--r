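# Least-squares fitting of the gel models to ln-transformed counts.
#
# The objective is sum over gels of (ln T_obs - ln T_pred)^2, minimized
# jointly over all (Ta, E, t) conditions with shared parameters. Scale
# parameters spanning many orders of magnitude (k, h, g2, a1, a2) are
# optimized on log10 scale; optimization is Levenberg-Marquardt with box
# bounds (minpack.lm), multistarted from Latin-hypercube draws.

theta_from_params <- function(spec, params) {
  th <- unlist(params[spec$par_names], use.names = FALSE)
  ifelse(spec$log10, log10(th), th)
}

params_from_theta <- function(spec, theta) {
  nat <- ifelse(spec$log10, 10^theta, theta)
  p <- as.list(nat)
  names(p) <- spec$par_names
  structure(p, class = "model_params", model = spec$name)
}

theta_bounds <- function(spec) {
  list(lower = ifelse(spec$log10, log10(spec$lower), spec$lower),
       upper = ifelse(spec$log10, log10(spec$upper), spec$upper))
}

# model frame: per-observation vectors used by the residual function
fit_frame <- function(data) {
  data <- as_gel_data(data)
  if (any(data$b16_measured <= 0)) {
    stop("data contain non-positive measured concentrations; ",
         "exclude or impute zero-count gels first (see gel_filter)")
  }
  data.frame(Ta = data$b16_desired, E = data$otl_conc,
             time_h = data$time_h, t_days = hours_to_days(data$time_h),
             lnT = log(data$b16_measured))
}

make_resid_fun <- function(spec, frame) {
  function(theta) {
    p <- params_from_theta(spec, theta)
    frame$lnT - log_prediction(spec, p, frame$Ta, frame$E, frame$t_days)
  }
}

# central-difference Jacobian of the residual vector
resid_jacobian <- function(resid_fun, theta) {
  p <- length(theta)
  r0 <- resid_fun(theta)
  J <- matrix(0, length(r0), p)
  for (j in seq_len(p)) {
    hstep <- max(1e-7, 1e-7 * abs(theta[j]))
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + hstep; tm[j] <- tm[j] - hstep
    J[, j] <- (resid_fun(tp) - resid_fun(tm)) / (2 * hstep)
  }
  J
}

#' Fit a model to gel measurements by least squares on log counts
#'
#' Minimizes the sum of squared differences between ln measured and ln
#' predicted B16 concentrations over all gels jointly, with shared
#' parameters. The optimizer is Levenberg-Marquardt with box bounds,
#' restarted from `n_starts` points: a documented default start plus Latin-
#' hypercube draws within the bounds. Deterministic given `seed`.
#'
#' @param data A `gel_data` frame with all measured concentrations positive
#'   (apply a [gel_filter()] first).
#' @param spec A [model_spec()]. For `var_alpha`/`EG_vr` specs the group
#'   levels must cover the data's desired concentrations.
#' @param n_starts Number of optimization starts (default 50).
#' @param seed Integer seed for the Latin-hypercube start draws.
#' @param lower,upper Optional named overrides of the fitting bounds, on the
#'   natural parameter scale.
#' @return An object of class `gel_fit`: estimates, 95% confidence
#'   intervals, SSR, AIC, residuals, convergence and start diagnostics.
#' @export
fit_model <- function(data, spec, n_starts = 50, seed = 1L,
                      lower = NULL, upper = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  frame <- fit_frame(data)
  npar <- length(spec$par_names)
  if (nrow(frame) < npar + 1) {
    stop("need at least ", npar + 1, " observations to fit ", spec$name)
  }
  if (!is.null(lower)) spec$lower[names(lower)] <- unlist(lower)
  if (!is.null(upper)) spec$upper[names(upper)] <- unlist(upper)
  tb <- theta_bounds(spec)
  resid_fun <- make_resid_fun(spec, frame)

  start0 <- pmin(pmax(ifelse(spec$log10, log10(spec$start), spec$start),
                      tb$lower), tb$upper)
  starts <- matrix(start0, nrow = 1)
  if (n_starts > 1) {
    u <- with_local_seed(seed, lhs::randomLHS(n_starts - 1, npar))
    rng <- matrix(tb$upper - tb$lower, n_starts - 1, npar, byrow = TRUE)
    starts <- rbind(starts,
                    u * rng + matrix(tb$lower, n_starts - 1, npar, byrow = TRUE))
  }

  best <- NULL
  diagnostics <- data.frame(start = seq_len(nrow(starts)), ssr = NA_real_,
                            info = NA_integer_, message = NA_character_)
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], fn = resid_fun,
        lower = tb$lower, upper = tb$upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      diagnostics$message[i] <- conditionMessage(res)
      next
    }
    ssr_i <- sum(res$fvec^2)
    diagnostics$ssr[i] <- ssr_i
    diagnostics$info[i] <- res$info
    diagnostics$message[i] <- res$message
    ok <- res$info %in% 1:4 && is.finite(ssr_i)
    if (ok && (is.null(best) || ssr_i < best$ssr)) {
      best <- list(theta = res$par, ssr = ssr_i)
    }
  }
  if (is.null(best)) {
    stop("no start converged for model ", spec$name, "; diagnostics:\n",
         paste(utils::capture.output(print(diagnostics)), collapse = "\n"))
  }

  theta <- best$theta
  ssr <- best$ssr
  n <- nrow(frame)
  at_bound <- theta <= tb$lower + 1e-8 * pmax(1, abs(tb$lower)) |
    theta >= tb$upper - 1e-8 * pmax(1, abs(tb$upper))
  if (any(at_bound)) {
    warning("estimate(s) pinned at fitting bound: ",
            paste(spec$par_names[at_bound], collapse = ", "))
  }

  # linearized (t-based) standard errors on the optimization scale
  J <- resid_jacobian(resid_fun, theta)
  JtJ <- crossprod(J)
  sigma2 <- ssr / (n - npar)
  se_theta <- rep(NA_real_, npar)
  cv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (!is.null(cv)) se_theta <- sqrt(pmax(diag(cv), 0) * sigma2)

  params <- params_from_theta(spec, theta)
  residuals <- resid_fun(theta)
  fit <- structure(
    list(
      spec = spec, par = params, theta = theta, se_theta = se_theta,
      ssr = ssr, n_obs = n, n_params = npar,
      aic = compute_aic(ssr, n, npar),
      residuals = residuals, fitted = frame$lnT - residuals,
      frame = frame, converged = TRUE, boundary = any(at_bound),
      n_starts_used = nrow(starts), seed = seed,
      start_diagnostics = diagnostics
    ),
    class = "gel_fit"
  )
  fit$ci95 <- tryCatch(confidence_intervals(fit),
                       error = function(e) NULL)
  fit
}

#' @export
print.gel_fit <- function(x, ...) {
  cat("Model ", x$spec$name, " fit: n = ", x$n_obs, ", SSR = ",
      format(x$ssr, digits = 5), ", AIC = ", format(x$aic, digits = 6),
      "\n", sep = "")
  est <- unlist(x$par)
  tab <- data.frame(estimate = est)
  if (!is.null(x$ci95)) {
    tab$ci_lower <- x$ci95[, 1]
    tab$ci_upper <- x$ci95[, 2]
  }
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.gel_fit <- function(object, ...) unlist(object$par)

#' AIC from a least-squares fit of log counts
#'
#' Gaussian-likelihood AIC for a least-squares fit:
#' `AIC = n log(2 pi SSR / n) + n + 2 (K + 1)`, where K is the number of
#' model parameters and the +1 counts the residual variance. Differences
#' (Delta) between models on the same data are independent of the additive
#' constant convention: `Delta = n log(SSR1/SSR2) + 2 (K1 - K2)`.
#'
#' @param ssr Sum of squared ln-scale residuals.
#' @param n_obs Number of observations.
#' @param n_params Number of model parameters K.
#' @return AIC value; `-Inf` (with a warning) when `ssr` is exactly 0.
#' @export
compute_aic <- function(ssr, n_obs, n_params) {
  stopifnot(ssr >= 0, n_obs > n_params)
  if (ssr == 0) {
    warning("SSR is exactly zero; AIC is -Inf")
    return(-Inf)
  }
  n_obs * log(2 * pi * ssr / n_obs) + n_obs + 2 * (n_params + 1)
}

#' Akaike differences and weights
#'
#' `Delta_i = AIC_i - min(AIC)` and `w_i = exp(-Delta_i/2) / sum_j
#' exp(-Delta_j/2)`. Invariant to adding any constant to all AICs.
#'
#' @param aic Numeric vector of AIC values (length >= 2).
#' @return List with `delta` and `weights` (both named like `aic`).
#' @export
akaike_weights <- function(aic) {
  stopifnot(length(aic) >= 2)
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  list(delta = delta, weights = w / sum(w))
}

#' Compare fitted models on the same data
#'
#' Builds the model-comparison table (K, SSR, AIC, Delta, Akaike weight) for
#' fits of different models to identical data and names the best model.
#' Exact AIC ties are broken toward the model with fewer parameters.
#'
#' @param fits List of `gel_fit` objects on the same observations.
#' @return Object of class `model_comparison` with fields `table`, `best`,
#'   and `fits`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "gel_fit")))
  n0 <- fits[[1]]$n_obs
  lnT0 <- fits[[1]]$frame$lnT
  for (f in fits) {
    if (f$n_obs != n0 || !isTRUE(all.equal(f$frame$lnT, lnT0))) {
      stop("fits must be on identical data")
    }
  }
  nm <- vapply(fits, function(f) f$spec$name, "")
  aic <- vapply(fits, `[[`, 0, "aic")
  K <- vapply(fits, `[[`, 0L, "n_params")
  aw <- akaike_weights(aic)
  tab <- data.frame(model = nm, n_params = K,
                    ssr = vapply(fits, `[[`, 0, "ssr"),
                    aic = aic, delta = aw$delta, weight = aw$weights)
  o <- order(tab$aic, tab$n_params)
  structure(list(table = tab, best = tab$model[o[1]],
                 fits = setNames(fits, nm)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (n =", x$fits[[1]]$n_obs, "gels):\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat("Best model:", x$best, "\n")
  invisible(x)
}

#' F-test for nested least-squares fits
#'
#' `F = ((SSR_r - SSR_f) / (K_f - K_r)) / (SSR_f / (n - K_f))` with
#' `(K_f - K_r, n - K_f)` degrees of freedom, comparing a reduced model
#' against a full model fitted to the same data.
#'
#' @param fit_reduced,fit_full `gel_fit` objects; the reduced model's
#'   parameters must be a subset (in count) of the full model's.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
nested_f_test <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "gel_fit"), inherits(fit_full, "gel_fit"))
  if (fit_reduced$n_obs != fit_full$n_obs) stop("fits are not on the same data")
  df1 <- fit_full$n_params - fit_reduced$n_params
  if (df1 <= 0) stop("full model must have more parameters than reduced")
  if (fit_reduced$ssr < fit_full$ssr - 1e-10 * fit_full$ssr) {
    stop("reduced SSR below full SSR: the full-model optimizer has not ",
         "converged; refit with more starts")
  }
  df2 <- fit_full$n_obs - fit_full$n_params
  Fstat <- ((fit_reduced$ssr - fit_full$ssr) / df1) / (fit_full$ssr / df2)
  list(statistic = Fstat, df = c(df1 = df1, df2 = df2),
       p_value = pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Likelihood-ratio chi-square test for nested least-squares fits
#'
#' Gaussian likelihood-ratio statistic `n log(SSR_r / SSR_f)` on
#' `K_f - K_r` degrees of freedom; an asymptotic alternative to
#' [nested_f_test()] for the same comparison.
#'
#' @inheritParams nested_f_test
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lr_chisq_test <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "gel_fit"), inherits(fit_full, "gel_fit"))
  if (fit_reduced$n_obs != fit_full$n_obs) stop("fits are not on the same data")
  df <- fit_full$n_params - fit_reduced$n_params
  if (df <= 0) stop("full model must have more parameters than reduced")
  stat <- fit_full$n_obs * log(fit_reduced$ssr / fit_full$ssr)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Lack-of-fit F-test against replicate pure error
#'
#' Decomposes the fit's SSR into pure error (variation of replicate gels
#' within each unique (Ta, E, t) condition about their mean) and lack of fit
#' (deviation of condition means from the model).
#' `F = (SS_lof / df_lof) / (SS_pe / df_pe)` with `df_lof = G - K` and
#' `df_pe = n - G`, G the number of distinct conditions.
#'
#' @param fit A `gel_fit`.
#' @return List with `statistic`, `df`, `p_value`, `ss_lof`, `ss_pe`,
#'   `n_groups`.
#' @export
lack_of_fit_test <- function(fit) {
  stopifnot(inherits(fit, "gel_fit"))
  fr <- fit$frame
  grp <- interaction(signif(fr$Ta, 10), signif(fr$E, 10), fr$time_h,
                     drop = TRUE)
  G <- nlevels(grp)
  n <- nrow(fr)
  if (n == G) stop("no replicated conditions: pure error is undefined")
  gmean <- ave(fr$lnT, grp)
  ss_pe <- sum((fr$lnT - gmean)^2)
  ss_lof <- fit$ssr - ss_pe
  df_pe <- n - G
  df_lof <- G - fit$n_params
  if (df_lof <= 0) stop("fewer conditions than parameters")
  Fstat <- (ss_lof / df_lof) / (ss_pe / df_pe)
  list(statistic = Fstat, df = c(df_lof = df_lof, df_pe = df_pe),
       p_value = pf(Fstat, df_lof, df_pe, lower.tail = FALSE),
       ss_lof = ss_lof, ss_pe = ss_pe, n_groups = G)
}

#' Residual diagnostics for a fit
#'
#' Shapiro-Wilk normality test of the ln-scale residuals, plus residual
#' means by time point and by (Ta, E) condition.
#'
#' @param fit A `gel_fit`, or a numeric vector of residuals.
#' @return List with `shapiro_W`, `shapiro_p` (`NA` with `degenerate = TRUE`
#'   for constant residuals), `by_time`, `by_condition`.
#' @export
residual_diagnostics <- function(fit) {
  if (is.numeric(fit)) {
    res <- fit
    fr <- NULL
  } else {
    stopifnot(inherits(fit, "gel_fit"))
    res <- fit$residuals
    fr <- fit$frame
  }
  if (length(res) < 3) stop("need at least 3 residuals")
  if (sd(res) == 0) {
    out <- list(shapiro_W = NA_real_, shapiro_p = NA_real_, degenerate = TRUE)
  } else {
    sw <- shapiro.test(res)
    out <- list(shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
                degenerate = FALSE)
  }
  if (!is.null(fr)) {
    out$by_time <- aggregate(list(mean_residual = res),
                             list(time_h = fr$time_h), mean)
    out$by_condition <- aggregate(list(mean_residual = res),
                                  list(Ta = fr$Ta, E = fr$E), mean)
  }
  out
}

#' Confidence intervals for fitted parameters
#'
#' Linearized (t-based) intervals from the Jacobian at the optimum: on the
#' optimization scale, `estimate +/- t(1 - level/2, n - K) * se` with
#' `se^2 = diag((J'J)^-1) SSR/(n - K)`; log10-scale parameters are
#' back-transformed, giving asymmetric intervals on the natural scale.
#' `method = "bootstrap"` resamples residuals with replacement, refits, and
#' takes percentile intervals.
#'
#' @param fit A converged `gel_fit`.
#' @param level Confidence level (default 0.95).
#' @param method `"linearized"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Seed for bootstrap resampling.
#' @return Matrix with one row per parameter, columns `lower`, `upper`.
#' @export
confidence_intervals <- function(fit, level = 0.95,
                                 method = c("linearized", "bootstrap"),
                                 n_boot = 200, seed = 1L) {
  stopifnot(inherits(fit, "gel_fit"))
  method <- match.arg(method)
  spec <- fit$spec
  if (method == "linearized") {
    if (anyNA(fit$se_theta)) {
      stop("singular Jacobian: linearized intervals unavailable; ",
           "use method = 'bootstrap'")
    }
    tcrit <- qt(1 - (1 - level) / 2, fit$n_obs - fit$n_params)
    lo <- fit$theta - tcrit * fit$se_theta
    hi <- fit$theta + tcrit * fit$se_theta
    ci <- cbind(lower = ifelse(spec$log10, 10^lo, lo),
                upper = ifelse(spec$log10, 10^hi, hi))
  } else {
    boot <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(fit$n_obs, replace = TRUE)
        frame_b <- fit$frame
        frame_b$lnT <- fit$fitted + fit$residuals[idx]
        rf <- make_resid_fun(spec, frame_b)
        tb <- theta_bounds(spec)
        res <- minpack.lm::nls.lm(par = fit$theta, fn = rf,
                                  lower = tb$lower, upper = tb$upper,
                                  control = minpack.lm::nls.lm.control(maxiter = 300))
        res$par
      }, numeric(length(fit$theta)))
    })
    qs <- apply(boot, 1, quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    ci <- cbind(lower = ifelse(spec$log10, 10^qs[1, ], qs[1, ]),
                upper = ifelse(spec$log10, 10^qs[2, ], qs[2, ]))
  }
  rownames(ci) <- spec$par_names
  ci
}

#' @export
confint.gel_fit <- function(object, parm, level = 0.95, ...) {
  ci <- confidence_intervals(object, level = level)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
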