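# Model family for B16 tumor dynamics in collagen-fibrin gels.
#
# All models share the skeleton dT/dt = (fg(E) - fk(E)) T with constant CTL
# concentration E, so ln T(t) = ln(Ta/alpha) + (fg(E) - fk(E)) t, where Ta is
# the desired (inoculated) tumor concentration and 1/alpha the effective
# recovery fraction of the clonogenic assay. Time t is in days; rates per day;
# concentrations in cell/mL.

# Per-parameter metadata: fitting bounds, log10-scale flag, default start.
par_info <- function(name, groups = NULL) {
  base <- list(
    alpha  = list(lower = 1, upper = 20, log10 = FALSE, start = 2.5),
    r      = list(lower = 0, upper = 10, log10 = FALSE, start = 0.6),
    g0     = list(lower = 0, upper = 10, log10 = FALSE, start = 0.2),
    g1     = list(lower = 0, upper = 10, log10 = FALSE, start = 0.5),
    d      = list(lower = 0, upper = 10, log10 = FALSE, start = 1),
    k      = list(lower = 1e-12, upper = 1e12, log10 = TRUE, start = 1e-6),
    h      = list(lower = 1e-12, upper = 1e12, log10 = TRUE, start = 1e6),
    g2     = list(lower = 1e-12, upper = 1e12, log10 = TRUE, start = 1e4),
    a1     = list(lower = 1e-12, upper = 1e12, log10 = TRUE, start = 1e-9),
    a2     = list(lower = 1e-12, upper = 1e12, log10 = TRUE, start = 1e-9),
    n      = list(lower = 0, upper = 10, log10 = FALSE, start = 1),
    fd     = list(lower = 0, upper = 1, log10 = FALSE, start = 0.5),
    tprime = list(lower = 0, upper = 10, log10 = FALSE, start = 0.25)
  )
  if (grepl("^alpha[0-9]+$", name)) return(base$alpha)
  if (grepl("^r[0-9]+$", name)) {
    # per-concentration growth rates may be negative (a condition can shrink)
    info <- base$r
    info$lower <- -10
    return(info)
  }
  base[[name]]
}

model_names <- function() {
  c("MA", "Sat", "Power", "SiGMA", "EG", "EG_vr", "Alt1", "Alt2", "SiGMA_ratio")
}

#' Define a growth/killing model
#'
#' Available models (fg = per capita growth rate, fk = per capita kill rate,
#' both per day, E = CTL concentration in cell/mL):
#' \describe{
#'   \item{MA}{exponential growth, mass-action killing: fg = r, fk = k E.}
#'   \item{Sat}{killing saturates in E: fg = r, fk = k E / (h + E).}
#'   \item{Power}{power-law killing: fg = r, fk = k E^n.}
#'   \item{SiGMA}{suppression-in-growth with mass-action killing:
#'     fg = g0 + g1 / (1 + E/g2), fk = k E; the CTL-free growth rate is
#'     r = g0 + g1.}
#'   \item{EG}{exponential growth only: fg = r, fk = 0.}
#'   \item{EG_vr}{exponential growth with one rate per desired tumor
#'     concentration (requires `groups`).}
#'   \item{Alt1}{algebraic-sigmoid per-capita growth for the early post-
#'     inoculation lag: ln T = ln(Ta/alpha) + r (sqrt(1 + (t - t')^2) -
#'     sqrt(1 + t'^2)); `raw_form = TRUE` drops the additive constant.}
#'   \item{Alt2}{two subpopulations, a fraction fd dying at rate d and the
#'     rest growing at rate r: T = fd (Ta/alpha) e^(-d t) +
#'     (1 - fd)(Ta/alpha) e^(r t).}
#'   \item{SiGMA_ratio}{SiGMA growth with ratio-dependent killing
#'     fk = k E / (1 + a1 T + a2 E); solved by numerical integration.}
#' }
#' Any closed-form model accepts `var_alpha = TRUE`, replacing the single
#' recovery parameter alpha by one alpha per desired tumor concentration.
#'
#' @param name Model name (see above).
#' @param var_alpha Use one alpha per desired concentration group.
#' @param groups Sorted vector of desired tumor concentrations (cell/mL)
#'   defining the groups for `var_alpha` or `EG_vr`.
#' @param raw_form For `Alt1` only: use the bare sqrt form without the
#'   constant that anchors T(0) = Ta/alpha.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, var_alpha = FALSE, groups = NULL,
                       raw_form = FALSE) {
  name <- match.arg(name, model_names())
  if (name %in% c("EG_vr") && is.null(groups)) {
    stop("EG_vr requires `groups` (desired tumor concentrations)")
  }
  if (var_alpha) {
    if (is.null(groups)) stop("var_alpha = TRUE requires `groups`")
    if (name %in% c("SiGMA_ratio")) {
      stop("var_alpha is only supported for closed-form models")
    }
  }
  if (!is.null(groups)) groups <- sort(unique(as.numeric(groups)))
  core <- switch(name,
    MA = c("alpha", "r", "k"),
    Sat = c("alpha", "r", "k", "h"),
    Power = c("alpha", "r", "k", "n"),
    SiGMA = c("alpha", "g0", "g1", "g2", "k"),
    EG = c("alpha", "r"),
    EG_vr = c("alpha", paste0("r", seq_along(groups))),
    Alt1 = c("alpha", "r", "tprime"),
    Alt2 = c("alpha", "fd", "d", "r"),
    SiGMA_ratio = c("alpha", "g0", "g1", "g2", "k", "a1", "a2")
  )
  if (var_alpha) {
    core <- c(paste0("alpha", seq_along(groups)), setdiff(core, "alpha"))
  }
  info <- lapply(core, par_info)
  structure(
    list(
      name = name, par_names = core, var_alpha = var_alpha, groups = groups,
      raw_form = raw_form,
      lower = setNames(vapply(info, `[[`, 0, "lower"), core),
      upper = setNames(vapply(info, `[[`, 0, "upper"), core),
      log10 = setNames(vapply(info, `[[`, TRUE, "log10"), core),
      start = setNames(vapply(info, `[[`, 0, "start"), core),
      uses_numerical_integration = identical(name, "SiGMA_ratio")
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model ", x$name,
      if (x$var_alpha) " (per-concentration alpha)", ": parameters ",
      paste(x$par_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct and validate a parameter set for a model
#'
#' Enforces the parameter constraints: `alpha > 0` (inverse recovery
#' fraction), `h, g2, n > 0`, `fd` in \[0, 1\], `k, d, a1, a2 >= 0`. Growth
#' rates and `tprime` are unconstrained here (net decline is biologically
#' possible); fitting applies its own bounds.
#'
#' @param spec A [model_spec()].
#' @param ... Named parameter values; per-group parameters (`alpha`, `r` under
#'   `var_alpha`/`EG_vr`) may be given as vectors named `alpha`/`r`.
#' @return Named list of class `model_params`.
#' @export
model_params <- function(spec, ...) {
  stopifnot(inherits(spec, "model_spec"))
  vals <- list(...)
  # allow vector alpha / r shorthand for grouped specs
  expand_vec <- function(vals, short, pat) {
    if (!is.null(vals[[short]]) && any(grepl(pat, spec$par_names))) {
      v <- vals[[short]]
      m <- sum(grepl(pat, spec$par_names))
      if (length(v) == 1) v <- rep(v, m)
      if (length(v) != m) stop("expected ", m, " values for ", short)
      vals[[short]] <- NULL
      vals <- c(vals, setNames(as.list(v), paste0(short, seq_len(m))))
    }
    vals
  }
  vals <- expand_vec(vals, "alpha", "^alpha[0-9]+$")
  vals <- expand_vec(vals, "r", "^r[0-9]+$")
  missing_p <- setdiff(spec$par_names, names(vals))
  if (length(missing_p)) {
    stop("missing parameter(s): ", paste(missing_p, collapse = ", "))
  }
  extra <- setdiff(names(vals), spec$par_names)
  if (length(extra)) stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  p <- lapply(spec$par_names, function(nm) as.numeric(vals[[nm]]))
  names(p) <- spec$par_names
  chk <- function(ok, msg) if (!ok) stop("invalid parameters: ", msg)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.finite(v)) chk(FALSE, paste(nm, "not finite"))
    if (grepl("^alpha", nm)) chk(v > 0, paste(nm, "must be > 0"))
    if (nm %in% c("h", "g2", "n")) chk(v > 0, paste(nm, "must be > 0"))
    if (nm %in% c("k", "d", "a1", "a2")) chk(v >= 0, paste(nm, "must be >= 0"))
    if (nm == "fd") chk(v >= 0 && v <= 1, "fd must be in [0, 1]")
  }
  structure(p, class = "model_params", model = spec$name)
}

# alpha (and EG_vr growth rate) per observation, via the desired-concentration
# group index.
obs_group <- function(spec, Ta) {
  if (is.null(spec$groups)) return(rep(1L, length(Ta)))
  idx <- match(signif(Ta, 10), signif(spec$groups, 10))
  if (anyNA(idx)) {
    stop("desired concentration(s) not in spec groups: ",
         paste(unique(Ta[is.na(idx)]), collapse = ", "))
  }
  idx
}

obs_alpha <- function(spec, params, Ta) {
  if (spec$var_alpha) {
    unlist(params[paste0("alpha", obs_group(spec, Ta))], use.names = FALSE)
  } else {
    params$alpha
  }
}

#' Per capita tumor growth rate fg(E)
#'
#' @param spec A [model_spec()].
#' @param params A [model_params()] set.
#' @param E CTL concentration(s), cell/mL.
#' @return Growth rate(s), per day.
#' @export
growth_rate <- function(spec, params, E) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(E < 0)) stop("E must be >= 0")
  switch(spec$name,
    MA = , Sat = , Power = , EG = rep(params$r, length(E)),
    SiGMA = , SiGMA_ratio = params$g0 + params$g1 / (1 + E / params$g2),
    stop("growth_rate has no CTL-only form for model ", spec$name,
         " (time- or group-dependent growth)")
  )
}

#' Per capita kill rate fk(E)
#'
#' @inheritParams growth_rate
#' @param tumor_conc Tumor concentration T (cell/mL); required only for
#'   `SiGMA_ratio`, whose kill rate is ratio-dependent.
#' @return Kill rate(s), per day.
#' @export
kill_rate <- function(spec, params, E, tumor_conc = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(E < 0)) stop("E must be >= 0")
  switch(spec$name,
    MA = , SiGMA = params$k * E,
    Sat = params$k * E / (params$h + E),
    Power = params$k * E^params$n,
    EG = , EG_vr = , Alt1 = , Alt2 = rep(0, length(E)),
    SiGMA_ratio = {
      if (is.null(tumor_conc)) {
        stop("SiGMA_ratio kill rate depends on tumor_conc; supply it")
      }
      params$k * E / (1 + params$a1 * tumor_conc + params$a2 * E)
    }
  )
}

# ln T(t) for the ratio-dependent killing model, by numerical integration of
# dT/dt = fg(E) T - k E T / (1 + a1 T + a2 E) per unique (Ta, E) condition.
log_prediction_ratio <- function(spec, params, Ta, E, t_days, rtol = 1e-8) {
  out <- numeric(length(Ta))
  cond <- paste(signif(Ta, 12), signif(E, 12))
  for (cc in unique(cond)) {
    sel <- cond == cc
    Ta_i <- Ta[sel][1]; E_i <- E[sel][1]
    T0 <- Ta_i / obs_alpha(spec, params, Ta_i)
    fg <- params$g0 + params$g1 / (1 + E_i / params$g2)
    times <- sort(unique(c(0, t_days[sel])))
    deriv <- function(t, y, p) {
      list(fg * y - params$k * E_i * y / (1 + params$a1 * y + params$a2 * E_i))
    }
    sol <- deSolve::ode(y = c(T = T0), times = times, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = rtol * max(T0, 1))
    if (attr(sol, "istate")[1] < 0) {
      stop("SiGMA_ratio integration failed for Ta=", Ta_i, ", E=", E_i)
    }
    Tt <- sol[match(t_days[sel], sol[, "time"]), "T"]
    out[sel] <- log(Tt)
  }
  out
}

#' Predicted log tumor concentration
#'
#' Natural log of the model-predicted B16 concentration at time `t_days`
#' (days) for desired concentration `Ta` and CTL concentration `E`. At t = 0
#' every model returns `ln(Ta/alpha)`. Arguments are vectorized and recycled
#' to a common length.
#'
#' @inheritParams growth_rate
#' @param Ta Desired tumor concentration(s), cell/mL.
#' @param t_days Time(s) since inoculation, days (see [hours_to_days()]).
#' @return ln predicted concentration (ln cell/mL).
#' @export
log_prediction <- function(spec, params, Ta, E, t_days) {
  stopifnot(inherits(spec, "model_spec"))
  m <- max(length(Ta), length(E), length(t_days))
  Ta <- rep_len(Ta, m); E <- rep_len(E, m); t_days <- rep_len(t_days, m)
  if (any(t_days < 0)) stop("t_days must be >= 0")
  if (any(E < 0)) stop("E must be >= 0")
  alpha <- obs_alpha(spec, params, Ta)
  base <- log(Ta / alpha)
  switch(spec$name,
    MA = base + (params$r - params$k * E) * t_days,
    Sat = base + (params$r - params$k * E / (params$h + E)) * t_days,
    Power = base + (params$r - params$k * E^params$n) * t_days,
    SiGMA = base + (params$g0 + params$g1 / (1 + E / params$g2) -
                      params$k * E) * t_days,
    EG = base + params$r * t_days,
    EG_vr = {
      r_i <- unlist(params[paste0("r", obs_group(spec, Ta))], use.names = FALSE)
      base + r_i * t_days
    },
    Alt1 = {
      s <- sqrt(1 + (t_days - params$tprime)^2)
      if (spec$raw_form) base + params$r * s
      else base + params$r * (s - sqrt(1 + params$tprime^2))
    },
    Alt2 = {
      T0 <- Ta / alpha
      log(params$fd * T0 * exp(-params$d * t_days) +
            (1 - params$fd) * T0 * exp(params$r * t_days))
    },
    SiGMA_ratio = log_prediction_ratio(spec, params, Ta, E, t_days)
  )
}

#' Time to kill 90% of targets
#'
#' t90(E) = ln(10) / (fk(E) - fg(E)), the time for the model to reduce the
#' initial tumor population ten-fold at CTL concentration E. When killing
#' does not outpace growth (fk <= fg) the tumor is never reduced and `Inf`
#' is returned as the explicit "never" sentinel.
#'
#' @inheritParams growth_rate
#' @return Time(s) in days, `Inf` where elimination never happens.
#' @export
t90 <- function(spec, params, E) {
  net <- kill_rate(spec, params, E) - growth_rate(spec, params, E)
  ifelse(net > 0, log(10) / net, Inf)
}

#' Control CTL concentration for tumor elimination
#'
#' The smallest CTL concentration Ec whose t90 does not exceed `horizon_days`,
#' i.e. the concentration needed to remove at least 90% of the initially
#' present tumor cells within the horizon. Found by bracketing plus bisection
#' (to relative tolerance 1e-6) of the net kill rate fk(E) - fg(E), which must
#' be monotone increasing in E over the search interval. Returns `Inf` when
#' no finite concentration suffices (killing saturates below the requirement,
#' as the Sat model permits).
#'
#' @inheritParams growth_rate
#' @param horizon_days Time horizon in days (default 100).
#' @param interval Initial search bracket in cell/mL; expanded automatically
#'   up to 1e12 if the requirement is not met at the upper end.
#' @return Ec in cell/mL, 0 if the tumor declines without CTLs, or `Inf` if
#'   infeasible.
#' @export
control_concentration <- function(spec, params, horizon_days = 100,
                                  interval = c(0, 1e9)) {
  stopifnot(horizon_days > 0)
  need <- log(10) / horizon_days
  f <- function(E) {
    kill_rate(spec, params, E) - growth_rate(spec, params, E) - need
  }
  grid <- c(0, 10^seq(0, log10(max(interval[2], 10)), length.out = 60))
  vals <- f(grid)
  if (any(diff(vals) < -1e-10 * max(1, abs(vals)))) {
    stop("net kill rate is not monotone increasing in E over the bracket; ",
         "use a grid search instead")
  }
  if (f(interval[1]) >= 0) return(interval[1])
  upper <- interval[2]
  while (f(upper) < 0 && upper < 1e12) upper <- upper * 10
  if (f(upper) < 0) return(Inf)
  root <- uniroot(f, lower = interval[1], upper = upper, tol = 1)$root
  uniroot(f, lower = max(interval[1], root / 2), upper = min(upper, root * 2),
          tol = 1e-6 * max(root, 1))$root
}

#' CTL-efficacy metrics over a CTL-concentration grid
#'
#' For each CTL concentration E (and each desired tumor concentration Ta for
#' the killed-cell metrics) computes: the growth rate fg(E); the kill rate
#' fk(E); the per capita kill rate fk(E)/E (per CTL per day; `NA` at E = 0);
#' tumor cells killed per day over the first 24 h, as the difference between
#' growth-only and full-model predictions at 24 h,
#' (Ta/alpha)(e^fg - e^(fg-fk)); and the same per inoculated CTL per mL.
#' The 24 h difference is formed first and divided by E second.
#'
#' @inheritParams growth_rate
#' @param E Vector of CTL concentrations (cell/mL).
#' @param Ta Vector of desired tumor concentrations (cell/mL).
#' @return Data frame with one row per (Ta, E) pair.
#' @export
efficacy_metrics <- function(spec, params, E, Ta) {
  grid <- expand.grid(Ta = Ta, E = E)
  fg <- growth_rate(spec, params, grid$E)
  fk <- kill_rate(spec, params, grid$E)
  alpha <- obs_alpha(spec, params, grid$Ta)
  T0 <- grid$Ta / alpha
  killed <- T0 * (exp(fg) - exp(fg - fk)) # at t = 1 day (24 h)
  data.frame(
    Ta = grid$Ta, E = grid$E,
    growth_rate = fg, kill_rate = fk,
    per_capita_kill = ifelse(grid$E > 0, fk / grid$E, NA_real_),
    killed_per_day = killed,
    killed_per_day_per_ctl = ifelse(grid$E > 0, killed / grid$E, NA_real_)
  )
}
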