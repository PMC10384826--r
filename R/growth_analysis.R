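# Regression view of the gel data: per-condition net growth rates, the
# CTL-attributable death rate K = r0 - r_net, and the power-law scaling of K
# with CTL concentration. A mass-action killer gives exponent 1; a sublinear
# exponent is the diagnostic against it.

#' Net tumor growth rates per condition
#'
#' For each (CTL concentration E, desired concentration Ta) condition, the
#' slope of ln measured concentration against time (days) by simple least
#' squares over all available time points; for two time points this equals
#' the mean-log difference over the interval. With `pool_desired = TRUE`,
#' slopes are averaged over Ta within each E, as when several desired
#' concentrations probe the same CTL level.
#'
#' @param data A `gel_data` frame with positive measured concentrations.
#' @param pool_desired Average rates over desired concentrations per E.
#' @return Data frame of class `net_rates`: `otl_conc`, (`b16_desired`,)
#'   `r_net` (per day), `stderr`, `n_obs`. Single-time-point conditions are
#'   skipped with a warning.
#' @export
net_growth_rates <- function(data, pool_desired = TRUE) {
  frame <- fit_frame(data)
  key <- interaction(signif(frame$E, 10), signif(frame$Ta, 10), drop = TRUE)
  pieces <- lapply(split(frame, key), function(d) {
    if (length(unique(d$t_days)) < 2) return(NULL)
    m <- lm(lnT ~ t_days, data = d)
    # noiseless simulated data fit exactly; lm's perfect-fit notice is
    # expected there, not a problem to surface
    se <- suppressWarnings(sqrt(diag(vcov(m)))[2])
    data.frame(otl_conc = d$E[1], b16_desired = d$Ta[1],
               r_net = unname(coef(m)[2]),
               stderr = se, n_obs = nrow(d))
  })
  skipped <- sum(vapply(pieces, is.null, TRUE))
  if (skipped > 0) {
    warning(skipped, " condition(s) with a single time point skipped")
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
  if (is.null(out)) stop("no condition has two or more time points")
  rownames(out) <- NULL
  if (pool_desired) {
    agg <- lapply(split(out, out$otl_conc), function(d) {
      data.frame(otl_conc = d$otl_conc[1], r_net = mean(d$r_net),
                 stderr = sqrt(sum(d$stderr^2)) / nrow(d),
                 n_obs = sum(d$n_obs))
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
  }
  out <- out[order(out$otl_conc), , drop = FALSE]
  class(out) <- c("net_rates", "data.frame")
  out
}

#' Power-law scaling of the CTL-attributable death rate
#'
#' Computes the death rate `K = r0 - r_net` for every CTL concentration
#' E > 0 and fits `K = c E^n` by ordinary least squares of ln K on ln E.
#' Conditions with `K <= 0` (growing at least as fast as the CTL-free
#' control) cannot enter the log regression and are excluded with a message.
#'
#' @param rates A `net_rates` frame from [net_growth_rates()] (pooled or
#'   per-Ta).
#' @param r0 CTL-free net growth rate, per day. Defaults to the `E = 0`
#'   entry of `rates` (averaged if several).
#' @return Object of class `death_rate_curve`: `r0`, `points` (E, r_net, K),
#'   `exponent` (n), `coefficient` (c), `n_excluded`.
#' @export
death_rate_power_fit <- function(rates, r0 = NULL) {
  stopifnot(is.data.frame(rates), all(c("otl_conc", "r_net") %in% names(rates)))
  if (is.null(r0)) {
    zero <- rates$otl_conc == 0
    if (!any(zero)) stop("no E = 0 condition in `rates`; supply r0")
    r0 <- mean(rates$r_net[zero])
  }
  pts <- rates[rates$otl_conc > 0, , drop = FALSE]
  pts$K <- r0 - pts$r_net
  usable <- pts$K > 0
  if (sum(usable) < 2) {
    stop("fewer than 2 conditions with positive death rate K")
  }
  if (any(!usable)) {
    message(sum(!usable), " condition(s) with K <= 0 excluded from the ",
            "ln-ln regression")
  }
  fitpts <- pts[usable, , drop = FALSE]
  m <- lm(log(K) ~ log(otl_conc), data = fitpts)
  structure(
    list(r0 = r0, points = pts,
         exponent = unname(coef(m)[2]),
         coefficient = exp(unname(coef(m)[1])),
         exponent_se = suppressWarnings(sqrt(diag(vcov(m)))[2]),
         n_excluded = sum(!usable), lm_fit = m),
    class = "death_rate_curve"
  )
}

#' @export
print.death_rate_curve <- function(x, ...) {
  cat("CTL-attributable death rate K = r0 - r_net, r0 =",
      format(x$r0, digits = 3), "/day\n")
  cat("Power-law fit K = c * E^n: n =", format(x$exponent, digits = 3),
      ", c =", format(x$coefficient, digits = 3), "\n")
  if (x$n_excluded > 0) cat(x$n_excluded, "condition(s) with K <= 0 excluded\n")
  invisible(x)
}
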