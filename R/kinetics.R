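#' Construct a coverage-vs-time series
#'
#' @param t timestamps in s, strictly increasing.
#' @param theta surface coverage fraction at each timestamp, in \[0, 1\].
#' @param series_id identifier.
#' @param concentration nominal monomer concentration in nM.
#' @return An object of class `coverage_series`.
#' @export
as_coverage_series <- function(t, theta, series_id = "series",
                               concentration = NA_real_) {
  if (length(t) != length(theta)) stop("t and theta must have equal length")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (any(theta < 0 | theta > 1)) stop("coverage must lie in [0, 1]")
  structure(list(t = as.numeric(t), theta = as.numeric(theta),
                 series_id = series_id,
                 concentration = as.numeric(concentration)),
            class = "coverage_series")
}

#' @export
print.coverage_series <- function(x, ...) {
  cat(sprintf(
    "coverage_series '%s': %d points, t in [%.1f, %.1f] s, theta in [%.3f, %.3f]\n",
    x$series_id, length(x$t), min(x$t), max(x$t), min(x$theta), max(x$theta)))
  invisible(x)
}

#' Fit the pseudo-first-order adsorption model
#'
#' Least-squares fit of the saturating kinetics
#' `theta(t) = theta_inf * (1 - exp(-k * (t - t0)))` with `t0` fixed to the
#' first timestamp. Starting values come from the data (saturation level
#' from the last decile, rate from a log-linearization of the early rise)
#' and the fit is restarted from a grid of rate scalings to avoid local
#' minima on noisy saturating traces; the best converged restart wins.
#'
#' @param series a [coverage_series] (or data frame with `t` and `theta`).
#' @return An object of class `pfo_fit`: `theta_inf`, `k` (s^-1), `se`
#'   (named standard errors), `rss`, `n_points`, `t0`.
#' @export
fit_pseudo_first_order <- function(series) {
  d <- if (inherits(series, "coverage_series"))
    data.frame(t = series$t, theta = series$theta) else as.data.frame(series)
  if (nrow(d) < 10) stop("need at least 10 points to fit")
  if (diff(range(d$theta)) == 0)
    stop("constant coverage series: rate constant k is unidentifiable")
  t0 <- d$t[1]
  d$tt <- d$t - t0

  theta_inf0 <- mean(utils::tail(d$theta, max(3, ceiling(nrow(d) / 10))))
  theta_inf0 <- min(max(theta_inf0, 0.01), 1.2)
  # log-linearization of 1 - theta/theta_inf on the rising part
  ok <- d$theta < 0.9 * theta_inf0 & d$tt > 0
  k0 <- if (sum(ok) >= 3) {
    y <- log(pmax(1 - d$theta[ok] / theta_inf0, 1e-8))
    max(-stats::coef(stats::lm(y ~ d$tt[ok] - 1))[1], 1e-6)
  } else 1 / max(d$tt[d$tt > 0][1], 1)

  best <- NULL
  for (f in c(1, 0.25, 4, 0.0625, 16)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        theta ~ theta_inf * (1 - exp(-k * tt)), data = d,
        start = list(theta_inf = theta_inf0, k = k0 * f),
        lower = c(theta_inf = 1e-6, k = 1e-9),
        upper = c(theta_inf = 1.2, k = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("pseudo-first-order fit failed to converge from any start ",
         sprintf("(starts: theta_inf = %.3g, k = %.3g)", theta_inf0, k0))
  co <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(theta_inf = NA_real_, k = NA_real_))
  structure(list(theta_inf = unname(co["theta_inf"]), k = unname(co["k"]),
                 se = se, rss = best$rss, n_points = nrow(d), t0 = t0,
                 model = best$fit),
            class = "pfo_fit")
}

#' @export
print.pfo_fit <- function(x, ...) {
  cat(sprintf(
    "pfo_fit: theta_inf = %.4f (se %.2g), k = %.5g s^-1 (se %.2g), rss = %.3g, n = %d\n",
    x$theta_inf, x$se["theta_inf"], x$k, x$se["k"], x$rss, x$n_points))
  invisible(x)
}

#' Time to monolayer formation
#'
#' The monolayer time is read from the coverage trace as the earliest
#' observed timestamp at which coverage reaches `fraction * theta_inf`
#' (operationalizing "coverage saturation"); the analytic crossing time of
#' the fitted curve, `t0 - log(1 - fraction) / k`, is reported alongside.
#'
#' @param series a [coverage_series].
#' @param fit a [pfo_fit] for the same series.
#' @param fraction saturation fraction defining a densely packed monolayer
#'   (default 0.95).
#' @return list: `t_ml` (observed, `NA` if never reached), `t_ml_analytic`,
#'   `fraction`, `reached` (logical flag).
#' @export
time_to_monolayer <- function(series, fit, fraction = 0.95) {
  stopifnot(inherits(fit, "pfo_fit"))
  target <- fraction * fit$theta_inf
  hit <- which(series$theta >= target)
  t_an <- fit$t0 - log(1 - fraction) / fit$k
  if (!length(hit))
    return(list(t_ml = NA_real_, t_ml_analytic = t_an, fraction = fraction,
                reached = FALSE))
  list(t_ml = series$t[hit[1]], t_ml_analytic = t_an, fraction = fraction,
       reached = TRUE)
}

# RSS of a shared-parameter fit over several series, each with its own t0.
fit_shared <- function(dlist) {
  d <- do.call(rbind, dlist)
  theta_inf0 <- min(max(mean(utils::tail(sort(d$theta),
                                         max(3, nrow(d) %/% 10))), 0.01), 1.2)
  k0 <- 1 / max(stats::median(d$tt[d$tt > 0]), 1)
  best <- NULL
  for (f in c(1, 0.25, 4, 0.0625, 16)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(theta ~ theta_inf * (1 - exp(-k * tt)), data = d,
                        start = list(theta_inf = theta_inf0, k = k0 * f),
                        lower = c(theta_inf = 1e-6, k = 1e-9),
                        upper = c(theta_inf = 1.2, k = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best) best <- rss
  }
  if (is.null(best)) stop("shared-parameter fit failed to converge")
  best
}

#' Extra-sum-of-squares F-test between coverage curves
#'
#' Compares a global pseudo-first-order fit with shared (theta_inf, k)
#' against independent per-series fits, for every pair of series and for
#' the omnibus comparison of all series at once. Each series keeps its own
#' time origin. Pairwise p-values are Holm-adjusted when more than two
#' series are compared.
#'
#' @param series_list list of [coverage_series] objects (>= 2).
#' @return list: `omnibus` (`F`, `df1`, `df2`, `p`) and `pairwise` data
#'   frame (`series_a`, `series_b`, `F`, `df1`, `df2`, `p`, `p_adj`).
#' @export
compare_datasets_ftest <- function(series_list) {
  if (length(series_list) < 2) stop("need at least 2 series to compare")
  ids <- vapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    if (!is.null(s$series_id) && nzchar(s$series_id)) s$series_id
    else paste0("series_", i)
  }, character(1))
  fits <- lapply(seq_along(series_list), function(i) {
    tryCatch(fit_pseudo_first_order(series_list[[i]]),
             error = function(e) stop("series '", ids[i],
                                      "' is not fittable: ",
                                      conditionMessage(e)))
  })
  dlist <- lapply(series_list, function(s)
    data.frame(tt = s$t - s$t[1], theta = s$theta))

  ftest <- function(idx) {
    rss_sep <- sum(vapply(idx, function(i) fits[[i]]$rss, numeric(1)))
    n <- sum(vapply(idx, function(i) fits[[i]]$n_points, numeric(1)))
    m <- length(idx)
    rss_glob <- fit_shared(dlist[idx])
    df1 <- 2 * (m - 1)
    df2 <- n - 2 * m
    Fv <- if (rss_sep <= 1e-12 * n) {
      # perfect separate fits: identical curves give F = 0 (p = 1),
      # genuinely different noiseless curves give an unbounded F
      if (rss_glob - rss_sep <= 1e-10 * n) 0 else Inf
    } else max(((rss_glob - rss_sep) / df1) / (rss_sep / df2), 0)
    list(F = Fv, df1 = df1, df2 = df2,
         p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }

  omni <- ftest(seq_along(series_list))
  pairs <- utils::combn(seq_along(series_list), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c) {
    r <- ftest(pairs[, c])
    data.frame(series_a = ids[pairs[1, c]], series_b = ids[pairs[2, c]],
               F = r$F, df1 = r$df1, df2 = r$df2, p = r$p)
  }))
  pw$p_adj <- if (nrow(pw) > 1) stats::p.adjust(pw$p, "holm") else pw$p
  list(omnibus = omni, pairwise = pw)
}

#' Pick representative order-parameter values from the end of a series
#'
#' Selects `n_values` values of n(Theta60) at evenly spaced frames within
#' the final `window_s` seconds of a time series — the sampling used to
#' compare final lattice order across concentrations.
#'
#' @param t timestamps in s.
#' @param n_theta60 order-parameter values per frame.
#' @param window_s length of the final window (default 50 s).
#' @param n_values number of values to select (default 5).
#' @return numeric vector of selected n(Theta60) values.
#' @export
select_final_orders <- function(t, n_theta60, window_s = 50, n_values = 5) {
  idx <- which(t >= max(t) - window_s)
  if (!length(idx)) stop("no frames inside the final window")
  pick <- unique(round(seq(1, length(idx), length.out = n_values)))
  n_theta60[idx[pick]]
}

#' One-way ANOVA on final order-parameter values
#'
#' Tests whether final n(Theta60) differs between groups (one group per
#' concentration, each contributing values selected by
#' [select_final_orders()]). Degenerate all-identical input returns F = 0,
#' p = 1 with a note rather than NaN.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return list: `F`, `df1`, `df2`, `p`, `table` (the aov summary data
#'   frame) and optionally `note`.
#' @export
final_order_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("every group needs >= 2 values (group '",
         names(groups)[which(sizes < 2)[1]], "' has ",
         min(sizes), ")")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group_", seq_along(groups))
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups), sizes)))
  if (stats::var(d$value) == 0)
    return(list(F = 0, df1 = length(groups) - 1,
                df2 = nrow(d) - length(groups), p = 1,
                table = NULL,
                note = "all values identical; F reported as 0, p as 1"))
  tab <- summary(stats::aov(value ~ group, data = d))[[1]]
  list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
       p = tab$`Pr(>F)`[1], table = tab)
}
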