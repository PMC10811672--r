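## Enzyme characterization analysis: initial rates from progress curves,
## Michaelis-Menten fitting, catalytic efficiency and fold improvement,
## thermal melt midpoints, benchtop activity retention.

#' Initial rate of a progress curve
#'
#' Ordinary least-squares slope of signal versus time over the chosen
#' window. The raw apparent rate of a fluorogenic cleavage assay is the
#' slope in RFU per second; with a fluorescence-to-concentration factor
#' the same slope becomes a molar rate. Negative slopes are reported
#' as-is.
#'
#' @param time time points (s), strictly increasing.
#' @param signal signal values (RFU), same length.
#' @param window either `NULL` (all points), a single fraction in (0,1\]
#'   of the time span measured from the start, or a length-2 time range
#'   `c(from, to)`.
#' @return list with `rate` (slope), `se`, `n`, `window`.
#' @export
initial_rate <- function(time, signal, window = NULL) {
  if (is.data.frame(time)) { signal <- time$signal; time <- time$time }
  stopifnot(length(time) == length(signal), !is.unsorted(time, strictly = TRUE))
  keep <- if (is.null(window)) {
    rep(TRUE, length(time))
  } else if (length(window) == 1) {
    stopifnot(window > 0, window <= 1)
    time <= min(time) + window * diff(range(time))
  } else {
    time >= window[1] & time <= window[2]
  }
  if (sum(keep) < 3) stop("fewer than 3 points in rate window", call. = FALSE)
  fit <- lm(signal[keep] ~ time[keep])
  sm <- suppressWarnings(summary(fit))$coefficients  # exact lines are legal input
  list(rate = unname(coef(fit)[2]),
       se = if (nrow(sm) > 1) unname(sm[2, 2]) else NA_real_,
       n = sum(keep),
       window = range(time[keep]))
}

## shared constructor for kinetic-parameter objects (fitted or printed)
new_kinfit <- function(kcat, km, kcat_se = NA_real_, km_se = NA_real_,
                       r_squared = NA_real_, converged = TRUE,
                       enzyme_conc = NA_real_, data = NULL, label = NULL) {
  stopifnot(kcat >= 0, km > 0)
  structure(list(kcat = kcat, km = km, kcat_se = kcat_se, km_se = km_se,
                 efficiency = kcat / km, r_squared = r_squared,
                 converged = converged, enzyme_conc = enzyme_conc,
                 data = data, label = label),
            class = "funcfix_kinfit")
}

#' Construct a kinetic-parameter object from known values
#'
#' Wraps published or otherwise known (kcat, Km) values — e.g. a printed
#' kinetics table — in the same object that [mm_fit()] returns, so that
#' [catalytic_efficiency()] and [fold_improvement()] apply uniformly.
#'
#' @param kcat turnover number, min^-1 (>= 0).
#' @param km Michaelis constant, uM (> 0).
#' @param kcat_se,km_se optional standard errors.
#' @param label optional variant name.
#' @return object of class `funcfix_kinfit`.
#' @export
kinetic_params <- function(kcat, km, kcat_se = NA_real_, km_se = NA_real_,
                           label = NULL) {
  new_kinfit(kcat, km, kcat_se, km_se, label = label)
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least squares of v = kcat * E * S / (Km + S) on a rate
#' table, with deterministic multi-start initialisation: Km is started
#' from a decade-spaced grid spanning one decade beyond the substrate
#' range, kcat from the maximum observed rate; the best start by
#' residual sum of squares wins. Loss is unweighted least squares.
#'
#' @param substrate_conc substrate concentrations (uM), or a data frame
#'   with columns `substrate_conc` and `rate` (an `enzyme_conc`
#'   attribute is honoured).
#' @param rate observed rates (uM min^-1).
#' @param enzyme_conc total enzyme concentration (uM, > 0).
#' @return object of class `funcfix_kinfit` with `kcat` (min^-1), `km`
#'   (uM), standard errors, `efficiency = kcat/km` (uM^-1 min^-1),
#'   `r_squared` and a `converged` flag. Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' tab <- make_rate_table(kcat = 0.014, km = 1.4, enzyme_conc = 0.5,
#'                        substrate_levels = c(0.3, 0.7, 1.4, 2.8, 7, 14),
#'                        noise_rel = 0, seed = 1)
#' fit <- mm_fit(tab)
#' coef(fit)
#' @export
mm_fit <- function(substrate_conc, rate = NULL, enzyme_conc = NULL) {
  if (is.data.frame(substrate_conc)) {
    df <- substrate_conc
    if (is.null(enzyme_conc)) enzyme_conc <- attr(df, "enzyme_conc")
    rate <- df$rate
    substrate_conc <- df$substrate_conc
  }
  s <- as.numeric(substrate_conc); v <- as.numeric(rate)
  if (is.null(enzyme_conc) || !is.finite(enzyme_conc) || enzyme_conc <= 0) {
    stop("enzyme_conc must be a positive concentration (uM)", call. = FALSE)
  }
  stopifnot(length(s) == length(v), all(s > 0))
  if (length(unique(s)) < 2) {
    stop("all substrate concentrations equal: Km unidentifiable", call. = FALSE)
  }
  if (length(s) < 4) {
    warning("fewer than 4 substrate levels; parameter errors will be unstable")
  }
  e <- enzyme_conc
  km_grid <- 10^seq(floor(log10(min(s))) - 1, ceiling(log10(max(s))) + 1)
  kcat0 <- max(v) / e
  dat <- data.frame(s = s, v = v)
  best <- NULL
  for (km0 in km_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ kcat * e * s / (km + s), data = dat,
                        start = list(kcat = max(kcat0, 1e-12), km = km0),
                        lower = c(0, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || deviance(fit) < deviance(best))) best <- fit
  }
  if (is.null(best)) {
    return(new_kinfit(kcat = max(kcat0, 1e-12), km = stats::median(s),
                      converged = FALSE, enzyme_conc = e,
                      data = data.frame(substrate_conc = s, rate = v)))
  }
  cf <- coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) c(kcat = NA_real_, km = NA_real_))
  sst <- sum((v - mean(v))^2)
  r2 <- if (sst > 0) 1 - deviance(best) / sst else NA_real_
  new_kinfit(kcat = unname(cf["kcat"]), km = unname(cf["km"]),
             kcat_se = unname(se["kcat"]), km_se = unname(se["km"]),
             r_squared = r2, converged = TRUE, enzyme_conc = e,
             data = data.frame(substrate_conc = s, rate = v))
}

#' @export
print.funcfix_kinfit <- function(x, digits = 3, ...) {
  cat("Michaelis-Menten parameters",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat(sprintf("  kcat    = %.*g min^-1%s\n", digits, x$kcat,
              if (is.finite(x$kcat_se)) sprintf(" (se %.2g)", x$kcat_se) else ""))
  cat(sprintf("  Km      = %.*g uM%s\n", digits, x$km,
              if (is.finite(x$km_se)) sprintf(" (se %.2g)", x$km_se) else ""))
  cat(sprintf("  kcat/Km = %.*g uM^-1 min^-1\n", digits, x$efficiency))
  if (is.finite(x$r_squared)) cat(sprintf("  R^2     = %.4f\n", x$r_squared))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
coef.funcfix_kinfit <- function(object, ...) {
  c(kcat = object$kcat, km = object$km)
}

#' @export
summary.funcfix_kinfit <- function(object, ...) {
  out <- data.frame(estimate = c(object$kcat, object$km),
                    se = c(object$kcat_se, object$km_se),
                    row.names = c("kcat", "km"))
  attr(out, "efficiency") <- object$efficiency
  attr(out, "r_squared") <- object$r_squared
  out
}

#' @export
predict.funcfix_kinfit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$substrate_conc
       else if (is.data.frame(newdata)) newdata$substrate_conc else newdata
  e <- object$enzyme_conc
  if (!is.finite(e)) stop("no enzyme concentration attached to this fit", call. = FALSE)
  object$kcat * e * s / (object$km + s)
}

#' @export
residuals.funcfix_kinfit <- function(object, ...) {
  if (is.null(object$data)) stop("no data attached to this fit", call. = FALSE)
  object$data$rate - predict(object)
}

#' @export
plot.funcfix_kinfit <- function(x, ...) {
  if (is.null(x$data)) stop("no data attached to this fit", call. = FALSE)
  s <- x$data$substrate_conc
  plot(s, x$data$rate, xlab = "[S] (uM)", ylab = "rate (uM/min)",
       main = "Michaelis-Menten fit", ...)
  sg <- seq(0, max(s) * 1.05, length.out = 200)
  lines(sg, x$kcat * x$enzyme_conc * sg / (x$km + sg))
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' @param fit a `funcfix_kinfit`, or a numeric kcat when `km` is given.
#' @param km Michaelis constant when `fit` is numeric.
#' @return efficiency in uM^-1 min^-1.
#' @export
catalytic_efficiency <- function(fit, km = NULL) {
  if (inherits(fit, "funcfix_kinfit")) return(fit$kcat / fit$km)
  stopifnot(is.numeric(fit), !is.null(km), km > 0)
  fit / km
}

#' Fold improvement in catalytic efficiency over a parent
#'
#' @param variant,parent `funcfix_kinfit` objects (or bare efficiency
#'   numbers).
#' @return ratio of catalytic efficiencies.
#' @export
fold_improvement <- function(variant, parent) {
  ev <- if (inherits(variant, "funcfix_kinfit")) variant$efficiency else variant
  ep <- if (inherits(parent, "funcfix_kinfit")) parent$efficiency else parent
  if (!is.finite(ep) || ep <= 0) stop("parent efficiency must be > 0", call. = FALSE)
  ev / ep
}

## ------------------------------------------------------------- melting ----

#' Thermal melt midpoint (Tm)
#'
#' Fits a two-state unfolding model with linear folded and unfolded
#' baselines, y(T) = base_f(T) + (base_u(T) - base_f(T)) * f(T) with
#' f(T) = 1 / (1 + exp((Tm - T)/width)), and reports the midpoint Tm.
#' The model is fitted by nonlinear least squares; when the fit fails,
#' the midpoint falls back to the temperature of maximum |dy/dT| on a
#' smoothed curve, flagged as `method = "derivative"`.
#'
#' Curves with no resolvable transition (signal change indistinguishable
#' from the baseline, as for proteins that remain folded over the whole
#' scan) return `transition = FALSE` and a lower bound `tm_gt` equal to
#' the highest scanned temperature instead of a Tm. Detection requires
#' the fitted transition amplitude to exceed 5x the residual noise, the
#' sigmoid to reduce the residual sum of squares of a plain linear
#' baseline by half, and the midpoint to lie inside the scanned range.
#' The result is invariant to affine rescaling of the signal axis.
#'
#' @param temperature scan temperatures (degrees C), increasing.
#' @param signal CD signal (e.g. molar residue ellipticity) or fraction
#'   folded, same length. A data frame with columns `temperature` and
#'   `signal` may be passed as the first argument.
#' @return object of class `funcfix_meltfit`: list with `tm`, `tm_se`,
#'   `transition`, `tm_gt`, `width`, `method`, `r_squared`.
#' @export
melt_tm <- function(temperature, signal = NULL) {
  if (is.data.frame(temperature)) {
    signal <- temperature$signal; temperature <- temperature$temperature
  }
  tt <- as.numeric(temperature); y <- as.numeric(signal)
  stopifnot(length(tt) == length(y), length(tt) >= 5, !is.unsorted(tt))

  ## scale-free working copy; Tm is invariant to affine signal rescaling
  sc <- diff(range(y))
  ys <- if (sc > 0) (y - min(y)) / sc else y * 0

  lin <- lm(ys ~ tt)
  rss_lin <- sum(residuals(lin)^2)

  ## derivative-based start (and fallback)
  k <- max(3, round(length(tt) / 15))
  sm <- stats::filter(ys, rep(1 / k, k), sides = 2)
  dy <- diff(as.numeric(sm)) / diff(tt)
  dy[!is.finite(dy)] <- 0
  tm0 <- tt[which.max(abs(dy))]
  w0 <- diff(range(tt)) / 20
  n <- length(tt)
  dat <- data.frame(tt = tt, ys = ys)
  q <- max(2, floor(n / 5))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ys ~ (af + bf * tt) + ((au + bu * tt) - (af + bf * tt)) /
        (1 + exp((tm - tt) / w)),
      data = dat,
      start = list(af = mean(ys[1:q]), bf = 0,
                   au = mean(ys[(n - q + 1):n]), bu = 0,
                   tm = tm0, w = w0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)

  if (is.null(fit)) {
    ## amplitude after removing the linear trend, so a sloping baseline
    ## alone cannot register as a transition
    smd <- stats::filter(residuals(lin), rep(1 / k, k), sides = 2)
    amp <- diff(range(as.numeric(smd), na.rm = TRUE))
    noise <- sd(diff(ys)) / sqrt(2)
    has_transition <- sc > 0 && amp > 5 * noise && tm0 > min(tt) && tm0 < max(tt)
    return(structure(list(tm = if (has_transition) tm0 else NA_real_,
                          tm_se = NA_real_, transition = has_transition,
                          tm_gt = max(tt), width = NA_real_,
                          method = "derivative", r_squared = NA_real_,
                          data = data.frame(temperature = tt, signal = y)),
                     class = "funcfix_meltfit"))
  }

  cf <- coef(fit)
  tm <- unname(cf["tm"])
  rss <- deviance(fit)
  resid_sd <- sqrt(rss / max(n - 6, 1))
  amplitude <- abs((cf["au"] + cf["bu"] * tm) - (cf["af"] + cf["bf"] * tm))
  has_transition <- sc > 0 &&
    amplitude > 5 * resid_sd &&
    (rss < 0.5 * rss_lin || rss_lin == 0) &&
    rss < rss_lin &&
    tm > min(tt) && tm < max(tt)
  se <- tryCatch(summary(fit)$coefficients["tm", "Std. Error"],
                 error = function(e) NA_real_)
  sst <- sum((ys - mean(ys))^2)
  structure(list(tm = if (has_transition) tm else NA_real_,
                 tm_se = if (has_transition) se else NA_real_,
                 transition = has_transition, tm_gt = max(tt),
                 width = unname(cf["w"]), method = "sigmoid",
                 r_squared = if (sst > 0) 1 - rss / sst else NA_real_,
                 data = data.frame(temperature = tt, signal = y)),
            class = "funcfix_meltfit")
}

#' @export
print.funcfix_meltfit <- function(x, ...) {
  if (x$transition) {
    cat(sprintf("Tm = %.1f C%s  [%s fit]\n", x$tm,
                if (is.finite(x$tm_se)) sprintf(" (se %.2f)", x$tm_se) else "",
                x$method))
  } else {
    cat(sprintf("no transition detected: Tm > %.1f C (folded over the scan)\n",
                x$tm_gt))
  }
  invisible(x)
}

#' @export
plot.funcfix_meltfit <- function(x, ...) {
  plot(x$data$temperature, x$data$signal, xlab = "temperature (C)",
       ylab = "signal", main = "thermal melt", ...)
  if (x$transition) abline(v = x$tm, lty = 2)
  invisible(x)
}

## ------------------------------------------------- benchtop stability ----

#' Activity retention after preincubation
#'
#' Rates measured after increasing preincubation times, each divided by
#' the rate at t = 0. A retained fraction of 0.9 after 4 h means the
#' enzyme kept 90% of its original activity on the bench.
#'
#' @param time preincubation times (h); the first must be 0 (or the
#'   minimum is treated as the reference).
#' @param rate measured rates, same length; rate at t = 0 must be > 0.
#' @return data frame with `time`, `rate`, `fraction`.
#' @export
activity_retention <- function(time, rate) {
  if (is.data.frame(time)) { rate <- time$rate; time <- time$time }
  stopifnot(length(time) == length(rate))
  r0 <- rate[which.min(time)]
  if (!is.finite(r0) || r0 <= 0) stop("rate at t = 0 must be > 0", call. = FALSE)
  data.frame(time = time, rate = rate, fraction = rate / r0)
}

#' Apparent turnover rate from cleaved-fraction time courses
#'
#' OLS slope of cleaved product fraction versus time over the linear
#' regime of a gel-based cleavage assay (band fractions are taken as
#' input numbers; densitometry is upstream).
#'
#' @param time_h incubation times (h), >= 3 points.
#' @param fraction cleaved fraction in \[0,1\], same length.
#' @return list with `rate` (h^-1) and `se`.
#' @export
linear_turnover_rate <- function(time_h, fraction) {
  if (is.data.frame(time_h)) { fraction <- time_h$fraction; time_h <- time_h$time }
  if (length(time_h) < 3) stop("need >= 3 time points", call. = FALSE)
  stopifnot(length(time_h) == length(fraction))
  fit <- lm(fraction ~ time_h)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(rate = unname(coef(fit)[2]), se = unname(sm[2, 2]))
}
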