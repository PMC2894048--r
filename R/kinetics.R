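# Aggregation kinetics: forward models for the growth curves, half-time
# arithmetic, and the log-acceleration statistic G.

#' Aggregation half-time from elongation rate and lag time
#'
#' Combines the apparent elongation rate constant and the lag-phase duration
#' into the half-time of the aggregation signal,
#' `t_half = t_lag + 2 / k_agg`. The `2 / k_agg` term is the
#' tangent-at-midpoint convention for the time between the end of the lag
#' phase and the signal midpoint of a sigmoidal growth curve; with no lag
#' phase the half-time is proportional to `1 / k_agg`, so the acceleration
#' statistic reduces to the log-ratio of the rate constants.
#'
#' @param k_agg Positive elongation rate constant(s), inverse time.
#' @param t_lag Non-negative lag time(s), same time unit. Default 0.
#' @return Half-time(s), same unit as `t_lag`.
#' @seealso [compute_G()]
#' @export
half_time_from_rate_and_lag <- function(k_agg, t_lag = 0) {
  if (any(!is.finite(k_agg)) || any(k_agg <= 0))
    stop("k_agg must be positive")
  if (any(!is.finite(t_lag)) || any(t_lag < 0))
    stop("t_lag must be non-negative")
  t_lag + 2 / k_agg
}

#' Log acceleration statistic G
#'
#' `G = log(t_half_no_gag / t_half_with_gag)`: positive when the GAG
#' accelerates aggregation (shorter half-time in its presence), negative when
#' it decelerates it. G is dimensionless and invariant to the common time
#' unit of the two half-times.
#'
#' @param t_half_no_gag,t_half_with_gag Positive half-times in the same unit.
#' @return G, dimensionless.
#' @export
compute_G <- function(t_half_no_gag, t_half_with_gag) {
  if (any(!is.finite(t_half_no_gag)) || any(t_half_no_gag <= 0) ||
      any(!is.finite(t_half_with_gag)) || any(t_half_with_gag <= 0))
    stop("half-times must be positive")
  log(t_half_no_gag / t_half_with_gag)
}

#' Construct a kinetic trace
#'
#' @param times Strictly increasing, non-negative times.
#' @param signals Signal intensities, same length (arbitrary units).
#' @return An object of class `kinetic_trace` (a data frame with columns
#'   `time` and `signal`).
#' @export
kinetic_trace <- function(times, signals) {
  times <- as.numeric(times); signals <- as.numeric(signals)
  if (length(times) != length(signals))
    stop("times and signals must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(signals)))
    stop("times and signals must be finite")
  if (any(times < 0)) stop("times must be non-negative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(data.frame(time = times, signal = signals),
            class = c("kinetic_trace", "data.frame"))
}

#' Read a digitized kinetic trace
#'
#' Two-column whitespace- or tab-delimited numeric text (time, signal), with
#' `#` comment lines — the format produced by graph-digitization tools.
#'
#' @param path File path.
#' @return A [kinetic_trace()].
#' @export
read_kinetic_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.table(path, comment.char = "#", header = FALSE)
  if (ncol(m) < 2L) stop("trace file must have two numeric columns")
  kinetic_trace(m[[1]], m[[2]])
}

# forward models ------------------------------------------------------------

# single exponential: no detectable lag phase
kin_exponential <- function(t, A0, A_inf, k_agg)
  A_inf + (A0 - A_inf) * exp(-k_agg * t)

# Boltzmann sigmoid: detectable lag phase, midpoint at t_half
kin_sigmoid <- function(t, A0, A_inf, k_agg, t_half)
  A0 + (A_inf - A0) / (1 + exp(-k_agg * (t - t_half)))

# data-driven starting values, jittered for multi-start
trace_starts <- function(time, signal, n_starts = 5L) {
  a0 <- signal[1L]; ainf <- signal[length(signal)]
  mid <- (a0 + ainf) / 2
  cross <- function(level) {
    idx <- which(diff(sign(signal - level)) != 0)
    if (length(idx)) time[idx[1L]] else stats::median(time)
  }
  th <- cross(mid)
  t10 <- cross(a0 + 0.1 * (ainf - a0)); t90 <- cross(a0 + 0.9 * (ainf - a0))
  k0 <- if (abs(t90 - t10) > 0) 4 / abs(t90 - t10) else 1 / max(time)
  base <- c(A0 = a0, A_inf = ainf, k_agg = k0, t_half = th)
  starts <- vector("list", n_starts)
  starts[[1L]] <- base
  for (i in seq_len(n_starts - 1L)) {
    f <- c(1, 1, 2^(i - 2), 1)
    starts[[i + 1L]] <- base * f + c(0, 0, 0, (i - 2) * diff(range(time)) / 8)
  }
  starts
}

fit_one_model <- function(trace, lag_model) {
  time <- trace$time; signal <- trace$signal
  resid_fn <- if (lag_model)
    function(p) signal - kin_sigmoid(time, p[1], p[2], p[3], p[4])
  else
    function(p) signal - kin_exponential(time, p[1], p[2], p[3])
  lower <- if (lag_model) c(-Inf, -Inf, 1e-10, -Inf) else c(-Inf, -Inf, 1e-10)
  best <- NULL
  for (st in trace_starts(time, signal)) {
    par0 <- st[if (lag_model) c("A0", "A_inf", "k_agg", "t_half")
               else c("A0", "A_inf", "k_agg")]
    par0["k_agg"] <- max(par0[["k_agg"]], 1e-8)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn, lower = lower,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$sse)
      best <- list(coef = fit$par, sse = fit$deviance)
  }
  best
}

#' Fit a kinetic trace with the exponential or sigmoidal growth model
#'
#' Fits the digitized trace by nonlinear least squares (Levenberg–Marquardt,
#' five data-driven starts) to the single-exponential model
#' `A(t) = A_inf + (A0 - A_inf) exp(-k_agg t)` (no detectable lag phase) or
#' the Boltzmann sigmoid
#' `A(t) = A0 + (A_inf - A0) / (1 + exp(-k_agg (t - t_half)))` (lag phase
#' present). With `lag = "auto"` both are fitted and the sigmoid is kept only
#' if it reduces the residual sum of squares with a significant
#' extra-sum-of-squares F ratio (alpha = 0.05); ties go to the simpler model.
#'
#' The half-time is the sigmoid midpoint under the lag model (with
#' `t_lag = max(0, t_half - 2 / k_agg)`, the tangent-at-midpoint convention),
#' or `2 / k_agg` with `t_lag = 0` under the no-lag model, so that
#' acceleration ratios of no-lag fits reduce to rate-constant ratios.
#'
#' @param trace A [kinetic_trace()] with at least 6 points.
#' @param lag `"auto"` (default), `TRUE` (sigmoid) or `FALSE` (exponential).
#' @return An object of class `kinetic_fit`: list with `A0`, `A_inf`,
#'   `k_agg`, `t_half`, `t_lag`, `residual_sse`, `lag_model_used`, `n`.
#' @export
fit_trace <- function(trace, lag = "auto") {
  if (!inherits(trace, "kinetic_trace"))
    trace <- kinetic_trace(trace[[1]], trace[[2]])
  n <- nrow(trace)
  if (n < 6L) stop("at least 6 points are required for a fit")
  rng <- diff(range(trace$signal))
  if (rng == 0 || rng < 1e-12 * max(abs(trace$signal), 1))
    stop("degenerate trace: signal spans no range")
  if (identical(lag, "auto")) {
    f0 <- fit_one_model(trace, lag_model = FALSE)
    f1 <- fit_one_model(trace, lag_model = TRUE)
    if (is.null(f0) && is.null(f1))
      stop("fit failure: no model converged from any start")
    use_lag <- FALSE
    sig_ss <- sum((trace$signal - mean(trace$signal))^2)
    if (is.null(f0)) use_lag <- TRUE
    else if (f0$sse <= 1e-14 * sig_ss) {
      use_lag <- FALSE  # simpler model already fits to numerical precision
    } else if (!is.null(f1) && f1$sse < f0$sse && n > 4L) {
      Fstat <- ((f0$sse - f1$sse) / 1) / (f1$sse / (n - 4L))
      if (f1$sse == 0 ||
          stats::pf(Fstat, 1, n - 4L, lower.tail = FALSE) < 0.05)
        use_lag <- TRUE
    }
    best <- if (use_lag) f1 else f0
    lag_model <- use_lag
  } else {
    lag_model <- isTRUE(lag) || identical(lag, "yes")
    best <- fit_one_model(trace, lag_model = lag_model)
    if (is.null(best))
      stop("fit failure: no start converged (model: ",
           if (lag_model) "sigmoid" else "exponential", ")")
  }
  cf <- best$coef
  if (lag_model) {
    t_half <- unname(cf["t_half"])
    t_lag <- max(0, t_half - 2 / unname(cf["k_agg"]))
  } else {
    t_half <- 2 / unname(cf["k_agg"])
    t_lag <- 0
  }
  structure(list(A0 = unname(cf["A0"]), A_inf = unname(cf["A_inf"]),
                 k_agg = unname(cf["k_agg"]), t_half = t_half, t_lag = t_lag,
                 residual_sse = best$sse, lag_model_used = lag_model, n = n),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit (%s model, n = %d)\n",
              if (x$lag_model_used) "sigmoid" else "exponential", x$n))
  cat(sprintf("  A0 = %.4g  A_inf = %.4g  k_agg = %.4g  t_half = %.4g  t_lag = %.4g\n",
              x$A0, x$A_inf, x$k_agg, x$t_half, x$t_lag))
  cat(sprintf("  residual SSE = %.4g\n", x$residual_sse))
  invisible(x)
}

#' G from a pair of kinetic traces
#'
#' Fits the GAG-free and GAG-containing traces independently (each with its
#' own automatic lag-model selection unless `lag` is forced) and returns the
#' log-ratio of the fitted half-times.
#'
#' @param trace_no_gag,trace_with_gag [kinetic_trace()] objects.
#' @param lag Passed to [fit_trace()] for both traces.
#' @return G (scalar), with attributes `fit_no_gag` and `fit_with_gag`.
#' @export
g_from_trace_pair <- function(trace_no_gag, trace_with_gag, lag = "auto") {
  f0 <- fit_trace(trace_no_gag, lag = lag)
  f1 <- fit_trace(trace_with_gag, lag = lag)
  structure(compute_G(f0$t_half, f1$t_half),
            fit_no_gag = f0, fit_with_gag = f1)
}
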