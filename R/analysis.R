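#' Sway evaluation stack
#'
#' Anterior-posterior centre-of-pressure (COP) velocity, Lomb-Scargle power
#' spectra normalized to unit sum with log-log slope estimates in a
#' low-frequency (0.1-1 Hz) and a high-frequency (1-5 Hz) band, the
#' correlation between muscle tone and sway variability, and Welch t-tests
#' with Bonferroni correction for comparing conditions.
#'
#' @name sway-analysis
#' @keywords internal
NULL

# Coerce a COP trace argument: a posture_trial, a data.frame/list with
# time and COP columns, or a 2-column matrix.
.cop_trace <- function(trace) {
  if (inherits(trace, "posture_trial"))
    return(list(t = trace$time, x = trace$x_cop))
  if (is.matrix(trace)) return(list(t = trace[, 1L], x = trace[, 2L]))
  nms <- names(trace)
  tcol <- intersect(c("time", "time_s", "t"), nms)[1L]
  xcol <- intersect(c("cop", "cop_x_m", "x_cop", "x"), nms)[1L]
  if (is.na(tcol) || is.na(xcol)) stop("cannot find time/COP columns in trace")
  list(t = as.numeric(trace[[tcol]]), x = as.numeric(trace[[xcol]]))
}

#' Mean anterior-posterior COP velocity
#'
#' Mean of `|delta x_COP / delta t|` over consecutive samples.
#'
#' @param trace a `posture_trial`, a data.frame with time/COP columns
#'   (`time_s`, `cop_x_m` accepted), or a 2-column matrix
#' @param burn_in initial transient to discard (s), default 0
#' @return mean absolute AP COP velocity (m/s)
#' @export
cop_velocity <- function(trace, burn_in = 0) {
  tr <- .cop_trace(trace)
  keep <- tr$t >= burn_in
  t <- tr$t[keep]; x <- tr$x[keep]
  if (length(x) < 2L) stop("need at least two COP samples")
  mean(abs(diff(x) / diff(t)))
}

#' Lomb-Scargle power spectrum, normalized to unit sum
#'
#' Classical Lomb-Scargle periodogram (with the tau phase correction) of a
#' possibly unevenly sampled trace, evaluated on a frequency grid and
#' normalized so the returned powers sum to 1.  On uniform sampling at
#' Fourier frequencies it coincides with the classical periodogram.
#'
#' @param trace as in [cop_velocity()]
#' @param freq frequency grid (Hz); default 100 log-spaced points in
#'   \[0.1, 5\] Hz
#' @return data.frame with columns `freq` and `power` (sums to 1)
#' @export
lomb_scargle_psd <- function(trace, freq = psd_freq_grid()) {
  tr <- .cop_trace(trace)
  t <- tr$t; x <- tr$x - mean(tr$x)
  if (length(x) < 8L) stop("need at least 8 samples for a periodogram")
  if (stats::sd(x) == 0) stop("constant trace: periodogram undefined")
  p <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, 0)
  data.frame(freq = freq, power = p / sum(p))
}

#' Default PSD frequency grid
#'
#' @param n number of points (default 100)
#' @param range frequency range (Hz), default \[0.1, 5\]
#' @return log-spaced frequency vector
#' @export
psd_freq_grid <- function(n = 100, range = c(0.1, 5)) {
  10^seq(log10(range[1L]), log10(range[2L]), length.out = n)
}

#' Log-log slopes of the COP power spectrum
#'
#' Ordinary least-squares slope of `log10(power)` on `log10(freq)` within a
#' low band (default 0.1-1 Hz, slope `beta1`; 1 Hz belongs to this band) and
#' a high band (default 1-5 Hz exclusive of 1 Hz, slope `beta2`).
#'
#' @param psd data.frame from [lomb_scargle_psd()]
#' @param band1,band2 band edges (Hz)
#' @return named vector `c(beta1, beta2)`
#' @export
psd_slopes <- function(psd, band1 = c(0.1, 1), band2 = c(1, 5)) {
  slope <- function(sel, name) {
    if (sum(sel) < 3L)
      stop("fewer than 3 grid points in band ", name)
    if (any(psd$power[sel] <= 0))
      stop("non-positive power in band ", name)
    unname(stats::coef(stats::lm(log10(psd$power[sel]) ~ log10(psd$freq[sel])))[2L])
  }
  c(beta1 = slope(psd$freq >= band1[1L] & psd$freq <= band1[2L], "beta1"),
    beta2 = slope(psd$freq > band2[1L] & psd$freq <= band2[2L], "beta2"))
}

#' Correlation between muscle tone and sway variability
#'
#' Pearson correlation between the tone norms and the standard deviation of
#' the COP velocity across tone levels.
#'
#' @param norms tone norms `||u_ff||_2` per level
#' @param sd_velocities SD of per-trial mean COP velocities per level
#' @return Pearson r
#' @export
tone_velocity_correlation <- function(norms, sd_velocities) {
  if (length(norms) < 3L) stop("need at least 3 (norm, SD) pairs")
  if (stats::sd(norms) == 0 || stats::sd(sd_velocities) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(norms, sd_velocities)
}

#' Compare COP velocity between conditions per tone level
#'
#' Welch two-sample t-tests on the per-trial mean COP velocities at each
#' tone level, with Bonferroni-corrected significance threshold
#' `alpha / n_levels` (e.g. 0.05/6 = 0.00833 for six compared levels).
#'
#' @param with_vst,without_vst lists of numeric vectors (per tone level) of
#'   per-trial mean COP velocities; single vectors are treated as one level
#' @param n_levels number of compared levels for the Bonferroni correction
#'   (default the number of levels supplied)
#' @param alpha family-wise error rate, default 0.05
#' @return data.frame per level: `t`, `p`, `alpha_corrected`, `significant`
#' @export
compare_conditions <- function(with_vst, without_vst,
                               n_levels = NULL, alpha = 0.05) {
  if (is.numeric(with_vst)) with_vst <- list(with_vst)
  if (is.numeric(without_vst)) without_vst <- list(without_vst)
  stopifnot(length(with_vst) == length(without_vst))
  if (is.null(n_levels)) n_levels <- length(with_vst)
  alpha_c <- alpha / n_levels
  rows <- lapply(seq_along(with_vst), function(i) {
    a <- with_vst[[i]]; b <- without_vst[[i]]
    if (length(a) < 2L || length(b) < 2L)
      stop("need at least 2 trials per condition per level")
    if (stats::sd(c(a, b)) == 0) {
      # identical constant samples: no evidence of a difference
      return(data.frame(level = i, t = 0, p = 1))
    }
    tt <- stats::t.test(a, b)
    data.frame(level = i, t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$alpha_corrected <- alpha_c
  out$significant <- out$p < alpha_c
  out
}

#' Pick the trial with the median objective
#'
#' Among replicate trials of one condition, returns the trial whose
#' objective J is the median; for an even count the lower median is used
#' (first in stable order among ties).
#'
#' @param trials list of `posture_trial`s
#' @param J optional numeric objectives; computed with [objective_J()] when
#'   missing
#' @return the selected trial (with attribute `"index"`)
#' @export
select_median_trial <- function(trials, J = NULL) {
  if (length(trials) == 0L) stop("no trials supplied")
  if (is.null(J)) J <- vapply(trials, function(tr) objective_J(tr)$J, 0)
  ord <- order(J)                      # stable for ties
  med <- J[ord[(length(J) + 1L) %/% 2L]]
  idx <- which(J == med)[1L]           # first trial attaining the median
  structure(trials[[idx]], index = idx)
}

#' Synthesize a power-law COP-like trace
#'
#' Spectral synthesis of Gaussian noise with power spectrum proportional to
#' `f^(-alpha)`: Fourier amplitudes `f^(-alpha/2)` with random phases,
#' uniformly sampled.  Used to validate the slope estimators on traces of
#' known spectral exponent.
#'
#' @param alpha spectral exponent (PSD slope is `-alpha` in log-log)
#' @param n number of samples
#' @param fs sampling frequency (Hz)
#' @param seed optional RNG seed
#' @return data.frame with columns `time` and `x`
#' @export
synth_powerlaw_trace <- function(alpha, n = 8192, fs = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- n %/% 2L
  f <- (1:nf) * fs / n
  amp <- f^(-alpha / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  full[n:(n - nf + 2L)] <- Conj(spec[1:(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  data.frame(time = (0:(n - 1L)) / fs, x = x)
}
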