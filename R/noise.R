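#' Gaussian sensory noise with calibrated per-channel magnitude
#'
#' Sensed feedback signals are corrupted as `y = x + k_noise * mu * X` with
#' `X ~ N(0, 1)` drawn independently per channel at every control step.
#' `mu` is a per-channel magnitude calibrated as the time-average of the
#' absolute value of each channel during one noise-free standing trial, so
#' that `k_noise` is a single dimensionless knob across heterogeneous
#' channels (lengths in m, velocities in m/s, head components in mixed
#' units).
#'
#' @name sensory-noise
#' @keywords internal
NULL

#' Calibrate per-channel noise magnitudes
#'
#' Runs one noise-free trial (`k_noise = 0`, all other settings as given) and
#' returns `mu_c = mean(|x_c(t)|)` for every sensory channel: all muscle
#' lengths, all lengthening velocities, and the 18 head components.
#' Channels whose mean magnitude falls below 1e-12 are floored at 1e-12.
#'
#' @param plant a `posture_plant`
#' @param params a [controller_params()] set under which the plant stands
#' @param config a [sim_config()]
#' @return named numeric vector of length `2 * n_muscles + 18`
#' @export
calibrate_mu <- function(plant, params, config) {
  config$k_noise <- 0
  trial <- run_trial(plant, params, config)
  if (trial$fell)
    stop("noise calibration trial fell at ", trial$T_fail,
         " ms; cannot calibrate mu")
  mu <- c(colMeans(abs(trial$L)), colMeans(abs(trial$Ldot)),
          colMeans(abs(trial$head)))
  names(mu) <- c(paste0("L_", plant$muscle_name),
                 paste0("Ldot_", plant$muscle_name),
                 head_component_names())
  pmax(mu, 1e-12)
}

#' Add calibrated Gaussian noise to a sensed value
#'
#' @param x true sensory values (vector)
#' @param mu calibrated magnitudes (same length as `x`)
#' @param k_noise dimensionless noise scale (default 0.01); `k_noise = 0`
#'   returns `x` exactly, without touching the RNG
#' @return noisy values
#' @export
apply_noise <- function(x, mu, k_noise = 0.01) {
  if (k_noise == 0) return(x)
  x + k_noise * mu * stats::rnorm(length(x))
}
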