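#' Fit a standing-balance controller to a plant
#'
#' Runs the full two-stage pipeline for one condition and one tone level:
#' (1) sweep the gain knobs without delays or noise to collect muscle-tone
#' candidates; (2) pick the candidate whose tone norm is closest to
#' `tone_target`; (3) tune the feedback gains with CMA-ES under the full
#' delays and sensory noise; if tuning cannot find standing gains for the
#' selected tone, the next-closest candidate is tried.  The fitted
#' controller is then evaluated on `n_trials` independently seeded noisy
#' trials.
#'
#' @param plant a `posture_plant`
#' @param condition `"vst"` (vestibular feedback enabled) or `"no_vst"`
#'   (vestibular gains identically zero throughout sweep and tuning)
#' @param tone_target desired tone norm `||u_ff||_2`; default the median
#'   candidate norm
#' @param knob_grid stage-1 sweep grid; default [default_knob_grid()] for
#'   the condition and profile
#' @param config a [sim_config()]; stage 1 always forces zero delay/noise
#' @param profile `"ci"` (reduced sweep and CMA budget) or `"full"`
#' @param n_trials evaluation trials (default 10)
#' @param base_seed seed base; trial i uses `base_seed + i`
#' @param cma_iter CMA-ES generations; default 30 (ci) or 100 (full)
#' @param eval_seeds noise-seed schedule during tuning (default one fixed
#'   seed derived from `base_seed`)
#' @param candidates optionally reuse a `tone_candidates` sweep
#' @return an object of class `"posture_fit"`
#' @seealso [run_experiment()] for the multi-level two-condition protocol
#' @export
fit_posture_controller <- function(plant, condition = c("vst", "no_vst"),
                                   tone_target = NULL, knob_grid = NULL,
                                   config = sim_config(),
                                   profile = c("ci", "full"),
                                   n_trials = 10, base_seed = 1,
                                   cma_iter = NULL, eval_seeds = NULL,
                                   candidates = NULL) {
  condition <- match.arg(condition)
  profile <- match.arg(profile)
  vst <- condition == "vst"
  if (is.null(cma_iter)) cma_iter <- if (profile == "ci") 30 else 100
  if (is.null(eval_seeds)) eval_seeds <- base_seed * 1000L + 1L
  if (is.null(knob_grid)) knob_grid <- default_knob_grid(vst, profile)
  if (is.null(candidates))
    candidates <- generate_candidates(plant, knob_grid, config)
  if (length(candidates) == 0L)
    stop("stage-1 sweep produced no standing tone candidate")
  norms <- vapply(candidates, `[[`, 0, "norm")
  if (is.null(tone_target)) tone_target <- stats::median(norms)

  rejected <- integer(0)
  tuning <- NULL; cand_idx <- NA_integer_
  repeat {
    sel <- select_tones(candidates, targets = tone_target, rejected = rejected)
    if (is.na(sel$index[1L]))
      stop("gain tuning failed for every tone candidate")
    cand_idx <- sel$index[1L]
    cand <- candidates[[cand_idx]]
    tuning <- tune_gains(plant, cand$u_ff, cand$q_target, cand$mu,
                         config = config, vst = vst,
                         eval_seeds = eval_seeds, max_iter = cma_iter,
                         seed = base_seed)
    if (tuning$success) break
    rejected <- c(rejected, cand_idx)
  }
  cand <- candidates[[cand_idx]]
  params <- controller_params(plant, u_ff = cand$u_ff,
                              k_p = tuning$knobs$k_p, k_d = tuning$knobs$k_d,
                              k_ves = tuning$knobs$k_ves,
                              q_target = cand$q_target)
  trials <- lapply(seq_len(n_trials), function(i)
    run_trial(plant, params, config, seed = base_seed + i, mu = cand$mu))
  J <- vapply(trials, function(tr) objective_J(tr)$J, 0)

  structure(list(
    plant = plant, condition = condition, vst = vst,
    tone_target = tone_target, candidate = cand, candidate_index = cand_idx,
    candidate_norms = norms, rejected = rejected,
    tuning = tuning, params = params, config = config,
    trials = trials, J = J,
    metrics = sway_metrics(trials, J = J),
    base_seed = base_seed
  ), class = "posture_fit")
}

#' Default stage-1 knob grids
#'
#' Grid resolutions over the standard knob ranges (`k_p`, `k_d` in \[1, 3\];
#' vestibular knobs log-spaced in \[1e-4, 1e-2\], or 0 when the channel is
#' absent): 5 x 3 x 3 for the reduced (`ci`) profile, 5 x 5 x 3 for `full`.
#'
#' @param vst logical; include non-zero vestibular knob values
#' @param profile `"ci"` or `"full"`
#' @return data.frame of knob combinations
#' @export
default_knob_grid <- function(vst, profile = c("ci", "full")) {
  profile <- match.arg(profile)
  k_p <- seq(1, 3, length.out = 5)
  k_d <- if (profile == "ci") c(1, 2, 3) else seq(1, 3, length.out = 5)
  k_ves <- if (vst) 10^c(-4, -3, -2) else 0
  tone_knob_grid(k_p, k_d, k_ves)
}

#' Sway metrics of a set of replicate trials
#'
#' Per-trial mean AP COP velocity, their mean and SD across trials, and the
#' normalized Lomb-Scargle PSD with band slopes of the median-objective
#' trial.
#'
#' @param trials list of `posture_trial`s
#' @param J optional objective values (computed if missing)
#' @return list of class `"sway_metrics"`: `velocities`, `mean_velocity`,
#'   `sd_velocity`, `psd`, `beta1`, `beta2`, `median_index`
#' @export
sway_metrics <- function(trials, J = NULL) {
  vel <- vapply(trials, cop_velocity, 0)
  med <- select_median_trial(trials, J = J)
  psd <- tryCatch(lomb_scargle_psd(med), error = function(e) NULL)
  betas <- if (is.null(psd)) c(beta1 = NA_real_, beta2 = NA_real_) else
    psd_slopes(psd)
  structure(list(velocities = vel, mean_velocity = mean(vel),
                 sd_velocity = stats::sd(vel), psd = psd,
                 beta1 = betas[["beta1"]], beta2 = betas[["beta2"]],
                 median_index = attr(med, "index")),
            class = "sway_metrics")
}

#' @export
print.sway_metrics <- function(x, ...) {
  cat("AP COP velocity:", format(x$mean_velocity), "+/-",
      format(x$sd_velocity), "m/s (", length(x$velocities), "trials )\n")
  cat("PSD slopes: beta1 =", format(x$beta1), ", beta2 =", format(x$beta2), "\n")
  invisible(x)
}

#' @export
print.posture_fit <- function(x, ...) {
  cat("Standing-balance controller fit (", x$condition, " condition)\n", sep = "")
  cat("  plant:", x$plant$name, "; tone ||u_ff||2 =",
      format(x$candidate$norm), "(target", format(x$tone_target), ")\n")
  kn <- x$tuning$knobs
  cat("  tuned knobs: k_p =", format(kn$k_p), ", k_d =", format(kn$k_d), "\n")
  if (x$vst) cat("  k_ves =", paste(format(kn$k_ves, digits = 3), collapse = " "), "\n")
  stood <- sum(!vapply(x$trials, `[[`, TRUE, "fell"))
  cat("  evaluation: stood", stood, "/", length(x$trials),
      "trials; mean J =", format(mean(x$J)), "\n")
  invisible(x)
}

#' @export
summary.posture_fit <- function(object, ...) {
  print(object)
  print(object$metrics)
  invisible(object)
}

#' @export
coef.posture_fit <- function(object, ...) {
  kn <- object$tuning$knobs
  c(k_p = kn$k_p, k_d = kn$k_d,
    stats::setNames(kn$k_ves, paste0("k_", 1:6)))
}

#' @importFrom stats simulate
#' @export
simulate.posture_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$base_seed + length(object$trials)
  lapply(seq_len(nsim), function(i)
    run_trial(object$plant, object$params, object$config,
              seed = seed + i, mu = object$candidate$mu))
}

#' @export
residuals.posture_fit <- function(object, ...) {
  med <- select_median_trial(object$trials, J = object$J)
  sweep(med$q, 2L, object$params$q_target, `-`)
}

#' @export
plot.posture_fit <- function(x, ...) {
  med <- select_median_trial(x$trials, J = x$J)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(med$time, med$x_cop * 100, type = "l", xlab = "time (s)",
       ylab = "AP COP (cm)", main = paste0(x$condition, ", ||u_ff||2 = ",
                                           signif(x$candidate$norm, 3)))
  if (!is.null(x$metrics$psd))
    plot(x$metrics$psd$freq, x$metrics$psd$power, log = "xy", type = "l",
         xlab = "frequency (Hz)", ylab = "normalized power",
         main = sprintf("beta1 = %.2f, beta2 = %.2f",
                        x$metrics$beta1, x$metrics$beta2))
  invisible(x)
}

#' Run the full two-condition standing experiment
#'
#' For each condition (vestibular feedback present/absent): sweep tone
#' candidates, fit a controller at each tone target, run the seeded
#' replicate trials, and compute sway metrics; then compare COP velocities
#' between conditions per tone level (Welch t-tests, Bonferroni corrected)
#' and correlate tone norm with velocity SD within each condition.
#'
#' @param plant a `posture_plant` (default the one-link fixture)
#' @param conditions subset of `c("vst", "no_vst")`
#' @param tone_targets tone-norm targets; default: quantiles of the
#'   vst-condition candidate norms (3 levels in `ci`, 7 in `full`)
#' @param trials_per_condition replicate trials per fitted controller
#'   (default 10)
#' @param base_seed experiment seed
#' @param profile `"ci"` or `"full"` compute profile
#' @param config a [sim_config()]
#' @param out_dir optional directory: per-fit trial CSVs and a JSON report
#'   are written there
#' @param cma_iter override the per-fit CMA-ES generation budget (see
#'   [fit_posture_controller()])
#' @return list of class `"posture_experiment"`: `fits` (per condition a
#'   list over tone levels), `metrics` (data.frame), `comparison`,
#'   `correlations`, `tone_targets`
#' @export
run_experiment <- function(plant = build_plant(make_fixture("one_link")),
                           conditions = c("vst", "no_vst"),
                           tone_targets = NULL, trials_per_condition = 10,
                           base_seed = 1, profile = c("ci", "full"),
                           config = sim_config(), out_dir = NULL,
                           cma_iter = NULL) {
  profile <- match.arg(profile)
  fits <- list(); cand_cache <- list()
  for (cond in conditions) {
    vst <- cond == "vst"
    grid <- default_knob_grid(vst, profile)
    cand_cache[[cond]] <- generate_candidates(plant, grid, config)
  }
  if (is.null(tone_targets)) {
    ref <- cand_cache[[conditions[1L]]]
    norms <- vapply(ref, `[[`, 0, "norm")
    n_lvl <- if (profile == "ci") 3L else 7L
    tone_targets <- unname(stats::quantile(norms, seq(0.1, 0.9,
                                                      length.out = n_lvl)))
  }
  rows <- list()
  for (cond in conditions) {
    fits[[cond]] <- lapply(tone_targets, function(tg) {
      fit <- fit_posture_controller(plant, condition = cond, tone_target = tg,
                                    config = config, profile = profile,
                                    n_trials = trials_per_condition,
                                    base_seed = base_seed, cma_iter = cma_iter,
                                    candidates = cand_cache[[cond]])
      rows[[length(rows) + 1L]] <<- data.frame(
        condition = cond, tone_target = tg, tone_norm = fit$candidate$norm,
        mean_velocity = fit$metrics$mean_velocity,
        sd_velocity = fit$metrics$sd_velocity,
        beta1 = fit$metrics$beta1, beta2 = fit$metrics$beta2,
        mean_J = mean(fit$J),
        stood = sum(!vapply(fit$trials, `[[`, TRUE, "fell")))
      fit
    })
  }
  metrics <- do.call(rbind, rows)
  comparison <- NULL
  if (all(c("vst", "no_vst") %in% conditions)) {
    comparison <- compare_conditions(
      lapply(fits$vst, function(f) f$metrics$velocities),
      lapply(fits$no_vst, function(f) f$metrics$velocities))
  }
  correlations <- lapply(fits, function(fl) {
    norms <- vapply(fl, function(f) f$candidate$norm, 0)
    sds <- vapply(fl, function(f) f$metrics$sd_velocity, 0)
    if (length(norms) >= 3L && stats::sd(norms) > 0 && stats::sd(sds) > 0)
      tone_velocity_correlation(norms, sds) else NA_real_
  })
  out <- structure(list(fits = fits, metrics = metrics,
                        comparison = comparison, correlations = correlations,
                        tone_targets = tone_targets, base_seed = base_seed,
                        profile = profile),
                   class = "posture_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    report <- list(profile = profile, base_seed = base_seed,
                   tone_targets = tone_targets, metrics = metrics,
                   correlations = correlations)
    if (!is.null(comparison)) report$comparison <- comparison
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' @export
print.posture_experiment <- function(x, ...) {
  cat("Standing experiment (", x$profile, " profile, seed ", x$base_seed,
      ")\n", sep = "")
  print(x$metrics, digits = 4)
  for (cond in names(x$correlations))
    cat("  tone vs velocity-SD correlation (", cond, "): r = ",
        format(x$correlations[[cond]]), "\n", sep = "")
  invisible(x)
}

#' Write a trial trajectory as tidy CSV
#'
#' Columns: time (s), joint angles, activations, COM position/height, COP,
#' and the 18 head channels.
#'
#' @param trial a `posture_trial`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trial_csv <- function(trial, path) {
  df <- data.frame(time = trial$time)
  q <- trial$q; colnames(q) <- paste0("q_", seq_len(ncol(q)))
  a <- trial$a; colnames(a) <- paste0("a_", seq_len(ncol(a)))
  head <- trial$head; colnames(head) <- head_component_names()
  df <- cbind(df, q, a,
              x_com = trial$x_com, h_com = trial$h_com, x_cop = trial$x_cop,
              head)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
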