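#' Two-stage controller parameter pipeline
#'
#' Stage 1 sweeps feedback-gain knobs under the no-delay, no-noise condition
#' with zero tone; every combination that stands yields a muscle-tone
#' candidate (time-averaged activations) and an updated target posture.
#' Stage 2 fixes a selected tone and tunes the feedback gains with CMA-ES
#' under the full delays and sensory noise, minimizing a weighted
#' fall/posture objective.
#'
#' @name tuning
#' @keywords internal
NULL

# trapezoidal integral of y(t) on an arbitrary grid
.trapz <- function(t, y) sum(diff(t) * (y[-1L] + y[-length(y)])) / 2

#' Muscle tone from the average muscle activity
#'
#' `u_ff_i = (1/(t2 - t1)) * integral of a_i(t) dt` over the settled window,
#' trapezoidal on the stored grid.  Defined only for trials that stood.
#'
#' @param trial a `posture_trial` that did not fall
#' @param t1,t2 integration window (ms), defaults 3000 and 5000
#' @return per-muscle tone vector
#' @export
compute_tone <- function(trial, t1 = 3000, t2 = 5000) {
  if (trial$fell) stop("tone is undefined for a trial that fell")
  idx <- which(trial$time >= t1 / 1000 - 1e-12 & trial$time <= t2 / 1000 + 1e-12)
  tt <- trial$time[idx]
  apply(trial$a[idx, , drop = FALSE], 2L, function(y) .trapz(tt, y)) /
    (tt[length(tt)] - tt[1L])
}

#' Updated target joint angles from the settled posture
#'
#' Same time-average as [compute_tone()], applied to the joint angles.
#'
#' @inheritParams compute_tone
#' @return target joint angles (rad)
#' @export
update_targets <- function(trial, t1 = 3000, t2 = 5000) {
  if (trial$fell) stop("targets are undefined for a trial that fell")
  idx <- which(trial$time >= t1 / 1000 - 1e-12 & trial$time <= t2 / 1000 + 1e-12)
  tt <- trial$time[idx]
  apply(trial$q[idx, , drop = FALSE], 2L, function(y) .trapz(tt, y)) /
    (tt[length(tt)] - tt[1L])
}

#' Cartesian grid of gain knobs for the tone sweep
#'
#' @param k_p,k_d proprioceptive knob values (within \[1, 3\])
#' @param k_ves common value for the six vestibular knobs (within
#'   \[1e-4, 1e-2\]), or 0 for the condition without the vestibulospinal
#'   channel
#' @return data.frame with one knob combination per row
#' @export
tone_knob_grid <- function(k_p, k_d, k_ves = 0) {
  expand.grid(k_p = k_p, k_d = k_d, k_ves = k_ves, KEEP.OUT.ATTRS = FALSE)
}

#' Generate muscle-tone candidates
#'
#' For each knob combination, runs a delay-free, noise-free trial with zero
#' tone; combinations under which the plant stands 5,000 ms produce a
#' candidate: the time-averaged activations (the tone), the updated target
#' posture, the tone norm, and the noise-calibration magnitudes taken from
#' the same standing trial.
#'
#' @param plant a `posture_plant`
#' @param knob_grid data.frame from [tone_knob_grid()] (columns `k_p`,
#'   `k_d`, `k_ves`)
#' @param config base [sim_config()]; its delays and noise are forced to
#'   zero for the sweep
#' @param q_init optional initial/target posture for the sweep trials
#'   (default the plant reference posture)
#' @return list of class `"tone_candidates"`; each element has `u_ff`,
#'   `norm`, `q_target`, `knobs`, `mu`, `stood`
#' @export
generate_candidates <- function(plant, knob_grid, config = sim_config(),
                                q_init = plant$q_ref) {
  if (nrow(knob_grid) == 0L) stop("empty knob grid")
  config$tau_fb <- 0; config$tau_trans <- 0; config$k_noise <- 0
  out <- vector("list", nrow(knob_grid))
  for (i in seq_len(nrow(knob_grid))) {
    kn <- knob_grid[i, ]
    params <- controller_params(plant, u_ff = 0, k_p = kn$k_p, k_d = kn$k_d,
                                k_ves = kn$k_ves, q_target = q_init)
    trial <- run_trial(plant, params, config)
    if (trial$fell) next
    u_ff <- compute_tone(trial)
    mu <- c(colMeans(abs(trial$L)), colMeans(abs(trial$Ldot)),
            colMeans(abs(trial$head)))
    out[[i]] <- list(u_ff = u_ff, norm = uff_norm(u_ff),
                     q_target = update_targets(trial),
                     knobs = c(k_p = kn$k_p, k_d = kn$k_d, k_ves = kn$k_ves),
                     mu = pmax(mu, 1e-12), stood = TRUE)
  }
  structure(Filter(Negate(is.null), out), class = "tone_candidates")
}

#' @export
print.tone_candidates <- function(x, ...) {
  cat("Tone candidates:", length(x), "standing combination(s)\n")
  if (length(x))
    cat("  ||u_ff||2 range [", format(min(vapply(x, `[[`, 0, "norm"))), ",",
        format(max(vapply(x, `[[`, 0, "norm"))), "]\n")
  invisible(x)
}

#' Select tone candidates closest to target norms
#'
#' For each target, the candidate minimizing `|norm - target|` is chosen,
#' ties broken toward the smaller norm.  Candidates listed in `rejected`
#' (e.g. because downstream gain tuning failed for them) are skipped, which
#' implements next-closest re-selection.
#'
#' @param candidates a `tone_candidates` list
#' @param targets tone-norm targets (default 1.5 to 4.5 by 0.5, the
#'   whole-body protocol; reduced fixtures use smaller targets)
#' @param rejected integer indices into `candidates` to skip
#' @return data.frame with one row per target: `target`, `index` (into
#'   `candidates`, NA if none available), `norm`; empty selection (all NA)
#'   with a warning when no candidates exist
#' @export
select_tones <- function(candidates, targets = seq(1.5, 4.5, by = 0.5),
                         rejected = integer(0)) {
  avail <- setdiff(seq_along(candidates), rejected)
  if (length(avail) == 0L) {
    warning("no tone candidates available for selection")
    return(data.frame(target = targets, index = NA_integer_, norm = NA_real_))
  }
  norms <- vapply(candidates, `[[`, 0, "norm")[avail]
  pick <- vapply(targets, function(tg) {
    d <- abs(norms - tg)
    cand <- which(d == min(d))
    avail[cand[which.min(norms[cand])]]  # tie -> smaller norm
  }, 0L)
  data.frame(target = targets, index = pick,
             norm = vapply(candidates[pick], `[[`, 0, "norm"))
}

#' Fall/posture objective of a trial
#'
#' `J = w_fail * J_fail + w_pos * J_pos` with
#' `J_fail = (T_simu - T_fail) / T_fail` (0 when the trial stood) and
#' `J_pos = sum over joints of integral |theta_j(t) - theta_j(0)| dt` up to
#' the fall (rad s).  A fall at t = 0 yields a large sentinel objective.
#'
#' @param trial a `posture_trial`
#' @param w_fail,w_pos weights; defaults taken from the trial's config
#' @return list of class `"objective_value"`: `J`, `J_fail`, `J_pos`,
#'   `T_fail`
#' @export
objective_J <- function(trial, w_fail = trial$config$w_fail,
                        w_pos = trial$config$w_pos) {
  if (trial$T_fail <= 0)
    return(structure(list(J = w_fail * trial$T_simu, J_fail = trial$T_simu,
                          J_pos = 0, T_fail = 0), class = "objective_value"))
  J_fail <- if (trial$fell) (trial$T_simu - trial$T_fail) / trial$T_fail else 0
  dev <- sweep(trial$q, 2L, trial$q[1L, ], `-`)
  J_pos <- sum(apply(abs(dev), 2L, function(y) .trapz(trial$time, y)))
  structure(list(J = w_fail * J_fail + w_pos * J_pos,
                 J_fail = J_fail, J_pos = J_pos, T_fail = trial$T_fail),
            class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  cat("J =", format(x$J), "( J_fail =", format(x$J_fail),
      ", J_pos =", format(x$J_pos), "rad s , T_fail =", x$T_fail, "ms )\n")
  invisible(x)
}

#' Tune feedback gains with CMA-ES
#'
#' Stage 2 of the pipeline: with the tone and target posture fixed, searches
#' the gain knobs (`k_p`, `k_d` in \[1, 3\]; `k_1..k_6` in \[1e-4, 1e-2\],
#' or absent when the vestibular channel is disabled) in log10 space with
#' bound clipping, minimizing the mean objective over trials run with the
#' full delays and sensory noise.  Each evaluation uses the same fixed noise
#' seeds (`eval_seeds`), so CMA-ES ranks candidates on a consistent
#' stochastic objective.
#'
#' @param plant a `posture_plant`
#' @param u_ff fixed tone vector from stage 1
#' @param q_target target posture from stage 1
#' @param mu noise-calibration magnitudes (from the candidate or
#'   [calibrate_mu()])
#' @param config a [sim_config()] (delays and noise as they should apply
#'   during tuning)
#' @param vst logical: include the six vestibular knobs (8-D search) or
#'   force them to zero (2-D search, tract absent)
#' @param eval_seeds integer seeds of the per-evaluation noise schedule
#' @param max_iter CMA-ES generations (default 60)
#' @param lambda population size (default `4 + floor(3 log d)`)
#' @param seed CMA-ES sampling seed
#' @return list: `knobs` (`k_p`, `k_d`, `k_ves`), `objective`
#'   (an `objective_value` of the best evaluation re-run), `success`
#'   (TRUE if the best gains stand on all evaluation seeds), `cma` details
#' @export
tune_gains <- function(plant, u_ff, q_target, mu, config = sim_config(),
                       vst = TRUE, eval_seeds = 1L, max_iter = 60,
                       lambda = NULL, seed = 1L) {
  lo <- if (vst) c(0, 0, rep(-4, 6)) else c(0, 0)          # log10 bounds
  hi <- if (vst) c(log10(3), log10(3), rep(-2, 6)) else c(log10(3), log10(3))
  knobs_of <- function(x) {
    k <- 10^x
    list(k_p = k[1L], k_d = k[2L],
         k_ves = if (vst) k[3:8] else rep(0, 6L))
  }
  eval_J <- function(x) {
    kn <- knobs_of(x)
    params <- controller_params(plant, u_ff = u_ff, k_p = kn$k_p,
                                k_d = kn$k_d, k_ves = kn$k_ves,
                                q_target = q_target)
    mean(vapply(eval_seeds, function(s)
      objective_J(run_trial(plant, params, config, seed = s, mu = mu))$J, 0))
  }
  x0 <- (lo + hi) / 2
  res <- cmaes_minimize(eval_J, x0, sigma0 = 0.3 * max(hi - lo),
                        lower = lo, upper = hi, lambda = lambda,
                        max_iter = max_iter, seed = seed, trace = TRUE)
  kn <- knobs_of(res$par)
  params <- controller_params(plant, u_ff = u_ff, k_p = kn$k_p, k_d = kn$k_d,
                              k_ves = kn$k_ves, q_target = q_target)
  objs <- lapply(eval_seeds, function(s)
    objective_J(run_trial(plant, params, config, seed = s, mu = mu)))
  success <- all(vapply(objs, function(o) o$J_fail == 0, TRUE))
  list(knobs = kn, objective = objs[[1L]], objectives = objs,
       success = success, cma = res)
}
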