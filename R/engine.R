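#' Simulation configuration
#'
#' Times named in milliseconds follow the convention of the quiet-standing
#' protocol (5,000 ms trials; 40/40/10/40 ms delays); they are converted to
#' integrator steps internally.  `dt` is in seconds; delays are rounded to
#' integer multiples of `dt`.
#'
#' @param dt integrator/control step (s), default 1 ms
#' @param T_simu trial duration (ms), default 5000
#' @param tau_fb sensory feedback delay (ms), default 40
#' @param tau_trans neural transmission delay on the motor command (ms),
#'   default 40
#' @param tau_act,tau_deact muscle activation/deactivation time constants
#'   (ms), defaults 10 and 40; with the feedback and transmission delays the
#'   slow (deactivation) branch totals a 120 ms loop lag
#' @param h_threshold fall threshold on COM height (m), default 0.7; applied
#'   directly for `full_anthropometry` plants, otherwise rescaled by the plant's
#'   standing COM height (see [detect_fall()])
#' @param w_fail,w_pos objective weights, defaults 10000 and 1
#' @param k_noise sensory noise scale, default 0.01
#' @param qdot_max blow-up guard (rad/s), default 50: exceeding it is flagged
#'   as a fall at that instant (gain search explores unstable regions)
#' @return a list of class `"sim_config"`
#' @export
sim_config <- function(dt = 0.001, T_simu = 5000,
                       tau_fb = 40, tau_trans = 40,
                       tau_act = 10, tau_deact = 40,
                       h_threshold = 0.7, w_fail = 10000, w_pos = 1,
                       k_noise = 0.01, qdot_max = 50) {
  stopifnot(dt > 0, T_simu > 0, tau_fb >= 0, tau_trans >= 0,
            tau_act > 0, tau_deact > 0, k_noise >= 0)
  structure(list(dt = dt, T_simu = T_simu, tau_fb = tau_fb,
                 tau_trans = tau_trans, tau_act = tau_act,
                 tau_deact = tau_deact, h_threshold = h_threshold,
                 w_fail = w_fail, w_pos = w_pos, k_noise = k_noise,
                 qdot_max = qdot_max), class = "sim_config")
}

#' Controller parameter set
#'
#' Bundles the feedforward tone, the scalar gain knobs with their per-group
#' expansion, and the target posture.  Reference sensory values (initial
#' muscle lengths/velocities and head kinematics) are taken at the start of
#' each trial, where the initial posture equals the target posture.
#'
#' @param plant a `posture_plant`
#' @param u_ff feedforward tone per muscle in \[0, 1\] (recycled)
#' @param k_p,k_d scalar proprioceptive gain knobs
#' @param k_ves vestibular knobs `k_1..k_6` (scalar recycled to 6); all-zero
#'   means the vestibulospinal channel is absent (`K_ves = 0` exactly)
#' @param q_target target joint angles (rad); default the plant reference
#'   posture
#' @return a list of class `"controller_params"` with expanded per-muscle
#'   gains `K_p`, `K_d` and the shared 18-vector `K_ves`
#' @export
controller_params <- function(plant, u_ff = 0, k_p = 0, k_d = 0, k_ves = 0,
                              q_target = plant$q_ref) {
  u_ff <- rep_len(u_ff, plant$n_muscles)
  if (any(u_ff < 0 | u_ff > 1)) stop("u_ff must lie in [0, 1]")
  if (length(k_ves) == 1L) k_ves <- rep(k_ves, 6L)
  gc <- plant$gain_coeffs
  ex <- expand_gains(k_p, k_d, k_ves, data.frame(group = rownames(gc),
                                                 c_p = gc[, 1], c_d = gc[, 2]))
  stopifnot(length(q_target) == plant$n_joints)
  structure(list(u_ff = u_ff, k_p = k_p, k_d = k_d, k_ves = k_ves,
                 K_p = ex$K_p, K_d = ex$K_d, K_ves = ex$K_ves,
                 q_target = as.numeric(q_target)),
            class = "controller_params")
}

#' Euclidean norm of the feedforward tone vector
#'
#' The whole-body muscle-tone index `||u_ff||_2 = sqrt(sum(u_ff_i^2))`.
#'
#' @param u_ff per-muscle tone vector
#' @return scalar norm
#' @export
uff_norm <- function(u_ff) sqrt(sum(u_ff^2))

#' Euclidean norm of the feedback activity
#'
#' `||u_fb||_2` over muscles, computed on the raw (unclipped) feedback
#' components; for a time-by-muscle matrix, one norm per time step.
#'
#' @param u_fb vector (per muscle) or matrix (time x muscle)
#' @return scalar, or vector over time steps
#' @export
ufb_norm <- function(u_fb) {
  if (is.matrix(u_fb)) sqrt(rowSums(u_fb^2)) else sqrt(sum(u_fb^2))
}

# Fall threshold on COM height for a given plant: the absolute 0.7 m
# criterion is tied to full-body anthropometry; reduced plants use the
# equivalent relative criterion 0.7 * h0 / 0.96 (approximately 72% of the
# standing COM height).
.fall_height_threshold <- function(plant, config, h0) {
  if (plant$full_anthropometry) config$h_threshold else config$h_threshold * h0 / 0.96
}

# branch-free clamps (hot loop; pmax/pmin/ifelse are too slow here)
.clip_lo0 <- function(x) (x + abs(x)) * 0.5
.clip01 <- function(x) {
  x <- (x + abs(x)) * 0.5
  1 - (1 - x + abs(1 - x)) * 0.5
}

#' Run one forward-dynamics standing trial
#'
#' Per control step: sense muscle lengths/velocities and head kinematics,
#' corrupt them with calibrated Gaussian noise, push them into the feedback
#' delay line, form the motor command (tone + delayed proprioceptive +
#' delayed vestibular feedback, clipped to \[0, 1\]), delay the command by
#' the transmission delay, update activations through the first-order
#' activation dynamics, and advance the rigid-body state by one RK4 step
#' with the muscle forces recomputed at each integrator stage.  The trial
#' stops at a fall (COM height below threshold, COM outside the base of
#' support, or the velocity blow-up guard) or at `T_simu`.
#'
#' Deterministic given `(params, config, seed)`; with `k_noise = 0` the
#' trial never touches the RNG.
#'
#' @param plant a `posture_plant`
#' @param params a [controller_params()]
#' @param config a [sim_config()]
#' @param seed optional integer seed for the sensory noise (the caller's RNG
#'   state is preserved)
#' @param mu calibrated noise magnitudes (see [calibrate_mu()]); required
#'   when `k_noise > 0` unless auto-calibration is acceptable, in which case
#'   it is run once internally
#' @return a `posture_trial`: time grid (s), state/command/sway series
#'   truncated at the fall, `T_fail` (ms), `fell`, tone and feedback norms
#' @export
run_trial <- function(plant, params, config = sim_config(), seed = NULL,
                      mu = NULL) {
  if (config$k_noise > 0 && is.null(mu))
    mu <- calibrate_mu(plant, params, config)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    } else on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                   add = TRUE)
    set.seed(seed)
  }

  dt <- config$dt
  n_steps <- as.integer(round(config$T_simu / 1000 / dt))
  n_fb <- as.integer(round(config$tau_fb / 1000 / dt))
  n_trans <- as.integer(round(config$tau_trans / 1000 / dt))
  tau_act <- config$tau_act / 1000
  tau_deact <- config$tau_deact / 1000

  nj <- plant$n_joints; nm <- plant$n_muscles
  one_link <- nj == 1L
  R <- plant$R; l_opt <- plant$l_opt; f_max <- plant$f_max
  v_max_abs <- plant$v_max_abs; q_ref <- plant$q_ref
  sig <- plant$sig
  A11 <- plant$A[1L, 1L]; A <- plant$A
  bgrav <- plant$b * plant$gravity
  inertia <- plant$inertia; lever <- plant$lever; mass <- plant$mass
  grav <- plant$gravity
  Itot1 <- A11 + inertia[1L]
  R1 <- R[1L, ]                      # one-link moment arms
  K_p <- as.numeric(params$K_p); K_d <- as.numeric(params$K_d)
  K_ves <- as.numeric(params$K_ves)
  vst_on <- any(K_ves != 0)
  u_ff <- params$u_ff
  has_head <- !is.na(plant$head_segment)
  hseg <- plant$head_segment
  hlev <- if (has_head) c(if (hseg > 1L) plant$length[seq_len(hseg - 1L)],
                          plant$head_sensor) else NULL
  fl_w2 <- 2 * .fl_width^2
  pe_s <- .pe_scale; pe_g <- .pe_steep; ecc <- .fv_ecc_cap

  force_of <- function(act, L, Ldot) {
    lt1 <- L / l_opt - 1
    f_l <- exp(-lt1 * lt1 / fl_w2)
    fv0 <- 1 + Ldot / v_max_abs
    fv0 <- (fv0 + abs(fv0)) * 0.5                  # floor at 0
    dv <- ecc - fv0
    f_v <- ecc - (dv + abs(dv)) * 0.5              # cap at ecc
    lp <- (lt1 + abs(lt1)) * 0.5
    f <- act * f_max * f_l * f_v + f_max * pe_s * (exp(pe_g * lp) - 1)
    (f + abs(f)) * 0.5
  }
  # time derivative of (q, qdot) with activations held constant
  deriv <- if (one_link) {
    function(q, qd, act) {
      forces <- force_of(act, l_opt - (q - q_ref) * R1, -qd * R1)
      c(qd, (sum(R1 * forces) + bgrav * sin(q)) / Itot1)
    }
  } else {
    iq <- seq_len(nj); iqd <- nj + iq
    function(y_q, y_qd, act) {
      dq <- y_q - q_ref
      L <- l_opt - as.vector(dq %*% R)
      Ldot <- -as.vector(y_qd %*% R)
      forces <- force_of(act, L, Ldot)
      tau <- as.vector(R %*% forces)
      Qphi <- tau - c(tau[-1L], 0)
      phi <- cumsum(y_q); phid <- cumsum(y_qd)
      dphi <- outer(phi, phi, "-")
      M <- A * cos(dphi); diag(M) <- diag(M) + inertia
      rhs <- Qphi + bgrav * sin(phi) - as.vector((A * sin(dphi)) %*% (phid^2))
      phidd <- solve(M, rhs)
      c(y_qd, phidd - c(0, phidd[-nj]))
    }
  }

  # initial state: posture = target posture, activations = tone
  q <- params$q_target; qd <- numeric(nj)
  a <- .clip01(u_ff)
  h0 <- com_position(plant, plant_state(plant, q))[["h"]]
  h_thresh <- .fall_height_threshold(plant, config, h0)

  # reference sensory values at the initial (= target) posture, at rest
  L0 <- l_opt - as.vector((q - q_ref) %*% R)
  Ldot0 <- numeric(nm)
  head0 <- if (has_head)
    as.numeric(head_kinematics(plant, plant_state(plant, q), numeric(nj)))
  else numeric(18L)

  k_noise <- config$k_noise
  if (k_noise > 0) {
    n_chan <- 2L * nm + 18L
    stopifnot(length(mu) == n_chan)
    noise <- matrix(stats::rnorm((n_steps + 1L) * n_chan), n_steps + 1L, n_chan)
    noise <- sweep(noise, 2L, k_noise * mu, `*`)
    iL <- seq_len(nm); iLd <- nm + iL; ihd <- 2L * nm + seq_len(18L)
  }

  ns1 <- n_steps + 1L
  rec_q <- matrix(NA_real_, ns1, nj); rec_qd <- matrix(NA_real_, ns1, nj)
  rec_a <- matrix(NA_real_, ns1, nm); rec_u <- matrix(NA_real_, ns1, nm)
  rec_up <- matrix(NA_real_, ns1, nm); rec_uv <- matrix(NA_real_, ns1, nm)
  rec_L <- matrix(NA_real_, ns1, nm); rec_Ld <- matrix(NA_real_, ns1, nm)
  rec_head <- matrix(NA_real_, ns1, 18L)
  rec_xcom <- numeric(ns1); rec_hcom <- numeric(ns1); rec_xcop <- numeric(ns1)
  hist_L <- matrix(NA_real_, ns1, nm); hist_Ld <- matrix(NA_real_, ns1, nm)
  hist_head <- matrix(NA_real_, ns1, 18L)

  T_fail_ms <- config$T_simu; fell <- FALSE; blew_up <- FALSE
  last <- ns1
  total_mass <- plant$total_mass
  bos_lo <- plant$bos[1L]; bos_hi <- plant$bos[2L]
  qdot_guard <- config$qdot_max
  head_sensor1 <- plant$head_sensor

  for (s in seq_len(ns1)) {
    if (one_link) {
      L <- l_opt - (q - q_ref) * R1
      Ldot <- -qd * R1
      forces <- force_of(a, L, Ldot)
      tau1 <- sum(R1 * forces)
      phidd <- (tau1 + bgrav * sin(q)) / Itot1
      sphi <- sin(q); cphi <- cos(q)
      lev1 <- lever[1L, 1L]
      segx <- -lev1 * sphi; segy <- lev1 * cphi
      segax <- lev1 * (-cphi * phidd + sphi * qd * qd)
      segay <- lev1 * (-sphi * phidd - cphi * qd * qd)
      fy <- mass * (segay + grav)
      xcom <- segx; hcom <- segy
      dLdt <- mass * (segx * segay - segy * segax) + inertia * phidd
      xcop <- (dLdt + grav * mass * segx) / fy
      if (has_head) {
        hs <- head_sensor1
        head <- c(hs * (-cphi * phidd + sphi * qd * qd),
                  hs * (-sphi * phidd - cphi * qd * qd),
                  0, 0, 0, phidd,
                  -hs * cphi * qd, -hs * sphi * qd, 0, 0, 0, qd,
                  -hs * sphi, hs * cphi, 0, 0, 0, q)
      } else head <- numeric(18L)
      qd_max_now <- abs(qd)
    } else {
      dq <- q - q_ref
      L <- l_opt - as.vector(dq %*% R)
      Ldot <- -as.vector(qd %*% R)
      forces <- force_of(a, L, Ldot)
      tau <- as.vector(R %*% forces)
      Qphi <- tau - c(tau[-1L], 0)
      phi <- cumsum(q); phid <- cumsum(qd)
      dphi <- outer(phi, phi, "-")
      M <- A * cos(dphi); diag(M) <- diag(M) + inertia
      rhs <- Qphi + bgrav * sin(phi) - as.vector((A * sin(dphi)) %*% (phid^2))
      phidd <- solve(M, rhs)
      sphi <- sin(phi); cphi <- cos(phi)
      segx <- -as.vector(lever %*% sphi); segy <- as.vector(lever %*% cphi)
      segax <- as.vector(lever %*% (-cphi * phidd + sphi * phid^2))
      segay <- as.vector(lever %*% (-sphi * phidd - cphi * phid^2))
      fy <- sum(mass * (segay + grav))
      xcom <- sum(mass * segx) / total_mass
      hcom <- sum(mass * segy) / total_mass
      dLdt <- sum(mass * (segx * segay - segy * segax)) + sum(inertia * phidd)
      xcop <- (dLdt + grav * sum(mass * segx)) / fy
      if (has_head) {
        idx <- seq_len(hseg)
        head <- c(sum(hlev * (-cphi[idx] * phidd[idx] + sphi[idx] * phid[idx]^2)),
                  sum(hlev * (-sphi[idx] * phidd[idx] - cphi[idx] * phid[idx]^2)),
                  0, 0, 0, phidd[hseg],
                  -sum(hlev * cphi[idx] * phid[idx]),
                  -sum(hlev * sphi[idx] * phid[idx]),
                  0, 0, 0, phid[hseg],
                  -sum(hlev * sphi[idx]), sum(hlev * cphi[idx]),
                  0, 0, 0, phi[hseg])
      } else head <- numeric(18L)
      qd_max_now <- max(abs(qd))
    }

    # sensed values (receptor noise applied before the delay line)
    if (k_noise > 0) {
      zL <- L + noise[s, iL]
      zLd <- Ldot + noise[s, iLd]
      zhead <- head + noise[s, ihd]
    } else { zL <- L; zLd <- Ldot; zhead <- head }
    hist_L[s, ] <- zL; hist_Ld[s, ] <- zLd; hist_head[s, ] <- zhead

    sd_row <- if (s > n_fb) s - n_fb else 1L
    u_prop <- K_p * (hist_L[sd_row, ] - L0) / L0 +
      K_d * (hist_Ld[sd_row, ] - Ldot0) / v_max_abs
    if (vst_on && has_head) {
      hd <- hist_head[sd_row, ]
      dy <- hd[14L] - head0[14L]
      e_ves <- c(hd[1:12],
                 abs(hd[13L] - head0[13L]),
                 if (dy < 0) -dy else 0,
                 abs(hd[15L] - head0[15L]),
                 abs(hd[16:18] - head0[16:18]))
      u_ves <- sig * sum(K_ves * e_ves)
    } else u_ves <- numeric(nm)
    u <- .clip01(u_ff + u_prop + u_ves)

    rec_q[s, ] <- q; rec_qd[s, ] <- qd; rec_a[s, ] <- a
    rec_u[s, ] <- u; rec_up[s, ] <- u_prop; rec_uv[s, ] <- u_ves
    rec_L[s, ] <- L; rec_Ld[s, ] <- Ldot; rec_head[s, ] <- head
    rec_xcom[s] <- xcom; rec_hcom[s] <- hcom; rec_xcop[s] <- xcop

    # fall detection at this sample
    if (hcom < h_thresh || xcom < bos_lo || xcom > bos_hi ||
        qd_max_now > qdot_guard) {
      fell <- TRUE
      blew_up <- qd_max_now > config$qdot_max
      T_fail_ms <- (s - 1L) * dt * 1000
      last <- s
      break
    }
    if (s == ns1) break

    # motor command delayed by the transmission delay, then activation lag
    u_cmd <- rec_u[if (s > n_trans) s - n_trans else 1L, ]
    taus <- tau_deact + (tau_act - tau_deact) * (u_cmd > a)
    a <- .clip01(u_cmd + (a - u_cmd) * exp(-dt / taus))

    # RK4 on (q, qdot) with the updated activation held constant
    if (one_link) {
      k1 <- deriv(q, qd, a)
      k2 <- deriv(q + dt / 2 * k1[1L], qd + dt / 2 * k1[2L], a)
      k3 <- deriv(q + dt / 2 * k2[1L], qd + dt / 2 * k2[2L], a)
      k4 <- deriv(q + dt * k3[1L], qd + dt * k3[2L], a)
      q <- q + dt / 6 * (k1[1L] + 2 * k2[1L] + 2 * k3[1L] + k4[1L])
      qd <- qd + dt / 6 * (k1[2L] + 2 * k2[2L] + 2 * k3[2L] + k4[2L])
    } else {
      k1 <- deriv(q, qd, a)
      k2 <- deriv(q + dt / 2 * k1[iq], qd + dt / 2 * k1[iqd], a)
      k3 <- deriv(q + dt / 2 * k2[iq], qd + dt / 2 * k2[iqd], a)
      k4 <- deriv(q + dt * k3[iq], qd + dt * k3[iqd], a)
      incr <- dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      q <- q + incr[iq]
      qd <- qd + incr[iqd]
    }
  }

  keep <- seq_len(last)
  ufb_raw <- rec_up[keep, , drop = FALSE] + rec_uv[keep, , drop = FALSE]
  structure(list(
    time = (keep - 1L) * dt,
    q = rec_q[keep, , drop = FALSE], qdot = rec_qd[keep, , drop = FALSE],
    a = rec_a[keep, , drop = FALSE], u = rec_u[keep, , drop = FALSE],
    u_fb_prop = rec_up[keep, , drop = FALSE],
    u_fb_ves = rec_uv[keep, , drop = FALSE],
    L = rec_L[keep, , drop = FALSE], Ldot = rec_Ld[keep, , drop = FALSE],
    head = rec_head[keep, , drop = FALSE],
    x_com = rec_xcom[keep], h_com = rec_hcom[keep], x_cop = rec_xcop[keep],
    T_fail = T_fail_ms, T_simu = config$T_simu, fell = fell,
    blew_up = blew_up,
    uff_norm = uff_norm(u_ff), ufb_norm = ufb_norm(ufb_raw),
    h_threshold = h_thresh, params = params, config = config, seed = seed
  ), class = "posture_trial")
}

#' @export
print.posture_trial <- function(x, ...) {
  cat("Standing trial:", if (x$fell) paste0("FELL at ", x$T_fail, " ms")
      else paste0("stood ", x$T_simu, " ms"), "\n")
  cat("  tone ||u_ff||2 =", format(x$uff_norm), "; mean ||u_fb||2 =",
      format(mean(x$ufb_norm)), "\n")
  cat("  COP range [", format(min(x$x_cop)), ",", format(max(x$x_cop)), "] m\n")
  invisible(x)
}

#' Detect the fall time in a stored trajectory
#'
#' Scans the recorded series for the first sample at which the COM height
#' drops below the fall threshold (0.7 m for full-anthropometry plants,
#' otherwise 72% of the standing height: `0.7 * h0 / 0.96`), the COM leaves
#' the base of support, or the velocity guard trips; returns `T_simu` if
#' none occurs.
#'
#' @param trial a `posture_trial`
#' @param plant the `posture_plant` it was run on
#' @param config the `sim_config` used
#' @return `T_fail` in ms
#' @export
detect_fall <- function(trial, plant, config) {
  h0 <- trial$h_com[1L]
  h_thresh <- .fall_height_threshold(plant, config, h0)
  bad <- trial$h_com < h_thresh | trial$x_com < plant$bos[1L] |
    trial$x_com > plant$bos[2L] |
    apply(abs(trial$qdot), 1L, max) > config$qdot_max
  if (any(bad)) trial$time[which(bad)[1L]] * 1000 else config$T_simu
}
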