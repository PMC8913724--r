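#' Functional muscle-group gain-expansion coefficients
#'
#' The 14 functional groups into which whole-body muscles are pooled, with
#' the dimensionless multipliers `(c_p, c_d)` that expand the two scalar
#' proprioceptive gain knobs `k_p`, `k_d` into per-group gains
#' `K_p = c_p * k_p`, `K_d = c_d * k_d`.  Muscles within a functional group
#' share feedback gains (functional-consistency and bilateral-symmetry
#' assumptions); feedforward tone may still differ per muscle.
#'
#' @return data.frame with columns `group`, `c_p`, `c_d` (14 rows); the same
#'   table ships as a CSV in `inst/extdata/gain_coefficients.csv`.
#' @export
gain_coefficients <- function() {
  data.frame(
    group = c("Lumbar extensor", "Lumbar flexor", "Hip extensor", "Hip flexor",
              "Knee extensor", "Knee flexor", "Ankle extensor", "Ankle flexor",
              "Subtalar evertor", "Subtalar invertor", "Biarticular",
              "Neck extensor", "Neck flexor", "Neck biarticular"),
    c_p = c(0.50, 0.48, 0.45, 0.50, 0.33, 0.28, 0.17, 0.30,
            0.50, 0.50, 0.39, 0.17, 0.17, 0.17),
    c_d = c(0.23, 0.11, 0.05, 0.16, 0.05, 0.23, 0.06, 0.27,
            0.11, 0.05, 0.05, 0.06, 0.27, 0.06),
    stringsAsFactors = FALSE
  )
}

#' Expand scalar gain knobs into per-group feedback gains
#'
#' Proprioceptive gains scale per group as `K_p_i = c_p_i * k_p`,
#' `K_d_i = c_d_i * k_d`.  The six vestibular knobs `k_1..k_6` each scale one
#' 3-component block of the 18-component vestibular gain vector (block order:
#' translational acceleration, angular acceleration, translational velocity,
#' angular velocity, position, angle), with an overall factor 0.01:
#' `K_ves = 0.01 * c(k_1, k_1, k_1, k_2, ..., k_6)`.  The vestibular gain
#' vector is shared by all groups; the sign split between extensors and
#' flexors is applied in [vestibular_fb()].
#'
#' @param k_p,k_d scalar proprioceptive gain knobs (>= 0)
#' @param k_ves vestibular knobs `k_1..k_6` (length 6, >= 0); a single scalar
#'   is recycled
#' @param gain_coeffs matrix/data.frame with columns `c_p`, `c_d`, one row
#'   per muscle group (rownames or a `group` column give labels)
#' @return list with `K_p`, `K_d` (per group) and `K_ves` (named 18-vector)
#' @export
expand_gains <- function(k_p, k_d, k_ves, gain_coeffs) {
  stopifnot(k_p >= 0, k_d >= 0)
  if (length(k_ves) == 1L) k_ves <- rep(k_ves, 6L)
  stopifnot(length(k_ves) == 6L, all(k_ves >= 0))
  if (is.data.frame(gain_coeffs)) {
    labels <- if ("group" %in% names(gain_coeffs)) gain_coeffs$group else rownames(gain_coeffs)
    gc <- as.matrix(gain_coeffs[, c("c_p", "c_d")])
    rownames(gc) <- labels
    gain_coeffs <- gc
  }
  K_ves <- 0.01 * rep(k_ves, each = 3L)
  names(K_ves) <- head_component_names()
  list(K_p = stats::setNames(gain_coeffs[, "c_p"] * k_p, rownames(gain_coeffs)),
       K_d = stats::setNames(gain_coeffs[, "c_d"] * k_d, rownames(gain_coeffs)),
       K_ves = K_ves)
}

#' Vestibular error vector
#'
#' Maps current and reference head kinematics to the 18-component error used
#' by the vestibulospinal feedback.  Acceleration and velocity blocks pass
#' through as raw current values; the position block is the component-wise
#' absolute deviation in x and z, while the vertical component is rectified:
#' it is `|y - y0|` only when the head is BELOW its reference (`y - y0 < 0`)
#' and 0 otherwise, because the tract acts to keep the head up; the angle
#' block is the component-wise absolute deviation.
#'
#' @param head,head0 current and reference 18-vectors (see
#'   [head_kinematics()])
#' @return numeric 18-vector; position and angle blocks are >= 0
#' @export
vestibular_error <- function(head, head0) {
  e <- head
  dy <- head[["pos_y"]] - head0[["pos_y"]]
  e["pos_x"] <- abs(head[["pos_x"]] - head0[["pos_x"]])
  e["pos_y"] <- if (dy < 0) -dy else 0
  e["pos_z"] <- abs(head[["pos_z"]] - head0[["pos_z"]])
  e[16:18] <- abs(head[16:18] - head0[16:18])
  e
}

#' Vestibular feedback output for one muscle group
#'
#' `u = sig * sum(K_ves * e_ves)` with `sig = +1` for extensors and `-1` for
#' flexors: the lateral vestibulospinal tract excites extensors and inhibits
#' flexors.  With `K_ves` identically zero (tract absent) the output is 0
#' for every muscle.
#'
#' @param sig +1 (extensor) or -1 (flexor)
#' @param K_ves 18-vector of vestibular gains for the group
#' @param e_ves 18-vector from [vestibular_error()]
#' @return scalar feedback contribution
#' @export
vestibular_fb <- function(sig, K_ves, e_ves) {
  if (length(K_ves) != length(e_ves)) stop("K_ves and e_ves dimensions differ")
  sig * sum(K_ves * e_ves)
}

#' Proprioceptive feedback output for one muscle group
#'
#' `u = K_p * (L - L0)/L0 + K_d * (Ldot - Ldot0)/v_max_abs`, with the
#' delayed musculotendon length and lengthening velocity and the group's
#' maximal lengthening speed `v_max_abs = v_max * l_opt` (m/s).
#'
#' @param K_p,K_d group feedback gains
#' @param L,Ldot delayed length (m) and lengthening velocity (m/s)
#' @param L0,Ldot0 reference length and velocity
#' @param v_max_abs maximal lengthening speed (m/s)
#' @return scalar feedback contribution
#' @export
proprio_fb <- function(K_p, K_d, L, Ldot, L0, Ldot0, v_max_abs) {
  stopifnot(L0 > 0, v_max_abs > 0)
  K_p * (L - L0) / L0 + K_d * (Ldot - Ldot0) / v_max_abs
}

#' Compose the total motor command
#'
#' The feedforward tone and the two feedback components are summed and
#' clipped to \[0, 1\] (activations are physical fractions); the raw,
#' unclipped components are retained so that feedback-activity norms can be
#' computed afterwards.
#'
#' @param u_ff feedforward tone in \[0, 1\]
#' @param u_fb_prop,u_fb_ves feedback components (unbounded)
#' @return list with `u` (clipped command) and the three raw components
#' @export
compose_command <- function(u_ff, u_fb_prop, u_fb_ves) {
  list(u = pmin(pmax(u_ff + u_fb_prop + u_fb_ves, 0), 1),
       u_ff = u_ff, u_fb_prop = u_fb_prop, u_fb_ves = u_fb_ves)
}

#' Delay line for sampled sensory signals
#'
#' A fixed-rate history buffer: values pushed once per control step can be
#' read back at a given delay.  Reads before the first stored sample return
#' the value recorded at t = 0 (at startup the plant sits in its initial
#' posture, so early feedback is referenced to that state).
#'
#' @param dt sampling interval (s)
#' @param n_steps capacity (number of control steps)
#' @param width number of channels
#' @return a `delay_line` object
#' @export
delay_line <- function(dt, n_steps, width = 1L) {
  structure(list(dt = dt, width = width,
                 buf = matrix(NA_real_, n_steps + 1L, width), n = 0L),
            class = "delay_line")
}

#' Push one sample into a delay line
#' @param line a `delay_line`
#' @param value numeric vector of length `width`
#' @return the updated line
#' @export
delay_push <- function(line, value) {
  line$n <- line$n + 1L
  line$buf[line$n, ] <- value
  line
}

#' Read a delayed sample
#'
#' Returns the value recorded at `t - tau`, where `t` is the time of the most
#' recent push, using the nearest earlier sample; for `t - tau < 0` the
#' t = 0 record is returned.
#'
#' @param line a `delay_line`
#' @param tau delay (s), >= 0
#' @return numeric vector of length `width`
#' @export
delay_read <- function(line, tau) {
  if (line$n == 0L) stop("delay line is empty")
  k <- line$n - as.integer(floor(tau / line$dt + 1e-9))
  line$buf[max(k, 1L), ]
}
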