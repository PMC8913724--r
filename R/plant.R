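#' Reduced sagittal-plane musculoskeletal plants
#'
#' A plant is a serial chain of rigid segments standing on a fixed ankle
#' pivot, actuated by antagonist muscle groups with constant moment arms.
#' Coordinates: x anterior, y vertical (up), z lateral.  Joint angles are
#' positive for extension (posterior rotation of the distal segment relative
#' to its parent), so the absolute angle of segment i from the vertical is
#' `phi_i = sum(q[1:i])`, positive posterior.  A small anterior standing lean
#' is therefore a negative ankle angle.
#'
#' @name plant
#' @keywords internal
NULL

#' Build a validated plant from a specification list
#'
#' @param spec A list with elements:
#'   \describe{
#'     \item{name}{label for the plant.}
#'     \item{segments}{list of segments, proximal to distal; each a list with
#'       `name`, `joint` (name of its proximal joint), `mass` (kg), `length`
#'       (m), `com_offset` (m from the proximal joint along the segment) and
#'       `inertia` (kg m^2 about the segment COM).}
#'     \item{muscles}{list of muscle groups; each a list with `name`, `role`
#'       (`"flexor"` or `"extensor"`), `f_max` (N), `l_opt` (m), `v_max`
#'       (optimal lengths per second), `moment_arms` (named numeric,
#'       joint -> m, signed, extension-positive) and `gain_coeffs`
#'       (`c(c_p, c_d)` dimensionless feedback-gain multipliers).}
#'     \item{bos}{heel/toe x-interval of the base of support, m about the
#'       ankle (default `c(-0.06, 0.18)`).}
#'     \item{head}{list with `segment` (name of the head segment carrying the
#'       vestibular organ) and optional `sensor_offset` (m along the segment;
#'       default the segment COM offset).}
#'     \item{posture}{reference joint angles (rad); also the default initial
#'       and target posture.}
#'     \item{full_anthropometry}{logical; `TRUE` if the plant uses full-body
#'       anthropometry so that the absolute 0.7 m fall threshold applies.}
#'   }
#'
#' @return An object of class `"posture_plant"` with precomputed dynamics
#'   coefficients (inertia coupling matrix, gravity lever vector, moment-arm
#'   matrix).
#' @export
build_plant <- function(spec) {
  segs <- spec$segments
  if (is.null(segs) || length(segs) < 1L) stop("plant spec needs at least one segment")
  mus <- spec$muscles
  if (is.null(mus) || length(mus) < 2L) stop("plant spec needs at least two muscle groups")

  n <- length(segs)
  seg_name <- vapply(segs, `[[`, "", "name")
  joint <- vapply(segs, `[[`, "", "joint")
  mass <- vapply(segs, function(s) as.numeric(s$mass), 0)
  len <- vapply(segs, function(s) as.numeric(s$length), 0)
  com <- vapply(segs, function(s) as.numeric(s$com_offset), 0)
  inertia <- vapply(segs, function(s) as.numeric(s$inertia), 0)
  if (any(mass <= 0)) stop("segment mass must be positive")
  if (any(len <= 0)) stop("segment length must be positive")
  if (any(com < 0 | com > len)) stop("com_offset must lie within the segment")
  if (any(inertia < 0)) stop("segment inertia must be non-negative")
  if (anyDuplicated(joint)) stop("joint names must be unique")

  m_name <- vapply(mus, `[[`, "", "name")
  role <- vapply(mus, `[[`, "", "role")
  if (!all(role %in% c("flexor", "extensor"))) stop("muscle role must be 'flexor' or 'extensor'")
  f_max <- vapply(mus, function(m) as.numeric(m$f_max), 0)
  l_opt <- vapply(mus, function(m) as.numeric(m$l_opt), 0)
  v_max <- vapply(mus, function(m) as.numeric(m$v_max), 0)
  if (any(f_max <= 0)) stop("f_max must be positive")
  if (any(l_opt <= 0)) stop("l_opt must be positive")
  if (any(v_max <= 0)) stop("v_max must be positive")

  nm <- length(mus)
  # moment-arm matrix, joints x muscles (extension-positive arms)
  R <- matrix(0, n, nm, dimnames = list(joint, m_name))
  for (k in seq_len(nm)) {
    arms <- mus[[k]]$moment_arms
    if (is.null(names(arms)) || any(!nzchar(names(arms))))
      stop("moment_arms must be a named vector (joint -> m)")
    unknown <- setdiff(names(arms), joint)
    if (length(unknown))
      stop("muscle '", m_name[k], "' references unknown joint(s): ",
           paste(unknown, collapse = ", "))
    R[names(arms), k] <- as.numeric(arms)
  }
  # every joint needs an antagonist pair among the muscles crossing it
  for (j in seq_len(n)) {
    crossing <- which(R[j, ] != 0)
    if (!any(role[crossing] == "extensor"))
      stop("joint '", joint[j], "' has no extensor muscle group")
    if (!any(role[crossing] == "flexor"))
      stop("joint '", joint[j], "' has no flexor muscle group")
  }

  gain_coeffs <- t(vapply(mus, function(m) {
    gc <- as.numeric(m$gain_coeffs)
    if (length(gc) != 2L) stop("gain_coeffs must be c(c_p, c_d)")
    gc
  }, numeric(2)))
  dimnames(gain_coeffs) <- list(m_name, c("c_p", "c_d"))

  bos <- if (is.null(spec$bos)) c(-0.06, 0.18) else as.numeric(spec$bos)
  if (length(bos) != 2L || bos[1] >= bos[2]) stop("bos must be c(heel, toe) with heel < toe")

  head_idx <- NA_integer_
  head_sensor <- NA_real_
  if (!is.null(spec$head)) {
    head_idx <- match(spec$head$segment, seg_name)
    if (is.na(head_idx)) stop("head segment '", spec$head$segment, "' not found")
    head_sensor <- if (is.null(spec$head$sensor_offset)) com[head_idx] else
      as.numeric(spec$head$sensor_offset)
  }

  posture <- if (is.null(spec$posture)) numeric(n) else as.numeric(spec$posture)
  if (length(posture) != n) stop("posture must have one angle per joint")

  # inertia coupling matrix A[j,k] = sum_{i >= max(j,k)} m_i a_ij a_ik where
  # a_ij is the lever of absolute angle phi_j in the COM position of segment i
  A <- matrix(0, n, n)
  b <- numeric(n)  # gravity lever: b_j = sum_{i >= j} m_i a_ij
  lev <- matrix(0, n, n)  # lev[i, j] = a_ij
  for (i in seq_len(n)) {
    if (i > 1L) lev[i, seq_len(i - 1L)] <- len[seq_len(i - 1L)]
    lev[i, i] <- com[i]
  }
  for (j in seq_len(n)) for (k in seq_len(n)) {
    i0 <- max(j, k)
    A[j, k] <- sum(mass[i0:n] * lev[i0:n, j] * lev[i0:n, k])
  }
  for (j in seq_len(n)) b[j] <- sum(mass[j:n] * lev[j:n, j])

  structure(list(
    name = if (is.null(spec$name)) "plant" else spec$name,
    n_joints = n, n_muscles = nm,
    seg_name = seg_name, joint = joint,
    mass = mass, length = len, com_offset = com, inertia = inertia,
    total_mass = sum(mass),
    muscle_name = m_name, role = role,
    sig = ifelse(role == "extensor", 1, -1),
    f_max = f_max, l_opt = l_opt, v_max = v_max,
    v_max_abs = v_max * l_opt,
    R = R, gain_coeffs = gain_coeffs,
    bos = bos, head_segment = head_idx, head_sensor = head_sensor,
    q_ref = posture,
    A = A, b = b, lever = lev,
    full_anthropometry = isTRUE(spec$full_anthropometry),
    gravity = 9.81
  ), class = "posture_plant")
}

#' @export
print.posture_plant <- function(x, ...) {
  cat("Sagittal musculoskeletal plant '", x$name, "'\n", sep = "")
  cat("  segments:", x$n_joints, "(", paste(x$seg_name, collapse = ", "), ")\n")
  cat("  muscle groups:", x$n_muscles, "(",
      sum(x$role == "extensor"), "extensor,", sum(x$role == "flexor"), "flexor )\n")
  cat("  total mass:", format(x$total_mass), "kg; BOS [",
      x$bos[1], ",", x$bos[2], "] m\n")
  if (!is.na(x$head_segment))
    cat("  head segment:", x$seg_name[x$head_segment],
        "(sensor at", x$head_sensor, "m)\n")
  invisible(x)
}

#' Plant state constructor
#'
#' @param plant a `posture_plant`
#' @param q joint angles (rad); default the plant's reference posture
#' @param qdot joint velocities (rad/s); default zero
#' @param a muscle-group activations in \[0, 1\]; default zero
#' @return a list of class `"plant_state"`
#' @export
plant_state <- function(plant, q = plant$q_ref, qdot = NULL, a = NULL) {
  n <- plant$n_joints
  if (is.null(qdot)) qdot <- numeric(n)
  if (is.null(a)) a <- numeric(plant$n_muscles)
  stopifnot(length(q) == n, length(qdot) == n, length(a) == plant$n_muscles)
  if (any(a < 0 | a > 1)) stop("activations must lie in [0, 1]")
  structure(list(q = as.numeric(q), qdot = as.numeric(qdot), a = as.numeric(a)),
            class = "plant_state")
}

#' Musculotendon lengths and lengthening velocities
#'
#' Constant-moment-arm linearization about the reference posture:
#' `L = l_opt - t(R) %*% (q - q_ref)` and `Ldot = -t(R) %*% qdot`.
#' Extension-positive arms mean extensors shorten when their joints extend.
#'
#' @param plant a `posture_plant`
#' @param q,qdot joint angles (rad) and velocities (rad/s)
#' @return list with numeric vectors `L` (m) and `Ldot` (m/s,
#'   lengthening-positive), one element per muscle group
#' @export
muscle_geometry <- function(plant, q, qdot) {
  dq <- q - plant$q_ref
  list(L = plant$l_opt - drop(crossprod(plant$R, dq)),
       Ldot = -drop(crossprod(plant$R, qdot)))
}

# Hill-curve constants: Gaussian force-length width, eccentric force cap,
# passive-element scale/steepness (engaged above optimal length).
.fl_width <- 0.45
.fv_ecc_cap <- 1.4
.pe_scale <- 0.02
.pe_steep <- 10

#' Hill-type muscle-group force
#'
#' Active force is `a * f_max * f_L * f_V` with a Gaussian force-length
#' factor (peak 1 at normalized length 1, width 0.45) and a clamped linear
#' force-velocity factor in `Vtilde = Ldot / (v_max * l_opt)`
#' (lengthening-positive): 1 at `Vtilde = 0`, 0 at `Vtilde = -1` (maximal
#' shortening), capped at 1.4 for fast lengthening.  An exponential passive
#' element engages above optimal length.  Force is never negative.
#'
#' @param plant a `posture_plant`
#' @param a activations in \[0, 1\] (one per muscle group)
#' @param L,Ldot musculotendon lengths (m) and lengthening velocities (m/s)
#' @return numeric vector of tensile forces (N), one per muscle group
#' @export
muscle_force <- function(plant, a, L, Ldot) {
  lt <- L / plant$l_opt
  vt <- Ldot / plant$v_max_abs
  f_l <- exp(-((lt - 1) / .fl_width)^2 / 2)
  f_v <- pmin(pmax(1 + vt, 0), .fv_ecc_cap)
  passive <- ifelse(lt > 1, plant$f_max * .pe_scale * (exp(.pe_steep * (lt - 1)) - 1), 0)
  pmax(a * plant$f_max * f_l * f_v + passive, 0)
}

#' First-order activation dynamics
#'
#' Exact exponential update of `da/dt = (u - a)/tau` over one step, with
#' `tau = tau_act` when the excitation exceeds the activation (muscle turning
#' on) and `tau = tau_deact` otherwise.
#'
#' @param a current activations in \[0, 1\]
#' @param u neural excitations in \[0, 1\]
#' @param dt step (s)
#' @param tau_act,tau_deact activation/deactivation time constants (s);
#'   defaults 10 ms and 40 ms
#' @return updated activations, guaranteed in \[0, 1\]
#' @export
activation_step <- function(a, u, dt, tau_act = 0.010, tau_deact = 0.040) {
  tau <- ifelse(u > a, tau_act, tau_deact)
  an <- u + (a - u) * exp(-dt / tau)
  pmin(pmax(an, 0), 1)
}

# Internal: core forward dynamics in absolute angles.
# Returns phiddot, qddot and ankle-ground reaction forces.
.chain_dynamics <- function(plant, q, qdot, forces) {
  n <- plant$n_joints
  tau <- drop(plant$R %*% forces)                 # joint torques, extension +
  Qphi <- tau - c(tau[-1L], 0)                    # generalized force on phi_j
  phi <- cumsum(q)
  phidot <- cumsum(qdot)
  if (n == 1L) {
    M <- plant$A[1L, 1L] + plant$inertia[1L]
    rhs <- Qphi + plant$gravity * plant$b * sin(phi)
    phiddot <- rhs / M
  } else {
    dphi <- outer(phi, phi, "-")
    M <- plant$A * cos(dphi)
    diag(M) <- diag(M) + plant$inertia
    cor_term <- drop((plant$A * sin(dphi)) %*% (phidot^2))
    rhs <- Qphi + plant$gravity * plant$b * sin(phi) - cor_term
    phiddot <- solve(M, rhs)
  }
  # COM accelerations of every segment -> net ground reaction at the ankle
  sphi <- sin(phi); cphi <- cos(phi)
  ax <- drop(plant$lever %*% (-cphi * phiddot + sphi * phidot^2))
  ay <- drop(plant$lever %*% (-sphi * phiddot - cphi * phidot^2))
  fx <- sum(plant$mass * ax)
  fy <- sum(plant$mass * (ay + plant$gravity))
  phiddot <- unname(phiddot)
  list(phiddot = phiddot, qddot = c(phiddot[1L], diff(phiddot)),
       reaction = c(fx = fx, fy = fy), tau = unname(tau),
       phi = phi, phidot = phidot)
}

#' Forward dynamics of the chain
#'
#' Computes joint accelerations from the chain's mass matrix (gravity
#' 9.81 m/s^2 along -y) given one tensile force per muscle group, together
#' with the net ground reaction at the ankle.
#'
#' @param plant a `posture_plant`
#' @param state a `plant_state`
#' @param forces tensile muscle forces (N), one per muscle group
#' @return list with `qddot` (rad/s^2), `phiddot` (absolute), `reaction`
#'   (`c(fx, fy)`, N) and `tau` (net joint torques, N m)
#' @export
dynamics <- function(plant, state, forces) {
  stopifnot(length(forces) == plant$n_muscles)
  .chain_dynamics(plant, state$q, state$qdot, forces)
}

#' Whole-body centre of mass
#'
#' @param plant a `posture_plant`
#' @param state a `plant_state`
#' @return `c(x, h)`: anterior position and height of the COM (m)
#' @export
com_position <- function(plant, state) {
  phi <- cumsum(state$q)
  x <- -drop(plant$lever %*% sin(phi))  # per-segment COM x
  y <- drop(plant$lever %*% cos(phi))
  c(x = sum(plant$mass * x) / plant$total_mass,
    h = sum(plant$mass * y) / plant$total_mass)
}

#' Anterior-posterior centre of pressure
#'
#' From the sagittal angular-momentum balance about the ankle: the ground
#' moment `M_ankle = dL/dt + g * sum(m_i x_i)` and `x_COP = M_ankle / F_y`
#' (ankle at the origin, ground at ankle height).  Reported unclamped; BOS
#' violation is handled by fall detection.
#'
#' @param plant a `posture_plant`
#' @param state a `plant_state`
#' @param phiddot absolute angular accelerations (from [dynamics()])
#' @param reaction ankle ground reaction `c(fx, fy)` (from [dynamics()])
#' @return x_COP (m)
#' @export
cop_position <- function(plant, state, phiddot, reaction) {
  fy <- reaction[["fy"]]
  if (fy <= 0) stop("vertical ground reaction is not positive: flight, trial invalid")
  phi <- cumsum(state$q)
  phidot <- cumsum(state$qdot)
  sphi <- sin(phi); cphi <- cos(phi)
  x <- -drop(plant$lever %*% sphi)
  y <- drop(plant$lever %*% cphi)
  ax <- drop(plant$lever %*% (-cphi * phiddot + sphi * phidot^2))
  ay <- drop(plant$lever %*% (-sphi * phiddot - cphi * phidot^2))
  dLdt <- sum(plant$mass * (x * ay - y * ax)) + sum(plant$inertia * phiddot)
  (dLdt + plant$gravity * sum(plant$mass * x)) / fy
}

# Fixed component order of the 18-vector of head kinematics:
# acc(x,y,z), angular acc(x,y,z), vel(x,y,z), angular vel(x,y,z),
# pos(x,y,z), angle(x,y,z).
head_component_names <- function() {
  blocks <- c("acc", "angacc", "vel", "angvel", "pos", "angle")
  paste(rep(blocks, each = 3L), rep(c("x", "y", "z"), 6L), sep = "_")
}

#' Head-sensor kinematics
#'
#' Position, velocity and acceleration of the vestibular sensor point on the
#' head segment, plus the segment's angle, angular velocity and angular
#' acceleration, in the world frame, as an 18-vector in the fixed block
#' order acc, angular acc, vel, angular vel, pos, angle (x, y, z each).
#' For a sagittal plant the out-of-plane components (translational z,
#' rotations about x and y) are exactly zero; the planar rotation appears
#' in the z angular components.
#'
#' @param plant a `posture_plant` with a designated head segment
#' @param state a `plant_state`
#' @param phiddot absolute angular accelerations (from [dynamics()])
#' @return named numeric 18-vector
#' @export
head_kinematics <- function(plant, state, phiddot) {
  h <- plant$head_segment
  if (is.na(h)) stop("plant has no designated head segment")
  phi <- cumsum(state$q)
  phidot <- cumsum(state$qdot)
  lev <- c(if (h > 1L) plant$length[seq_len(h - 1L)], plant$head_sensor)
  idx <- seq_len(h)
  sphi <- sin(phi[idx]); cphi <- cos(phi[idx])
  pos <- c(-sum(lev * sphi), sum(lev * cphi))
  vel <- c(-sum(lev * cphi * phidot[idx]), -sum(lev * sphi * phidot[idx]))
  acc <- c(sum(lev * (-cphi * phiddot[idx] + sphi * phidot[idx]^2)),
           sum(lev * (-sphi * phiddot[idx] - cphi * phidot[idx]^2)))
  out <- c(acc[1], acc[2], 0,
           0, 0, phiddot[h],
           vel[1], vel[2], 0,
           0, 0, phidot[h],
           pos[1], pos[2], 0,
           0, 0, phi[h])
  names(out) <- head_component_names()
  out
}
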