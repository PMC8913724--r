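test_that("build_plant validates fixtures and rejects inconsistent specs", {
  ol <- one_link_plant()
  expect_equal(ol$bos, c(-0.06, 0.18))
  expect_equal(ol$total_mass, 70)
  expect_equal(ol$n_joints, 1L)
  expect_equal(sort(ol$role), c("extensor", "flexor"))

  fl <- four_link_plant()
  expect_equal(fl$n_joints, 4L)
  expect_equal(fl$n_muscles, 8L)
  expect_false(is.na(fl$head_segment))
  expect_equal(fl$seg_name[fl$head_segment], "head")
  expect_equal(fl$total_mass, 70)

  spec <- make_fixture("one_link")
  spec$muscles[[2]]$role <- "extensor"       # two extensors, no flexor
  expect_error(build_plant(spec), "no flexor")
  spec2 <- make_fixture("one_link")
  spec2$segments[[1]]$mass <- -1
  expect_error(build_plant(spec2), "mass")
  spec3 <- make_fixture("one_link")
  spec3$muscles[[1]]$moment_arms <- c(hip = 0.1)
  expect_error(build_plant(spec3), "unknown joint")
})

test_that("muscle geometry is the constant-arm linearization", {
  tp <- toy_plant(r = 0.05, l_opt = 0.3)
  g0 <- muscle_geometry(tp, tp$q_ref, 0)
  expect_equal(g0$L, tp$l_opt, ignore_attr = TRUE)
  expect_equal(g0$Ldot, c(0, 0), ignore_attr = TRUE)

  g1 <- muscle_geometry(tp, tp$q_ref + 0.1, 0)
  expect_equal(unname(g1$L[1L]), 0.3 - 0.005)  # extensor shortens on extension
  expect_equal(unname(g1$L[2L]), 0.3 + 0.005)  # antagonist lengthens

  # antagonist pair: length changes have opposite sign for any displacement
  for (dq in c(-0.2, -0.01, 0.05, 0.3)) {
    g <- muscle_geometry(tp, tp$q_ref + dq, 0.7)
    expect_lt((g$L[1L] - 0.3) * (g$L[2L] - 0.3), 0)
    expect_lt(g$Ldot[1L] * g$Ldot[2L], 0)
  }
})

test_that("Hill-type force matches its closed form and never pulls negative", {
  tp <- toy_plant()
  lo <- tp$l_opt[1L]
  expect_equal(muscle_force(tp, c(0, 0), c(lo, 0.9 * lo), c(0, 0)), c(0, 0))
  f1 <- muscle_force(tp, c(1, 1), c(lo, lo), c(0, 0))
  expect_equal(f1, tp$f_max, ignore_attr = TRUE)
  # independent scalar evaluation of the chosen curves at a = 0.5
  expect_equal(muscle_force(tp, c(0.5, 0), c(lo, lo), c(0, 0))[1L],
               0.5 * tp$f_max[1L])
  lt <- 1.1; vt <- -0.3
  expected <- 0.5 * tp$f_max[1L] * exp(-((lt - 1) / 0.45)^2 / 2) * (1 + vt) +
    tp$f_max[1L] * 0.02 * (exp(10 * (lt - 1)) - 1)
  got <- muscle_force(tp, c(0.5, 0), c(lt * lo, lo),
                      c(vt * tp$v_max_abs[1L], 0))[1L]
  expect_equal(got, expected, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:50) {
    f <- muscle_force(tp, stats::runif(2), stats::runif(2, 0.5, 1.5) * lo,
                      stats::runif(2, -2, 2))
    expect_true(all(f >= 0))
  }
})

test_that("activation dynamics follow the exact exponential law without overshoot", {
  expect_equal(activation_step(0.4, 0.4, 0.01), 0.4)
  expect_equal(activation_step(0, 1, 0.010), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(activation_step(1, 0, 0.040), exp(-1), tolerance = 1e-12)

  # monotone approach to a held excitation, never overshooting
  for (u in c(0.2, 0.9)) {
    a <- 0.5; prev_gap <- abs(u - a)
    for (i in 1:200) {
      a <- activation_step(a, u, 0.002)
      gap <- abs(u - a)
      expect_lte(gap, prev_gap + 1e-15)
      prev_gap <- gap
    }
    expect_equal(a, u, tolerance = 1e-3)
  }
})

test_that("chain dynamics reproduce the inverted-pendulum closed form", {
  ol <- one_link_plant()
  st <- plant_state(ol, q = 0)
  d <- dynamics(ol, st, c(0, 0))
  expect_equal(d$qddot, 0)

  for (th in c(-0.3, 0.05, 0.1, 0.8)) {
    d <- dynamics(ol, plant_state(ol, q = th), c(0, 0))
    I_tot <- ol$mass * ol$com_offset^2 + ol$inertia
    expect_equal(d$qddot, ol$mass * ol$gravity * ol$com_offset / I_tot * sin(th),
                 tolerance = 1e-12)
  }
})

test_that("passive chain conserves energy under RK4 at 1 ms over 5 s", {
  ol <- one_link_plant()
  zero_f <- c(0, 0)
  energy <- function(q, qd) {
    I_tot <- ol$mass * ol$com_offset^2 + ol$inertia
    0.5 * I_tot * qd^2 + ol$mass * ol$gravity * ol$com_offset * cos(q)
  }
  q <- 0.3; qd <- 0; dt <- 1e-3
  E0 <- energy(q, qd)
  f <- function(q, qd) {
    d <- dynamics(ol, plant_state(ol, q = q, qdot = qd), zero_f)
    c(qd, d$qddot)
  }
  for (s in 1:5000) {
    k1 <- f(q, qd)
    k2 <- f(q + dt / 2 * k1[1], qd + dt / 2 * k1[2])
    k3 <- f(q + dt / 2 * k2[1], qd + dt / 2 * k2[2])
    k4 <- f(q + dt * k3[1], qd + dt * k3[2])
    q <- q + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    qd <- qd + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  }
  expect_lt(abs(energy(q, qd) - E0) / abs(E0), 1e-6)
})

test_that("COM position equals a brute-force mass-weighted sum", {
  fl <- four_link_plant()
  set.seed(21)
  for (i in 1:10) {
    q <- stats::runif(4, -0.3, 0.3)
    st <- plant_state(fl, q = q)
    com <- com_position(fl, st)
    # independent forward kinematics, segment by segment
    phi <- cumsum(q); px <- 0; py <- 0; sx <- 0; sy <- 0
    for (k in 1:4) {
      cx <- px - fl$com_offset[k] * sin(phi[k])
      cy <- py + fl$com_offset[k] * cos(phi[k])
      sx <- sx + fl$mass[k] * cx; sy <- sy + fl$mass[k] * cy
      px <- px - fl$length[k] * sin(phi[k])
      py <- py + fl$length[k] * cos(phi[k])
    }
    expect_equal(com[["x"]], sx / fl$total_mass, tolerance = 1e-9)
    expect_equal(com[["h"]], sy / fl$total_mass, tolerance = 1e-9)
  }

  ol <- one_link_plant()
  expect_equal(com_position(ol, plant_state(ol, q = 0))[["h"]], 1)
  expect_equal(com_position(ol, plant_state(ol, q = pi / 2))[["h"]], 0,
               tolerance = 1e-12)
})

test_that("COP agrees with the ankle-torque inverse-dynamics oracle", {
  ol <- one_link_plant()
  # static torque balance: COP projects onto the COM
  st <- plant_state(ol, q = ol$q_ref, a = balance_tone_one_link())
  geo <- muscle_geometry(ol, st$q, st$qdot)
  d <- dynamics(ol, st, muscle_force(ol, st$a, geo$L, geo$Ldot))
  expect_equal(d$qddot, 0, tolerance = 1e-12)
  xcop <- cop_position(ol, st, d$phiddot, d$reaction)
  expect_equal(xcop, com_position(ol, st)[["x"]], tolerance = 1e-9)

  # zero net ankle moment, static and vertical: COP at the ankle
  st0 <- plant_state(ol, q = 0)
  d0 <- dynamics(ol, st0, c(0, 0))
  expect_equal(cop_position(ol, st0, d0$phiddot, d0$reaction), 0,
               tolerance = 1e-12)

  # oscillating trial: stored COP equals tau_ankle / F_y at every sample
  cand <- cached_candidate()
  params <- controller_params(ol, u_ff = cand$u_ff, k_p = 2, k_d = 2,
                              q_target = cand$q_target)
  tr <- run_trial(ol, params, nodelay_config())
  idx <- seq(1, length(tr$time), by = 97)
  for (s in idx) {
    st <- plant_state(ol, q = tr$q[s, ], qdot = tr$qdot[s, ], a = tr$a[s, ])
    forces <- muscle_force(ol, st$a, tr$L[s, ], tr$Ldot[s, ])
    d <- dynamics(ol, st, forces)
    oracle <- sum(ol$R[1L, ] * forces) / d$reaction[["fy"]]
    expect_equal(tr$x_cop[s], oracle, tolerance = 1e-9)
  }

  # flight (non-positive vertical reaction) is an error
  expect_error(cop_position(ol, st0, d0$phiddot, c(fx = 0, fy = -1)), "flight")
})

test_that("head kinematics match rigid-body closed forms and stay planar", {
  ol <- one_link_plant()
  hk <- head_kinematics(ol, plant_state(ol, q = ol$q_ref), 0)
  expect_equal(unname(hk[7:12]), rep(0, 6))       # static: no velocities
  expect_equal(hk[["pos_x"]], -sin(ol$q_ref) * ol$head_sensor)
  expect_equal(hk[["pos_y"]], cos(ol$q_ref) * ol$head_sensor)
  expect_equal(hk[["angle_z"]], ol$q_ref)

  # constant rotation about the ankle: tangential speed = omega * r
  omega <- 0.7
  hk2 <- head_kinematics(ol, plant_state(ol, q = 0.2, qdot = omega), 0)
  speed <- sqrt(hk2[["vel_x"]]^2 + hk2[["vel_y"]]^2)
  expect_equal(speed, omega * ol$head_sensor, tolerance = 1e-12)
  expect_equal(hk2[["angvel_z"]], omega)

  # sagittal plant: out-of-plane components identically zero
  fl <- four_link_plant()
  set.seed(31)
  for (i in 1:5) {
    st <- plant_state(fl, q = stats::runif(4, -0.4, 0.4),
                      qdot = stats::runif(4, -1, 1))
    d <- dynamics(fl, st, stats::runif(8, 0, 500))
    hk <- head_kinematics(fl, st, d$phiddot)
    planar_zero <- c("acc_z", "angacc_x", "angacc_y", "vel_z",
                     "angvel_x", "angvel_y", "pos_z", "angle_x", "angle_y")
    expect_identical(unname(hk[planar_zero]), rep(0, 9))
  }

  tp <- toy_plant()                                # no head segment
  expect_error(head_kinematics(tp, plant_state(tp), 0), "head")
})
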