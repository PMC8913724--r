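test_that("gain expansion reproduces the functional-group coefficient table", {
  gc <- gain_coefficients()
  expect_equal(nrow(gc), 14L)
  # the same table ships as a plain-text file
  csv <- utils::read.csv(system.file("extdata", "gain_coefficients.csv",
                                     package = "posturesim"))
  expect_equal(csv$group, gc$group)
  expect_equal(csv$c_p, gc$c_p)
  expect_equal(csv$c_d, gc$c_d)

  ex <- expand_gains(2, 2, 1e-3, gc)
  expect_equal(unname(ex$K_p["Lumbar extensor"]), 1.00)
  expect_equal(unname(ex$K_d["Lumbar extensor"]), 0.46)
  expect_equal(unname(ex$K_p["Ankle extensor"]), 0.34)
  expect_equal(unname(ex$K_ves), rep(1e-5, 18L))   # 0.01 * 1e-3 per component

  ex0 <- expand_gains(0, 0, 0, gc)
  expect_true(all(ex0$K_p == 0) && all(ex0$K_d == 0) && all(ex0$K_ves == 0))

  # homogeneity: doubling a knob doubles every expanded gain exactly
  ex1 <- expand_gains(1.3, 0.7, 2e-3, gc)
  ex2 <- expand_gains(2.6, 0.7, 2e-3, gc)
  expect_identical(ex2$K_p, 2 * ex1$K_p)
  expect_identical(ex2$K_d, ex1$K_d)
  ex3 <- expand_gains(1.3, 0.7, 4e-3, gc)
  expect_identical(ex3$K_ves, 2 * ex1$K_ves)

  # the six knobs map block-wise in the fixed component order
  exb <- expand_gains(1, 1, c(1, 2, 3, 4, 5, 6) * 1e-3, gc)
  expect_equal(unname(exb$K_ves), 0.01 * rep(c(1, 2, 3, 4, 5, 6) * 1e-3,
                                             each = 3L))
})

test_that("vestibular error rectifies position and angle blocks", {
  h0 <- stats::setNames(numeric(18), head_component_names())
  h0["pos_y"] <- 1.6
  h <- h0
  expect_equal(unname(vestibular_error(h, h0)), rep(0, 18L))

  # head above its reference: vertical error is zero
  h["pos_y"] <- 1.61
  expect_equal(vestibular_error(h, h0)[["pos_y"]], 0)
  # head below: magnitude of the drop
  h["pos_y"] <- 1.58
  expect_equal(vestibular_error(h, h0)[["pos_y"]], 0.02)

  # x/z position and all angles: absolute deviations; acc/vel pass raw
  set.seed(41)
  for (i in 1:20) {
    h <- stats::setNames(stats::rnorm(18), head_component_names())
    e <- vestibular_error(h, h0)
    expect_true(all(e[13:18] >= 0))
    expect_identical(unname(e[1:12]), unname(h[1:12]))
    expect_equal(e[["pos_x"]], abs(h[["pos_x"]] - h0[["pos_x"]]))
    expect_equal(e[["angle_z"]], abs(h[["angle_z"]] - h0[["angle_z"]]))
  }
})

test_that("vestibulospinal output excites extensors and inhibits flexors antisymmetrically", {
  K <- rep(0.01 * 1e-3, 18L)
  e <- rep(1, 18L)
  expect_equal(vestibular_fb(+1, K, e), 1.8e-4)
  expect_equal(vestibular_fb(-1, K, e), -1.8e-4)

  set.seed(42)
  for (i in 1:20) {
    K <- stats::runif(18, 0, 1e-4)
    e <- abs(stats::rnorm(18))
    expect_identical(vestibular_fb(+1, K, e), -vestibular_fb(-1, K, e))
  }
  expect_equal(vestibular_fb(+1, rep(0, 18L), e), 0)  # tract absent
  expect_error(vestibular_fb(+1, K[1:6], e), "dimension")
})

test_that("proprioceptive feedback is zero at reference and linear in its errors", {
  expect_equal(proprio_fb(1, 1, L = 0.3, Ldot = 0.1, L0 = 0.3, Ldot0 = 0.1,
                          v_max_abs = 1), 0)
  expect_equal(proprio_fb(1, 0, L = 0.33, Ldot = 0, L0 = 0.3, Ldot0 = 0,
                          v_max_abs = 1), 0.1)
  expect_equal(proprio_fb(0.5, 0.2, L = 0.96 * 0.3, Ldot = 0.05, L0 = 0.3,
                          Ldot0 = 0, v_max_abs = 1), -0.01, tolerance = 1e-12)
})

test_that("command composition clips to [0, 1] but keeps raw components", {
  expect_equal(compose_command(0.2, 0, 0)$u, 0.2)
  lo <- compose_command(0.1, -0.25, -0.05)
  expect_equal(lo$u, 0)
  expect_equal(lo$u_fb_prop, -0.25)
  hi <- compose_command(0.9, 0.3, 0.1)
  expect_equal(hi$u, 1)
})

test_that("delay line reads the sample stored tau earlier, with startup hold", {
  dl <- delay_line(dt = 0.001, n_steps = 200)
  for (t_ms in 0:100) dl <- delay_push(dl, t_ms)
  expect_equal(delay_read(dl, 0), 100)
  expect_equal(delay_read(dl, 0.040), 60)

  dl2 <- delay_line(dt = 0.001, n_steps = 200)
  for (t_ms in 0:20) dl2 <- delay_push(dl2, t_ms * 10)
  expect_equal(delay_read(dl2, 0.040), 0)          # before t = 0: first record
  expect_error(delay_read(delay_line(0.001, 10), 0), "empty")
})

test_that("disabling the vestibular gains reproduces the proprioception-only controller exactly", {
  ol <- one_link_plant()
  params <- controller_params(ol, u_ff = 0, k_p = 2, k_d = 2, k_ves = 0)
  expect_identical(unname(params$K_ves), rep(0, 18L))
  tr_a <- run_trial(ol, params, nodelay_config())

  # same plant without any head segment: identical trajectories bit for bit
  spec <- make_fixture("one_link")
  spec$head <- NULL
  ol_nohead <- build_plant(spec)
  tr_b <- run_trial(ol_nohead, controller_params(ol_nohead, u_ff = 0, k_p = 2,
                                                 k_d = 2, k_ves = 0),
                    nodelay_config())
  expect_identical(tr_a$q, tr_b$q)
  expect_identical(tr_a$a, tr_b$a)
  expect_true(all(tr_a$u_fb_ves == 0))
})

test_that("muscles in a group share feedback gains while tone may differ per muscle", {
  fl <- four_link_plant()
  params <- controller_params(fl, u_ff = seq(0.01, 0.08, by = 0.01),
                              k_p = 2, k_d = 1, k_ves = 1e-3)
  # per-muscle gains derive only from the group coefficient rows
  expect_equal(unname(params$K_p), unname(fl$gain_coeffs[, "c_p"] * 2))
  expect_equal(unname(params$K_d), unname(fl$gain_coeffs[, "c_d"] * 1))
  # tone kept per muscle
  expect_equal(params$u_ff, seq(0.01, 0.08, by = 0.01))
})
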