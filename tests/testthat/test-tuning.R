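test_that("tone and target averaging match closed-form integrals", {
  tt <- seq(0, 5, by = 0.001)
  # constant activation
  tr <- synthetic_trial(tt, a = rep(0.3, length(tt)))
  expect_equal(unname(compute_tone(tr)), 0.3)
  # linear ramp a(t) = t/5000 (t in ms): mean over [3000, 5000] ms is 0.8
  tr2 <- synthetic_trial(tt, a = tt / 5)
  expect_equal(unname(compute_tone(tr2)), 0.8, tolerance = 1e-9)
  # sinusoid over whole periods rides on its mean
  tr3 <- synthetic_trial(tt, a = 0.2 + 0.1 * sin(2 * pi * tt))
  expect_equal(unname(compute_tone(tr3)), 0.2, tolerance = 1e-9)

  # joint angles: same integral contract
  tr4 <- synthetic_trial(tt, q = 0.05 * tt / 5)
  expect_equal(unname(update_targets(tr4)), 0.04, tolerance = 1e-9)
  tr5 <- synthetic_trial(tt, q = rep(0.123, length(tt)))
  expect_equal(unname(update_targets(tr5)), 0.123)

  # arbitrary trace against an independent quadrature oracle
  set.seed(7)
  y <- cumsum(stats::rnorm(length(tt))) * 1e-4
  tr6 <- synthetic_trial(tt, q = y)
  sel <- tt >= 3 & tt <= 5
  oracle <- sum(diff(tt[sel]) * (y[sel][-1] + y[sel][-sum(sel)]) / 2) / 2
  expect_equal(unname(update_targets(tr6)), oracle, tolerance = 1e-9)

  fell <- synthetic_trial(tt[1:100], fell = TRUE, T_fail = 99)
  expect_error(compute_tone(fell), "fell")
  expect_error(update_targets(fell), "fell")
})

test_that("candidate generation records exactly the standing knob combinations", {
  ol <- one_link_plant()
  grid <- tone_knob_grid(c(0.5, 2, 3), 2, 0)   # 0.5 is too weak to stand
  cands <- generate_candidates(ol, grid, sim_config())
  # oracle: independently re-run each combination
  stood <- vapply(seq_len(nrow(grid)), function(i) {
    p <- controller_params(ol, u_ff = 0, k_p = grid$k_p[i], k_d = grid$k_d[i],
                           k_ves = grid$k_ves[i])
    !run_trial(ol, p, nodelay_config())$fell
  }, TRUE)
  expect_equal(length(cands), sum(stood))
  expect_true(all(vapply(cands, `[[`, TRUE, "stood")))
  # norms are recomputable from the tone vectors
  for (cd in cands) expect_equal(cd$norm, uff_norm(cd$u_ff))

  # deterministic: repeating the sweep gives identical candidates
  cands2 <- generate_candidates(ol, grid, sim_config())
  expect_equal(cands, cands2)

  expect_error(generate_candidates(ol, grid[0, ], sim_config()), "empty")
})

test_that("tone selection picks the closest norm with tie and rejection rules", {
  cands <- structure(lapply(c(1.50, 1.93, 2.48), function(n)
    list(u_ff = n, norm = n)), class = "tone_candidates")
  sel <- select_tones(cands, targets = 2.0)
  expect_equal(sel$norm, 1.93)

  tie <- structure(lapply(c(1.9, 2.1), function(n) list(norm = n)),
                   class = "tone_candidates")
  expect_equal(select_tones(tie, targets = 2.0)$norm, 1.9)

  # rejection of the first pick returns the next closest
  sel2 <- select_tones(cands, targets = 2.0, rejected = 2L)
  expect_equal(sel2$norm, 2.48)

  expect_warning(empty <- select_tones(structure(list(),
                                                 class = "tone_candidates"),
                                       targets = c(1.5, 2)),
                 "no tone candidates")
  expect_true(all(is.na(empty$index)))
})

test_that("the objective weighs falls and posture deviation as specified", {
  tt <- seq(0, 5, by = 0.001)
  still <- synthetic_trial(tt, q = rep(0.1, length(tt)))
  o <- objective_J(still)
  expect_equal(o$J, 0)
  expect_equal(o$J_fail, 0)

  # fall at 2000 ms with |theta - theta0| = 0.1 rad held: J_pos = 0.2 rad s
  t2 <- seq(0, 2, by = 0.001)
  fallen <- synthetic_trial(t2, q = c(0, rep(0.1, length(t2) - 1)),
                            fell = TRUE, T_fail = 2000)
  o2 <- objective_J(fallen)
  expect_equal(o2$J_fail, 1.5)
  expect_equal(o2$J_pos, 0.2, tolerance = 1e-3)
  expect_equal(o2$J, 10000 * 1.5 + o2$J_pos)

  # constant 0.01 rad deviation for 5 s, no fall
  dev <- synthetic_trial(tt, q = c(0, rep(0.01, length(tt) - 1)))
  expect_equal(objective_J(dev)$J_pos, 0.05, tolerance = 1e-4)

  # J below the fall weight implies the trial stood
  expect_lt(objective_J(still)$J, 10000)
  expect_gt(objective_J(fallen)$J, 10000)

  degenerate <- synthetic_trial(0, fell = TRUE, T_fail = 0)
  expect_gte(objective_J(degenerate)$J, 1e7)
})

test_that("CMA-ES solves the sphere and is seed-deterministic", {
  res <- cmaes_minimize(function(x) sum(x^2), x0 = rep(0.5, 8), sigma0 = 0.3,
                        lower = -1, upper = 1, max_iter = 200, seed = 2,
                        trace = TRUE)
  expect_lt(sqrt(sum(res$par^2)), 1e-3)
  res2 <- cmaes_minimize(function(x) sum(x^2), x0 = rep(0.5, 8), sigma0 = 0.3,
                         lower = -1, upper = 1, max_iter = 200, seed = 2,
                         trace = TRUE)
  expect_identical(res$incumbents, res2$incumbents)
  expect_identical(res$par, res2$par)
  # incumbent sequence is monotone non-increasing
  expect_true(all(diff(res$incumbents) <= 0))
})

test_that("replaying a candidate tone under its generating gains is a fixed point", {
  ol <- one_link_plant()
  cand <- cached_candidate()
  params <- controller_params(ol, u_ff = cand$u_ff,
                              k_p = cand$knobs[["k_p"]],
                              k_d = cand$knobs[["k_d"]],
                              k_ves = cand$knobs[["k_ves"]],
                              q_target = cand$q_target)
  tr <- run_trial(ol, params, nodelay_config())
  expect_false(tr$fell)
  replay_tone <- compute_tone(tr)
  active <- cand$u_ff > 1e-4
  expect_true(all(abs(replay_tone[active] - cand$u_ff[active]) /
                    cand$u_ff[active] < 0.10))
})
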