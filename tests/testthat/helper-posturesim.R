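# shared fixtures, memoized so expensive objects are built once per run
.ps_cache <- new.env(parent = emptyenv())

one_link_plant <- function() {
  if (is.null(.ps_cache$ol)) .ps_cache$ol <- build_plant(make_fixture("one_link"))
  .ps_cache$ol
}

four_link_plant <- function() {
  if (is.null(.ps_cache$fl)) .ps_cache$fl <- build_plant(make_fixture("four_link"))
  .ps_cache$fl
}

nodelay_config <- function() sim_config(tau_fb = 0, tau_trans = 0, k_noise = 0)

# one standing tone candidate on the one-link plant (delay-free sweep)
cached_candidate <- function() {
  if (is.null(.ps_cache$cand)) {
    cands <- generate_candidates(one_link_plant(),
                                 tone_knob_grid(c(2, 2.5, 3), c(1, 2), 1e-3),
                                 sim_config())
    .ps_cache$cand <- cands[[1L]]
  }
  .ps_cache$cand
}

# analytic torque-balance tone for the one-link fixture at its reference
# posture: extensor activation a with a * f_max * r = -m g l_com sin(q0)
balance_tone_one_link <- function(plant = one_link_plant()) {
  q0 <- plant$q_ref
  tau_grav <- -plant$gravity * plant$b[1L] * sin(q0)   # torque muscles must add
  a_ext <- tau_grav / (plant$f_max[1L] * plant$R[1L, 1L])
  c(a_ext, 0)
}

# minimal hand-built trial object for quadrature-based operations
synthetic_trial <- function(time, a = NULL, q = NULL, fell = FALSE,
                            T_simu = 5000, T_fail = NULL) {
  n <- length(time)
  if (is.null(a)) a <- matrix(0, n, 1L)
  if (is.null(q)) q <- matrix(0, n, 1L)
  if (!is.matrix(a)) a <- matrix(a, n)
  if (!is.matrix(q)) q <- matrix(q, n)
  structure(list(time = time, a = a, q = q, fell = fell,
                 T_simu = T_simu,
                 T_fail = if (is.null(T_fail)) T_simu else T_fail,
                 config = sim_config()),
            class = "posture_trial")
}

# tiny single-joint plant with bespoke muscle parameters for geometry tests
toy_plant <- function(r = 0.05, l_opt = 0.3) {
  build_plant(list(
    name = "toy",
    segments = list(list(name = "rod", joint = "j1", mass = 10, length = 1,
                         com_offset = 0.5, inertia = 0.8)),
    muscles = list(
      list(name = "ext", role = "extensor", f_max = 1000, l_opt = l_opt,
           v_max = 10, moment_arms = c(j1 = r), gain_coeffs = c(0.5, 0.2)),
      list(name = "flex", role = "flexor", f_max = 1000, l_opt = l_opt,
           v_max = 10, moment_arms = c(j1 = -r), gain_coeffs = c(0.5, 0.2))),
    posture = 0
  ))
}
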