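#' Built-in plant fixtures
#'
#' Self-contained sagittal plants with anthropometry summing to 70 kg and a
#' stature analogue of about 1.7 m:
#'
#' * `one_link`: an ankle inverted pendulum, 70 kg point mass 1 m above the
#'   ankle, actuated by one lumped whole-body extensor and one flexor group.
#'   The single segment carries the vestibular sensor at the mass point.
#' * `four_link`: shank, thigh, trunk and head-neck segments with 8
#'   antagonist muscle groups (ankle/knee/hip/neck extensor and flexor) using
#'   the functional-group gain coefficients of [gain_coefficients()].
#'
#' Muscle parameters (maximal isometric force, optimal length, moment arm)
#' are lumped bilateral values chosen at fixture design so that the standard
#' proprioceptive gain box (`k_p`, `k_d` in \[1, 3\]) stabilizes the chain;
#' individual values are therefore larger than single-muscle physiology.
#' The default posture leans slightly anterior (negative ankle angle in the
#' extension-positive convention), placing the COM a few centimetres ahead
#' of the ankle, inside the base of support `[-0.06, 0.18]` m.
#'
#' @param kind `"one_link"` or `"four_link"`
#' @param path optional file path; when given, the spec is also written as
#'   YAML (readable back with [read_plant_spec()])
#' @return the plant specification list (pass to [build_plant()])
#' @export
make_fixture <- function(kind = c("one_link", "four_link"), path = NULL) {
  kind <- match.arg(kind)
  gc <- gain_coefficients()
  cc <- function(group) {
    row <- gc[gc$group == group, ]
    c(row$c_p, row$c_d)
  }
  spec <- if (kind == "one_link") {
    list(
      name = "one_link",
      segments = list(
        list(name = "body", joint = "ankle", mass = 70, length = 1.0,
             com_offset = 1.0, inertia = 0)
      ),
      muscles = list(
        list(name = "extensor", role = "extensor", f_max = 20000,
             l_opt = 0.15, v_max = 5, moment_arms = c(ankle = 0.10),
             gain_coeffs = cc("Lumbar extensor")),
        list(name = "flexor", role = "flexor", f_max = 10000,
             l_opt = 0.15, v_max = 5, moment_arms = c(ankle = -0.10),
             gain_coeffs = cc("Lumbar flexor"))
      ),
      bos = c(-0.06, 0.18),
      head = list(segment = "body", sensor_offset = 1.0),
      posture = -0.04,
      full_anthropometry = FALSE
    )
  } else {
    list(
      name = "four_link",
      segments = list(
        list(name = "shank", joint = "ankle", mass = 7, length = 0.44,
             com_offset = 0.20, inertia = 0.11),
        list(name = "thigh", joint = "knee", mass = 14, length = 0.45,
             com_offset = 0.20, inertia = 0.24),
        list(name = "trunk", joint = "hip", mass = 43, length = 0.50,
             com_offset = 0.25, inertia = 0.90),
        list(name = "head", joint = "neck", mass = 6, length = 0.25,
             com_offset = 0.12, inertia = 0.03)
      ),
      muscles = list(
        list(name = "ankle_ext", role = "extensor", f_max = 25000,
             l_opt = 0.08, v_max = 5, moment_arms = c(ankle = 0.10),
             gain_coeffs = cc("Ankle extensor")),
        list(name = "ankle_flex", role = "flexor", f_max = 12000,
             l_opt = 0.08, v_max = 5, moment_arms = c(ankle = -0.10),
             gain_coeffs = cc("Ankle flexor")),
        list(name = "knee_ext", role = "extensor", f_max = 15000,
             l_opt = 0.06, v_max = 5, moment_arms = c(knee = 0.06),
             gain_coeffs = cc("Knee extensor")),
        list(name = "knee_flex", role = "flexor", f_max = 8000,
             l_opt = 0.06, v_max = 5, moment_arms = c(knee = -0.06),
             gain_coeffs = cc("Knee flexor")),
        list(name = "hip_ext", role = "extensor", f_max = 8000,
             l_opt = 0.08, v_max = 5, moment_arms = c(hip = 0.08),
             gain_coeffs = cc("Hip extensor")),
        list(name = "hip_flex", role = "flexor", f_max = 5000,
             l_opt = 0.08, v_max = 5, moment_arms = c(hip = -0.08),
             gain_coeffs = cc("Hip flexor")),
        list(name = "neck_ext", role = "extensor", f_max = 3000,
             l_opt = 0.05, v_max = 5, moment_arms = c(neck = 0.03),
             gain_coeffs = cc("Neck extensor")),
        list(name = "neck_flex", role = "flexor", f_max = 1500,
             l_opt = 0.05, v_max = 5, moment_arms = c(neck = -0.03),
             gain_coeffs = cc("Neck flexor"))
      ),
      bos = c(-0.06, 0.18),
      head = list(segment = "head", sensor_offset = 0.12),
      posture = c(-0.04, 0.01, 0.01, 0.01),
      full_anthropometry = FALSE
    )
  }
  if (!is.null(path)) write_plant_spec(spec, path)
  invisible(spec)
}

#' Write a plant specification as YAML
#'
#' @param spec a plant spec list (see [build_plant()])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_plant_spec <- function(spec, path) {
  spec$muscles <- lapply(spec$muscles, function(m) {
    m$moment_arms <- as.list(m$moment_arms)
    m
  })
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Read a plant specification from YAML
#'
#' Moment arms given as named lists are converted back to named vectors;
#' the result is validated through [build_plant()] on use.
#'
#' @param path YAML file written by [write_plant_spec()] or hand-authored
#'   with the same schema (SI units: kg, m, N; `v_max` in optimal lengths/s)
#' @return a plant spec list
#' @export
read_plant_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  spec$muscles <- lapply(spec$muscles, function(m) {
    m$moment_arms <- unlist(m$moment_arms)
    m$gain_coeffs <- as.numeric(unlist(m$gain_coeffs))
    m
  })
  spec$posture <- as.numeric(unlist(spec$posture))
  spec$bos <- as.numeric(unlist(spec$bos))
  spec
}
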