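# Shared fixtures, built in code at test time.

the_model <- default_spine_model()
the_ligaments <- default_ligament_table(the_model)

# A random proper rigid transform with rotations up to pi and translations
# of the given scale.
random_pose <- function(t_scale = 50) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  rigid_pose(ucspine:::rot_axis(ax, stats::runif(1, -pi, pi)),
             stats::rnorm(3, sd = t_scale))
}

# A random well-conditioned triangle (rows = vertices).
random_triangle <- function(scale = 30, min_area = 5) {
  repeat {
    tri <- matrix(stats::rnorm(9, sd = scale), 3, 3)
    if (ucspine:::triangle_area(tri) > min_area) return(tri)
  }
}

# Short noise-free scenario for fast pipeline tests.
quick_scenario <- function(condition = "physiological", ...) {
  scenario_config(condition, noise_sigma_mm = 0, duration_s = 0.4,
                  seed = 11L, ...)
}
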