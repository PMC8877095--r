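# shared fixtures: parametric bowls spanning the size range of common
# household bowls (diameters ~100-156 mm, depths 42-65 mm, capacities
# ~210-850 mL), and a few small constructors used across test files

test_bowl_grid <- function() {
  list(
    parametric_bowl("spherical_cap", rb = 30, rr = 52, depth = 42),
    parametric_bowl("spherical_cap", rb = 40, rr = 68, depth = 52),
    parametric_bowl("spherical_cap", rb = 42, rr = 76, depth = 60),
    parametric_bowl("power_wall",    rb = 32, rr = 50, depth = 45, p = 2),
    parametric_bowl("power_wall",    rb = 40, rr = 65, depth = 55, p = 2),
    parametric_bowl("power_wall",    rb = 48, rr = 75, depth = 65, p = 2),
    parametric_bowl("cone_frustum",  rb = 35, rr = 55, depth = 45),
    parametric_bowl("cone_frustum",  rb = 42, rr = 68, depth = 55),
    parametric_bowl("cone_frustum",  rb = 50, rr = 78, depth = 65))
}

# one mid-size bowl per family
test_bowl_trio <- function() test_bowl_grid()[c(2, 5, 8)]

# annotation of a flat plate (all markers on the bottom) at depth h
flat_plate_annotation <- function(h = 400, half_width = 40, C = 12.7, D = 19,
                                  k = default_intrinsics()) {
  u <- seq(-half_width, half_width, by = C)
  n <- length(u)
  up <- plane_to_pixel(project_points(cbind(u, -D / 2, h), k), k)
  lo <- plane_to_pixel(project_points(cbind(u, +D / 2, h), k), k)
  ruler_annotation(up, lo, marker_spacing = C, ruler_width = D,
                   flat_bottom = seq_len(n),
                   image_width = k$image_width, image_height = k$image_height)
}

# exact points on an ellipse, used by the ellipse/pose tests
exact_ellipse_points <- function(center, a, b, angle = 0, n = 8L) {
  ellipse_points(ellipse_params(center, a, b, angle), n)
}

expect_rel_error <- function(actual, calculated, tol_pct) {
  expect_lt(abs(relative_error(actual, calculated)), tol_pct)
}
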