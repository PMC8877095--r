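# identity-pitch camera: pixel coordinates equal image-plane mm
k_id <- camera_intrinsics(f = 3, sx = 1, sy = 1,
                          image_width = 100, image_height = 100)

# ruler annotation with both borders on horizontal lines y' = -w/2, +w/2
parallel_annotation <- function(x = seq(-30, 30, by = 10), w = 2,
                                beta = NULL, C = 10, D = 19) {
  n <- length(x)
  ruler_annotation(cbind(x, -w / 2), cbind(x, w / 2),
                   marker_spacing = C, ruler_width = D,
                   flat_bottom = beta %||% seq_len(n),
                   image_width = 100, image_height = 100)
}

test_that("fit_borders fits horizontal borders exactly and flags bad input", {
  a <- parallel_annotation()
  fit <- fit_borders(a, k_id)
  xs <- seq(-25, 25, by = 5)
  expect_equal(predict_border(fit, xs, "up"), rep(-1, length(xs)), tolerance = 1e-9)
  expect_equal(predict_border(fit, xs, "low"), rep(1, length(xs)), tolerance = 1e-9)
  expect_equal(predict_border(fit, xs, "mid"), rep(0, length(xs)), tolerance = 1e-9)

  dup <- parallel_annotation(x = c(-30, -10, -10, 10, 30, 40, 50))
  expect_error(fit_borders(dup, k_id), "duplicate")

  vert <- ruler_annotation(cbind(c(-1, 0, 0.5, 1), c(-30, -10, 10, 30)),
                           cbind(c(1, 2, 2.5, 3), c(-30, -10, 10, 30)),
                           10, 19, 1:4, 100, 100)
  expect_error(suppressWarnings(fit_borders(vert, k_id)), "vertical")

  small <- parallel_annotation(x = seq(-20, 20, by = 10))  # I = 5
  expect_warning(fit_borders(small, k_id), "degree reduced")
})

test_that("pair_and_measure yields widths, signed offsets and ordering", {
  a <- parallel_annotation()
  fan <- suppressWarnings(pair_and_measure(a, k_id))
  expect_s3_class(fan, "ray_fan")
  expect_equal(fan$W, rep(2, 7), tolerance = 1e-9)
  # V positive in the left half-plane, antisymmetric for symmetric input,
  # sorted decreasing (left to right)
  expect_equal(fan$V, rev(-fan$V))
  expect_true(all(diff(fan$V) < 0))
})

test_that("a simulated fronto-parallel flat plate has equal widths", {
  a <- flat_plate_annotation(h = 400)
  k <- default_intrinsics()
  fan <- pair_and_measure(a, k)
  expect_lt(diff(range(fan$W)), 1e-9)
  # width encodes the plate depth: f D / W = Z exactly for a fronto-parallel
  # plane, so r0 approximates the rays within the small-angle factor
  r0 <- initial_rays(fan, a$ruler_width, k)
  expect_equal(r0, rep(400, length(r0)), tolerance = 1e-9)
  depths <- r0 * cos(ray_angle(fan$V, k$f))
  expect_true(all(abs(depths - 400) < 2.5))
})

test_that("initial_rays implements r0 = f D / W", {
  fan <- structure(list(W = c(0.19, 0.38)), class = "ray_fan")
  expect_equal(initial_rays(fan, D = 19, camera_intrinsics(3, 1, 1)),
               c(300, 150))
  expect_error(initial_rays(structure(list(W = c(0.1, -0.1)), class = "ray_fan"),
                            19, k_id), "> 0")
})

test_that("inter_ray_angles follows the arctan difference formula", {
  fan <- structure(list(V = c(3, 0, -3)), class = "ray_fan")
  th <- inter_ray_angles(fan, k_id)   # f = 3
  expect_equal(th, c(pi / 4, pi / 4))
  # telescoping: sum of angles equals the end-to-end angle
  set.seed(5)
  V <- sort(runif(9, -2, 2), decreasing = TRUE)
  fan2 <- structure(list(V = V), class = "ray_fan")
  expect_equal(sum(inter_ray_angles(fan2, k_id)),
               atan(V[1] / 3) - atan(V[9] / 3))
  expect_error(inter_ray_angles(structure(list(V = c(1, 1, 0)), class = "ray_fan"),
                                k_id), "mis-sorted")
})

test_that("chord_objective matches the law of cosines", {
  expect_equal(chord_objective(c(1, 1), pi / 3, 1), 0)          # equilateral
  expect_equal(chord_objective(c(1, 1), pi / 2, 1), (sqrt(2) - 1)^2)
  # any configuration measured against its own chords gives J = 0
  set.seed(9)
  r <- runif(6, 200, 500); th <- runif(5, 0.01, 0.05)
  chats <- sqrt(r[-6]^2 + r[-1]^2 - 2 * r[-6] * r[-1] * cos(th))
  expect_equal(chord_objective(r, th, chats), 0, tolerance = 1e-18)
})

test_that("flat_bottom_residuals vanish iff bottom points share one depth", {
  a <- parallel_annotation(beta = 3:5)
  fan <- suppressWarnings(pair_and_measure(a, k_id))
  alpha <- ray_angle(fan$V, k_id$f)
  r_flat <- 400 / cos(alpha)          # every marker at depth 400
  expect_equal(flat_bottom_residuals(r_flat, fan, k_id), rep(0, 2),
               tolerance = 1e-9)
  # symmetric pair at equal rays
  fan2 <- structure(list(V = c(2, 1, -1, -2), beta = 2:3), class = "ray_fan")
  expect_equal(flat_bottom_residuals(c(1, 5, 5, 1), fan2, k_id), 0)
  # perturbing one flat ray touches exactly the adjacent residuals
  r2 <- r_flat; r2[4] <- r2[4] + 1
  res <- flat_bottom_residuals(r2, fan, k_id)
  expect_equal(sum(res != 0), 2)
  fan3 <- structure(list(V = c(1, -1), beta = 1L), class = "ray_fan")
  expect_warning(out <- flat_bottom_residuals(c(1, 1), fan3, k_id), "fewer than 2")
  expect_length(out, 0)
})

test_that("optimize_rays improves J, honours constraints and is a fixed point", {
  b <- test_bowl_trio()[[1]]
  sim <- simulate_ruler_annotation(b, simulation_config(noise_px = 0, seed = 1))
  k <- sim$config$intrinsics
  fan <- pair_and_measure(sim$annotation, k)
  fan_opt <- optimize_rays(fan, k, D = sim$annotation$ruler_width)
  d <- fan_opt$diagnostics
  expect_lte(d$J, d$J0)
  expect_lt(d$max_constraint_violation, 1e-9)
  # raw single-pass rays stay close to truth (model error only)
  expect_lt(max(abs(fan_opt$r - sim$r_true) / sim$r_true), 0.025)
  # restarting at the optimum leaves J unchanged
  fan_again <- optimize_rays(fan, k, r0 = fan_opt$r)
  expect_equal(fan_again$diagnostics$J, d$J, tolerance = 1e-6)
})

test_that("J never increases over noisy replicates", {
  b <- test_bowl_trio()[[2]]
  for (seed in 1:5) {
    sim <- simulate_ruler_annotation(b, simulation_config(noise_px = 0.5,
                                                          seed = seed))
    k <- sim$config$intrinsics
    fan <- optimize_rays(pair_and_measure(sim$annotation, k), k,
                         D = sim$annotation$ruler_width)
    expect_lte(fan$diagnostics$J, fan$diagnostics$J0)
  }
})

test_that("rays_to_cross_section maps rays into the ruler plane", {
  fan <- structure(list(V = c(3, 0, -3), r = c(sqrt(2) * 300, 300, sqrt(2) * 300),
                        beta = 2L, C = 10, theta = NULL),
                   class = "ray_fan")
  cs <- rays_to_cross_section(fan, k_id)
  expect_equal(cs$points[2, ], c(u = 0, w = 300))
  expect_equal(as.numeric(cs$points[1, "w"]), 300, tolerance = 1e-9)  # 45 deg ray
  # flat-bottom markers share w after constrained optimization
  b <- test_bowl_trio()[[3]]
  sim <- simulate_ruler_annotation(b, simulation_config(noise_px = 0, seed = 2))
  k <- sim$config$intrinsics
  fan2 <- optimize_rays(pair_and_measure(sim$annotation, k), k, D = 19)
  cs2 <- rays_to_cross_section(fan2, k)
  expect_lt(diff(range(cs2$points[cs2$beta, "w"])), 1e-9)
  # consecutive point spacing approximates the marker spacing
  d <- sqrt(diff(cs2$points[, 1])^2 + diff(cs2$points[, 2])^2)
  C <- sim$annotation$marker_spacing
  expect_lt(max(abs(d - C) / C), 0.15)
})

test_that("symmetrize is the identity on symmetric input and mirror-invariant", {
  # symmetric V-shape (cone cross-section); deepest point farthest below
  # the camera (largest w)
  u <- seq(-50, 50, by = 10)
  cs <- structure(list(points = cbind(u = u, w = 400 - 0.8 * abs(u)),
                       beta = 6L, C = 10), class = "cross_section")
  prof <- symmetrize_cross_section(cs)
  expect_equal(prof$depth, 40, tolerance = 1e-6)
  expect_equal(prof$rho[length(prof$rho)], 50, tolerance = 1e-3)

  # mirror invariance on an asymmetric curve
  set.seed(3)
  ua <- c(seq(-52, -20, by = 8), seq(-15, 15, by = 10), seq(22, 55, by = 8))
  wa <- 400 - pmax(abs(ua) - 18, 0)^1.3 / 6 + rnorm(length(ua), sd = 0.2)
  csa <- structure(list(points = cbind(u = ua, w = wa),
                        beta = which(abs(ua) <= 18), C = 10),
                   class = "cross_section")
  csm <- structure(list(points = cbind(u = rev(-ua), w = rev(wa)),
                        beta = rev(length(ua) + 1 - which(abs(ua) <= 18)), C = 10),
                   class = "cross_section")
  p1 <- symmetrize_cross_section(csa)
  p2 <- symmetrize_cross_section(csm)
  expect_equal(p1$rho, p2$rho, tolerance = 1e-9)
  expect_equal(p1$depth, p2$depth, tolerance = 1e-9)
})

test_that("revolve reproduces closed-form solids within 0.1%", {
  z <- seq(0, 100, length.out = 501)
  expect_rel_error(pi * 50^2 * 100 / 1000,
                   revolve_profile(half_profile(z, rep(50, 501)))$capacity, 0.1)
  zh <- seq(0, 60, length.out = 501)
  expect_rel_error(2 * pi * 60^3 / 3 / 1000,
                   revolve_profile(half_profile(zh, sqrt(60^2 - (60 - zh)^2)))$capacity,
                   0.1)
  zc <- seq(0, 90, length.out = 501)
  expect_rel_error(pi * 60^2 * 90 / 3 / 1000,
                   revolve_profile(half_profile(zc, zc * 60 / 90))$capacity, 0.1)
  expect_error(half_profile(zc, zc - 45), "negative")
})

test_that("level/volume table is consistent with capacity and monotone", {
  m <- bowl_model_of(test_bowl_trio()[[1]])
  tab <- m$level_volume_table
  expect_equal(tab$volume_ml[nrow(tab)], m$capacity)
  expect_true(all(diff(tab$volume_ml) > 0))
  expect_equal(m$diameter, 2 * m$rho[length(m$rho)])
})

test_that("reconstruction is scale-equivariant in D and C", {
  b <- test_bowl_trio()[[2]]
  sim <- simulate_ruler_annotation(b, simulation_config(noise_px = 0, seed = 1))
  k <- sim$config$intrinsics
  m1 <- reconstruct_bowl(sim$annotation, k)
  a2 <- sim$annotation
  a2$marker_spacing <- a2$marker_spacing * 2
  a2$ruler_width <- a2$ruler_width * 2
  m2 <- reconstruct_bowl(a2, k)
  expect_rel_error(2 * m1$diameter, m2$diameter, 0.1)
  expect_rel_error(2 * m1$depth, m2$depth, 0.1)
  expect_rel_error(8 * m1$capacity, m2$capacity, 0.3)
})

test_that("a degenerate all-flat annotation reconstructs a flat plate", {
  # half-width a multiple of the marker spacing so markers reach both edges
  a <- flat_plate_annotation(h = 400, half_width = 3 * 12.7)
  m <- reconstruct_bowl(a, default_intrinsics())
  expect_lt(m$depth, 0.5)
  expect_lt(m$capacity, 1)
  expect_equal(m$diameter / 2, 3 * 12.7, tolerance = 0.02)
})

test_that("noiseless end-to-end reconstruction recovers the trio bowls", {
  for (b in test_bowl_trio()) {
    sim <- simulate_ruler_annotation(b, simulation_config(noise_px = 0, seed = 1))
    m <- reconstruct_bowl(sim$annotation, sim$config$intrinsics)
    expect_rel_error(b$capacity, m$capacity, 2)
    expect_rel_error(2 * b$rr, m$diameter, 2)
    expect_rel_error(b$depth, m$depth, 2)
  }
})
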