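#' Parametric bowl families
#'
#' Idealized round bowls with a flat bottom of radius `rb`, rim radius `rr`
#' and depth `depth` (all mm), used as ground truth by the forward
#' simulator:
#' * `cylinder` — vertical wall, `rho(z) = rr`;
#' * `spherical_cap` — spherical wall through `(rb, 0)` and `(rr, depth)`
#'   with its centre on the axis (a flat-bottomed dome section);
#' * `power_wall` — `rho(z) = rb + (rr - rb) (z / depth)^p`;
#' * `cone_frustum` — `power_wall` with `p = 1`.
#'
#' Capacity is closed-form for every family.
#'
#' @param family one of `"cylinder"`, `"spherical_cap"`, `"power_wall"`,
#'   `"cone_frustum"`.
#' @param rb flat-bottom radius (mm), `0 <= rb <= rr`; forced to `rr` for
#'   the cylinder.
#' @param rr rim radius (mm).
#' @param depth interior depth (mm).
#' @param p wall exponent for `power_wall` (default 2).
#' @return object of class `parametric_bowl` with fields `rho(z)` (a
#'   function), `capacity` (mL) and the parameters.
#' @export
parametric_bowl <- function(family = c("spherical_cap", "cylinder",
                                       "power_wall", "cone_frustum"),
                            rb, rr, depth, p = 2) {
  family <- match.arg(family)
  check_positive(c(rr, depth), "rr/depth")
  if (family == "cylinder") rb <- rr
  check_finite(rb, "rb")
  if (rb < 0 || rb > rr) stop_bowl("need 0 <= rb <= rr")
  H <- depth
  if (family == "spherical_cap") {
    zc <- (rr^2 - rb^2 + H^2) / (2 * H)   # sphere centre height above bottom
    if (zc < H) {
      stop_bowl("spherical_cap parameters curl inward past the equator ",
                "(need rr^2 - rb^2 >= depth^2)")
    }
    rs2 <- rb^2 + zc^2
    rho <- function(z) sqrt(pmax(rs2 - (zc - z)^2, 0))
    cap <- pi * (rs2 * H - (zc^3 - (zc - H)^3) / 3) / 1000
  } else if (family == "cylinder") {
    rho <- function(z) rep(rr, length(z))
    cap <- pi * rr^2 * H / 1000
  } else {
    if (family == "cone_frustum") p <- 1
    check_positive(p, "p")
    dr <- rr - rb
    rho <- function(z) rb + dr * (z / H)^p
    cap <- pi * H * (rb^2 + 2 * rb * dr / (p + 1) + dr^2 / (2 * p + 1)) / 1000
  }
  structure(list(family = family, rb = rb, rr = rr, depth = H, p = p,
                 rho = rho, capacity = cap),
            class = "parametric_bowl")
}

#' @export
print.parametric_bowl <- function(x, ...) {
  cat(sprintf("parametric_bowl (%s): rb = %g, rr = %g, depth = %g mm, capacity = %.1f mL\n",
              x$family, x$rb, x$rr, x$depth, x$capacity))
  invisible(x)
}

#' Sample a parametric bowl's half-profile
#'
#' @param b a [parametric_bowl()].
#' @param n number of uniform height samples.
#' @return a [half_profile()].
#' @export
make_profile <- function(b, n = 501L) {
  stopifnot(inherits(b, "parametric_bowl"))
  z <- seq(0, b$depth, length.out = n)
  half_profile(z, b$rho(z))
}

#' Bowl model of a parametric bowl
#'
#' Convenience composition of [make_profile()] and [revolve_profile()].
#'
#' @inheritParams make_profile
#' @return a `bowl_model`.
#' @export
bowl_model_of <- function(b, n = 501L) revolve_profile(make_profile(b, n))

## dense polyline of the full cross-section in the ruler plane, left rim ->
## bottom -> right rim; returns u (signed horizontal mm), z (height mm) and
## the cumulative arc length s
cross_section_curve <- function(b, n_wall = 2000L, n_bottom = 400L) {
  zw <- seq(b$depth, 0, length.out = n_wall)   # left wall, rim -> bottom
  zr <- rev(zw)[-1]                            # right wall, bottom -> rim
  u <- c(-b$rho(zw), seq(-b$rb, b$rb, length.out = n_bottom)[-1], b$rho(zr))
  z <- c(zw, rep(0, n_bottom - 1L), zr)
  ## drop duplicated consecutive points (rb = 0 collapses the bottom span)
  keep <- c(TRUE, diff(u)^2 + diff(z)^2 > 1e-18)
  u <- u[keep]; z <- z[keep]
  s <- c(0, cumsum(sqrt(diff(u)^2 + diff(z)^2)))
  list(u = u, z = z, s = s, length = s[length(s)])
}

#' Simulation configuration
#'
#' The stated world for the forward simulator: a camera looking straight
#' down from `camera_height` mm above the centre of the bowl bottom, a
#' paper ruler of physical width `ruler_width` mm with markers every
#' `marker_spacing` mm of arc (half-inch ticks by default), and i.i.d.
#' Gaussian landmark noise of `noise_px` pixels per coordinate.
#'
#' @param intrinsics a [camera_intrinsics()]; default is a phone-like
#'   camera (f = 4 mm, 1.5 um pixels, 4000 x 3000).
#' @param camera_height optical centre height above the bowl's interior
#'   bottom (mm); must exceed the bowl depth.
#' @param ruler_width physical ruler width D (mm), default 19 (standard
#'   adhesive tape).
#' @param marker_spacing marker arc spacing C (mm), default 12.7 (0.5 in).
#' @param noise_px landmark noise standard deviation in pixels, default 0.5.
#' @param seed RNG seed used for the landmark noise.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(intrinsics = default_intrinsics(),
                              camera_height = 400, ruler_width = 19,
                              marker_spacing = 12.7, noise_px = 0.5,
                              seed = 1L) {
  check_positive(camera_height, "camera_height")
  check_positive(ruler_width, "ruler_width")
  check_positive(marker_spacing, "marker_spacing")
  if (noise_px < 0) stop_bowl("noise_px must be >= 0")
  structure(list(intrinsics = intrinsics, camera_height = camera_height,
                 ruler_width = ruler_width, marker_spacing = marker_spacing,
                 noise_px = noise_px, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_intrinsics <- function() {
  camera_intrinsics(f = 4, sx = 0.0015, sy = 0.0015,
                    image_width = 4000, image_height = 3000)
}

#' Simulate a ruler annotation of a parametric bowl
#'
#' Emulates the physical measurement: the ruler centreline follows the
#' bowl's central cross-section from rim to rim; markers are arc-length
#' samples every `marker_spacing` mm starting at one rim, plus the tape end
#' at the other rim (the end interval is shorter, recorded in the
#' per-interval spacing list).  Each marker's upper/lower border points sit
#' half a ruler width away from the centreline along the circumferential
#' surface direction, all points are projected by the pinhole model, and
#' centred Gaussian noise is added to the pixel coordinates.  Markers whose
#' centreline height is below 1e-6 mm form the flat-bottom set.
#'
#' @param b a [parametric_bowl()].
#' @param cfg a [simulation_config()]; `cfg$camera_height` must exceed the
#'   bowl depth.
#' @param include_tape_end keep the rim-end marker with its short interval
#'   (default TRUE; set FALSE for strictly uniform spacing).
#' @return list with `annotation` (a [ruler_annotation()]),
#'   `r_true` (true optical-centre-to-centreline distances, mm),
#'   `centerline` (u, z positions, mm), `profile` (the true
#'   [half_profile()]), `arc_length` (mm) and `config`.
#' @export
simulate_ruler_annotation <- function(b, cfg = simulation_config(),
                                      include_tape_end = TRUE) {
  stopifnot(inherits(b, "parametric_bowl"), inherits(cfg, "simulation_config"))
  if (cfg$camera_height <= b$depth) {
    stop_bowl("camera_height must exceed the bowl depth")
  }
  cc <- cross_section_curve(b)
  C <- cfg$marker_spacing
  if (C >= cc$length) stop_bowl("marker spacing exceeds the ruler arc length")
  s_mark <- seq(0, cc$length, by = C)
  spacing <- rep(C, length(s_mark) - 1L)
  residual <- cc$length - s_mark[length(s_mark)]
  if (include_tape_end && residual > 1e-9) {
    s_mark <- c(s_mark, cc$length)
    spacing <- c(spacing, residual)
  }
  u <- stats::approx(cc$s, cc$u, xout = s_mark, ties = "ordered")$y
  z <- stats::approx(cc$s, cc$z, xout = s_mark, ties = "ordered")$y
  h <- cfg$camera_height
  D <- cfg$ruler_width
  flat <- abs(z) < 1e-6

  border_point <- function(i, side) {  # side +1 = lower (y > 0), -1 = upper
    if (flat[i]) {
      c(u[i], side * D / 2, h)
    } else {
      rho <- abs(u[i])
      phi <- D / (2 * rho)              # arc of the tape on the level circle
      c(sign(u[i]) * rho * cos(phi), side * rho * sin(phi), h - z[i])
    }
  }
  I <- length(s_mark)
  upper3 <- t(vapply(seq_len(I), border_point, numeric(3), side = -1))
  lower3 <- t(vapply(seq_len(I), border_point, numeric(3), side = +1))
  k <- cfg$intrinsics
  up_px <- plane_to_pixel(project_points(upper3, k), k)
  lo_px <- plane_to_pixel(project_points(lower3, k), k)
  if (cfg$noise_px > 0) {
    set.seed(cfg$seed)
    up_px <- up_px + matrix(stats::rnorm(2L * I, sd = cfg$noise_px), I, 2L)
    lo_px <- lo_px + matrix(stats::rnorm(2L * I, sd = cfg$noise_px), I, 2L)
  }
  flat_idx <- which(flat)
  if (length(flat_idx) == 0L) {
    ## always annotate at least the marker nearest the bottom
    flat_idx <- which.min(z)
  }
  ann <- ruler_annotation(
    upper_border = up_px, lower_border = lo_px,
    marker_spacing = spacing, ruler_width = D, flat_bottom = flat_idx,
    image_width = k$image_width, image_height = k$image_height)
  list(annotation = ann,
       r_true = sqrt(u^2 + (h - z)^2),
       centerline = cbind(u = u, z = z),
       profile = make_profile(b),
       arc_length = cc$length,
       config = cfg)
}

#' Simulate a flat liquid fill of a posed bowl
#'
#' Computes the fill height for the requested volume, poses the rim and the
#' liquid-surface circles, and projects both to image ellipses.  Emits
#' sample points on the surface ellipse (for level matching) and the exact
#' projected areas (for FAR work).
#'
#' @param b a [parametric_bowl()] or `bowl_model`.
#' @param pose the rim [bowl_pose()].
#' @param k a [camera_intrinsics()].
#' @param volume fill volume (mL), `0 < volume <= capacity`.
#' @param n_points number of surface sample points (>= 8).
#' @param noise_px optional Gaussian pixel noise on the sample points.
#' @param seed RNG seed for the noise.
#' @return list with `rim` and `surface` [ellipse_params()],
#'   `surface_points` (n x 2 image-plane mm), `rim_area`, `surface_area`
#'   (mm^2), `area_ratio` and the true `fill_height` (mm).
#' @export
simulate_fill <- function(b, pose, k, volume, n_points = 12L,
                          noise_px = 0, seed = NULL) {
  model <- if (inherits(b, "parametric_bowl")) bowl_model_of(b) else b
  stopifnot(inherits(model, "bowl_model"))
  if (volume <= 0 || volume > model$capacity * (1 + 1e-9)) {
    stop_bowl("volume must be in (0, capacity]")
  }
  if (n_points < 8L) stop_bowl("need at least 8 surface sample points")
  z <- fill_height(model, volume)
  rim_c <- level_circle(model, pose, model$depth)
  srf_c <- level_circle(model, pose, z)
  rim <- project_circle(rim_c$center, pose$normal, rim_c$radius, k)
  surface <- project_circle(srf_c$center, pose$normal,
                            max(srf_c$radius, 1e-9), k)
  pts <- ellipse_points(surface, n_points)
  if (noise_px > 0) {
    if (!is.null(seed)) set.seed(seed)
    pts <- pts + matrix(stats::rnorm(2L * n_points, sd = noise_px), n_points, 2L) *
      rep(c(k$sx, k$sy), each = n_points)
  }
  list(rim = rim, surface = surface, surface_points = pts,
       rim_area = ellipse_area(rim), surface_area = ellipse_area(surface),
       area_ratio = ellipse_area(surface) / ellipse_area(rim),
       fill_height = z)
}

#' Canonical top-down pose of a bowl
#'
#' Pose of a bowl standing upright with its rim centre at depth `Z` under
#' the camera, optionally tilted.
#'
#' @param Z rim-centre depth (mm).
#' @param tilt tilt of the bowl axis away from the optical axis (rad).
#' @param azimuth direction of the tilt (rad).
#' @param offset optional XY offset of the rim centre (mm).
#' @return a [bowl_pose()].
#' @export
top_down_pose <- function(Z, tilt = 0, azimuth = 0, offset = c(0, 0)) {
  n <- c(sin(tilt) * cos(azimuth), sin(tilt) * sin(azimuth), -cos(tilt))
  bowl_pose(center = c(offset[1], offset[2], Z), normal = n)
}
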