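#' Fit polynomial border curves and the ruler midline
#'
#' Converts the landmark pairs to image-plane millimetres and least-squares
#' fits one polynomial per border, `y' = p(x')`, of degree `min(5, I - 2)`
#' (degree 5 when enough markers are available, as the border curves of a
#' centrally taped ruler are smooth and low-order; reduced with a warning
#' for very short rulers).  The midline is the average of the two fits.
#'
#' @param a a [ruler_annotation()].
#' @param k a [camera_intrinsics()].
#' @return an object of class `border_fit` with coefficient vectors
#'   `up`, `low` (increasing powers), the fitted degree, and predictors
#'   accessible through [predict_border()].
#' @export
fit_borders <- function(a, k) {
  stopifnot(inherits(a, "ruler_annotation"), inherits(k, "camera_intrinsics"))
  up <- pixel_to_plane(a$upper_border, k)
  lo <- pixel_to_plane(a$lower_border, k)
  I <- nrow(up)
  degree <- min(5L, I - 2L)
  if (degree < 5L) {
    warning("only ", I, " landmark pairs: border polynomial degree reduced to ", degree)
  }
  fit_one <- function(p, which) {
    x <- p[, 1]
    if (anyDuplicated(signif(x, 12))) {
      stop_bowl("duplicate x abscissae in ", which, " border landmarks")
    }
    if (diff(range(x)) < diff(range(p[, 2]))) {
      stop_bowl("ruler image is nearly vertical; re-orient the camera so the ",
                "ruler runs parallel to the bottom edge of the image")
    }
    X <- outer(x, 0:degree, `^`)
    qr_X <- qr(X)
    if (qr_X$rank < degree + 1L) {
      stop_bowl("rank-deficient border fit; landmarks may be degenerate")
    }
    qr.coef(qr_X, p[, 2])
  }
  structure(
    list(up = fit_one(up, "upper"), low = fit_one(lo, "lower"),
         degree = degree,
         upper_plane = up, lower_plane = lo),
    class = "border_fit")
}

#' Evaluate a fitted border polynomial
#'
#' @param fit a `border_fit` from [fit_borders()].
#' @param x image-plane abscissae (mm).
#' @param which one of `"up"`, `"low"`, `"mid"`.
#' @return fitted ordinates `y'` (mm).
#' @export
predict_border <- function(fit, x, which = c("mid", "up", "low")) {
  which <- match.arg(which)
  ev <- function(co) drop(outer(x, seq_along(co) - 1L, `^`) %*% co)
  switch(which,
         up = ev(fit$up),
         low = ev(fit$low),
         mid = (ev(fit$up) + ev(fit$low)) / 2)
}

#' Measure observed ruler widths and landmark offsets
#'
#' For each landmark pair the bar abscissa is the mean of the pair's
#' image-plane x'; the observed ruler width `W[i]` is the vertical chord
#' between the two fitted border curves at that abscissa (valid because the
#' ruler is imaged parallel to the bottom edge of the frame), and `V[i]` is
#' the signed offset of the bar midpoint from the image-plane centre,
#' positive in the left half-plane.  Landmarks are ordered left to right
#' (`V` decreasing); an annotation supplied right to left is reversed,
#' together with its flat-bottom indices and spacing intervals.
#'
#' @param a a [ruler_annotation()].
#' @param k a [camera_intrinsics()].
#' @param borders a `border_fit` from [fit_borders()]; computed when `NULL`.
#' @return an object of class `ray_fan` holding `V`, `W` (mm), the
#'   per-interval spacings `C`, the flat-bottom index set and later the
#'   inter-ray angles and optimized ray lengths.
#' @export
pair_and_measure <- function(a, k, borders = NULL) {
  borders <- borders %||% fit_borders(a, k)
  up <- pixel_to_plane(a$upper_border, k)
  lo <- pixel_to_plane(a$lower_border, k)
  xbar <- (up[, 1] + lo[, 1]) / 2
  W <- predict_border(borders, xbar, "low") - predict_border(borders, xbar, "up")
  if (any(W <= 0)) {
    stop_bowl("fitted border curves cross (non-positive width W)")
  }
  V <- -xbar  # positive in the left half image plane
  C <- spacing_intervals(a)
  beta <- a$flat_bottom
  if (all(diff(V) > 0)) {        # annotation ran right to left: flip
    I <- length(V)
    V <- rev(V); W <- rev(W); C <- rev(C)
    beta <- sort(I + 1L - beta)
  }
  if (any(diff(V) >= 0)) {
    stop_bowl("landmark offsets V are not strictly monotone along the ruler; ",
              "markers appear mis-ordered")
  }
  structure(list(V = V, W = W, C = C, beta = beta,
                 theta = NULL, r = NULL, f = k$f),
            class = "ray_fan")
}

#' Initial ray lengths from the observed ruler width
#'
#' The pinhole similar-triangle estimate `r0[i] = f * D / W[i]`, taking the
#' physical distance spanned by a landmark pair as the known ruler width
#' `D` (the local surface curvature across the narrow tape is small, so the
#' curve length, which equals the ruler width, approximates the chord
#' closely).  Used as the optimizer's starting point.
#'
#' @param fan a `ray_fan` from [pair_and_measure()].
#' @param D physical ruler width in mm.
#' @param k a [camera_intrinsics()].
#' @return numeric vector of initial ray lengths (mm).
#' @export
initial_rays <- function(fan, D, k) {
  check_positive(D, "D")
  check_positive(fan$W, "W")
  k$f * D / fan$W
}

#' Inter-ray angles from landmark offsets
#'
#' `theta[i] = atan(V[i] / f) - atan(V[i+1] / f)` for consecutive
#' landmarks; all positive for a left-to-right ordered fan.
#'
#' @inheritParams initial_rays
#' @return numeric vector of `I - 1` angles (rad).
#' @export
inter_ray_angles <- function(fan, k) {
  if (any(diff(fan$V) >= 0)) {
    stop_bowl("V must be strictly decreasing (landmarks mis-sorted)")
  }
  alpha <- ray_angle(fan$V, k$f)
  alpha[-length(alpha)] - alpha[-1]
}

#' Law-of-cosines chord objective
#'
#' For candidate ray lengths `r`, the estimated chord between consecutive
#' landmark centre points is `Chat[i] = sqrt(r[i]^2 + r[i+1]^2 -
#' 2 r[i] r[i+1] cos(theta[i]))`; the objective is the sum of squared
#' deviations of these chords from the known marker spacings.
#'
#' @param r ray lengths (mm).
#' @param theta inter-ray angles (rad), length `length(r) - 1`.
#' @param C marker spacings (mm), scalar or length `length(r) - 1`.
#' @return non-negative scalar.
#' @export
chord_objective <- function(r, theta, C) {
  n <- length(r)
  stopifnot(length(theta) == n - 1L, length(C) %in% c(1L, n - 1L))
  r1 <- r[-n]; r2 <- r[-1]
  chat <- sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(theta))
  sum((chat - C)^2)
}

## gradient of chord_objective with respect to r
chord_objective_grad <- function(r, theta, C) {
  n <- length(r)
  r1 <- r[-n]; r2 <- r[-1]
  ct <- cos(theta)
  chat <- sqrt(r1^2 + r2^2 - 2 * r1 * r2 * ct)
  common <- 2 * (chat - C) / chat
  g <- numeric(n)
  g[-n] <- g[-n] + common * (r1 - r2 * ct)
  g[-1] <- g[-1] + common * (r2 - r1 * ct)
  g
}

#' Flat-bottom equality-constraint residuals
#'
#' Markers on the bowl's planar bottom all lie at the same vertical depth
#' below the camera, i.e. `r[j] * cos(alpha[j])` is constant over the
#' flat-bottom index set.  Returns the consecutive differences
#' `r[j] cos(alpha[j]) - r[j+1] cos(alpha[j+1])` for flat-bottom pairs.
#'
#' @param r ray lengths (mm).
#' @param fan a `ray_fan`.
#' @param k a [camera_intrinsics()].
#' @return numeric vector of `|beta| - 1` residuals (mm); length 0 with a
#'   warning when fewer than two flat-bottom markers are annotated.
#' @export
flat_bottom_residuals <- function(r, fan, k) {
  b <- fan$beta
  if (length(b) < 2L) {
    warning("fewer than 2 flat-bottom markers: no flatness constraints")
    return(numeric(0))
  }
  depth <- r[b] * cos(ray_angle(fan$V[b], k$f))
  depth[-length(depth)] - depth[-1]
}

#' Optimize ray lengths under the flat-bottom constraint
#'
#' Minimizes the chord objective over the ray lengths subject to the
#' flat-bottom equality constraints and the bounds
#' `r[i] in [0.2 r0[i], 5 r0[i]]`.  The equality constraints are imposed
#' exactly by eliminating them: all flat-bottom rays are expressed through a
#' single common bottom depth `d` as `r[j] = d / cos(alpha[j])`, and the
#' reduced problem (`d` plus the free rays) is solved with a bounded
#' quasi-Newton method (PORT routines via [stats::nlminb()]) using the
#' analytic gradient.
#'
#' @param fan a `ray_fan` with `V`, `W`, `C`, `beta` filled (see
#'   [pair_and_measure()]).
#' @param k a [camera_intrinsics()].
#' @param r0 initial ray lengths; defaults to [initial_rays()] with the
#'   annotated ruler width (pass `D` instead to override).
#' @param D ruler width used for the default `r0`.
#' @param max_iter,tol iteration cap and relative convergence tolerance
#'   passed to the solver.
#' @return the input `ray_fan` with elements `r` (optimized ray lengths),
#'   `theta`, and `diagnostics` (initial/final objective, iterations,
#'   solver message, maximum constraint violation).
#' @export
optimize_rays <- function(fan, k, r0 = NULL, D = NULL,
                          max_iter = 500L, tol = 1e-10) {
  stopifnot(inherits(fan, "ray_fan"))
  theta <- inter_ray_angles(fan, k)
  if (is.null(r0)) {
    if (is.null(D)) stop_bowl("supply r0 or the ruler width D")
    r0 <- initial_rays(fan, D, k)
  }
  check_positive(r0, "r0")
  I <- length(fan$V)
  C <- if (length(fan$C) == 1L) rep(fan$C, I - 1L) else fan$C
  beta <- fan$beta
  free <- setdiff(seq_len(I), beta)
  cosb <- cos(ray_angle(fan$V[beta], k$f))

  expand <- function(p) {
    r <- numeric(I)
    r[beta] <- p[1] / cosb
    r[free] <- p[-1]
    r
  }
  obj <- function(p) chord_objective(expand(p), theta, C)
  grad <- function(p) {
    g <- chord_objective_grad(expand(p), theta, C)
    c(sum(g[beta] / cosb), g[free])
  }

  d0 <- mean(r0[beta] * cosb)
  lower <- c(max(0.2 * r0[beta] * cosb), 0.2 * r0[free])
  upper <- c(min(5 * r0[beta] * cosb), 5 * r0[free])
  if (lower[1] >= upper[1]) {
    stop_bowl("flat-bottom initial rays are mutually inconsistent; check the ",
              "flat_bottom index range")
  }
  p0 <- pmin(pmax(c(d0, r0[free]), lower), upper)

  sol <- stats::nlminb(p0, obj, gradient = grad, lower = lower, upper = upper,
                       control = list(iter.max = max_iter,
                                      eval.max = 4L * max_iter,
                                      rel.tol = tol))
  if (sol$convergence != 0 &&
      !grepl("relative convergence|both X.* and relative|singular convergence",
             sol$message, ignore.case = TRUE)) {
    stop_bowl("ray optimization failed: ", sol$message,
              " (iterations = ", sol$iterations, ", J = ", sol$objective, ")",
              class = "bowlrecon_solver_error")
  }
  r <- expand(sol$par)
  J0 <- chord_objective(r0, theta, C)
  J <- sol$objective
  if (J > J0 + 1e-9 * (1 + J0)) {
    stop_bowl("optimizer did not improve on the initial rays (J = ", J,
              " > J0 = ", J0, ")", class = "bowlrecon_solver_error")
  }
  resid <- suppressWarnings(flat_bottom_residuals(r, fan, k))
  fan$theta <- theta
  fan$r <- r
  fan$r0 <- r0
  fan$diagnostics <- list(J0 = J0, J = J, iterations = sol$iterations,
                          message = sol$message,
                          max_constraint_violation =
                            if (length(resid)) max(abs(resid)) else 0)
  fan
}

#' Intersect optimized rays with the ruler plane
#'
#' Maps each ray length to the planar point where the ray meets the bowl
#' surface, in the ruler's vertical cross-section plane: horizontal
#' coordinate `u = r sin(alpha)` and depth below the optical centre
#' `w = r cos(alpha)`, with `alpha = atan(V / f)`.
#'
#' @param fan a `ray_fan` with optimized `r` (see [optimize_rays()]).
#' @param k a [camera_intrinsics()].
#' @param D physical ruler width (mm); when given, wall points are
#'   corrected for tape wrap (see Details).
#' @details On the bowl wall the tape bends around the level circle of
#'   radius `rho`, so the midpoint between the two border landmarks is the
#'   projection of a point at radius `rho cos(D / (2 rho))`, slightly
#'   inside the surface.  Given `D`, the wall radii are un-shrunk by
#'   inverting `rho cos(D / (2 rho)) = |u|` (a few Newton steps); the
#'   flat-bottom points, where the tape lies flat, are left untouched.
#'   The vertical coordinate `w` is unaffected by the wrap.
#' @return an object of class `cross_section`: matrix `points` with columns
#'   `u`, `w` (mm) and the flat-bottom index set.
#' @export
rays_to_cross_section <- function(fan, k, D = NULL) {
  if (is.null(fan$r)) stop_bowl("ray fan has no optimized ray lengths")
  alpha <- ray_angle(fan$V, k$f)
  u <- fan$r * sin(alpha)
  w <- fan$r * cos(alpha)
  if (any(w <= 0)) stop_bowl("cross-section point at non-positive depth")
  if (!is.null(D)) {
    wall <- setdiff(seq_along(u), fan$beta)
    for (i in wall) {
      ui <- abs(u[i])
      if (ui <= 0.6 * D) next            # too close to the axis to unwrap
      rho <- ui                           # Newton on g(rho) = rho cos(D/2rho) - ui
      for (it in 1:8) {
        phi <- D / (2 * rho)
        gval <- rho * cos(phi) - ui
        gder <- cos(phi) + phi * sin(phi)
        step <- gval / gder
        rho <- rho - step
        if (abs(step) < 1e-12 * rho) break
      }
      u[i] <- sign(u[i]) * rho
    }
  }
  pts <- cbind(u = u, w = w)
  structure(list(points = pts, beta = fan$beta, C = fan$C,
                 diagnostics = fan$diagnostics),
            class = "cross_section")
}

#' Half-profile container
#'
#' A bowl half-profile: interior radius `rho` (mm) sampled on a uniform
#' height grid `z` (mm) with `z = 0` at the interior bottom.
#'
#' @param z heights (mm), non-negative, increasing, uniform.
#' @param rho radii (mm), non-negative, same length as `z`.
#' @param diagnostics optional list carried through from reconstruction.
#' @return object of class `half_profile`.
#' @export
half_profile <- function(z, rho, diagnostics = NULL) {
  check_finite(z, "z"); check_finite(rho, "rho")
  if (length(z) != length(rho)) stop_bowl("z and rho lengths differ")
  if (any(rho < -1e-9)) stop_bowl("negative radius in profile")
  structure(list(z = as.numeric(z), rho = pmax(as.numeric(rho), 0),
                 depth = z[length(z)], diagnostics = diagnostics),
            class = "half_profile")
}

#' Symmetrize a reconstructed cross-section into a half-profile
#'
#' A round bowl's cross-section must be symmetric, but the optimized point
#' set need not be.  The cross-section points are cubic-spline interpolated
#' (parametrically, in arc length, so vertical walls are handled), the curve
#' is shifted horizontally so the midpoint of its two endpoints sits on the
#' optical axis, rigidly rotated about that midpoint so both rim endpoints
#' share one depth, and the left and right halves are then averaged on a
#' common uniform height grid.
#'
#' @param cs a `cross_section` from [rays_to_cross_section()].
#' @param n_grid number of half-profile samples (default 501).
#' @param n_dense number of dense spline samples used internally.
#' @return a [half_profile()] whose `diagnostics` record the applied shift
#'   (mm), rotation (degrees) and the endpoint height mismatch.
#' @export
symmetrize_cross_section <- function(cs, n_grid = 501L, n_dense = 2001L) {
  pts <- cs$points
  I <- nrow(pts)
  if (I < 4L) stop_bowl("need at least 4 cross-section points")
  u <- pts[, 1]; w <- pts[, 2]
  if (!(any(u < 0) && any(u > 0))) {
    stop_bowl("cross-section does not span both sides of the bowl bottom")
  }
  ## parametric natural cubic spline in cumulative chord length
  s <- c(0, cumsum(sqrt(diff(u)^2 + diff(w)^2)))
  sd <- seq(0, s[I], length.out = n_dense)
  ud <- stats::spline(s, u, xout = sd, method = "natural")$y
  wd <- stats::spline(s, w, xout = sd, method = "natural")$y

  ## centre = midpoint of the two curve endpoints
  uc <- (u[1] + u[I]) / 2
  wc <- (w[1] + w[I]) / 2
  ud <- ud - uc
  u1 <- u[1] - uc; uI <- u[I] - uc

  ## rotate about the centre so the endpoints share one depth; the
  ## endpoint direction is a line, so reduce the angle modulo pi
  phi <- atan2(w[I] - w[1], uI - u1)
  phi <- phi - pi * round(phi / pi)
  rot_u <- cos(-phi) * ud - sin(-phi) * (wd - wc)
  rot_w <- sin(-phi) * ud + cos(-phi) * (wd - wc) + wc

  ## depth from the transformed polygon vertices: the deepest marker lies on
  ## the flat bottom, and the dense spline may overshoot slightly between
  ## markers
  vu <- cos(-phi) * (u - uc) - sin(-phi) * (w - wc)
  vw <- sin(-phi) * (u - uc) + cos(-phi) * (w - wc) + wc
  w_rim <- vw[1]                          # endpoints now share this depth
  w_deep <- max(vw)
  depth <- w_deep - w_rim
  endpoint_gap <- abs(w[I] - w[1])
  if (depth > 0 && endpoint_gap > 0.2 * depth) {
    warning(sprintf(paste0("rim endpoints differ in depth by %.1f mm (>20%% of ",
                           "depth) before rotation; the ruler may not be taped ",
                           "centrally or the camera is off-centre"),
                    endpoint_gap))
  }
  diag_out <- c(cs$diagnostics %||% list(),
                list(shift_mm = uc, rotation_deg = phi * 180 / pi,
                     endpoint_gap_mm = endpoint_gap))
  if (depth < 1e-6) {
    ## degenerate flat plate: profile collapses to a disk
    return(half_profile(rep(0, n_grid), rep(max(abs(rot_u)), n_grid),
                        diagnostics = diag_out))
  }
  z_dense <- pmin(pmax(w_deep - rot_w, 0), depth)

  zg <- seq(0, depth, length.out = n_grid)
  side_profile <- function(sel) {
    if (sum(sel) < 2L) stop_bowl("one side of the cross-section has too few points")
    stats::approx(z_dense[sel], abs(rot_u[sel]), xout = zg,
                  ties = max, rule = 2)$y
  }
  rho_left <- side_profile(rot_u < 0)
  rho_right <- side_profile(rot_u >= 0)
  half_profile(zg, (rho_left + rho_right) / 2, diagnostics = diag_out)
}

## ---- model-based measurement refinement -----------------------------------
##
## The raw pipeline carries three small, systematic model errors that a first
## reconstruction pass can estimate and remove:
##   1. tape wrap: on the wall the landmark-bar midpoint images the point at
##      radius rho*cos(phi), phi = D/(2 rho); the centreline-equivalent
##      measurements are V' = V / cos(phi) and W' = W * phi / sin(phi);
##   2. arc vs chord: the marker spacing C is an arc length along the
##      cross-section, while the objective compares straight chords; each
##      interval's chord target is C times the chord/arc ratio of the
##      current reconstructed curve (exactly 1 on the flat bottom);
##   3. the bottom-wall corner: the interval that straddles the junction
##      bends sharply, so its chord target is computed from an explicit
##      local model -- the wall curve (a circle through the three innermost
##      wall points, or a line when they are collinear) extrapolated to the
##      known bottom plane.
## Iterating measurement correction + re-optimization converges in a few
## passes and removes the depth bias that the raw objective cannot see.

## chord target for the corner-straddling interval.  uf: u of the adjacent
## flat marker; d: bottom depth (w); wall_pts: cross-section points of that
## wall ordered inner -> outer; C: interval arc length.
corner_chord <- function(uf, d, wall_pts, C) {
  if (nrow(wall_pts) < 2L) return(C)
  P <- cbind(abs(wall_pts[, 1]), wall_pts[, 2])[seq_len(min(3L, nrow(wall_pts))), ,
                                                drop = FALSE]
  use_line <- nrow(P) < 3L
  if (!use_line) {
    ax <- P[1, 1]; ay <- P[1, 2]; bx <- P[2, 1]; by <- P[2, 2]
    cx <- P[3, 1]; cy <- P[3, 2]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    use_line <- abs(dd) < 1e-8 * max(abs(c(ax, ay, bx, by, cx, cy)))
  }
  chord <- if (use_line) {
    dir <- c(P[min(2L, nrow(P)), 1] - P[1, 1], P[min(2L, nrow(P)), 2] - P[1, 2])
    dir <- dir / sqrt(sum(dir^2))
    if (abs(dir[2]) < 1e-9) return(C)
    t <- (d - P[1, 2]) / dir[2]
    rb <- P[1, 1] + t * dir[1]
    a <- rb - abs(uf)
    if (a <= 0 || a >= C) return(C)
    pe <- c(rb, d) - (C - a) * dir * sign(t)
    sqrt((pe[1] - abs(uf))^2 + (pe[2] - d)^2)
  } else {
    ux <- (ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
      (cx^2 + cy^2) * (ay - by)
    uy <- (ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
      (cx^2 + cy^2) * (bx - ax)
    ctr <- c(ux, uy) / dd
    R <- sqrt((ax - ctr[1])^2 + (ay - ctr[2])^2)
    disc <- R^2 - (d - ctr[2])^2
    if (disc <= 0) return(C)
    roots <- ctr[1] + c(-1, 1) * sqrt(disc)
    rb <- roots[which.min(abs(roots - P[1, 1]))]
    a <- rb - abs(uf)
    if (a <= 0 || a >= C) return(C)
    th0 <- atan2(d - ctr[2], rb - ctr[1])
    th1 <- atan2(P[1, 2] - ctr[2], P[1, 1] - ctr[1])
    sgn <- sign(sin(th1 - th0)); if (sgn == 0) sgn <- 1
    th <- th0 + sgn * (C - a) / R
    pe <- ctr + R * c(cos(th), sin(th))
    sqrt((pe[1] - abs(uf))^2 + (pe[2] - d)^2)
  }
  min(max(chord, 0.7 * C), C)
}

## one full refinement: returns the final cross_section
refine_cross_section <- function(fan, cs, k, D, n_iter = 6L, r_start = NULL) {
  I <- length(fan$V)
  beta <- fan$beta
  C0 <- if (length(fan$C) == 1L) rep(fan$C, I - 1L) else fan$C
  ivs <- seq_len(I - 1L)
  iv_flat <- (ivs %in% beta) & ((ivs + 1L) %in% beta)
  iv_corner_left <- which(!(ivs %in% beta) & ((ivs + 1L) %in% beta))
  iv_corner_right <- which((ivs %in% beta) & !((ivs + 1L) %in% beta))
  r_prev <- r_start %||% fan$r
  for (it in seq_len(n_iter)) {
    pts <- cs$points
    wall <- setdiff(seq_len(I), beta)
    phi <- numeric(I)
    phi[wall] <- D / (2 * pmax(abs(pts[wall, 1]), 0.6 * D))
    Vp <- fan$V / cos(phi)
    Wp <- fan$W * ifelse(phi > 0, phi / sin(phi), 1)
    if (any(diff(Vp) >= 0)) {
      warning("wrap-corrected landmark offsets lost monotonicity; ",
              "stopping refinement at iteration ", it)
      break
    }
    ## chord/arc ratio of the current curve per interval
    s <- c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
    sd <- seq(0, s[I], length.out = 4001L)
    ud <- stats::spline(s, pts[, 1], xout = sd, method = "natural")$y
    wd <- stats::spline(s, pts[, 2], xout = sd, method = "natural")$y
    cum <- c(0, cumsum(sqrt(diff(ud)^2 + diff(wd)^2)))
    arc <- diff(stats::approx(sd, cum, xout = s, ties = "ordered")$y)
    chord <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    Cp <- C0 * pmin(chord / arc, 1)
    Cp[iv_flat] <- C0[iv_flat]
    d_bot <- mean(pts[beta, 2])
    if (length(iv_corner_left) == 1L && min(beta) > 2L) {
      wall_left <- pts[seq(min(beta) - 1L, 1L), , drop = FALSE]
      Cp[iv_corner_left] <- corner_chord(pts[min(beta), 1], d_bot, wall_left,
                                         C0[iv_corner_left])
    }
    if (length(iv_corner_right) == 1L && max(beta) < I - 1L) {
      wall_right <- pts[seq(max(beta) + 1L, I), , drop = FALSE]
      Cp[iv_corner_right] <- corner_chord(pts[max(beta), 1], d_bot, wall_right,
                                          C0[iv_corner_right])
    }
    fan_it <- fan
    fan_it$V <- Vp; fan_it$W <- Wp; fan_it$C <- Cp
    fan_it <- optimize_rays(fan_it, k, r0 = r_prev)
    cs <- rays_to_cross_section(fan_it, k, D = NULL)  # V already centreline
    if (max(abs(fan_it$r - r_prev)) < 1e-6) break
    r_prev <- fan_it$r
  }
  cs
}

#' Revolve a half-profile into a bowl model
#'
#' Rotating the half-profile 360 degrees about the vertical axis yields the
#' bowl interior.  Capacity is `pi * integral of rho(z)^2 dz` by composite
#' trapezoidal quadrature on the profile grid; the cumulative integral gives
#' the fill-level/volume table used for level projection.
#'
#' @param profile a [half_profile()].
#' @return an object of class `bowl_model`: `z`, `rho` (mm), `depth` (mm),
#'   `diameter` (mm, `= 2 rho(depth)`), `capacity` (mL) and
#'   `level_volume_table` (data frame of height `z_mm` vs cumulative volume
#'   `volume_ml`).
#' @export
revolve_profile <- function(profile) {
  stopifnot(inherits(profile, "half_profile"))
  z <- profile$z; rho <- profile$rho
  if (any(rho < 0)) stop_bowl("negative radius in profile")
  vol <- pi * cumtrapz(z, rho^2) / 1000  # mm^3 -> mL
  structure(
    list(z = z, rho = rho, depth = profile$depth,
         diameter = 2 * rho[length(rho)],
         capacity = vol[length(vol)],
         level_volume_table = data.frame(z_mm = z, volume_ml = vol),
         diagnostics = profile$diagnostics),
    class = "bowl_model")
}

#' @export
print.bowl_model <- function(x, ...) {
  cat(sprintf("bowl_model: diameter %.1f mm, depth %.1f mm, capacity %.1f mL (%d profile samples)\n",
              x$diameter, x$depth, x$capacity, length(x$z)))
  invisible(x)
}

#' Reconstruct a bowl from a ruler annotation
#'
#' End-to-end single-view reconstruction: border fitting, width and offset
#' measurement, initial rays from the ruler width, constrained ray
#' optimization, cross-section recovery, symmetrization and revolution.
#'
#' After a first pass, the measurements are rectified against the current
#' reconstruction (tape-wrap correction of offsets and widths, arc-to-chord
#' conversion of the marker spacings including an explicit model of the
#' bottom-wall corner) and the optimization repeated until the rays are
#' stable; see the package vignette for the rationale.  Set
#' `refine_iterations = 0` for the raw single-pass method.
#'
#' @param a a [ruler_annotation()].
#' @param k a [camera_intrinsics()].
#' @param n_grid number of half-profile samples.
#' @param refine_iterations maximum measurement-refinement passes.
#' @param ... passed to [optimize_rays()] (e.g. `max_iter`, `tol`).
#' @return a `bowl_model`; `$diagnostics` carries the solver summary and
#'   the symmetrization corrections.
#' @examples
#' bowl <- parametric_bowl("spherical_cap", rb = 40, rr = 60, depth = 45)
#' sim <- simulate_ruler_annotation(bowl, simulation_config(noise_px = 0, seed = 1))
#' m <- reconstruct_bowl(sim$annotation, sim$config$intrinsics)
#' m$capacity   # close to bowl$capacity
#' @export
reconstruct_bowl <- function(a, k, n_grid = 501L, refine_iterations = 6L, ...) {
  fan <- pair_and_measure(a, k)
  fan1 <- optimize_rays(fan, k, D = a$ruler_width, ...)
  cs <- rays_to_cross_section(fan1, k, D = a$ruler_width)
  if (refine_iterations > 0L) {
    cs <- refine_cross_section(fan, cs, k, D = a$ruler_width,
                               n_iter = refine_iterations, r_start = fan1$r)
  }
  prof <- symmetrize_cross_section(cs, n_grid = n_grid)
  revolve_profile(prof)
}
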