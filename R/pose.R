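#' Bowl pose in the camera frame
#'
#' Position and orientation of a reconstructed bowl in a meal image: the 3D
#' centre of the rim circle (mm, camera frame) and the unit normal of the
#' rim plane, oriented toward the camera (interior visible).
#'
#' @param center length-3 numeric, rim-circle centre (mm), `Z > 0`.
#' @param normal length-3 numeric, rim-plane normal; normalized and flipped
#'   toward the camera if needed.
#' @param diagnostics optional list (e.g. both circle-pose candidates).
#' @return object of class `bowl_pose`.
#' @export
bowl_pose <- function(center, normal, diagnostics = NULL) {
  check_finite(center, "center"); check_finite(normal, "normal")
  if (center[3] <= 0) stop_bowl("rim centre must be in front of the camera")
  normal <- normal / sqrt(sum(normal^2))
  if (sum(normal * center) > 0) normal <- -normal  # point toward the camera
  structure(list(center = as.numeric(center), normal = as.numeric(normal),
                 diagnostics = diagnostics),
            class = "bowl_pose")
}

#' @export
print.bowl_pose <- function(x, ...) {
  cat(sprintf("bowl_pose: rim centre (%.1f, %.1f, %.1f) mm, tilt %.2f deg\n",
              x$center[1], x$center[2], x$center[3],
              acos(min(1, abs(x$normal[3]))) * 180 / pi))
  invisible(x)
}

## orthonormal in-plane basis for a circle with unit normal n
plane_basis <- function(n) {
  seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

#' Project a 3D circle to its image ellipse
#'
#' @param center length-3 circle centre (mm, camera frame, Z > 0).
#' @param normal circle-plane normal.
#' @param radius circle radius (mm).
#' @param k a [camera_intrinsics()].
#' @param n number of boundary samples used for the (exact, conic) fit.
#' @return an [ellipse_params()] in image-plane mm.
#' @export
project_circle <- function(center, normal, radius, k, n = 72L) {
  check_positive(radius, "radius")
  normal <- normal / sqrt(sum(normal^2))
  b <- plane_basis(normal)
  t <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  P <- cbind(center[1] + radius * (cos(t) * b$u[1] + sin(t) * b$v[1]),
             center[2] + radius * (cos(t) * b$u[2] + sin(t) * b$v[2]),
             center[3] + radius * (cos(t) * b$u[3] + sin(t) * b$v[3]))
  fit_ellipse(project_points(P, k))
}

#' Recover the pose of a circle of known diameter from its image ellipse
#'
#' The viewing rays through an ellipse form an elliptic cone through the
#' optical centre; every such cone has exactly two families of circular
#' cross-sections, giving the classic two-fold pose ambiguity.  Writing the
#' cone as `x^T Q x = 0` with eigenvalues `l1 >= l2 > 0 > l3` and
#' eigenvectors `e1, e2, e3`, the circle-plane normal in the eigenframe is
#' `(+-g, 0, +-h)` with `g = sqrt((l1 - l2)/(l1 - l3))`,
#' `h = sqrt((l2 - l3)/(l1 - l3))`, and the centre of the circle of radius
#' `R` is `-R / sqrt(-l1 l3) * (+-l3 g, 0, +-l1 h)` with matching signs.
#' Of the two solutions in front of the camera, the one whose
#' (camera-facing) normal makes the smaller angle with the viewing ray is
#' returned — the bowl interior is visible from above; both candidates are
#' reported in `$diagnostics$candidates`.
#'
#' @param e an [ellipse_params()] (image-plane mm), e.g. the fitted rim.
#' @param diameter physical circle diameter (mm), e.g. the reconstructed
#'   rim diameter.
#' @param k a [camera_intrinsics()].
#' @param reproject_tol relative tolerance on the re-projection check.
#' @return a [bowl_pose()].
#' @export
estimate_circle_pose <- function(e, diameter, k, reproject_tol = 1e-3) {
  stopifnot(inherits(e, "ellipse_params"))
  check_positive(diameter, "diameter")
  R <- diameter / 2
  co <- e$conic %||% ellipse_to_conic(e)
  f <- k$f
  Q <- matrix(c(co[[1]], co[[2]] / 2, co[[4]] / (2 * f),
                co[[2]] / 2, co[[3]], co[[5]] / (2 * f),
                co[[4]] / (2 * f), co[[5]] / (2 * f), co[[6]] / f^2), 3, 3)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values; V <- eg$vectors
  if (sum(lam > 0) == 1L) { lam <- -lam }       # want two positive, one negative
  o <- order(lam, decreasing = TRUE)
  lam <- lam[o]; V <- V[, o]
  if (!(lam[2] > 0 && lam[3] < 0)) {
    stop_bowl("ellipse does not correspond to a circle at positive depth",
              class = "bowlrecon_pose_error")
  }
  g <- sqrt((lam[1] - lam[2]) / (lam[1] - lam[3]))
  h <- sqrt((lam[2] - lam[3]) / (lam[1] - lam[3]))
  scale <- R / sqrt(-lam[1] * lam[3])
  cand <- list()
  for (s1 in c(1, -1)) for (s3 in c(1, -1)) {
    n <- drop(V %*% c(s1 * g, 0, s3 * h))
    ctr <- drop(V %*% (-scale * c(s1 * lam[3] * g, 0, s3 * lam[1] * h)))
    if (ctr[3] > 0) cand[[length(cand) + 1L]] <- list(center = ctr, normal = n)
  }
  if (length(cand) == 0L) {
    stop_bowl("no circle pose at positive depth", class = "bowlrecon_pose_error")
  }
  ## orient normals toward the camera; of the two geometrically valid poses
  ## pick the more upright bowl (normal closest to the upward optical axis),
  ## the right reading for a roughly top-down view of a standing container
  score <- vapply(cand, function(cc) {
    n <- cc$normal
    if (sum(n * cc$center) > 0) n <- -n
    -n[3]
  }, numeric(1))
  best <- cand[[which.max(score)]]
  pose <- bowl_pose(best$center, best$normal,
                    diagnostics = list(candidates = cand, eigenvalues = lam))
  ## re-projection contract
  re <- project_circle(pose$center, pose$normal, R, k)
  err <- max(abs(c(re$center - e$center, re$a - e$a, re$b - e$b))) / e$a
  if (err > reproject_tol) {
    stop_bowl(sprintf("circle pose re-projection error %.2g exceeds tolerance %.2g",
                      err, reproject_tol), class = "bowlrecon_pose_error")
  }
  pose$diagnostics$reprojection_error <- err
  pose
}

## fill height (mm above bowl bottom) at cumulative volume v (mL)
fill_height <- function(model, v) {
  tab <- model$level_volume_table
  stats::approx(tab$volume_ml, tab$z_mm, xout = v, ties = "ordered", rule = 2)$y
}

## 3D centre of the level circle at height z, given the rim pose
level_circle <- function(model, pose, z) {
  list(center = pose$center - pose$normal * (model$depth - z),
       radius = stats::approx(model$z, model$rho, xout = z, rule = 2)$y)
}

#' Project volume levels of a posed bowl into the image
#'
#' For cumulative volumes `increment, 2 increment, ..., capacity`, finds
#' each fill height from the level/volume table (monotone interpolation),
#' forms the horizontal circle of the corresponding radius in the bowl
#' frame, places it by the pose and projects it to an image ellipse.
#'
#' @param model a `bowl_model`.
#' @param pose a [bowl_pose()] of the rim circle.
#' @param k a [camera_intrinsics()].
#' @param increment volume step in mL (default 50, the usual display step).
#' @param volumes optional explicit volume vector overriding `increment`.
#' @return a list with numeric `volume` (mL) and list `ellipse` of
#'   [ellipse_params()], rim level included last.
#' @export
project_levels <- function(model, pose, k, increment = 50, volumes = NULL) {
  if (is.null(volumes)) {
    check_positive(increment, "increment")
    volumes <- seq(increment, model$capacity, by = increment)
    if (length(volumes) == 0L || max(volumes) < model$capacity) {
      volumes <- c(volumes, model$capacity)
    }
  }
  ell <- lapply(volumes, function(v) {
    lc <- level_circle(model, pose, fill_height(model, v))
    project_circle(lc$center, pose$normal, max(lc$radius, 1e-9), k)
  })
  list(volume = volumes, ellipse = ell)
}

#' Estimate liquid volume by matching the surface ellipse to volume levels
#'
#' Fits an ellipse to points marked on the flat liquid surface, scores every
#' projected level by the mean squared distance from the surface points to
#' the level ellipse, then refines around the best coarse level with
#' `fine_factor` times finer volume steps.
#'
#' @param surface_points n x 2 matrix (n >= 5) of image-plane points (mm) on
#'   the liquid surface.
#' @param model a `bowl_model`.
#' @param pose the rim [bowl_pose()].
#' @param k a [camera_intrinsics()].
#' @param increment coarse volume step (mL).
#' @param fine_factor refinement ratio for the second pass (default 10).
#' @param levels optional precomputed coarse levels from [project_levels()].
#' @return estimated volume (mL) with attribute `"match"` holding the score
#'   of the winning level.
#' @export
match_surface <- function(surface_points, model, pose, k,
                          increment = 50, fine_factor = 10L, levels = NULL) {
  surface_points <- as_points(surface_points, "surface_points")
  if (nrow(surface_points) < 5L) stop_bowl("need at least 5 surface points")
  se <- fit_ellipse(surface_points)
  rim <- project_circle(level_circle(model, pose, model$depth)$center,
                        pose$normal, model$diameter / 2, k)
  if (se$a > rim$a * 1.05) {
    stop_bowl("surface ellipse larger than the rim ellipse: liquid above rim?")
  }
  levels <- levels %||% project_levels(model, pose, k, increment = increment)
  score <- vapply(levels$ellipse, function(le) {
    mean(ellipse_point_distance(surface_points, le)^2)
  }, numeric(1))
  i <- which.min(score)
  v0 <- levels$volume[i]
  ## one refinement pass around the winner
  fine <- increment / fine_factor
  vf <- seq(max(fine, v0 - increment), min(model$capacity, v0 + increment), by = fine)
  fine_levels <- project_levels(model, pose, k, volumes = vf)
  fscore <- vapply(fine_levels$ellipse, function(le) {
    mean(ellipse_point_distance(surface_points, le)^2)
  }, numeric(1))
  j <- which.min(fscore)
  structure(fine_levels$volume[j], match = fscore[j])
}

#' Fullness of a bowl
#'
#' The normalized volumetric measure: 100 x volume / capacity (percent).
#' Values above 100 are allowed (food mounded above the rim) but warn.
#'
#' @param volume food/liquid volume (mL), >= 0.
#' @param capacity bowl capacity (mL), > 0.
#' @return fullness in percent.
#' @export
fullness <- function(volume, capacity) {
  check_positive(capacity, "capacity")
  check_finite(volume, "volume")
  if (any(volume < 0)) stop_bowl("volume must be >= 0")
  if (any(volume > capacity)) warning("volume exceeds capacity (overfull bowl)")
  100 * volume / capacity
}

#' Food area ratio from segmentation pixel counts
#'
#' FAR = (# pixels of visible liquid) / (# pixels inside the bowl rim).
#'
#' @param liquid_px non-negative liquid pixel count.
#' @param rim_px positive within-rim pixel count, `>= liquid_px`.
#' @return FAR in `[0, 1]`.
#' @export
compute_far <- function(liquid_px, rim_px) {
  check_finite(c(liquid_px, rim_px), "pixel counts")
  if (rim_px <= 0) stop_bowl("rim pixel count must be > 0")
  if (liquid_px < 0 || liquid_px > rim_px) {
    stop_bowl("need 0 <= liquid_px <= rim_px")
  }
  liquid_px / rim_px
}

#' Regress volume on the simulated food area ratio
#'
#' Simulates flat liquid fills of the posed bowl at the requested volumes,
#' computes each fill's FAR as the projected surface-ellipse area over the
#' projected rim-ellipse area, and fits the ordinary least-squares line
#' `volume = slope * FAR + intercept` used to look volumes up from observed
#' FAR values.
#'
#' @param model a `bowl_model`.
#' @param pose the rim [bowl_pose()].
#' @param k a [camera_intrinsics()].
#' @param volumes simulated fill volumes (mL), at least 3, below capacity;
#'   default 10 equal steps up to 95% capacity.
#' @return object of class `far_regression` with `slope` (mL per unit FAR),
#'   `intercept` (mL), `r_squared`, the support points and the capacity.
#' @export
build_far_regression <- function(model, pose, k, volumes = NULL) {
  volumes <- volumes %||% (seq(0.1, 0.95, length.out = 10L) * model$capacity)
  if (length(volumes) < 3L) stop_bowl("need at least 3 support volumes")
  if (any(volumes <= 0 | volumes > model$capacity)) {
    stop_bowl("support volumes must lie in (0, capacity]")
  }
  rim <- project_circle(level_circle(model, pose, model$depth)$center,
                        pose$normal, model$diameter / 2, k)
  far <- vapply(volumes, function(v) {
    lc <- level_circle(model, pose, fill_height(model, v))
    se <- project_circle(lc$center, pose$normal, max(lc$radius, 1e-9), k)
    ellipse_area(se) / ellipse_area(rim)
  }, numeric(1))
  if (stats::sd(far) < 1e-9) {
    stop_bowl("degenerate FAR support (constant area ratio; vertical-walled bowl?)",
              class = "bowlrecon_far_error")
  }
  fit <- stats::lm.fit(cbind(1, far), volumes)
  fitted <- drop(cbind(1, far) %*% fit$coefficients)
  r2 <- 1 - sum((volumes - fitted)^2) / sum((volumes - mean(volumes))^2)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2,
                 support = data.frame(far = far, volume_ml = volumes),
                 capacity = model$capacity),
            class = "far_regression")
}

#' Volume from an observed food area ratio
#'
#' Evaluates the FAR regression line and clamps to `[0, capacity]`.
#'
#' @param far observed FAR in `[0, 1]` (see [compute_far()]).
#' @param reg a [build_far_regression()] result.
#' @return volume in mL.
#' @export
volume_from_far <- function(far, reg) {
  stopifnot(inherits(reg, "far_regression"))
  check_finite(far, "far")
  pmin(pmax(reg$slope * far + reg$intercept, 0), reg$capacity)
}

#' Density-based ground-truth volume
#'
#' Weighs a measuring-cup sample to get the food density `rho = wc / vc`,
#' then converts the bowl's food weight to volume, `vf = wf / rho`.
#'
#' @param wc sample weight in the cup (g).
#' @param vc cup volume (mL), usually 237.
#' @param wf food weight in the bowl (g).
#' @return ground-truth food volume `vf` (mL).
#' @export
density_ground_truth <- function(wc, vc, wf) {
  check_positive(c(wc, vc, wf), "weights and volumes")
  wf * vc / wc
}
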