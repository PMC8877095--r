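#' Ellipse parameters
#'
#' Geometric ellipse description in image-plane millimetres: centre,
#' semi-axes `a >= b > 0` and the rotation of the major axis (radians,
#' counter-clockwise from +x, reported in `[0, pi)`).
#'
#' @param center length-2 numeric, ellipse centre (mm).
#' @param a,b semi-major / semi-minor axes (mm), `a >= b > 0`.
#' @param angle major-axis rotation (rad).
#' @param rms optional root-mean-square fit residual.
#' @return object of class `ellipse_params`.
#' @export
ellipse_params <- function(center, a, b, angle = 0, rms = NA_real_) {
  check_finite(center, "center")
  check_positive(c(a, b), "semi-axes")
  if (b > a * (1 + 1e-12)) stop_bowl("require a >= b")
  angle <- angle %% pi
  structure(list(center = as.numeric(center), a = a, b = b, angle = angle,
                 rms = rms),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("ellipse: centre (%.3f, %.3f) mm, a = %.4f, b = %.4f mm, angle = %.2f deg\n",
              x$center[1], x$center[2], x$a, x$b, x$angle * 180 / pi))
  invisible(x)
}

#' Area of an ellipse
#' @param e an [ellipse_params()] object.
#' @return area (mm^2), `pi * a * b`.
#' @export
ellipse_area <- function(e) pi * e$a * e$b

#' Sample points along an ellipse
#' @param e an [ellipse_params()] object.
#' @param n number of points.
#' @return n x 2 matrix.
#' @export
ellipse_points <- function(e, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  ca <- cos(e$angle); sa <- sin(e$angle)
  x <- e$a * cos(t); y <- e$b * sin(t)
  cbind(e$center[1] + ca * x - sa * y,
        e$center[2] + sa * x + ca * y)
}

## approximate distance from points to an ellipse boundary: min distance to
## a dense polygonal sampling of the ellipse (adequate at the tolerances
## used for level matching)
ellipse_point_distance <- function(pts, e, n = 256L) {
  pts <- as_points(pts)
  poly <- ellipse_points(e, n)
  apply(pts, 1L, function(p) {
    sqrt(min((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2))
  })
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (`4AC - B^2 = 1`) through five
#' or more points, using the numerically stable partitioned formulation of
#' the direct least-squares method, and converts it to geometric
#' parameters.
#'
#' @param pts n x 2 matrix of points (n >= 5), image-plane mm.
#' @return an [ellipse_params()] with the RMS point-to-ellipse residual in
#'   `$rms` and the conic coefficients `(A, B, C, D, E, F)` in
#'   `$conic`.
#' @export
fit_ellipse <- function(pts) {
  pts <- as_points(pts, "ellipse points")
  if (nrow(pts) < 5L) stop_bowl("need at least 5 points to fit an ellipse")
  x <- pts[, 1]; y <- pts[, 2]
  ## centre and scale for conditioning
  mx <- mean(x); my <- mean(y)
  sc <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (sc < .Machine$double.eps) stop_bowl("degenerate (coincident) points")
  xs <- (x - mx) / sc; ys <- (y - my) / sc

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) stop_bowl("degenerate point configuration (collinear?)")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  ## premultiply by inv(C) where C is the ellipse-constraint matrix
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  evec <- Re(eg$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop_bowl("no elliptic solution (points may be collinear or hyperbolic)")
  a1 <- evec[, ok[1]]
  co <- c(a1, drop(Tm %*% a1))  # A B C D E F in scaled frame
  ## un-condition back to the original frame
  A <- co[1] / sc^2
  B <- co[2] / sc^2
  Cc <- co[3] / sc^2
  Dd <- co[4] / sc - 2 * A * mx - B * my
  E <- co[5] / sc - B * mx - 2 * Cc * my
  Fc <- co[6] + A * mx^2 + B * mx * my + Cc * my^2 - co[4] * mx / sc - co[5] * my / sc
  conic <- c(A = A, B = B, C = Cc, D = Dd, E = E, F = Fc)
  e <- conic_to_ellipse(conic)
  e$rms <- sqrt(mean(ellipse_point_distance(pts, e, n = 720L)^2))
  e$conic <- conic
  e
}

## convert conic coefficients (A,B,C,D,E,F) of an ellipse to geometric form
conic_to_ellipse <- function(co) {
  A <- co[[1]]; B <- co[[2]]; Cc <- co[[3]]; Dd <- co[[4]]; E <- co[[5]]; Fc <- co[[6]]
  den <- 4 * A * Cc - B^2
  if (den <= 0) stop_bowl("conic is not an ellipse")
  cx <- (B * E - 2 * Cc * Dd) / den
  cy <- (B * Dd - 2 * A * E) / den
  ## constant after recentring
  Fc2 <- Fc + A * cx^2 + B * cx * cy + Cc * cy^2 + Dd * cx + E * cy
  M <- matrix(c(A, B / 2, B / 2, Cc), 2, 2)
  eg <- eigen(M, symmetric = TRUE)
  lam <- eg$values  # decreasing
  axes2 <- -Fc2 / lam
  if (any(axes2 <= 0)) stop_bowl("conic is not a real ellipse")
  imaj <- which.max(axes2)
  a <- sqrt(axes2[imaj]); b <- sqrt(min(axes2))
  vmaj <- eg$vectors[, imaj]
  angle <- if (abs(a - b) < 1e-9 * a) 0 else atan2(vmaj[2], vmaj[1])
  ellipse_params(c(cx, cy), a, b, angle)
}

## conic of an ellipse in geometric form (A,B,C,D,E,F with 4AC - B^2 > 0)
ellipse_to_conic <- function(e) {
  ca <- cos(e$angle); sa <- sin(e$angle)
  ## x^T R diag(1/a^2, 1/b^2) R^T x = 1 recentred
  M <- matrix(c(ca, sa, -sa, ca), 2, 2) %*% diag(c(1 / e$a^2, 1 / e$b^2)) %*%
    t(matrix(c(ca, sa, -sa, ca), 2, 2))
  cx <- e$center[1]; cy <- e$center[2]
  A <- M[1, 1]; B <- 2 * M[1, 2]; Cc <- M[2, 2]
  Dd <- -2 * A * cx - B * cy
  E <- -B * cx - 2 * Cc * cy
  Fc <- A * cx^2 + B * cx * cy + Cc * cy^2 - 1
  c(A = A, B = B, C = Cc, D = Dd, E = E, F = Fc)
}
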