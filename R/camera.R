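#' Pinhole camera intrinsics
#'
#' Bundles the intrinsic parameters of a pinhole camera: focal length `f`
#' (mm), pixel pitch `sx`, `sy` (mm per pixel along the image x and y axes)
#' and the principal-point offset `ox`, `oy` (pixels, relative to the image
#' centre).  All image-plane arithmetic in this package is done in
#' millimetres; pixel coordinates are always taken relative to the image
#' centre, with y growing downward.
#'
#' @param f focal length in mm (> 0).
#' @param sx,sy pixel pitch in mm/pixel (> 0).
#' @param ox,oy principal-point offset in pixels relative to the image-plane
#'   centre.  Default 0 (principal point at the centre).
#' @param image_width,image_height sensor size in pixels; used by the
#'   annotation readers to convert top-left-origin pixel coordinates to the
#'   centred convention.
#' @param undistorted logical flag asserting that images measured with these
#'   intrinsics have been undistorted upstream.  The reconstruction assumes
#'   an ideal pinhole; wide-angle images must be rectified first.
#' @return an object of class `camera_intrinsics`.
#' @examples
#' k <- camera_intrinsics(f = 4, sx = 0.0015, sy = 0.0015)
#' pixel_to_plane(c(500, 0), k)
#' @export
camera_intrinsics <- function(f, sx, sy, ox = 0, oy = 0,
                              image_width = NA_real_, image_height = NA_real_,
                              undistorted = TRUE) {
  check_positive(f, "f")
  check_positive(sx, "sx")
  check_positive(sy, "sy")
  check_finite(c(ox, oy), "ox/oy")
  structure(
    list(f = f, sx = sx, sy = sy, ox = ox, oy = oy,
         image_width = image_width, image_height = image_height,
         undistorted = isTRUE(undistorted)),
    class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: f = %g mm, pitch = (%g, %g) mm/px, principal point offset = (%g, %g) px\n",
              x$f, x$sx, x$sy, x$ox, x$oy))
  if (is.finite(x$image_width)) {
    cat(sprintf("  image: %g x %g px, undistorted: %s\n",
                x$image_width, x$image_height, x$undistorted))
  }
  invisible(x)
}

#' Convert centred pixel coordinates to image-plane millimetres
#'
#' Applies the affine sensor map `x' = sx * (x + ox)`, `y' = sy * (y + oy)`.
#' Pixel coordinates are relative to the image centre (y down).
#'
#' @param p pixel point(s): length-2 vector, n x 2 matrix or data frame.
#' @param k a [camera_intrinsics()] object.
#' @return n x 2 matrix of image-plane coordinates in mm.
#' @export
pixel_to_plane <- function(p, k) {
  p <- as_points(p, "pixel points")
  cbind(k$sx * (p[, 1] + k$ox), k$sy * (p[, 2] + k$oy))
}

#' Convert image-plane millimetres to centred pixel coordinates
#'
#' Exact inverse of [pixel_to_plane()].
#'
#' @inheritParams pixel_to_plane
#' @param p image-plane point(s) in mm.
#' @return n x 2 matrix of centred pixel coordinates.
#' @export
plane_to_pixel <- function(p, k) {
  p <- as_points(p, "plane points")
  cbind(p[, 1] / k$sx - k$ox, p[, 2] / k$sy - k$oy)
}

#' Pinhole projection of camera-frame scene points
#'
#' The camera frame has its origin at the optical centre, +Z along the
#' optical axis toward the scene (downward when the camera looks into the
#' bowl) and X parallel to the image x axis.  A scene point (X, Y, Z) with
#' Z > 0 projects to image-plane coordinates `(f X / Z, f Y / Z)` in mm.
#'
#' @param s scene point(s): length-3 vector or n x 3 matrix (mm).
#' @param k a [camera_intrinsics()] object.
#' @return n x 2 matrix of image-plane coordinates (mm).
#' @export
project_points <- function(s, k) {
  if (is.null(dim(s))) s <- matrix(s, ncol = 3L)
  s <- unname(as.matrix(s))
  check_finite(s, "scene points")
  if (any(s[, 3] <= 0)) {
    stop_bowl("scene point behind camera (Z <= 0)", class = "bowlrecon_projection_error")
  }
  cbind(k$f * s[, 1] / s[, 3], k$f * s[, 2] / s[, 3])
}

#' Viewing-ray angle of an image-plane offset
#'
#' Angle between the optical axis and the ray through an image-plane point
#' at signed offset `V` (mm) from the centre: `atan(V / f)`.  By convention
#' `V` is positive for landmarks in the left half of the image plane, so the
#' angles decrease monotonically along a left-to-right ruler.
#'
#' @param V signed image-plane offset(s) in mm.
#' @param f focal length in mm.
#' @return angle(s) in radians.
#' @export
ray_angle <- function(V, f) {
  check_positive(f, "f")
  check_finite(V, "V")
  atan(V / f)
}

#' Read / write camera intrinsics as JSON
#'
#' The file holds keys `f_mm`, `sx_mm_per_px`, `sy_mm_per_px`, `ox_px`,
#' `oy_px`, `image_width_px`, `image_height_px`, `undistorted`.
#'
#' @param path file path.
#' @return [read_intrinsics()] returns a [camera_intrinsics()] object.
#' @export
read_intrinsics <- function(path) {
  if (!file.exists(path)) stop_bowl("intrinsics file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("f_mm", "sx_mm_per_px", "sy_mm_per_px")
  if (!all(need %in% names(j))) {
    stop_bowl("intrinsics file missing keys: ",
              paste(setdiff(need, names(j)), collapse = ", "))
  }
  camera_intrinsics(f = j$f_mm, sx = j$sx_mm_per_px, sy = j$sy_mm_per_px,
                    ox = j$ox_px %||% 0, oy = j$oy_px %||% 0,
                    image_width = j$image_width_px %||% NA_real_,
                    image_height = j$image_height_px %||% NA_real_,
                    undistorted = j$undistorted %||% TRUE)
}

#' @rdname read_intrinsics
#' @param k a [camera_intrinsics()] object.
#' @export
write_intrinsics <- function(k, path) {
  jsonlite::write_json(
    list(f_mm = k$f, sx_mm_per_px = k$sx, sy_mm_per_px = k$sy,
         ox_px = k$ox, oy_px = k$oy,
         image_width_px = k$image_width, image_height_px = k$image_height,
         undistorted = k$undistorted),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
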