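#' Ruler annotation
#'
#' Labelled landmark pairs along the adhesive paper ruler: one ordered set
#' of points on the ruler's upper border (smaller pixel y) and one on the
#' lower border, index-paired marker by marker, plus the physical marker
#' spacing, the physical ruler width and the indices of the markers lying on
#' the bowl's flat bottom.
#'
#' Coordinates are stored in the centred pixel convention (origin at the
#' image centre, y down).  [read_ruler_annotation()] converts from the
#' top-left-origin coordinates used in annotation files.
#'
#' @param upper_border,lower_border n x 2 matrices (or data frames) of pixel
#'   coordinates, centred convention, same number of rows, ordered along the
#'   ruler.
#' @param marker_spacing physical arc length between adjacent markers in mm.
#'   Either a scalar (uniform spacing) or a vector of length `I - 1` giving
#'   per-interval spacings (the tape ends are usually shorter intervals).
#' @param ruler_width physical width of the paper ruler in mm.
#' @param flat_bottom integer indices (into the marker order) of the
#'   landmark pairs lying on the flat bottom; must be a non-empty contiguous
#'   range.
#' @param image_width,image_height image size in pixels.
#' @return an object of class `ruler_annotation`.
#' @export
ruler_annotation <- function(upper_border, lower_border, marker_spacing,
                             ruler_width, flat_bottom,
                             image_width = NA_real_, image_height = NA_real_) {
  up <- as_points(upper_border, "upper_border")
  lo <- as_points(lower_border, "lower_border")
  if (nrow(up) != nrow(lo)) {
    stop_bowl("upper/lower border length mismatch (", nrow(up), " vs ", nrow(lo), ")")
  }
  I <- nrow(up)
  if (I < 4L) stop_bowl("need at least 4 landmark pairs, got ", I)
  check_positive(marker_spacing, "marker_spacing")
  if (!length(marker_spacing) %in% c(1L, I - 1L)) {
    stop_bowl("marker_spacing must be a scalar or have length I - 1 = ", I - 1L)
  }
  check_positive(ruler_width, "ruler_width")
  flat_bottom <- as.integer(flat_bottom)
  if (length(flat_bottom) == 0L) stop_bowl("flat_bottom index set is empty")
  if (any(flat_bottom < 1L | flat_bottom > I)) {
    stop_bowl("flat_bottom indices out of range 1..", I)
  }
  flat_bottom <- sort(unique(flat_bottom))
  if (!all(diff(flat_bottom) == 1L)) stop_bowl("flat_bottom indices must be contiguous")
  structure(
    list(upper_border = up, lower_border = lo,
         marker_spacing = as.numeric(marker_spacing),
         ruler_width = as.numeric(ruler_width),
         flat_bottom = flat_bottom,
         image_width = image_width, image_height = image_height),
    class = "ruler_annotation")
}

#' @export
print.ruler_annotation <- function(x, ...) {
  cat(sprintf("ruler_annotation: %d landmark pairs, ruler width %g mm, flat bottom %d..%d\n",
              nrow(x$upper_border), x$ruler_width,
              min(x$flat_bottom), max(x$flat_bottom)))
  invisible(x)
}

## per-interval spacing vector, broadcasting a scalar spacing
spacing_intervals <- function(a) {
  I <- nrow(a$upper_border)
  if (length(a$marker_spacing) == 1L) rep(a$marker_spacing, I - 1L) else a$marker_spacing
}

#' Read and write ruler annotations
#'
#' The point list lives in a CSV with columns `index`, `border` (`upper` or
#' `lower`), `x_px`, `y_px` in top-left-origin pixel coordinates; physical
#' metadata (`marker_spacing_mm`, `ruler_width_mm`, `flat_bottom` index
#' range, `image_width_px`, `image_height_px`) live in a JSON sidecar.
#'
#' @param csv_path path to the landmark CSV.
#' @param meta_path path to the JSON sidecar; defaults to the CSV path with
#'   the extension replaced by `.json`.
#' @return a [ruler_annotation()] (coordinates converted to the centred
#'   pixel convention).
#' @export
read_ruler_annotation <- function(csv_path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.[^.]*$", ".json", csv_path)
  for (p in c(csv_path, meta_path)) {
    if (!file.exists(p)) stop_bowl("annotation file not found: ", p)
  }
  pts <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("index", "border", "x_px", "y_px")
  if (!all(need %in% names(pts))) {
    stop_bowl("annotation CSV must have columns ", paste(need, collapse = ", "))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("marker_spacing_mm", "ruler_width_mm", "flat_bottom",
                "image_width_px", "image_height_px")) {
    if (is.null(meta[[key]])) stop_bowl("annotation sidecar missing key: ", key)
  }
  up <- pts[pts$border == "upper", ]
  lo <- pts[pts$border == "lower", ]
  if (nrow(up) != nrow(lo)) {
    stop_bowl("upper/lower border length mismatch (", nrow(up), " vs ", nrow(lo), ")")
  }
  up <- up[order(up$index), ]
  lo <- lo[order(lo$index), ]
  if (!identical(up$index, lo$index)) stop_bowl("upper/lower marker indices do not pair up")
  w <- meta$image_width_px
  h <- meta$image_height_px
  ruler_annotation(
    upper_border = cbind(up$x_px - w / 2, up$y_px - h / 2),
    lower_border = cbind(lo$x_px - w / 2, lo$y_px - h / 2),
    marker_spacing = meta$marker_spacing_mm,
    ruler_width = meta$ruler_width_mm,
    flat_bottom = meta$flat_bottom,
    image_width = w, image_height = h)
}

#' @rdname read_ruler_annotation
#' @param a a [ruler_annotation()] object.
#' @export
write_ruler_annotation <- function(a, csv_path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.[^.]*$", ".json", csv_path)
  if (!is.finite(a$image_width) || !is.finite(a$image_height)) {
    stop_bowl("annotation has no image dimensions; cannot write top-left coordinates")
  }
  I <- nrow(a$upper_border)
  df <- data.frame(
    index = rep(seq_len(I), 2L),
    border = rep(c("upper", "lower"), each = I),
    x_px = c(a$upper_border[, 1], a$lower_border[, 1]) + a$image_width / 2,
    y_px = c(a$upper_border[, 2], a$lower_border[, 2]) + a$image_height / 2)
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(marker_spacing_mm = a$marker_spacing, ruler_width_mm = a$ruler_width,
         flat_bottom = a$flat_bottom,
         image_width_px = a$image_width, image_height_px = a$image_height),
    meta_path, auto_unbox = FALSE, digits = NA)
  invisible(csv_path)
}

#' Rim / liquid-surface annotation for a meal image
#'
#' Points on the observed elliptical bowl rim (at least five), optionally
#' points on a flat liquid surface (at least five) and/or pixel counts of
#' the segmented visible liquid and of the region inside the rim.
#'
#' @param rim_points n x 2 matrix of centred pixel coordinates on the rim,
#'   n >= 5.
#' @param surface_points optional n x 2 matrix of centred pixel coordinates
#'   on the liquid surface, n >= 5.
#' @param liquid_pixel_count,rim_pixel_count optional non-negative counts
#'   from an external segmentation, `liquid <= rim`.
#' @return an object of class `rim_annotation`.
#' @export
rim_annotation <- function(rim_points, surface_points = NULL,
                           liquid_pixel_count = NULL, rim_pixel_count = NULL) {
  rim <- as_points(rim_points, "rim_points")
  if (nrow(rim) < 5L) stop_bowl("need at least 5 rim points, got ", nrow(rim))
  if (!is.null(surface_points)) {
    surface_points <- as_points(surface_points, "surface_points")
    if (nrow(surface_points) < 5L) stop_bowl("need at least 5 surface points")
  }
  if (!is.null(liquid_pixel_count) || !is.null(rim_pixel_count)) {
    if (is.null(liquid_pixel_count) || is.null(rim_pixel_count)) {
      stop_bowl("liquid and rim pixel counts must be given together")
    }
    if (rim_pixel_count <= 0 || liquid_pixel_count < 0 ||
        liquid_pixel_count > rim_pixel_count) {
      stop_bowl("pixel counts must satisfy 0 <= liquid <= rim, rim > 0")
    }
  }
  structure(list(rim_points = rim, surface_points = surface_points,
                 liquid_pixel_count = liquid_pixel_count,
                 rim_pixel_count = rim_pixel_count),
            class = "rim_annotation")
}

BOWL_MODEL_FORMAT <- 1L

#' Read and write reconstructed bowl models
#'
#' A bowl model is stored as JSON: the half-profile `rho(z)` sampled on a
#' uniform height grid, the derived diameter, depth and capacity, and a
#' format version.  The round trip is lossless (values are written at full
#' double precision); the derived quantities are recomputed on read and
#' checked against the stored ones.
#'
#' @param model a `bowl_model` (see [revolve_profile()]).
#' @param path file path.
#' @return [read_bowl_model()] returns a `bowl_model`.
#' @export
write_bowl_model <- function(model, path) {
  stopifnot(inherits(model, "bowl_model"))
  jsonlite::write_json(
    list(format = BOWL_MODEL_FORMAT,
         z_mm = model$z, rho_mm = model$rho,
         depth_mm = model$depth, diameter_mm = model$diameter,
         capacity_ml = model$capacity),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bowl_model
#' @export
read_bowl_model <- function(path) {
  if (!file.exists(path)) stop_bowl("bowl model file not found: ", path)
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop_bowl("cannot parse bowl model file: ",
                                              conditionMessage(e)))
  if (is.null(j$format) || j$format != BOWL_MODEL_FORMAT) {
    stop_bowl("unsupported bowl model format version: ", j$format %||% "<missing>")
  }
  if (is.null(j$z_mm) || is.null(j$rho_mm) || length(j$z_mm) != length(j$rho_mm)) {
    stop_bowl("bowl model file is corrupt: profile arrays missing or mismatched")
  }
  m <- revolve_profile(half_profile(z = j$z_mm, rho = j$rho_mm))
  ## stored derived values must agree with the profile they came from
  if (abs(m$capacity - j$capacity_ml) > 1e-3 * max(1, j$capacity_ml)) {
    stop_bowl("stored capacity inconsistent with stored profile")
  }
  m
}

#' Export a bowl model as a Wavefront OBJ mesh
#'
#' Revolves the half-profile into a triangle mesh for visual inspection.
#' The mesh is for display only; all volume arithmetic uses the profile.
#'
#' @param model a `bowl_model`.
#' @param path output `.obj` path.
#' @param n_around number of vertices around the axis of revolution.
#' @param n_along number of profile samples along the wall.
#' @export
export_bowl_obj <- function(model, path, n_around = 72L, n_along = 40L) {
  stopifnot(inherits(model, "bowl_model"))
  zi <- seq(0, model$depth, length.out = n_along)
  ri <- stats::approx(model$z, model$rho, xout = zi, rule = 2)$y
  ang <- seq(0, 2 * pi, length.out = n_around + 1L)[seq_len(n_around)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bowl interior surface of revolution", con)
  for (i in seq_len(n_along)) {
    for (a in ang) {
      writeLines(sprintf("v %.6f %.6f %.6f",
                         ri[i] * cos(a), ri[i] * sin(a), zi[i]), con)
    }
  }
  idx <- function(i, j) (i - 1L) * n_around + ((j - 1L) %% n_around) + 1L
  for (i in seq_len(n_along - 1L)) {
    for (j in seq_len(n_around)) {
      writeLines(c(sprintf("f %d %d %d", idx(i, j), idx(i, j + 1L), idx(i + 1L, j)),
                   sprintf("f %d %d %d", idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j))),
                 con)
    }
  }
  invisible(path)
}
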