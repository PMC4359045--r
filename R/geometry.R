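#' Read a binary cortical profile mask
#'
#' Reads a PNG (or, with the tiff package installed, a TIFF) image and
#' thresholds it at 0.5: cortical bone is the bright foreground, background
#' dark, following the usual white-cortex-on-black convention of traced bone
#' profiles.
#'
#' @param path image path (`.png`, `.tif`, `.tiff`)
#' @param pixel_scale physical size of one pixel (e.g. mm/px)
#' @return object of class `cortical_profile`: list with `mask` (logical
#'   matrix), `pixel_scale`
#' @export
read_profile_mask <- function(path, pixel_scale) {
  stopifnot(pixel_scale > 0)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  cortical_profile(img > 0.5, pixel_scale)
}

#' Construct a cortical profile from a logical mask
#'
#' @param mask logical (or 0/1) matrix, cortex = TRUE
#' @param pixel_scale physical size of one pixel
#' @return object of class `cortical_profile`
#' @export
cortical_profile <- function(mask, pixel_scale) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  stopifnot(pixel_scale > 0)
  if (!any(mask)) stop("empty mask: no foreground pixels")
  structure(list(mask = mask, pixel_scale = pixel_scale),
            class = "cortical_profile")
}

#' Write a profile mask as PNG
#' @param profile a `cortical_profile`
#' @param path output path; a sidecar `<path>.scale.txt` records the pixel scale
#' @export
write_profile_mask <- function(profile, path) {
  png::writePNG(profile$mask * 1, path)
  writeLines(format(profile$pixel_scale, digits = 17),
             paste0(path, ".scale.txt"))
  invisible(path)
}

## background pixels connected to the image border (i.e. outside the section)
.outside_mask <- function(mask) {
  bg <- EBImage::bwlabel(!mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  array(bg %in% border_labels, dim(mask))
}

#' Cortical and total area of a profile
#'
#' CA is the area of the cortical bone itself (foreground pixel count times
#' pixel area); TA is the area enclosed by the periosteal boundary, i.e. the
#' cortex plus any enclosed medullary cavity. The centroid is the area
#' centroid of the cortex in physical units (x = column direction, y = row
#' direction, origin at the first pixel centre).
#'
#' @param profile a `cortical_profile`
#' @return list with `CA`, `TA`, `centroid` (length-2, physical units)
#' @export
compute_areas <- function(profile) {
  m <- profile$mask
  s <- profile$pixel_scale
  filled <- !.outside_mask(m)
  idx <- which(m, arr.ind = TRUE)
  centroid <- c(x = mean(idx[, 2]), y = mean(idx[, 1])) * s
  list(CA = sum(m) * s^2, TA = sum(filled) * s^2, centroid = centroid)
}

#' Principal second moments of area
#'
#' Second-moment tensor of the cortical area about its centroid (midpoint
#' rule: each foreground pixel contributes its area at its centre),
#' eigen-decomposed into the principal moments Imax >= Imin and the principal
#' axis angle.
#'
#' @param profile a `cortical_profile`
#' @return list with `Imax`, `Imin` (physical units^4), `angle` (degrees,
#'   major principal axis), `centroid`
#' @export
compute_second_moments <- function(profile) {
  m <- profile$mask
  s <- profile$pixel_scale
  idx <- which(m, arr.ind = TRUE)
  if (length(unique(idx[, 1])) < 2 && length(unique(idx[, 2])) < 2)
    stop("degenerate mask: foreground spans a single row and column")
  x <- idx[, 2] - mean(idx[, 2])
  y <- idx[, 1] - mean(idx[, 1])
  a <- s^2                               # pixel area
  Ixx <- sum(y^2) * s^2 * a              # about horizontal axis
  Iyy <- sum(x^2) * s^2 * a
  Ixy <- sum(x * y) * s^2 * a
  tens <- matrix(c(Ixx, -Ixy, -Ixy, Iyy), 2, 2)
  e <- eigen(tens, symmetric = TRUE)
  # principal direction of the *max* moment; angle of the associated axis of
  # bending is perpendicular to the eigenvector of the inertia tensor
  v <- e$vectors[, 1]
  list(Imax = e$values[1], Imin = e$values[2],
       angle = (atan2(v[2], v[1]) * 180 / pi) %% 180,
       centroid = c(x = mean(idx[, 2]), y = mean(idx[, 1])) * s)
}

#' Polar moment and polar section modulus
#'
#' By the perpendicular-axis identity J = Imax + Imin. The polar section
#' modulus Zp divides J by the section's moment arm: by default `r_max`, the
#' maximum distance from the area centroid to the periosteal (outer)
#' boundary; `radius = "mean"` uses the mean periosteal radius instead.
#'
#' @param profile a `cortical_profile`
#' @param moments optional result of [compute_second_moments()] (recomputed
#'   if missing)
#' @param radius `"max"` (default) or `"mean"` periosteal radius for the
#'   moment arm
#' @return list with `J`, `r`, `Zp`
#' @export
compute_polar_modulus <- function(profile, moments = NULL,
                                  radius = c("max", "mean")) {
  radius <- match.arg(radius)
  if (is.null(moments)) moments <- compute_second_moments(profile)
  m <- profile$mask
  s <- profile$pixel_scale
  outside <- .outside_mask(m)
  # periosteal boundary: foreground pixels 4-adjacent to the outside
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(mm, dr, dc) {
    out <- matrix(TRUE, nr, nc)
    out[max(1, 1 + dr):min(nr, nr + dr), max(1, 1 + dc):min(nc, nc + dc)] <-
      mm[max(1, 1 - dr):min(nr, nr - dr), max(1, 1 - dc):min(nc, nc - dc)]
    out
  }
  nb_out <- pad(outside, 1, 0) | pad(outside, -1, 0) |
            pad(outside, 0, 1) | pad(outside, 0, -1)
  boundary <- m & nb_out
  idx <- which(boundary, arr.ind = TRUE)
  cen <- moments$centroid / s
  d <- sqrt((idx[, 2] - cen["x"])^2 + (idx[, 1] - cen["y"])^2) * s
  r <- if (radius == "max") max(d) else mean(d)
  J <- moments$Imax + moments$Imin
  list(J = J, r = unname(r), Zp = unname(J / r))
}

#' Full cross-sectional geometry of a cortical profile
#'
#' Convenience wrapper computing CA, TA, centroid, Imax, Imin, J, r, Zp and
#' the shape ratio Imax/Imin in one pass, with an advisory circularity
#' caution (see [circularity_caution()]).
#'
#' @param profile a `cortical_profile`
#' @param radius moment-arm convention, see [compute_polar_modulus()]
#' @param shape_ratio_threshold threshold for the circularity caution
#' @return object of class `section_geometry`: list with the fields above
#'   plus `shape_ratio` and `caution`
#' @export
section_geometry <- function(profile, radius = c("max", "mean"),
                             shape_ratio_threshold = 1.5) {
  radius <- match.arg(radius)
  areas <- compute_areas(profile)
  mom <- compute_second_moments(profile)
  pol <- compute_polar_modulus(profile, mom, radius)
  g <- structure(list(
    CA = areas$CA, TA = areas$TA, centroid = areas$centroid,
    Imax = mom$Imax, Imin = mom$Imin, principal_angle = mom$angle,
    J = pol$J, r = pol$r, Zp = pol$Zp,
    shape_ratio = mom$Imax / mom$Imin), class = "section_geometry")
  g$caution <- circularity_caution(g, shape_ratio_threshold)
  g
}

#' Circularity caution for strongly elliptical sections
#'
#' Zp estimates torsional rigidity well only for near-circular sections; this
#' flags (with a message) sections whose shape ratio Imax/Imin exceeds a
#' threshold. Values are never altered.
#'
#' @param geometry a `section_geometry` (or any list with `shape_ratio`)
#' @param threshold shape-ratio threshold, default 1.5 (use `Inf` to disable)
#' @return logical flag, invisibly usable
#' @export
circularity_caution <- function(geometry, threshold = 1.5) {
  flag <- is.finite(threshold) && geometry$shape_ratio > threshold
  if (flag)
    message(sprintf(
      "section is strongly elliptical (Imax/Imin = %.2f > %.2f); Zp is only a heuristic",
      geometry$shape_ratio, threshold))
  flag
}

#' @export
print.section_geometry <- function(x, ...) {
  cat("Cross-sectional geometry\n")
  cat(sprintf("  CA = %.4g  TA = %.4g\n", x$CA, x$TA))
  cat(sprintf("  Imax = %.4g  Imin = %.4g  (shape ratio %.3f)\n",
              x$Imax, x$Imin, x$shape_ratio))
  cat(sprintf("  J = %.4g  r = %.4g  Zp = %.4g\n", x$J, x$r, x$Zp))
  invisible(x)
}
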