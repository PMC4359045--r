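## Image-side canal morphometry: octant extraction, periosteal straightening
## with deformation validation, branched-canal splitting, moment-based
## ellipse fitting. Image convention throughout: matrices indexed
## [row = y, col = x]; angles in degrees from the +x (column) axis toward
## +y (row) axis; pixel units unless stated.

#' Extract the four cardinal cortical octants of a ring section
#'
#' Divides the cortex into eight 45-degree sectors about the section
#' centroid and returns the four centred on the anatomical axes (the
#' diagonal octants are excluded). Each octant carries its sub-mask and a
#' periosteal contour segment obtained by radial ray casting.
#'
#' @param mask logical matrix, cortical ring = TRUE; must enclose a
#'   medullary cavity
#' @param axes_angle orientation of the first anatomical axis, degrees
#'   (default 0)
#' @param labels cardinal labels for the octants at `axes_angle` + 0, 90,
#'   180, 270 degrees
#' @param angle_step ray-casting step along the contour, degrees
#' @return list of four octant objects (class `cortical_octant`): `label`,
#'   `angle_center` (deg), `mask` (full-size logical), `contour`
#'   (matrix of x, y pixel coordinates along the periosteal surface),
#'   `center` (section centroid, px)
#' @export
extract_cardinal_octants <- function(mask, axes_angle = 0,
                                     labels = c("anterior", "lateral",
                                                "posterior", "medial"),
                                     angle_step = 0.05) {
  stopifnot(is.matrix(mask), length(labels) == 4)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  ## ring check: cavity = background not connected to the border
  cavity <- !mask & !.outside_mask(mask)
  if (!any(cavity))
    stop("mask is not ring-like: no enclosed medullary cavity")
  ctr <- c(x = mean(idx[, 2]), y = mean(idx[, 1]))
  ang <- (atan2(idx[, 1] - ctr["y"], idx[, 2] - ctr["x"]) * 180 / pi) %% 360
  out <- vector("list", 4)
  for (k in 0:3) {
    a0 <- (axes_angle + 90 * k) %% 360
    dd <- (ang - a0 + 180) %% 360 - 180
    sel <- abs(dd) <= 22.5
    sub <- matrix(FALSE, nrow(mask), ncol(mask))
    sub[idx[sel, , drop = FALSE]] <- TRUE
    contour <- .trace_outer_contour(mask, ctr, a0 - 22.5, a0 + 22.5,
                                    angle_step)
    out[[k + 1]] <- structure(
      list(label = labels[k + 1], angle_center = a0, mask = sub,
           contour = contour, center = ctr), class = "cortical_octant")
  }
  names(out) <- labels
  out
}

## periosteal contour by radial ray casting between two polar angles
.trace_outer_contour <- function(mask, ctr, a_from, a_to, angle_step) {
  angs <- seq(a_from, a_to, by = angle_step) * pi / 180
  rmax_img <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  radii <- seq(1, rmax_img, by = 0.5)
  pts <- matrix(NA_real_, length(angs), 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_along(angs)) {
    px <- ctr["x"] + radii * cos(angs[i])
    py <- ctr["y"] + radii * sin(angs[i])
    ok <- which(px >= 1 & px <= ncol(mask) & py >= 1 & py <= nrow(mask))
    hit <- ok[mask[cbind(round(py[ok]), round(px[ok]))]]
    if (length(hit) == 0) next
    pts[i, ] <- c(px[max(hit)], py[max(hit)])
  }
  pts[stats::complete.cases(pts), , drop = FALSE]
}

#' Straighten a cortical octant relative to its periosteal surface
#'
#' Resamples the octant into a frame whose horizontal axis is arc length
#' along the (smoothed) periosteal contour and whose vertical axis is depth
#' along the inward normal, so the periosteal surface maps to the top row
#' and becomes the constant tangent reference line. Sampling is bilinear at
#' unit-pixel steps. The transform is rejected with a diagnostic when the
#' contour's curvature radius is smaller than the sampled depth (fold-over).
#'
#' @param image numeric or logical matrix to resample (e.g. the section or
#'   the canal mask)
#' @param octant a `cortical_octant` from [extract_cardinal_octants()]
#' @param depth sampled cortical depth in px (default: estimated by probing
#'   the section mask along the normals, plus 2 px)
#' @param smooth_window contour smoothing window in px (default 24; about
#'   50 micrometres at histology resolution)
#' @param step arc-length sampling step in px
#' @return object of class `straightened_octant`: `image` (rows = depth,
#'   cols = arc length), `contour`, `tangent`, `normal` (resampled, px),
#'   `map_forward(s, d)` mapping straightened to original pixel
#'   coordinates, `map_inverse(xy)` mapping original points to (s, d),
#'   `step`, `depth`
#' @export
straighten_octant <- function(image, octant, depth = NULL,
                              smooth_window = 24, step = 1) {
  stopifnot(step > 0)
  C <- octant$contour
  if (nrow(C) < 8) stop("contour segment too short")
  ## two-pass smoothing: once on the ray-cast polyline (pixel-quantization
  ## noise), then again after arc-length resampling, so tangents are stable
  spacing <- mean(sqrt(diff(C[, "x"])^2 + diff(C[, "y"])^2))
  ## the window must stay well below the segment length or curvature is lost
  w1 <- max(1, min(round(smooth_window / spacing), nrow(C) %/% 4))
  sm <- function(v, w) {
    if (w <= 1) return(v)
    h <- ceiling(w / 2)
    ## reflect the series at both ends so the window never shrinks
    vp <- c(2 * v[1] - v[(h + 1):2], v, 2 * v[length(v)] -
              v[(length(v) - 1):(length(v) - h)])
    out <- as.numeric(stats::filter(vp, rep(1 / w, w), sides = 2))
    out[(h + 1):(h + length(v))]
  }
  xs <- sm(C[, "x"], w1); ys <- sm(C[, "y"], w1)
  arc <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  s_grid <- seq(0, max(arc), by = step)
  cx <- stats::approx(arc, xs, s_grid)$y
  cy <- stats::approx(arc, ys, s_grid)$y
  n_s <- length(s_grid)
  w2 <- max(1, min(round(smooth_window / step), n_s %/% 4))
  cx <- sm(cx, w2); cy <- sm(cy, w2)
  tx <- .cgrad(cx); ty <- .cgrad(cy)
  tl <- sqrt(tx^2 + ty^2); tx <- tx / tl; ty <- ty / tl
  ## inward normal: rotate tangent by 90 deg, orient toward section centre
  nx <- -ty; ny <- tx
  toc_x <- octant$center["x"] - cx; toc_y <- octant$center["y"] - cy
  flip <- (nx * toc_x + ny * toc_y) < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]

  if (is.null(depth)) {
    probe <- seq(0, max(nrow(image), ncol(image)) / 2, by = 1)
    dmax <- 0
    for (i in seq(1, n_s, length.out = min(40, n_s))) {
      px <- cx[i] + probe * nx[i]; py <- cy[i] + probe * ny[i]
      ok <- px >= 1 & px <= ncol(image) & py >= 1 & py <= nrow(image)
      inside <- (image[cbind(round(py[ok]), round(px[ok]))] > 0.5)
      run <- which(!inside)
      dmax <- max(dmax, if (length(run)) probe[ok][run[1]] else max(probe[ok]))
    }
    depth <- ceiling(dmax) + 2
  }
  ## signed curvature (positive when the inward normals converge, i.e. a
  ## convex periosteal surface); fold-over gate: curvature radius must
  ## exceed the sampled depth
  dtx <- .cgrad(tx); dty <- .cgrad(ty)
  curv_signed <- (dtx * nx + dty * ny) / step
  curv <- sqrt(dtx^2 + dty^2) / step
  min_radius <- 1 / max(curv, 1e-12)
  if (min_radius < depth)
    stop(sprintf(
      "straightening fold-over: curvature radius %.1f px < sampled depth %d px",
      min_radius, depth))

  d_grid <- seq(0, depth, by = step)
  PX <- outer(d_grid, nx) + matrix(cx, length(d_grid), n_s, byrow = TRUE)
  PY <- outer(d_grid, ny) + matrix(cy, length(d_grid), n_s, byrow = TRUE)
  img <- matrix(.bilinear(image, PX, PY), length(d_grid), n_s)

  map_forward <- function(s, d) {
    i <- pmin(pmax(s / step, 0), n_s - 1)
    i0 <- floor(i); f <- i - i0
    i0 <- i0 + 1; i1 <- pmin(i0 + 1, n_s)
    bx <- (1 - f) * cx[i0] + f * cx[i1]
    by <- (1 - f) * cy[i0] + f * cy[i1]
    bnx <- (1 - f) * nx[i0] + f * nx[i1]
    bny <- (1 - f) * ny[i0] + f * ny[i1]
    cbind(x = bx + d * bnx, y = by + d * bny)
  }
  map_inverse <- function(xy) {
    xy <- matrix(xy, ncol = 2)
    t(apply(xy, 1, function(p) {
      dx <- p[1] - cx; dy <- p[2] - cy
      dd <- dx * nx + dy * ny
      res <- (dx - dd * nx)^2 + (dy - dd * ny)^2
      k <- which.min(res)
      c(s = s_grid[k] + dx[k] * tx[k] + dy[k] * ty[k], d = dd[k])
    }))
  }
  structure(list(image = img, contour = cbind(x = cx, y = cy),
                 tangent = cbind(tx, ty), normal = cbind(nx, ny),
                 map_forward = map_forward, map_inverse = map_inverse,
                 curvature = curv_signed,
                 step = step, depth = depth, s_grid = s_grid),
            class = "straightened_octant")
}

## central-difference gradient with one-sided ends
.cgrad <- function(v) {
  n <- length(v)
  c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
}

## vectorized bilinear interpolation; 0 outside the image
.bilinear <- function(img, X, Y) {
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  x0 <- floor(X); y0 <- floor(Y)
  fx <- X - x0; fy <- Y - y0
  val <- numeric(length(X))
  ok <- x0 >= 1 & x0 + 1 <= ncol(img) & y0 >= 1 & y0 + 1 <= nrow(img)
  g <- function(r, c) img[cbind(r[ok], c[ok])]
  val[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * g(y0, x0) +
             fx[ok] * (1 - fy[ok]) * g(y0, x0 + 1) +
             (1 - fx[ok]) * fy[ok] * g(y0 + 1, x0) +
             fx[ok] * fy[ok] * g(y0 + 1, x0 + 1)
  val
}

#' Validate a straightening transform with test angles and circles
#'
#' Overlays known test angles (short segments at stated angles to the local
#' periosteal tangent) and circular profiles on the original frame, pushes
#' them through the straightening map, and reports the maximum angular
#' deviation and the aspect-ratio range of the transformed circles. A
#' transform is conventionally acceptable when angles deviate by at most 5
#' degrees and circle aspect ratios stay within 1.00-1.17.
#'
#' @param st a `straightened_octant`
#' @param test_angles angles to the tangent, degrees
#' @param test_depths depths (px) at which to place the probes (default:
#'   25%, 50%, 75% of the sampled depth)
#' @param circle_radius radius of the test circles, px
#' @param segment_length test segment length, px
#' @return object of class `deformation_report`: `max_angle_deviation`
#'   (deg), `aspect_ratio_range` (length 2), `pass` (logical, 5 deg / 1.17
#'   gates)
#' @export
validate_straightening <- function(st, test_angles = c(0, 30, 45, 60, 90),
                                   test_depths = NULL, circle_radius = 5,
                                   segment_length = 10) {
  if (is.null(test_depths))
    test_depths <- round(st$depth * c(0.25, 0.5, 0.75))
  n_s <- length(st$s_grid)
  s_pos <- st$s_grid[round(seq(0.15, 0.85, length.out = 5) * n_s)]
  devs <- numeric(0); ratios <- numeric(0)
  for (s0 in s_pos) {
    k <- which.min(abs(st$s_grid - s0))
    tvec <- st$tangent[k, ]; nvec <- st$normal[k, ]
    for (d0 in test_depths) {
      p0 <- st$map_forward(s0, d0)
      for (a in test_angles) {
        u <- cos(a * pi / 180) * tvec + sin(a * pi / 180) * nvec
        e1 <- st$map_inverse(p0 - segment_length / 2 * rbind(u))
        e2 <- st$map_inverse(p0 + segment_length / 2 * rbind(u))
        meas <- atan2(e2[2] - e1[2], e2[1] - e1[1]) * 180 / pi
        dev <- abs(((meas - a) + 90) %% 180 - 90)
        devs <- c(devs, dev)
      }
      tt <- seq(0, 2 * pi, length.out = 72)[-72]
      circ <- cbind(p0[1] + circle_radius * cos(tt),
                    p0[2] + circle_radius * sin(tt))
      sd_ <- st$map_inverse(circ)
      cc <- stats::cov(sd_)
      ev <- eigen(cc, symmetric = TRUE)$values
      ratios <- c(ratios, sqrt(ev[1] / max(ev[2], 1e-12)))
    }
  }
  structure(list(max_angle_deviation = max(devs),
                 aspect_ratio_range = range(ratios),
                 pass = max(devs) <= 5 && max(ratios) <= 1.17),
            class = "deformation_report")
}

#' @export
print.deformation_report <- function(x, ...) {
  cat(sprintf(
    "Straightening deformation: max angle deviation %.2f deg; circle aspect ratios %.3f-%.3f (%s)\n",
    x$max_angle_deviation, x$aspect_ratio_range[1], x$aspect_ratio_range[2],
    if (x$pass) "acceptable" else "FAILS 5 deg / 1.17 gates"))
  invisible(x)
}

## 8-connected labelling of a logical matrix by flood fill (small regions)
.label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask)
  todo <- which(mask)
  cur <- 0L
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  row_of <- function(i) ((i - 1L) %% nr) + 1L
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- p + offs
      r <- row_of(p)
      ok <- nb >= 1L & nb <= length(mask) &
        abs(row_of(nb) - r) <= 1L
      nb <- nb[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  lab
}

## Zhang-Suen thinning of a logical matrix to a 1-px skeleton
.zhang_suen <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  pad <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  m <- pad
  nr <- nrow(m); nc <- ncol(m)
  nb <- function(mm) {
    P <- function(dr, dc) mm[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
    list(p2 = P(-1, 0), p3 = P(-1, 1), p4 = P(0, 1), p5 = P(1, 1),
         p6 = P(1, 0), p7 = P(1, -1), p8 = P(0, -1), p9 = P(-1, -1))
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      v <- nb(m)
      core <- m[2:(nr - 1), 2:(nc - 1)]
      B <- v$p2 + v$p3 + v$p4 + v$p5 + v$p6 + v$p7 + v$p8 + v$p9
      seqs <- list(v$p2, v$p3, v$p4, v$p5, v$p6, v$p7, v$p8, v$p9, v$p2)
      A <- Reduce(`+`, lapply(1:8, function(i)
        (seqs[[i]] == 0) & (seqs[[i + 1]] == 1)))
      if (phase == 1) {
        cond <- core == 1 & B >= 2 & B <= 6 & A == 1 &
          (v$p2 * v$p4 * v$p6 == 0) & (v$p4 * v$p6 * v$p8 == 0)
      } else {
        cond <- core == 1 & B >= 2 & B <= 6 & A == 1 &
          (v$p2 * v$p4 * v$p8 == 0) & (v$p2 * v$p6 * v$p8 == 0)
      }
      if (any(cond)) {
        core[cond] <- 0L
        m[2:(nr - 1), 2:(nc - 1)] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nr - 1), 2:(nc - 1)] == 1
}

#' Split a branched canal region at its skeleton junctions
#'
#' Skeletonizes a connected canal region (Zhang-Suen thinning), finds
#' junction pixels (skeleton pixels with three or more skeleton
#' neighbours), removes them to cut the skeleton into branch-free arms, and
#' assigns every region pixel to the nearest arm. An unbranched region is
#' returned unchanged. The union of the output regions equals the input
#' region.
#'
#' @param region logical matrix, a single connected canal region
#' @return list of logical matrices, one branch-free region each
#' @export
split_branched_canal <- function(region) {
  stopifnot(is.logical(region) || all(region %in% c(0, 1)))
  region <- matrix(as.logical(region), nrow(region), ncol(region))
  skel <- .zhang_suen(region)
  sk_idx <- which(skel, arr.ind = TRUE)
  if (nrow(sk_idx) == 0) return(list(region))
  ## candidate junction pixels have >= 3 skeleton neighbours; cut them (with
  ## a one-pixel dilation, or arms stay 8-connected through their
  ## neighbours) and count the substantial arms that remain. Fewer than
  ## three real arms means the candidates were staircase/spur artifacts of
  ## the thinning, not a branch point.
  cand <- skel & .neighbour_count(skel) >= 3
  if (!any(cand)) return(list(region))
  cand_d <- cand | (.neighbour_count(cand) > 0)
  arms <- .label8(skel & !cand_d)
  sizes <- tabulate(arms[arms > 0])
  if (length(sizes) == 0) return(list(region))
  real <- which(sizes >= max(5, 0.25 * max(sizes)))
  if (length(real) <= 2) return(list(region))
  arms[!(arms %in% real)] <- 0L
  arms[arms > 0] <- match(arms[arms > 0], real)
  n_arm <- length(real)
  ## assign every region pixel to the nearest arm pixel
  reg_idx <- which(region, arr.ind = TRUE)
  arm_idx <- which(arms > 0, arr.ind = TRUE)
  arm_lab <- arms[arms > 0]
  assign <- apply(reg_idx, 1, function(p) {
    d <- (arm_idx[, 1] - p[1])^2 + (arm_idx[, 2] - p[2])^2
    arm_lab[which.min(d)]
  })
  lapply(seq_len(n_arm), function(k) {
    out <- matrix(FALSE, nrow(region), ncol(region))
    out[reg_idx[assign == k, , drop = FALSE]] <- TRUE
    out
  })
}

## count of 8-neighbours that are TRUE
.neighbour_count <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  nr <- nrow(m) + 2; nc <- ncol(m) + 2
  pad <- matrix(0L, nr, nc)
  pad[2:(nr - 1), 2:(nc - 1)] <- m
  s <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + pad[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
  }
  s
}

#' Fit a moment-matched ellipse to a canal pixel region
#'
#' Matches an ellipse to the region's area centroid and second moments
#' (with the per-pixel 1/12 correction), the standard construction for
#' canal cross sections. Regions under 5 pixels are rejected as unstable.
#'
#' @param region logical matrix, or a 2-column matrix of (row, col) pixel
#'   indices
#' @param pixel_scale physical size of one pixel (default 1: pixel units)
#' @return list with `centroid` (x, y), `major`, `minor` (full axis
#'   lengths), `angle` (degrees in \[0, 180)), `aspect_ratio`, `n_pixels`
#' @export
fit_canal_ellipse <- function(region, pixel_scale = 1) {
  idx <- if (is.matrix(region) && ncol(region) == 2 && !is.logical(region))
    region else which(region, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 5) stop("region has fewer than 5 pixels; ellipse fit unstable")
  x <- idx[, 2]; y <- idx[, 1]
  if (stats::sd(x) == 0 && stats::sd(y) == 0) stop("degenerate region")
  cxx <- stats::var(x) * (n - 1) / n + 1 / 12
  cyy <- stats::var(y) * (n - 1) / n + 1 / 12
  cxy <- stats::cov(x, y) * (n - 1) / n
  raw <- eigen(matrix(c(stats::var(x), stats::cov(x, y),
                        stats::cov(x, y), stats::var(y)), 2, 2),
               symmetric = TRUE)$values
  if (raw[2] <= 1e-12) stop("degenerate (collinear) region")
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  v <- e$vectors[, 1]
  list(centroid = c(x = mean(x), y = mean(y)) * pixel_scale,
       major = 4 * sqrt(e$values[1]) * pixel_scale,
       minor = 4 * sqrt(e$values[2]) * pixel_scale,
       angle = (atan2(v[2], v[1]) * 180 / pi) %% 180,
       aspect_ratio = sqrt(e$values[1] / e$values[2]),
       n_pixels = n)
}

#' Measure and classify all canals of a simulated field, end to end
#'
#' Runs the full measurement pipeline on a [simulate_canal_field()] result:
#' extracts the four cardinal octants, straightens each (section and canal
#' masks through the same map), labels canal regions in the straightened
#' frame, fits ellipses (regions under `min_pixels` dropped with a logged
#' count; regions clipped by the octant window skipped), measures
#' orientation against the now-horizontal periosteal tangent, classifies,
#' and matches each detection back to the nearest true canal for scoring.
#' Because uncurving stretches deeper tissue tangentially by a known factor
#' 1/(1 - kappa d), each region is measured after rescaling its tangential
#' offsets by the local metric (curvature compensation); this removes the
#' systematic downward bias in the measured angle near the class
#' boundaries.
#'
#' @param field a `canal_field`
#' @param axes_angle anatomical axis orientation, degrees
#' @param min_pixels minimum region size for ellipse fitting
#' @return list with `measurements` (data frame: octant, s/d centroid,
#'   mapped x/y in micrometres, aspect_ratio, theta, class, true_class),
#'   `octants`, `reports` (deformation reports per octant),
#'   `n_dropped` (undersized regions)
#' @export
analyze_canal_field <- function(field, axes_angle = 0, min_pixels = 5) {
  octs <- extract_cardinal_octants(field$mask, axes_angle)
  res <- list(); reports <- list(); dropped <- 0L
  for (oc in octs) {
    st <- straighten_octant(field$mask, oc)
    reports[[oc$label]] <- validate_straightening(st)
    stc <- straighten_octant(field$canal_mask, oc, depth = st$depth)
    cm <- stc$image >= 0.5
    labs <- .label8(cm)
    for (k in seq_len(max(labs, 0))) {
      idx <- which(labs == k, arr.ind = TRUE)
      ## regions clipped by the octant window are not fully measurable
      if (any(idx[, 1] %in% c(1L, nrow(cm))) ||
          any(idx[, 2] %in% c(1L, ncol(cm)))) next
      if (nrow(idx) < min_pixels) { dropped <- dropped + 1L; next }
      ## curvature compensation: uncurving stretches the tangential axis of
      ## deeper tissue by 1/(1 - kappa d); undo it about the region centroid
      ## so orientation and aspect are measured in the true local metric
      d_px <- (idx[, 1] - 1) * st$step
      s_ctr <- mean(idx[, 2])
      kap <- st$curvature[round(s_ctr)]
      corr <- idx
      corr[, 2] <- s_ctr + (idx[, 2] - s_ctr) * (1 - kap * d_px)
      fit <- fit_canal_ellipse(corr)
      fit_raw <- fit_canal_ellipse(idx)
      fit$centroid <- fit_raw$centroid
      m <- measure_canal(fit$major, fit$minor, fit$angle, tangent_angle = 0)
      orig <- st$map_forward(fit$centroid["x"] - 1, fit$centroid["y"] - 1)
      ox_um <- (orig[1] - field$center["x"]) * field$pixel_scale
      oy_um <- (orig[2] - field$center["y"]) * field$pixel_scale
      true_cls <- NA_character_
      if (nrow(field$canals) > 0) {
        d2 <- (field$canals$x - ox_um)^2 + (field$canals$y - oy_um)^2
        true_cls <- field$canals$class_true[which.min(d2)]
      }
      res[[length(res) + 1]] <- data.frame(
        octant = oc$label, x_um = ox_um, y_um = oy_um,
        aspect_ratio = m$aspect_ratio, theta = m$theta,
        class = classify_canal(m$aspect_ratio, m$theta),
        true_class = true_cls, stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0)
    message(sprintf("dropped %d undersized canal region(s) (< %d px)",
                    dropped, min_pixels))
  measurements <- if (length(res)) do.call(rbind, res) else
    data.frame(octant = character(0), x_um = numeric(0), y_um = numeric(0),
               aspect_ratio = numeric(0), theta = numeric(0),
               class = character(0), true_class = character(0))
  list(measurements = measurements, octants = octs, reports = reports,
       n_dropped = dropped)
}
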