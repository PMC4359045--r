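## Synthetic-data generators. Every generator takes an integer seed and is
## bit-reproducible; the RNG state of the caller is restored on exit.

#' Simulate a labeled vascular canal field on an annular cortex
#'
#' Places elliptical canals inside an annular cortical ring with controlled
#' orientation-class proportions. Canal angles are drawn relative to the
#' local periosteal tangent (the tangent of the outer circle at the canal's
#' polar angle), so the true class labels are exact under the classifier's
#' own angle convention: circumferential and radial canals are uniform
#' within their closed +/-22.5 degree bands, oblique canals uniform in the
#' open (22.5, 67.5) degree band with random sign, and longitudinal canals
#' get an aspect ratio uniform in \[1, 3) with arbitrary angle. Canal
#' centroids are kept non-overlapping by rejection sampling.
#'
#' @param n_canals number of canals, `>= 0`
#' @param class_proportions named fractions over
#'   `c("longitudinal", "circumferential", "radial", "oblique")`; must sum
#'   to 1 (tolerance 1e-9)
#' @param outer_radius,inner_radius annulus radii in micrometres
#'   (`inner_radius < outer_radius`); the defaults keep the curvature
#'   radius at 10x the cortical thickness, the gently-curved regime in
#'   which straightening deformation stays within its acceptance gates
#' @param pixel_scale micrometres per pixel (default 2.1, typical of
#'   high-resolution histology montages)
#' @param major_range range of full major-axis lengths, micrometres
#' @param aspect_range aspect-ratio range for the non-longitudinal classes
#'   (must be `>= 3`)
#' @param seed integer seed
#' @return object of class `canal_field`: list with `canals` (data frame:
#'   `x`, `y`, `major`, `minor`, `angle`, `theta_true`, `class_true`,
#'   `secondary`), `mask` (annulus, logical matrix), `canal_mask` (logical
#'   matrix), `center` (px), `outer_radius`, `inner_radius`, `pixel_scale`
#' @export
simulate_canal_field <- function(n_canals,
                                 class_proportions = c(longitudinal = 0.25,
                                                       circumferential = 0.25,
                                                       radial = 0.25,
                                                       oblique = 0.25),
                                 outer_radius = 2000, inner_radius = 1800,
                                 pixel_scale = 2.1,
                                 major_range = c(30, 55),
                                 aspect_range = c(3.2, 6),
                                 seed = 1) {
  classes <- c("longitudinal", "circumferential", "radial", "oblique")
  stopifnot(n_canals >= 0, inner_radius < outer_radius, inner_radius > 0,
            all(names(class_proportions) %in% classes),
            aspect_range[1] >= 3)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  restore <- .Random.seed_safe_set(seed)
  on.exit(restore())

  ## annulus mask
  npx <- 2 * ceiling(outer_radius / pixel_scale) + 9
  ctr <- (npx + 1) / 2
  xs <- ((1:npx) - ctr) * pixel_scale
  r2 <- outer(xs^2, xs^2, "+")            # [row=y, col=x]
  mask <- r2 <= outer_radius^2 & r2 >= inner_radius^2
  canal_mask <- matrix(FALSE, npx, npx)

  cols <- c("x", "y", "major", "minor", "angle", "theta_true")
  canals <- as.data.frame(matrix(numeric(0), 0, length(cols),
                                 dimnames = list(NULL, cols)))
  canals$class_true <- character(0)
  if (n_canals > 0) {
    p <- stats::setNames(rep(0, 4), classes)
    p[names(class_proportions)] <- class_proportions
    lab <- sample(classes, n_canals, replace = TRUE, prob = p)
    major <- stats::runif(n_canals, major_range[1], major_range[2])
    aspect <- ifelse(lab == "longitudinal",
                     stats::runif(n_canals, 1, 3),
                     stats::runif(n_canals, aspect_range[1], aspect_range[2]))
    minor <- major / aspect
    theta <- numeric(n_canals)              # angle to local tangent, [0,90]
    theta[lab == "circumferential"] <- abs(stats::runif(
      sum(lab == "circumferential"), -22.5, 22.5))
    theta[lab == "radial"] <- 90 - abs(stats::runif(
      sum(lab == "radial"), -22.5, 22.5))
    theta[lab == "oblique"] <- stats::runif(sum(lab == "oblique"), 22.5, 67.5)
    theta[lab == "longitudinal"] <- stats::runif(
      sum(lab == "longitudinal"), 0, 90)
    sgn <- sample(c(-1, 1), n_canals, replace = TRUE)

    ## rejection-sample non-overlapping positions in the mid-annulus band
    pos <- matrix(NA_real_, n_canals, 2)
    phi <- numeric(n_canals)
    placed_r <- numeric(0)
    for (i in seq_len(n_canals)) {
      margin <- major[i] / 2 + 4
      lo <- inner_radius + margin
      hi <- outer_radius - margin
      if (lo >= hi) stop("annulus too thin for the requested canal sizes")
      ok <- FALSE
      for (try in 1:500) {
        ph <- stats::runif(1, 0, 2 * pi)
        rr <- stats::runif(1, lo, hi)
        pt <- c(rr * cos(ph), rr * sin(ph))
        if (i == 1 || all(sqrt((pos[seq_len(i - 1), 1] - pt[1])^2 +
                               (pos[seq_len(i - 1), 2] - pt[2])^2) >
                          (major[seq_len(i - 1)] + major[i]) / 2 + 6)) {
          pos[i, ] <- pt; phi[i] <- ph; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place canal ", i,
                    " without overlap; reduce n_canals or canal size")
    }
    tangent <- (phi * 180 / pi + 90) %% 180
    angle <- (tangent + sgn * theta) %% 180
    canals <- data.frame(x = pos[, 1], y = pos[, 2], major = major,
                         minor = minor, angle = angle, theta_true = theta,
                         class_true = lab, stringsAsFactors = FALSE)
    ## rasterize canal interiors
    for (i in seq_len(n_canals)) {
      canal_mask <- .paint_ellipse(canal_mask, ctr + canals$x[i] / pixel_scale,
                                   ctr + canals$y[i] / pixel_scale,
                                   major[i] / 2 / pixel_scale,
                                   minor[i] / 2 / pixel_scale,
                                   angle[i] * pi / 180)
    }
  }
  canals$secondary <- rep(FALSE, nrow(canals))
  structure(list(canals = canals, mask = mask, canal_mask = canal_mask,
                 center = c(x = ctr, y = ctr), outer_radius = outer_radius,
                 inner_radius = inner_radius, pixel_scale = pixel_scale),
            class = "canal_field")
}

## set TRUE all pixels inside the ellipse (cx, cy in px, semi-axes a >= b px,
## angle radians); x = column, y = row
.paint_ellipse <- function(mask, cx, cy, a, b, ang) {
  rr <- ceiling(a) + 1
  rows <- max(1, floor(cy - rr)):min(nrow(mask), ceiling(cy + rr))
  cols <- max(1, floor(cx - rr)):min(ncol(mask), ceiling(cx + rr))
  dx <- outer(rep(1, length(rows)), cols - cx)
  dy <- outer(rows - cy, rep(1, length(cols)))
  u <- dx * cos(ang) + dy * sin(ang)
  v <- -dx * sin(ang) + dy * cos(ang)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask[rows, cols] <- mask[rows, cols] | inside
  mask
}

#' Generate a cortical profile mask with attached closed-form geometry
#'
#' Rasterizes an annular (or solid) cortical profile and attaches the exact
#' analytic values of CA, TA, centroid, Imax, Imin, J, r_max and Zp computed
#' from closed forms - never from the raster - so raster-based geometry can
#' be tested for convergence.
#'
#' Shapes: `"circular_annulus"` (semi-axes ignored beyond the first),
#' `"elliptical_annulus"` and `"offset_hole"` (circular outer boundary,
#' circular hole displaced by `hole_offset`). Set the inner semi-axes to 0
#' for a solid section.
#'
#' @param shape one of `"circular_annulus"`, `"elliptical_annulus"`,
#'   `"offset_hole"`
#' @param outer_semi_axes length-2 outer semi-axes (mm); for circular shapes
#'   only the first is used
#' @param inner_semi_axes length-2 inner semi-axes (mm); 0 for solid
#' @param hole_offset length-2 displacement of the hole centre (mm),
#'   `"offset_hole"` only
#' @param resolution pixels spanning the outer diameter (`>= 64`)
#' @return object of class `synthetic_profile`: list with `profile`
#'   (a [cortical_profile()]) and `analytic` (list: CA, TA, centroid, Imax,
#'   Imin, J, r_max, Zp, shape_ratio)
#' @export
generate_cortical_profile <- function(shape = c("circular_annulus",
                                                "elliptical_annulus",
                                                "offset_hole"),
                                      outer_semi_axes = c(2, 2),
                                      inner_semi_axes = c(1, 1),
                                      hole_offset = c(0, 0),
                                      resolution = 1024) {
  shape <- match.arg(shape)
  stopifnot(resolution >= 64, all(outer_semi_axes > 0),
            all(inner_semi_axes >= 0))
  if (shape == "circular_annulus") {
    outer_semi_axes <- rep(outer_semi_axes[1], 2)
    inner_semi_axes <- rep(inner_semi_axes[1], 2)
    hole_offset <- c(0, 0)
  }
  if (shape == "elliptical_annulus") hole_offset <- c(0, 0)
  if (shape == "offset_hole") {
    outer_semi_axes <- rep(outer_semi_axes[1], 2)
    inner_semi_axes <- rep(inner_semi_axes[1], 2)
  }
  a <- outer_semi_axes[1]; b <- outer_semi_axes[2]
  ai <- inner_semi_axes[1]; bi <- inner_semi_axes[2]
  ox <- hole_offset[1]; oy <- hole_offset[2]
  solid <- ai == 0 || bi == 0
  ## hole strictly inside the outer boundary
  if (!solid) {
    tt <- seq(0, 2 * pi, length.out = 720)
    hx <- ox + ai * cos(tt); hy <- oy + bi * sin(tt)
    if (any((hx / a)^2 + (hy / b)^2 >= 1))
      stop("hole touches or crosses the outer boundary")
  }
  pixel_scale <- 2 * a / resolution
  npx_x <- resolution + 8
  npx_y <- ceiling(2 * b / pixel_scale) + 8
  cx <- (npx_x + 1) / 2; cy <- (npx_y + 1) / 2
  xs <- ((1:npx_x) - cx) * pixel_scale
  ys <- ((1:npx_y) - cy) * pixel_scale
  ex <- outer(rep(1, npx_y), xs); ey <- outer(ys, rep(1, npx_x))
  outer_in <- (ex / a)^2 + (ey / b)^2 <= 1
  mask <- if (solid) outer_in else
    outer_in & !(((ex - ox) / ai)^2 + ((ey - oy) / bi)^2 < 1)

  A_out <- pi * a * b
  A_in <- if (solid) 0 else pi * ai * bi
  CA <- A_out - A_in
  cen <- if (A_in == 0) c(0, 0) else -A_in * c(ox, oy) / CA
  Ix_out <- pi * a * b^3 / 4; Iy_out <- pi * a^3 * b / 4
  Ix_in <- if (solid) 0 else pi * ai * bi^3 / 4
  Iy_in <- if (solid) 0 else pi * ai^3 * bi / 4
  Ix <- (Ix_out + A_out * cen[2]^2) - (Ix_in + A_in * (oy - cen[2])^2)
  Iy <- (Iy_out + A_out * cen[1]^2) - (Iy_in + A_in * (ox - cen[1])^2)
  Ixy <- A_out * cen[1] * cen[2] - A_in * (ox - cen[1]) * (oy - cen[2])
  ev <- eigen(matrix(c(Ix, -Ixy, -Ixy, Iy), 2, 2), symmetric = TRUE)$values
  tt <- seq(0, 2 * pi, length.out = 20001)
  r_max <- max(sqrt((a * cos(tt) - cen[1])^2 + (b * sin(tt) - cen[2])^2))
  J <- Ix + Iy
  analytic <- list(CA = CA, TA = A_out, centroid = cen,
                   Imax = ev[1], Imin = ev[2], J = J, r_max = r_max,
                   Zp = J / r_max, shape_ratio = ev[1] / ev[2])
  structure(list(profile = cortical_profile(mask, pixel_scale),
                 analytic = analytic, shape = shape),
            class = "synthetic_profile")
}

#' Generate a sigmoidal growth series with optional noise
#'
#' Evaluates the chosen growth model at the sampling times and adds
#' independent Gaussian noise. With `noise_sd = 0` the series equals the
#' model curve exactly.
#'
#' @param model `"logistic"`, `"gompertz"` or `"von_bertalanffy"`
#' @param A asymptotic mass (g), `> 0`
#' @param K growth constant (1/day), `> 0`
#' @param t0 location parameter (day)
#' @param times sampling ages (days), non-empty
#' @param noise_sd additive noise SD (g), `>= 0`
#' @param seed integer seed (used only when `noise_sd > 0`)
#' @return data frame with `age`, `mass`
#' @export
generate_growth_series <- function(model, A, K, t0, times, noise_sd = 0,
                                   seed = 1) {
  stopifnot(A > 0, K > 0, noise_sd >= 0)
  if (length(times) == 0) stop("empty sampling times")
  m <- growth_curve_value(model, times, A, K, t0)
  if (noise_sd > 0) {
    restore <- .Random.seed_safe_set(seed)
    on.exit(restore())
    m <- m + stats::rnorm(length(times), 0, noise_sd)
  }
  data.frame(age = times, mass = m)
}

#' Simulate a phylogeny with a bivariate scaling relationship
#'
#' Simulates a pure-birth tree (rescaled to unit root-to-tip depth by
#' default, making alpha and sigma2 dimensionless), draws the predictor
#' uniformly, and adds phylogenetically structured residuals about the true
#' line y = slope x + intercept: multivariate normal with covariance
#' sigma2 * V where V is the Brownian variance-covariance matrix
#' (`trait_model = "BM"`) or the stationary Ornstein-Uhlenbeck covariance
#' sigma2 * exp(-alpha d_ij) (`trait_model = "OU"`).
#'
#' @param n_tips number of tips, `>= 3`
#' @param birth_rate pure-birth speciation rate (1/My)
#' @param trait_model `"BM"` or `"OU"`
#' @param sigma2 residual variance scale, `>= 0`
#' @param alpha OU restraining strength (unit-depth scale), `>= 0`
#' @param slope,intercept true regression parameters
#' @param x_range range of the predictor
#' @param rescale_depth rescale the tree to unit depth (default TRUE)
#' @param seed integer seed
#' @param tree optional fixed [ape::phylo] to simulate on (skips the
#'   pure-birth simulation; used for replicate draws on a common tree)
#' @return list with `tree` (an [ape::phylo]) and `traits` (data frame:
#'   `species`, `x`, `y`), plus the generating parameters in `$params`
#' @export
simulate_scaling_dataset <- function(n_tips, birth_rate = 1,
                                     trait_model = c("BM", "OU"),
                                     sigma2 = 0.1, alpha = 1,
                                     slope = 0.75, intercept = -2,
                                     x_range = c(0, 3),
                                     rescale_depth = TRUE, seed = 1,
                                     tree = NULL) {
  trait_model <- match.arg(trait_model)
  stopifnot(n_tips >= 3, sigma2 >= 0, alpha >= 0)
  restore <- .Random.seed_safe_set(seed)
  on.exit(restore())
  if (is.null(tree)) {
    tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    if (rescale_depth) {
      depth <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length / depth
    }
  } else {
    n_tips <- length(tree$tip.label)
  }
  x <- stats::runif(n_tips, x_range[1], x_range[2])
  resid <- rep(0, n_tips)
  if (sigma2 > 0) {
    V <- if (trait_model == "BM") sigma2 * vcv_brownian(tree)
         else sigma2 * exp(-alpha * ape::cophenetic.phylo(tree))
    V <- V[tree$tip.label, tree$tip.label]
    resid <- drop(t(chol(V)) %*% stats::rnorm(n_tips))
  }
  traits <- data.frame(species = tree$tip.label, x = x,
                       y = intercept + slope * x + resid,
                       stringsAsFactors = FALSE)
  list(tree = tree, traits = traits,
       params = list(trait_model = trait_model, sigma2 = sigma2,
                     alpha = alpha, slope = slope, intercept = intercept,
                     seed = seed))
}

#' Write a simulated canal field to plain-text/PNG files
#'
#' Writes `canals.csv` (one row per canal: centroid, axes, angle, true
#' class, secondary flag), `mask.png`, `canal_mask.png` and a
#' `metadata.txt` sidecar with the pixel scale and annulus radii.
#'
#' @param field a `canal_field`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_canal_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(field$canals, file.path(dir, "canals.csv"),
                   row.names = FALSE)
  png::writePNG(field$mask * 1, file.path(dir, "mask.png"))
  png::writePNG(field$canal_mask * 1, file.path(dir, "canal_mask.png"))
  writeLines(c(sprintf("pixel_scale_um: %.17g", field$pixel_scale),
               sprintf("outer_radius_um: %.17g", field$outer_radius),
               sprintf("inner_radius_um: %.17g", field$inner_radius)),
             file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' Read a per-canal measurement CSV
#'
#' Reads a canal table in the layout written by [write_canal_field()] (or
#' any table with `major`, `minor`, `angle` columns and optional
#' `secondary` flag) and attaches `aspect_ratio`.
#'
#' @param path CSV path
#' @return data frame of canal records
#' @export
read_canal_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("major", "minor", "angle")
  if (!all(need %in% names(d)))
    stop("canal CSV must have columns: ", paste(need, collapse = ", "))
  d$aspect_ratio <- d$major / d$minor
  d
}
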