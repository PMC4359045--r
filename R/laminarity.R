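#' Wilson estimate of a population proportion
#'
#' Small-sample point estimate and confidence interval for a binomial
#' proportion. The default `"score"` variant uses the Wilson score centre
#' \eqn{\tilde p = (x + z^2/2)/(n + z^2)} with interval
#' \eqn{\tilde p \pm [z/(n + z^2)]\sqrt{x(n-x)/n + z^2/4}}; the `"plus4"`
#' variant is the add-two-successes/two-failures simplification
#' \eqn{\tilde p = (x+2)/(n+4)} with a Wald interval about that centre.
#' Both shrink the estimate away from 0 and 1 and are well behaved at the
#' small per-octant canal counts typical of histological sections.
#'
#' @param x number of successes (non-negative integer)
#' @param n number of trials (positive integer, `n >= x`)
#' @param conf.level confidence level, default 0.95
#' @param variant `"score"` (default) or `"plus4"`
#' @return list with `estimate`, `ci.low`, `ci.high`, `conf.level`
#' @examples
#' wilson_estimate(5, 20)
#' @export
wilson_estimate <- function(x, n, conf.level = 0.95,
                            variant = c("score", "plus4")) {
  variant <- match.arg(variant)
  stopifnot(length(x) == 1, length(n) == 1, x >= 0, n > 0, x <= n,
            conf.level > 0, conf.level < 1)
  x <- unname(x); n <- unname(n)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  if (variant == "score") {
    centre <- (x + z^2 / 2) / (n + z^2)
    half <- (z / (n + z^2)) * sqrt(x * (n - x) / n + z^2 / 4)
  } else {
    centre <- (x + 2) / (n + 4)
    half <- z * sqrt(centre * (1 - centre) / (n + 4))
  }
  list(estimate = centre,
       ci.low = max(0, centre - half),
       ci.high = min(1, centre + half),
       half.width = half,
       conf.level = conf.level)
}

#' Laminarity index with small-sample confidence interval
#'
#' The laminarity index (LI) is the proportion of circumferential canals among
#' the primary vascular canals of a section. For sections with at least one
#' circumferential canal the Wilson estimate is reported with its confidence
#' interval; with zero circumferential canals the index is exactly 0 and no
#' interval is attached; with no measurable primary canals at all the index is
#' undefined (`NA`, mirroring avascular sections reported as "n/a"). Canals of
#' secondary osteons must be excluded before counting.
#'
#' @param n_circumferential count of circumferential primary canals
#' @param n_total total count of primary canals
#' @param conf.level confidence level for the interval (default 0.95)
#' @param variant Wilson variant passed to [wilson_estimate()]
#' @return object of class `laminarity_estimate`: list with `n_total`,
#'   `n_circumferential`, `estimate`, `ci.low`, `ci.high`, `half.width`,
#'   `conf.level`
#' @export
laminarity_index <- function(n_circumferential, n_total, conf.level = 0.95,
                             variant = c("score", "plus4")) {
  variant <- match.arg(variant)
  stopifnot(n_circumferential >= 0, n_total >= 0,
            n_circumferential <= n_total)
  if (n_total == 0) {
    out <- list(n_total = 0L, n_circumferential = 0L, estimate = NA_real_,
                ci.low = NA_real_, ci.high = NA_real_, half.width = NA_real_,
                conf.level = conf.level)
  } else if (n_circumferential == 0) {
    out <- list(n_total = as.integer(n_total), n_circumferential = 0L,
                estimate = 0, ci.low = NA_real_, ci.high = NA_real_,
                half.width = NA_real_, conf.level = conf.level)
  } else {
    w <- wilson_estimate(n_circumferential, n_total, conf.level, variant)
    out <- c(list(n_total = as.integer(n_total),
                  n_circumferential = as.integer(n_circumferential)), w)
  }
  class(out) <- "laminarity_estimate"
  out
}

#' @export
print.laminarity_estimate <- function(x, ...) {
  if (x$n_total == 0) {
    cat("Laminarity index: n/a (no measurable primary canals)\n")
  } else if (x$n_circumferential == 0) {
    cat(sprintf("Laminarity index: 0 (0 of %d canals circumferential)\n",
                x$n_total))
  } else {
    cat(sprintf(
      "Laminarity index: %.3f [%.3f, %.3f] (%d of %d canals, %g%% Wilson CI)\n",
      x$estimate, x$ci.low, x$ci.high, x$n_circumferential, x$n_total,
      100 * x$conf.level))
  }
  invisible(x)
}

#' Reduce a fitted canal ellipse to orientation measurements
#'
#' Converts a canal ellipse (major/minor axis lengths and absolute major-axis
#' angle) into the two quantities the orientation criteria use: the aspect
#' ratio a/b and the acute angle theta between the major axis and the local
#' periosteal tangent, folded into \[0, 90\] degrees. In a straightened octant
#' the tangent is horizontal (`tangent_angle = 0`).
#'
#' @param major,minor major and minor axis lengths (same units, `major >= minor > 0`)
#' @param angle absolute angle of the major axis in degrees
#' @param tangent_angle absolute angle of the local periosteal tangent in
#'   degrees (default 0, the straightened-frame convention)
#' @return list with `aspect_ratio` and `theta` (degrees in \[0, 90\])
#' @export
measure_canal <- function(major, minor, angle, tangent_angle = 0) {
  stopifnot(major >= minor, minor > 0)
  rel <- (angle - tangent_angle) %% 180
  theta <- ifelse(rel > 90, 180 - rel, rel)
  list(aspect_ratio = major / minor, theta = theta)
}

#' Classify a primary vascular canal by orientation
#'
#' Four-way orientation criteria for primary canals in transverse section:
#' (1) canals with aspect ratio strictly less than 3 are longitudinal;
#' otherwise (2) major axis within 22.5 degrees of the periosteal tangent
#' (theta in \[0, 22.5\]) is circumferential; (3) within 22.5 degrees of the
#' radial direction (theta in \[67.5, 90\]) is radial; (4) all remaining
#' canals are oblique. The longitudinal test is applied first; the angle
#' bands are closed, so the boundary angles 22.5 and 67.5 belong to the
#' circumferential and radial classes respectively.
#'
#' @param aspect_ratio canal ellipse aspect ratio(s), `>= 1`
#' @param theta acute angle(s) to the periosteal tangent, degrees in \[0, 90\]
#' @return character vector in
#'   `c("longitudinal", "circumferential", "radial", "oblique")`
#' @export
classify_canal <- function(aspect_ratio, theta) {
  stopifnot(all(aspect_ratio >= 1), all(theta >= 0), all(theta <= 90))
  cls <- rep("oblique", length(aspect_ratio))
  cls[theta <= 22.5] <- "circumferential"
  cls[theta >= 67.5] <- "radial"
  cls[aspect_ratio < 3] <- "longitudinal"
  cls
}

#' Classify a table of canal measurements and summarize laminarity
#'
#' Applies [classify_canal()] to a per-canal table and computes the
#' laminarity index over primary canals (rows flagged secondary are dropped,
#' with a message).
#'
#' @param canals data frame with columns `aspect_ratio`, `theta`, and
#'   optionally `secondary` (logical)
#' @param conf.level,variant passed to [laminarity_index()]
#' @return list with `canals` (input plus a `class` column, secondaries
#'   removed) and `laminarity` (a `laminarity_estimate`)
#' @export
classify_canal_table <- function(canals, conf.level = 0.95,
                                 variant = c("score", "plus4")) {
  variant <- match.arg(variant)
  stopifnot(all(c("aspect_ratio", "theta") %in% names(canals)))
  if (!is.null(canals$secondary)) {
    n_sec <- sum(canals$secondary)
    if (n_sec > 0)
      message(sprintf("excluding %d secondary-osteon canal(s)", n_sec))
    canals <- canals[!canals$secondary, , drop = FALSE]
  }
  canals$class <- if (nrow(canals) > 0)
    classify_canal(canals$aspect_ratio, canals$theta) else character(0)
  li <- laminarity_index(sum(canals$class == "circumferential"),
                         nrow(canals), conf.level, variant)
  list(canals = canals, laminarity = li)
}
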