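# Independent oracles used across tests. These restate the science by
# brute force or closed form, independently of the package's code paths.

# literal restatement of the four orientation criteria
oracle_classify <- function(aspect, theta) {
  if (aspect < 3) return("longitudinal")
  if (theta >= 0 && theta <= 22.5) return("circumferential")
  if (theta >= 67.5 && theta <= 90) return("radial")
  "oblique"
}

# GLS coefficients by explicit matrix inversion
oracle_gls_coef <- function(x, y, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# exact runs-count distribution by enumeration of all sign arrangements
oracle_runs_distribution <- function(n_pos, n_neg) {
  pos <- utils::combn(n_pos + n_neg, n_pos, simplify = FALSE)
  counts <- integer(n_pos + n_neg)
  for (p in pos) {
    s <- rep(-1, n_pos + n_neg)
    s[p] <- 1
    r <- 1 + sum(diff(s) != 0)
    counts[r] <- counts[r] + 1
  }
  counts / length(pos)
}

# numerical maximum of dm/dt for a growth curve, by fine grid + refinement
oracle_max_growth <- function(model, A, K, t0) {
  f <- function(t) wingbone:::growth_curve_value(model, t, A, K, t0)
  dm <- function(t) (f(t + 1e-4) - f(t - 1e-4)) / 2e-4
  opt <- stats::optimize(dm, interval = c(t0 - 50 / K, t0 + 50 / K),
                         maximum = TRUE, tol = 1e-10)
  list(max_rate = opt$objective, inflection_mass = f(opt$maximum))
}

# rasterize a filled ellipse as a logical matrix (independent of the
# package's painters)
oracle_ellipse_mask <- function(nrow, ncol, cx, cy, a, b, angle_deg) {
  ang <- angle_deg * pi / 180
  out <- matrix(FALSE, nrow, ncol)
  for (r in 1:nrow) for (cc in 1:ncol) {
    dx <- cc - cx; dy <- r - cy
    u <- dx * cos(ang) + dy * sin(ang)
    v <- -dx * sin(ang) + dy * cos(ang)
    if ((u / a)^2 + (v / b)^2 <= 1) out[r, cc] <- TRUE
  }
  out
}
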