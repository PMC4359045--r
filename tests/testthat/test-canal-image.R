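make_annulus <- function(R_px = 200, r_px = 160, npx = 2 * R_px + 9) {
  ctr <- (npx + 1) / 2
  xs <- (1:npx) - ctr
  r2 <- outer(xs^2, xs^2, "+")
  list(mask = r2 <= R_px^2 & r2 >= r_px^2, center = ctr, R = R_px, r = r_px)
}

test_that("cardinal octants are 45-degree sectors holding 1/8 of the cortex", {
  an <- make_annulus()
  octs <- extract_cardinal_octants(an$mask)
  expect_named(octs, c("anterior", "lateral", "posterior", "medial"))
  total <- sum(an$mask)
  for (oc in octs)
    expect_equal(sum(oc$mask) / total, 1 / 8, tolerance = 0.02)
  # disjoint
  expect_equal(sum(octs[[1]]$mask & octs[[2]]$mask), 0)
  # rotating the axes rotates the octants but keeps the union size
  octs30 <- extract_cardinal_octants(an$mask, axes_angle = 30)
  u0 <- sum(Reduce(`|`, lapply(octs, `[[`, "mask")))
  u30 <- sum(Reduce(`|`, lapply(octs30, `[[`, "mask")))
  expect_equal(u30 / u0, 1, tolerance = 0.01)
  # a point at polar angle 10 degrees belongs to the octant centred at 0
  p <- c(round(an$center + 180 * sin(10 * pi / 180)),
         round(an$center + 180 * cos(10 * pi / 180)))
  expect_true(octs$anterior$mask[p[1], p[2]])
  expect_false(octs$lateral$mask[p[1], p[2]])
})

test_that("a solid disc is rejected as non-ring-like", {
  npx <- 101; ctr <- 51
  xs <- (1:npx) - ctr
  disc <- outer(xs^2, xs^2, "+") <= 45^2
  expect_error(extract_cardinal_octants(disc), "medullary")
})

test_that("straightening an annulus octant yields the expected rectangle", {
  an <- make_annulus(R_px = 200, r_px = 180)
  octs <- extract_cardinal_octants(an$mask)
  st <- straighten_octant(an$mask, octs$anterior)
  # width = 45-degree arc length at the periosteal radius, within 2%
  expect_equal(ncol(st$image), an$R * pi / 4, tolerance = 0.02)
  # the top rows are cortex (periosteal surface maps to the top)
  expect_gt(mean(st$image[2, ] > 0.5), 0.97)
  # thickness: rows until the cortex ends ~ R - r
  prof <- rowMeans(st$image > 0.5)
  expect_equal(sum(prof > 0.5), an$R - an$r, tolerance = 0.15)
  # fold-over gate: tightly curved contour with deep sampling is rejected
  tiny <- make_annulus(R_px = 40, r_px = 12)
  toct <- extract_cardinal_octants(tiny$mask)
  expect_error(straighten_octant(tiny$mask, toct$anterior, depth = 60),
               "fold-over")
})

test_that("deformation validation: gentle curvature passes, strong fails", {
  # curvature radius 10x thickness: inside the published tolerance gates
  an <- make_annulus(R_px = 300, r_px = 270)
  octs <- extract_cardinal_octants(an$mask)
  st <- straighten_octant(an$mask, octs$anterior)
  rep_ <- validate_straightening(st)
  expect_lte(rep_$max_angle_deviation, 5)
  expect_lte(rep_$aspect_ratio_range[2], 1.17)
  expect_gte(rep_$aspect_ratio_range[1], 1)
  expect_true(rep_$pass)
  # curvature radius ~2x thickness: the gates flag the deformation
  bad <- make_annulus(R_px = 80, r_px = 40)
  boct <- extract_cardinal_octants(bad$mask)
  stb <- straighten_octant(bad$mask, boct$anterior)
  repb <- validate_straightening(stb)
  expect_false(repb$pass)
})

test_that("branched canals split at skeleton junctions, pixels preserved", {
  # unbranched: returned unchanged
  blob <- oracle_ellipse_mask(40, 60, 30, 20, 20, 5, 15)
  expect_length(split_branched_canal(blob), 1)
  # Y-shaped region: three branch-free parts
  Y <- matrix(FALSE, 60, 60)
  for (t in 0:24) {
    Y[30 - t, 30 + c(-1, 0, 1)] <- TRUE                       # vertical arm
    Y[30 + round(t * 0.7) + c(-1, 0, 1), 30 - round(t * 0.7)] <- TRUE
    Y[30 + round(t * 0.7) + c(-1, 0, 1), 30 + round(t * 0.7)] <- TRUE
  }
  partsY <- split_branched_canal(Y)
  expect_equal(length(partsY), 3)
  expect_identical(Reduce(`|`, partsY), Y)                    # union preserved
  # X-shaped region: four parts
  X <- matrix(FALSE, 61, 61)
  for (t in -25:25) {
    X[31 + t, 31 + t + c(-1, 0, 1)] <- TRUE
    X[31 + t, 31 - t + c(-1, 0, 1)] <- TRUE
  }
  partsX <- split_branched_canal(X)
  expect_equal(length(partsX), 4)
  expect_identical(Reduce(`|`, partsX), X)
})

test_that("moment-matched ellipse fitting recovers shape and orientation", {
  # rasterized disc: isotropic
  disc <- oracle_ellipse_mask(41, 41, 21, 21, 10, 10, 0)
  f <- fit_canal_ellipse(disc)
  expect_equal(f$aspect_ratio, 1, tolerance = 0.05)
  # 30 x 6 px rectangle: aspect 5, angle along the long side
  rect <- matrix(FALSE, 40, 60)
  rect[18:23, 16:45] <- TRUE
  fr <- fit_canal_ellipse(rect)
  expect_equal(fr$aspect_ratio, 5, tolerance = 0.03)
  expect_lt(min(fr$angle, 180 - fr$angle), 2)
  # oriented ellipse: angle recovered within 2 degrees
  ell <- oracle_ellipse_mask(80, 80, 40, 40, 18, 5, 37)
  fe <- fit_canal_ellipse(ell)
  expect_lt(abs(fe$angle - 37), 2)
  # preconditions
  tiny <- matrix(FALSE, 5, 5); tiny[2, 2:5] <- TRUE
  expect_error(fit_canal_ellipse(tiny), "fewer than 5")
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_error(fit_canal_ellipse(line), "collinear")
})

test_that("end-to-end field analysis recovers true classes at 95%+", {
  f <- simulate_canal_field(200, c(circumferential = 0.5,
                                   longitudinal = 0.3, radial = 0.1,
                                   oblique = 0.1), seed = 7)
  a <- suppressMessages(analyze_canal_field(f))
  m <- a$measurements
  expect_gt(nrow(m), 60)
  expect_gte(mean(m$class == m$true_class), 0.95)
  # the straightening gates hold on this gently curved annulus
  for (r in a$reports) expect_true(r$pass)
  # laminarity of the field is near the generated circumferential share
  res <- classify_canal_table(data.frame(aspect_ratio = m$aspect_ratio,
                                         theta = m$theta))
  expect_equal(res$laminarity$estimate, 0.5, tolerance = 0.15)
})
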