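test_that("all four generators are bit-reproducible under a fixed seed", {
  f1 <- simulate_canal_field(40, seed = 3)
  f2 <- simulate_canal_field(40, seed = 3)
  expect_identical(f1, f2)
  g1 <- generate_growth_series("gompertz", 100, 0.1, 30, 0:50,
                               noise_sd = 2, seed = 4)
  expect_identical(g1, generate_growth_series("gompertz", 100, 0.1, 30,
                                              0:50, noise_sd = 2, seed = 4))
  s1 <- simulate_scaling_dataset(10, seed = 5)
  s2 <- simulate_scaling_dataset(10, seed = 5)
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$tree$edge.length, s2$tree$edge.length)
  p1 <- generate_cortical_profile("circular_annulus", resolution = 64)
  expect_identical(p1, generate_cortical_profile("circular_annulus",
                                                 resolution = 64))
  # generators restore the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_canal_field(5, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("canal fields honour proportions within the 3-sigma binomial bound", {
  f <- simulate_canal_field(200, c(circumferential = 0.5, longitudinal = 0.3,
                                   radial = 0.1, oblique = 0.1), seed = 7)
  n_circ <- sum(f$canals$class_true == "circumferential")
  expect_lte(abs(n_circ - 100), 3 * sqrt(200 * 0.5 * 0.5))
  # invalid proportions rejected
  expect_error(simulate_canal_field(10, c(circumferential = 0.6,
                                          longitudinal = 0.6), seed = 1),
               "sum to 1")
  expect_error(simulate_canal_field(10, outer_radius = 100,
                                    inner_radius = 200, seed = 1))
})

test_that("empty and single-class canal fields behave as constructed", {
  f0 <- simulate_canal_field(0, seed = 2)
  expect_equal(nrow(f0$canals), 0)
  expect_true(any(f0$mask))
  fl <- simulate_canal_field(60, c(longitudinal = 1), seed = 2)
  expect_true(all(fl$canals$major / fl$canals$minor < 3))
  # truth labels are consistent with the classifier's own criteria
  f <- simulate_canal_field(120, seed = 9)
  got <- classify_canal(f$canals$major / f$canals$minor, f$canals$theta_true)
  expect_identical(got, f$canals$class_true)
  # canal centres lie inside the annulus
  r <- sqrt(f$canals$x^2 + f$canals$y^2)
  expect_true(all(r > f$inner_radius & r < f$outer_radius))
})

test_that("profile generator attaches exact closed-form geometry", {
  sp <- generate_cortical_profile("circular_annulus", c(2, 2), c(1, 1),
                                  resolution = 64)
  expect_equal(sp$analytic$J, 7.5 * pi, tolerance = 1e-12)
  expect_equal(sp$analytic$Zp, 3.75 * pi, tolerance = 1e-12)
  solid <- generate_cortical_profile("circular_annulus", c(1, 1), c(0, 0),
                                     resolution = 64)
  expect_equal(solid$analytic$CA, pi, tolerance = 1e-12)
  expect_equal(solid$analytic$J, pi / 2, tolerance = 1e-12)
  # elliptical annulus with a proportional hole: Imax/Imin = (a/b)^2
  ell <- generate_cortical_profile("elliptical_annulus", c(2, 1), c(1, 0.5),
                                   resolution = 64)
  expect_equal(ell$analytic$shape_ratio, 4, tolerance = 1e-12)
})

test_that("growth series equal the model curve exactly when noiseless", {
  s <- generate_growth_series("logistic", A = 100, K = 0.1, t0 = 40,
                              times = c(0, 40, 80))
  expect_equal(s$mass[2], 50)  # logistic inflection mass is A/2 at t0
  g <- generate_growth_series("gompertz", A = 100, K = 0.1, t0 = 30,
                              times = 0:60)
  expect_true(all(diff(g$mass) > 0))
})

test_that("scaling datasets carry the stated residual covariance", {
  # degenerate noise: points exactly on the line
  s0 <- simulate_scaling_dataset(8, sigma2 = 0, slope = 0.75,
                                 intercept = -2, seed = 6)
  expect_equal(s0$traits$y, 0.75 * s0$traits$x - 2, tolerance = 1e-12)
  # Monte-Carlo check of the BM residual covariance on a fixed 8-tip tree
  tree <- simulate_scaling_dataset(8, seed = 17)$tree
  V <- vcv_brownian(tree)[tree$tip.label, tree$tip.label]
  R <- sapply(1:4000, function(i) {
    s <- simulate_scaling_dataset(8, sigma2 = 1, slope = 0.5, intercept = 1,
                                  seed = 1000 + i, tree = tree)
    s$traits$y[match(tree$tip.label, s$traits$species)] -
      (1 + 0.5 * s$traits$x[match(tree$tip.label, s$traits$species)])
  })
  emp <- cov(t(R))
  expect_lt(max(abs(emp - V)), 0.1 * max(V))
  # strong OU: off-diagonal correlations vanish
  tr2 <- read_tree("(((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5):0,((E:0.5,F:0.5):0.5,(G:0.5,H:0.5):0.5):0);")
  R2 <- sapply(1:800, function(i) {
    s <- simulate_scaling_dataset(8, trait_model = "OU", alpha = 10,
                                  sigma2 = 1, slope = 0, intercept = 0,
                                  seed = 4000 + i, tree = tr2)
    s$traits$y[match(tr2$tip.label, s$traits$species)]
  })
  cors <- cor(t(R2))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.15)
  expect_error(simulate_scaling_dataset(2, seed = 1))
})

test_that("canal fields round-trip through their CSV/PNG writers", {
  f <- simulate_canal_field(15, seed = 12)
  dir <- file.path(tempdir(), "field_io")
  write_canal_field(f, dir)
  back <- read_canal_csv(file.path(dir, "canals.csv"))
  expect_equal(nrow(back), 15)
  expect_equal(back$aspect_ratio, f$canals$major / f$canals$minor,
               tolerance = 1e-12)
  m <- png::readPNG(file.path(dir, "mask.png")) > 0.5
  expect_identical(m, f$mask)
})
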