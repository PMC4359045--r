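test_that("tree reading, pruning and path-length preservation", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  big <- read_tree("(((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,(E:2,F:2):1);")
  pr <- prune_tree(big, c("A", "C", "E"))
  expect_equal(sort(pr$tip.label), c("A", "C", "E"))
  d_big <- ape::cophenetic.phylo(big)[c("A", "C", "E"), c("A", "C", "E")]
  d_pr <- ape::cophenetic.phylo(pr)[c("A", "C", "E"), c("A", "C", "E")]
  expect_equal(d_pr, d_big)
  # pruning to all tips is the identity
  expect_identical(prune_tree(big, big$tip.label), big)
  expect_error(prune_tree(big, c("A", "Zz")), "Zz")
})

test_that("polytomy resolution inserts zero-length branches, distances fixed", {
  star <- read_tree("(A:1,B:1,C:1,D:1,E:1);")
  bin <- resolve_polytomies(star)
  expect_true(ape::is.binary(bin))
  # a star with 5 tips needs 3 inserted zero-length internal branches
  expect_equal(sum(bin$edge.length == 0), 3)
  expect_equal(ape::cophenetic.phylo(bin)[star$tip.label, star$tip.label],
               ape::cophenetic.phylo(star)[star$tip.label, star$tip.label])
  # binary input unchanged
  tr <- read_tree("((A:1,B:1):1,C:2);")
  expect_identical(resolve_polytomies(tr), tr)
})

test_that("Brownian covariance equals shared path lengths", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  V <- vcv_brownian(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "A"], 2)
  expect_equal(V["A", "C"], 0)
  # two tips straight from the root share nothing
  V2 <- vcv_brownian(read_tree("(A:3,B:3);"))
  expect_equal(unname(V2), matrix(c(3, 0, 0, 3), 2))
})

test_that("OU correlation is exp(-alpha d) with the documented limits", {
  tr <- read_tree("(A:1,B:1);")
  C <- suppressWarnings(vcv_ou(tr, 0.5))
  expect_equal(C["A", "B"], exp(-1))
  expect_equal(diag(C), c(A = 1, B = 1))
  expect_message(C0 <- vcv_ou(tr, 0), "alpha = 0")
  expect_true(all(C0 == 1))
  Cinf <- vcv_ou(tr, 1e4)
  expect_equal(unname(Cinf), diag(2), tolerance = 1e-12)
})

test_that("identity-structure GLS reproduces lm exactly, CIs included", {
  set.seed(42)
  x <- rnorm(20); y <- 1 + 0.5 * x + rnorm(20, 0, 0.3)
  f <- fit_gls(x, y)
  lmf <- lm(y ~ x)
  expect_equal(unname(f$coefficients), unname(coef(lmf)), tolerance = 1e-12)
  expect_equal(unname(f$ci["slope", ]), unname(confint(lmf)["x", ]),
               tolerance = 1e-12)
  expect_equal(f$logLik, as.numeric(logLik(lmf, REML = TRUE)),
               tolerance = 1e-8)
})

test_that("GLS equals the explicit-inversion oracle to 1e-10 for n <= 6", {
  set.seed(9)
  for (n in 3:6) {
    sim <- simulate_scaling_dataset(n, sigma2 = 0.2, seed = 300 + n)
    V <- vcv_brownian(sim$tree)[sim$traits$species, sim$traits$species]
    f <- fit_gls(sim$traits$x, sim$traits$y, V)
    o <- oracle_gls_coef(sim$traits$x, sim$traits$y, V)
    expect_equal(unname(f$coefficients), unname(drop(o)), tolerance = 1e-10)
  }
})

test_that("GLS agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  sim <- simulate_scaling_dataset(12, sigma2 = 0.05, seed = 3)
  f <- fit_pgls(sim$traits, sim$tree, "BM")
  d <- sim$traits
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, sim$tree, form = ~species),
                 method = "REML")
  expect_equal(unname(f$coefficients["slope"]), unname(coef(g)["x"]),
               tolerance = 1e-8)
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("star phylogeny makes PGLS-BM identical to OLS", {
  star <- resolve_polytomies(read_tree("(A:1,B:1,C:1,D:1,E:1,F:1,G:1);"))
  set.seed(5)
  traits <- data.frame(species = star$tip.label, x = rnorm(7),
                       y = rnorm(7))
  fb <- fit_pgls(traits, star, "BM")
  fo <- fit_pgls(traits, model = "OLS")
  expect_equal(fb$coefficients, fo$coefficients, tolerance = 1e-12)
  expect_equal(fb$ci, fo$ci, tolerance = 1e-12)
})

test_that("PGLS-OU converges to OLS at large alpha", {
  sim <- simulate_scaling_dataset(24, sigma2 = 0.1, seed = 8)
  fo <- fit_pgls(sim$traits, model = "OLS")
  d_min <- min(ape::cophenetic.phylo(sim$tree)[upper.tri(diag(24))])
  fou <- fit_pgls(sim$traits, sim$tree, "OU", alpha = 40 / d_min)
  expect_lt(abs(fou$coefficients["slope"] - fo$coefficients["slope"]), 1e-6)
  # and the deviation shrinks as alpha grows past the correlation scale
  a_big <- 4 / d_min
  d1 <- abs(fit_pgls(sim$traits, sim$tree, "OU", alpha = a_big)$coefficients["slope"] -
            fo$coefficients["slope"])
  d2 <- abs(fit_pgls(sim$traits, sim$tree, "OU", alpha = 4 * a_big)$coefficients["slope"] -
            fo$coefficients["slope"])
  expect_lt(d2, d1)
})

test_that("AICc formula and preconditions", {
  expect_equal(aicc(-10, k = 3, n = 14), 28.4)
  expect_error(aicc(-10, k = 3, n = 4), "undefined")
  # approaches AIC for large n
  expect_equal(aicc(-10, k = 3, n = 1e7), 26, tolerance = 1e-5)
  f <- fit_gls(1:10, rnorm(10))
  expect_equal(f$AICc, aicc(f$logLik, 3, 10))
})

test_that("profiled-alpha OU fit uses k = 4 and a recorded alpha", {
  sim <- simulate_scaling_dataset(16, trait_model = "OU", alpha = 3,
                                  sigma2 = 0.2, seed = 21)
  f <- fit_pgls(sim$traits, sim$tree, "OU", alpha = "profile")
  expect_equal(f$k, 4)
  expect_true(is.finite(f$alpha) && f$alpha > 0)
  # profiled likelihood is at least as good as a fixed nearby alpha
  ffix <- fit_pgls(sim$traits, sim$tree, "OU", alpha = 1)
  expect_gte(f$logLik, ffix$logLik - 1e-8)
})

test_that("runs test matches the exact enumeration oracle", {
  dist <- oracle_runs_distribution(4, 3)
  # alternating signs: maximal runs r = 7 for +-+-+-+
  rt <- runs_test(c(1, -1, 1, -1, 1, -1, 1))
  expect_equal(rt$runs, 7L)
  p_exact <- min(1, 2 * min(sum(dist[2:7]), dist[7]))
  expect_equal(rt$p.value, p_exact, tolerance = 1e-12)
  # a low-runs sequence: +++----
  rt2 <- runs_test(c(1, 1, 1, 1, -1, -1, -1))
  expect_equal(rt2$runs, 2L)
  expect_equal(rt2$p.value, min(1, 2 * min(dist[2], sum(dist[2:7]))),
               tolerance = 1e-12)
  # all one sign is degenerate
  expect_true(is.na(runs_test(rep(1, 6))$p.value))
})

test_that("residual randomness flags a quadratic misfit, passes a linear fit", {
  x <- seq(-3, 3, length.out = 40)
  set.seed(11)
  f_bad <- fit_gls(x, x^2 + rnorm(40, 0, 0.1))
  expect_false(residual_randomness(f_bad)$random)
  f_ok <- fit_gls(x, 2 * x + rnorm(40, 0, 0.5))
  expect_true(residual_randomness(f_ok)$random)
  # indeterminate below 5 residuals
  expect_true(is.na(residual_randomness(fit_gls(1:4, c(1, 3, 2, 4)))$random))
})

test_that("Blomberg's K matches picante and is seed-deterministic", {
  skip_if_not_installed("picante")
  sim <- simulate_scaling_dataset(12, sigma2 = 0.05, seed = 3)
  y <- setNames(sim$traits$y, sim$traits$species)
  k1 <- phylo_signal_K(y, sim$tree, 999, seed = 5)
  k2 <- phylo_signal_K(y, sim$tree, 999, seed = 5)
  expect_identical(k1$p.value, k2$p.value)
  expect_equal(k1$K,
               as.numeric(picante::Kcalc(y[sim$tree$tip.label], sim$tree)),
               tolerance = 1e-8)
  expect_error(phylo_signal_K(setNames(rep(1, 12), names(y)), sim$tree),
               "constant")
})

test_that("random traits rarely show significant signal", {
  sim <- simulate_scaling_dataset(16, sigma2 = 1, seed = 2)
  ps <- sapply(1:30, function(i) {
    restore <- wingbone:::.Random.seed_safe_set(500 + i)
    y <- setNames(rnorm(16), sim$tree$tip.label)
    restore()
    phylo_signal_K(y, sim$tree, 199, seed = i)$p.value
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("three-criterion model selection follows the stated order", {
  sim <- simulate_scaling_dataset(20, sigma2 = 0.3, seed = 13)
  fits <- list(OLS = fit_pgls(sim$traits, model = "OLS"),
               BM = fit_pgls(sim$traits, sim$tree, "BM"))
  # criterion 1: no signal means OLS wins regardless of AICc
  sel <- select_model(fits, signal = list(K = 0.2, p.value = 0.4))
  expect_equal(sel$selected$label, "OLS")
  # criterion 3: with signal, lowest AICc among random-residual fits wins
  sel2 <- select_model(fits, signal = list(K = 1.1, p.value = 0.01))
  surv <- Filter(function(f) isTRUE(f$residual_random), sel2$candidates)
  expect_equal(sel2$selected$AICc, min(sapply(surv, `[[`, "AICc")))
  expect_true(length(sel2$trace) >= 3)
})
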