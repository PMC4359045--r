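#' Read a phylogeny from Newick text or file
#'
#' Thin wrapper over [ape::read.tree()] accepting either a file path or a
#' literal Newick string.
#'
#' @param x path to a Newick file, or a Newick string (contains "(")
#' @return an [ape::phylo] tree
#' @export
read_tree <- function(x) {
  tr <- if (grepl("(", x, fixed = TRUE)) ape::read.tree(text = x)
        else ape::read.tree(x)
  if (is.null(tr)) stop("could not parse Newick input")
  tr
}

#' Prune a phylogeny to a set of species
#'
#' Drops all tips not in `species`, preserving root-to-tip path lengths of
#' the retained tips.
#'
#' @param tree an [ape::phylo] tree
#' @param species character vector of tip labels to keep
#' @return pruned tree
#' @export
prune_tree <- function(tree, species) {
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0)
    stop("species not in tree: ", paste(missing, collapse = ", "))
  if (setequal(species, tree$tip.label)) return(tree)
  ape::keep.tip(tree, species)
}

#' Resolve polytomies with zero-length branches
#'
#' Breaks every multifurcation into an arbitrary sequence of bifurcations
#' joined by zero-length branches, leaving all pairwise patristic distances
#' unchanged.
#'
#' @param tree an [ape::phylo] tree
#' @return strictly binary tree
#' @export
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}

#' Brownian-motion variance-covariance matrix of a tree
#'
#' V\[i, j\] is the shared root-to-MRCA path length of tips i and j;
#' the diagonal holds root-to-tip depths.
#'
#' @param tree an [ape::phylo] tree with non-negative branch lengths
#' @return symmetric positive semi-definite matrix, tip labels as dimnames
#' @export
vcv_brownian <- function(tree) {
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ape::vcv.phylo(tree)
}

#' Ornstein-Uhlenbeck correlation matrix of a tree
#'
#' Martins-Hansen stationary correlation: corr\[i, j\] = exp(-alpha d_ij)
#' with d_ij the patristic distance between tips; the diagonal is 1. With
#' alpha = 0 every pair is perfectly correlated (degenerate; flagged).
#' Large alpha approaches the identity, making PGLS-OU converge to OLS.
#'
#' @param tree an [ape::phylo] tree (a warning is issued if not ultrametric)
#' @param alpha OU restraining strength (1/time), `>= 0`
#' @return correlation matrix with tip labels as dimnames
#' @export
vcv_ou <- function(tree, alpha) {
  stopifnot(alpha >= 0)
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    warning("tree is not ultrametric; OU correlation is approximate")
  if (alpha == 0)
    message("alpha = 0: OU correlation degenerates to an all-ones matrix")
  D <- ape::cophenetic.phylo(tree)
  exp(-alpha * D)
}

#' Generalized least squares regression with REML inference
#'
#' Model-I simple linear regression y = b0 + b1 x + e with
#' e ~ N(0, sigma^2 V), fit by generalized least squares. With `V = NULL`
#' (identity) the fit is exactly ordinary least squares. The restricted
#' (REML) log-likelihood is recorded by default and used for AICc;
#' 95% confidence intervals are Wald-t with n - 2 degrees of freedom.
#' A near-singular V (e.g. duplicated zero-length tips) is ridged on the
#' diagonal with a message.
#'
#' @param x,y predictor and response vectors
#' @param V error covariance/correlation matrix (NULL for identity/OLS);
#'   only its correlation structure matters, overall scale is profiled out
#' @param method `"REML"` (default) or `"ML"` likelihood
#' @param k parameter count for AICc (default 3: slope, intercept, residual
#'   variance; use 4 when an OU alpha was estimated from the same data)
#' @param label model label carried into summaries
#' @param conf.level confidence level for the Wald-t intervals
#' @param ridge diagonal ridge applied if V is computationally singular,
#'   as a fraction of mean(diag(V))
#' @return object of class `gls_fit`: list with `coefficients` (intercept,
#'   slope), `se`, `ci` (2x2 matrix), `sigma2`, `logLik`, `method`, `k`,
#'   `n`, `AICc`, `fitted`, `residuals`, `label`
#' @export
fit_gls <- function(x, y, V = NULL, method = c("REML", "ML"), k = 3,
                    label = if (is.null(V)) "OLS" else "GLS",
                    conf.level = 0.95, ridge = 1e-10) {
  method <- match.arg(method)
  n <- length(y)
  stopifnot(length(x) == n, n >= 3)
  X <- cbind(intercept = 1, slope = x)
  p <- 2L
  if (is.null(V)) {
    cV <- diag(n)
    logdetV <- 0
    Xs <- X; ys <- y
  } else {
    stopifnot(nrow(V) == n, ncol(V) == n)
    cV <- tryCatch(chol(V), error = function(e) {
      message(sprintf("covariance singular; adding ridge %g * mean(diag)", ridge))
      chol(V + diag(ridge * mean(diag(V)), n))
    })
    logdetV <- 2 * sum(log(diag(cV)))
    Xs <- backsolve(cV, X, transpose = TRUE)
    ys <- backsolve(cV, y, transpose = TRUE)
  }
  qrX <- qr(Xs)
  b <- stats::setNames(qr.coef(qrX, ys), c("intercept", "slope"))
  rs <- ys - Xs %*% b
  rss <- sum(rs^2)
  XtViX <- crossprod(Xs)
  if (method == "REML") {
    sigma2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2) +
                  logdetV + determinant(XtViX, logarithm = TRUE)$modulus[1] +
                  (n - p))
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  }
  se <- stats::setNames(sqrt(diag(rss / (n - p) * solve(XtViX))),
                        c("intercept", "slope"))
  tcrit <- stats::qt(1 - (1 - conf.level) / 2, df = n - 2)
  ci <- cbind(low = b - tcrit * se, high = b + tcrit * se)
  rownames(ci) <- c("intercept", "slope")
  fitted <- drop(X %*% b)
  fit <- structure(list(
    coefficients = b, se = se,
    ci = ci, sigma2 = sigma2, logLik = as.numeric(ll), method = method,
    k = k, n = n, fitted = fitted, residuals = y - fitted,
    conf.level = conf.level, label = label), class = "gls_fit")
  fit$AICc <- if (n > k + 1) aicc(fit$logLik, k = k, n = n) else NA_real_
  fit
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s, n = %d)\n", x$label, x$method, x$n))
  cat(sprintf("  slope     %8.4f  [%7.4f, %7.4f]\n", x$coefficients["slope"],
              x$ci["slope", "low"], x$ci["slope", "high"]))
  cat(sprintf("  intercept %8.4f  [%7.4f, %7.4f]\n",
              x$coefficients["intercept"],
              x$ci["intercept", "low"], x$ci["intercept", "high"]))
  cat(sprintf("  logLik %.3f  AICc %.3f\n", x$logLik, x$AICc))
  invisible(x)
}

#' Corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1); requires n > k + 1.
#'
#' @param logLik log-likelihood (or a `gls_fit`, whose stored values are used)
#' @param k number of estimated parameters
#' @param n sample size
#' @return AICc value
#' @export
aicc <- function(logLik, k, n) {
  if (inherits(logLik, "gls_fit")) {
    if (missing(k)) k <- logLik$k
    if (missing(n)) n <- logLik$n
    logLik <- logLik$logLik
  }
  if (n <= k + 1) stop("AICc undefined for n <= k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Phylogenetic generalized least squares on a trait table
#'
#' Aligns a trait table to a tree, builds the requested correlation
#' structure and calls [fit_gls()]. `model = "OU"` accepts a fixed `alpha`
#' (k = 3, mirroring analyses reported at stated alpha values) or
#' `alpha = "profile"` to maximize the REML likelihood over alpha
#' (k = 4).
#'
#' @param traits data frame with columns `species`, `x`, `y`; species must
#'   match the tree's tips exactly for phylogenetic models
#' @param tree an [ape::phylo] tree (ignored for `model = "OLS"`)
#' @param model `"OLS"`, `"BM"` or `"OU"`
#' @param alpha OU strength: a single number, or `"profile"`
#' @param method,conf.level passed to [fit_gls()]
#' @return a `gls_fit`; OU fits carry the alpha used in `$alpha` and label
#' @export
fit_pgls <- function(traits, tree = NULL, model = c("OLS", "BM", "OU"),
                     alpha = NULL, method = c("REML", "ML"),
                     conf.level = 0.95) {
  model <- match.arg(model)
  method <- match.arg(method)
  stopifnot(all(c("species", "x", "y") %in% names(traits)))
  if (anyNA(traits$x) || anyNA(traits$y)) stop("trait table contains NAs")
  if (model == "OLS")
    return(fit_gls(traits$x, traits$y, NULL, method, k = 3, label = "OLS",
                   conf.level = conf.level))
  stopifnot(!is.null(tree))
  if (!setequal(traits$species, tree$tip.label))
    stop("trait species and tree tips differ: ",
         paste(c(setdiff(traits$species, tree$tip.label),
                 setdiff(tree$tip.label, traits$species)), collapse = ", "))
  tree <- resolve_polytomies(tree)
  ord <- traits$species
  if (model == "BM") {
    V <- vcv_brownian(tree)[ord, ord]
    return(fit_gls(traits$x, traits$y, V, method, k = 3, label = "PGLS-BM",
                   conf.level = conf.level))
  }
  ## OU
  if (is.null(alpha)) stop("model = 'OU' needs alpha (number or 'profile')")
  if (identical(alpha, "profile")) {
    depth <- max(ape::node.depth.edgelength(tree))
    obj <- function(a) {
      V <- suppressWarnings(vcv_ou(tree, a))[ord, ord]
      -fit_gls(traits$x, traits$y, V, method, k = 4)$logLik
    }
    opt <- stats::optimize(obj, interval = c(1e-8, 50 / depth))
    a_hat <- opt$minimum
    V <- suppressWarnings(vcv_ou(tree, a_hat))[ord, ord]
    fit <- fit_gls(traits$x, traits$y, V, method, k = 4,
                   label = sprintf("PGLS-OU (alpha = %.3g, profiled)", a_hat),
                   conf.level = conf.level)
    fit$alpha <- a_hat
    return(fit)
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0)
  V <- vcv_ou(tree, alpha)[ord, ord]
  fit <- fit_gls(traits$x, traits$y, V, method, k = 3,
                 label = sprintf("PGLS-OU (alpha = %g)", alpha),
                 conf.level = conf.level)
  fit$alpha <- alpha
  fit
}

#' Blomberg's K with a tip-permutation significance test
#'
#' K compares the observed ratio of tip variance to phylogenetically
#' corrected variance against its Brownian-motion expectation on the same
#' tree; K is near 1 under BM, below 1 with less signal than BM. The
#' p-value is the permutation rank of the observed phylogenetically
#' corrected mean squared error (MSE) among tip-shuffled traits: traits with
#' signal have a smaller MSE than shuffled ones.
#'
#' @param trait named numeric vector (names = tip labels)
#' @param tree an [ape::phylo] tree
#' @param n_permutations number of tip shuffles (default 999, minimum 99)
#' @param seed integer seed for the permutations
#' @return list with `K`, `p.value`, `n_permutations`, `seed`
#' @export
phylo_signal_K <- function(trait, tree, n_permutations = 999, seed = 1) {
  stopifnot(n_permutations >= 99)
  if (is.null(names(trait))) stop("trait must be named by tip label")
  if (!setequal(names(trait), tree$tip.label))
    stop("trait names and tree tips differ")
  if (stats::sd(trait) == 0) stop("constant trait: K undefined")
  tree <- resolve_polytomies(tree)
  y <- trait[tree$tip.label]
  V <- vcv_brownian(tree)
  n <- length(y)
  Vi <- solve(V)
  one <- rep(1, n)
  denom_a <- drop(one %*% Vi %*% one)
  mse_of <- function(yy) {
    a <- drop(one %*% Vi %*% yy) / denom_a
    d <- yy - a
    c(mse0 = sum(d^2) / (n - 1), mse = drop(d %*% Vi %*% d) / (n - 1))
  }
  obs <- mse_of(y)
  expected_ratio <- (sum(diag(V)) - n / denom_a) / (n - 1)
  K <- (obs["mse0"] / obs["mse"]) / expected_ratio
  old <- .Random.seed_safe_set(seed)
  on.exit(old())
  perm_mse <- replicate(n_permutations, mse_of(sample(y))["mse"])
  p <- (1 + sum(perm_mse <= obs["mse"])) / (n_permutations + 1)
  list(K = unname(K), p.value = p, n_permutations = n_permutations,
       seed = seed)
}

## set the RNG seed, returning a restorer for the previous state
.Random.seed_safe_set <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Runs test for randomness of a sign sequence
#'
#' Two-sided Wald-Wolfowitz runs test on the signs of a numeric sequence
#' (zeros dropped). Exact run-count distribution for n <= 40, normal
#' approximation with continuity correction beyond.
#'
#' @param x numeric sequence (typically residuals in a meaningful order)
#' @return list with `runs`, `n_pos`, `n_neg`, `p.value`, `method`
#' @export
runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0)
    return(list(runs = 1L, n_pos = n1, n_neg = n2, p.value = NA_real_,
                method = "degenerate"))
  r <- 1L + sum(diff(s) != 0)
  if (n <= 40) {
    probs <- vapply(2:n, .runs_prob, 0, n1 = n1, n2 = n2)
    cdf_lo <- sum(probs[seq_len(r - 1)])
    cdf_hi <- sum(probs[(r - 1):length(probs)])
    p <- min(1, 2 * min(cdf_lo, cdf_hi))
    method <- "exact"
  } else {
    mu <- 1 + 2 * n1 * n2 / n
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    z <- (r - mu + ifelse(r < mu, 0.5, -0.5)) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(runs = r, n_pos = n1, n_neg = n2, p.value = p, method = method)
}

## P(R = r) for runs of two types with n1, n2 elements
.runs_prob <- function(r, n1, n2) {
  if (r %% 2 == 0) {
    k <- r / 2
    2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / choose(n1 + n2, n1)
  } else {
    k <- (r - 1) / 2
    (choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
     choose(n1 - 1, k - 1) * choose(n2 - 1, k)) / choose(n1 + n2, n1)
  }
}

#' Assess residual randomness of a regression fit
#'
#' Operationalizes the visual residual-plot check as a two-sided runs test
#' on the signs of the residuals ordered by fitted value; the fit is flagged
#' "random" when p >= `alpha`. Advisory only - the flag never alters the
#' fitted values.
#'
#' @param fit a `gls_fit`
#' @param alpha significance threshold, default 0.05
#' @return list with `random` (logical, NA when n < 5), `p.value`, `runs`
#' @export
residual_randomness <- function(fit, alpha = 0.05) {
  r <- fit$residuals[order(fit$fitted)]
  if (length(r) < 5)
    return(list(random = NA, p.value = NA_real_, runs = NA_integer_))
  rt <- runs_test(r)
  list(random = !is.na(rt$p.value) && rt$p.value >= alpha,
       p.value = rt$p.value, runs = rt$runs)
}

#' Three-criterion model selection among OLS and PGLS fits
#'
#' (1) If the response shows no significant phylogenetic signal, select the
#' OLS fit regardless of AICc. (2) Otherwise discard fits whose residuals
#' fail the randomness check. (3) Among survivors, pick the lowest AICc.
#' If every candidate is eliminated, the OLS fit is returned with a warning.
#'
#' @param fits named list of `gls_fit` objects; one must be labelled "OLS"
#' @param signal result of [phylo_signal_K()] for the response trait (or
#'   NULL to skip the gate)
#' @param signal_alpha significance threshold for the signal gate
#' @param resid_alpha threshold for the residual runs test
#' @return list with `selected` (a `gls_fit`), `trace` (character vector
#'   describing each decision), `candidates` (the input fits, each annotated
#'   with `$residual_random`)
#' @export
select_model <- function(fits, signal = NULL, signal_alpha = 0.05,
                         resid_alpha = 0.05) {
  stopifnot(length(fits) >= 1)
  labs <- vapply(fits, `[[`, "", "label")
  trace <- character(0)
  for (i in seq_along(fits)) {
    rr <- residual_randomness(fits[[i]], resid_alpha)
    fits[[i]]$residual_random <- rr$random
    trace <- c(trace, sprintf("%s: AICc = %.3f, residuals %s (runs p = %.3f)",
                              labs[i], fits[[i]]$AICc,
                              ifelse(isTRUE(rr$random), "random", "non-random"),
                              rr$p.value))
  }
  ols_i <- which(labs == "OLS")
  if (!is.null(signal) && signal$p.value >= signal_alpha) {
    trace <- c(trace, sprintf(
      "no significant phylogenetic signal (K = %.3f, p = %.3f >= %.2f): OLS selected",
      signal$K, signal$p.value, signal_alpha))
    if (length(ols_i) == 0) stop("no OLS candidate to fall back to")
    return(list(selected = fits[[ols_i[1]]], trace = trace,
                candidates = fits))
  }
  if (!is.null(signal))
    trace <- c(trace, sprintf(
      "significant phylogenetic signal (K = %.3f, p = %.3f)", signal$K,
      signal$p.value))
  keep <- vapply(fits, function(f) isTRUE(f$residual_random), NA)
  if (!any(keep)) {
    warning("all candidates eliminated by the residual check; returning OLS")
    return(list(selected = fits[[ols_i[1]]], trace = c(trace,
                "all candidates eliminated: OLS fallback"),
                candidates = fits))
  }
  surv <- fits[keep]
  best <- which.min(vapply(surv, `[[`, 0, "AICc"))
  trace <- c(trace, sprintf("selected %s by lowest AICc", surv[[best]]$label))
  list(selected = surv[[best]], trace = trace, candidates = fits)
}
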