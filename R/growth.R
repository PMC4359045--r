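## Sigmoidal growth models in mass form.
##   logistic:        m(t) = A / (1 + exp(-K (t - t0)))
##   Gompertz:        m(t) = A exp(-exp(-K (t - t0)))
##   von Bertalanffy: m(t) = A (1 - exp(-K (t - t0)))^3   (t >= t0 branch used)
.growth_models <- c("logistic", "gompertz", "von_bertalanffy")

growth_curve_value <- function(model, t, A, K, t0) {
  switch(match.arg(model, .growth_models),
    logistic = A / (1 + exp(-K * (t - t0))),
    gompertz = A * exp(-exp(-K * (t - t0))),
    von_bertalanffy = A * pmax(0, 1 - exp(-K * (t - t0)))^3)
}

#' Growth metrics at the inflection point
#'
#' Closed-form maximum growth rate and body mass at the growth-curve
#' inflection for the three standard sigmoidal models (mass form):
#' logistic inflects at mass A/2 with rate KA/4; Gompertz at A/e with rate
#' KA/e; von Bertalanffy (cubed-exponential mass form) at 8A/27 with rate
#' 4KA/9. The relative growth rate (RGR) is max rate / inflection mass and
#' is independent of the asymptote A (logistic: K/2; Gompertz: K;
#' von Bertalanffy: 3K/2).
#'
#' @param model one of `"logistic"`, `"gompertz"`, `"von_bertalanffy"`
#' @param A asymptotic mass (g), `> 0`
#' @param K growth constant (1/day), `> 0`
#' @return list with `model`, `A`, `K`, `max_rate` (g/day),
#'   `inflection_mass` (g), `rgr` (1/day), `log10_rgr`, `log10_A`
#' @export
inflection_metrics <- function(model, A, K) {
  model <- match.arg(model, .growth_models)
  stopifnot(A > 0, K > 0)
  im <- switch(model,
    logistic = A / 2,
    gompertz = A / exp(1),
    von_bertalanffy = 8 * A / 27)
  mr <- switch(model,
    logistic = K * A / 4,
    gompertz = K * A / exp(1),
    von_bertalanffy = 4 * K * A / 9)
  rgr <- relative_growth_rate(mr, im)
  list(model = model, A = A, K = K, max_rate = mr, inflection_mass = im,
       rgr = rgr, log10_rgr = log10(rgr), log10_A = log10(A))
}

#' Relative growth rate
#'
#' RGR = maximum growth rate divided by mass at inflection; removes the
#' confounding effect of body size from growth-rate comparisons.
#'
#' @param max_rate maximum growth rate (g/day)
#' @param inflection_mass body mass at inflection (g), `> 0`
#' @return RGR in 1/day
#' @export
relative_growth_rate <- function(max_rate, inflection_mass) {
  stopifnot(inflection_mass > 0)
  max_rate / inflection_mass
}

#' Fit a sigmoidal growth curve to a mass time series
#'
#' Nonlinear least squares (Levenberg-Marquardt via minpack.lm) fit of the
#' chosen model to (age, mass) data. Starting values: A from the series
#' maximum, t0 from the age nearest the model's inflection mass fraction,
#' K from the central slope.
#'
#' @param age ages (days)
#' @param mass masses (g)
#' @param model one of `"logistic"`, `"gompertz"`, `"von_bertalanffy"`
#' @return list with `model`, `A`, `K`, `t0`, `sigma` (residual SD),
#'   `fit` (the nls object)
#' @export
fit_growth_curve <- function(age, mass, model = c("logistic", "gompertz",
                                                  "von_bertalanffy")) {
  model <- match.arg(model)
  stopifnot(length(age) == length(mass))
  if (length(age) < 5)
    stop("need at least 5 time points spanning the inflection")
  A0 <- max(mass) * 1.05
  frac <- switch(model, logistic = 0.5, gompertz = exp(-1),
                 von_bertalanffy = 8 / 27)
  t00 <- age[which.min(abs(mass - frac * A0))]
  span <- diff(range(age))
  K0 <- 4 / span
  df <- data.frame(age = age, mass = mass)
  form <- switch(model,
    logistic = mass ~ A / (1 + exp(-K * (age - t0))),
    gompertz = mass ~ A * exp(-exp(-K * (age - t0))),
    von_bertalanffy = mass ~ A * (1 - exp(-K * (age - t0)))^3)
  ## the initial Jacobian can be near rank-deficient for some starts,
  ## so retry over a small grid of K and t0 candidates
  starts <- expand.grid(K = K0 * c(1, 2, 0.5, 4),
                        t0 = unique(c(t00, stats::quantile(age, c(0.25, 0.5)))))
  fit <- NULL; last_err <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df,
                        start = list(A = A0, K = starts$K[i],
                                     t0 = starts$t0[i]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop(sprintf(
      "growth-curve fit did not converge (starts tried: A=%.3g, K in {%s}, t0 in {%s}): %s",
      A0, paste(signif(unique(starts$K), 3), collapse = ", "),
      paste(signif(unique(starts$t0), 3), collapse = ", "), last_err))
  co <- stats::coef(fit)
  list(model = model, A = unname(co["A"]), K = unname(co["K"]),
       t0 = unname(co["t0"]), sigma = stats::sigma(fit), fit = fit)
}

#' Mass-specific field metabolic rate
#'
#' Standardizes a field metabolic rate by body mass and attaches the log10
#' transforms used in scaling regressions. The log transform is applied
#' after standardization.
#'
#' @param mass body mass (g), `> 0`
#' @param fmr field metabolic rate (kJ/day), `> 0`
#' @param species optional species label(s)
#' @return data frame with `species`, `mass`, `fmr`, `mass_specific_fmr`
#'   (kJ/(g day)), `log10_mass`, `log10_msfmr`
#' @export
mass_specific_fmr <- function(mass, fmr, species = NULL) {
  stopifnot(all(mass > 0), all(fmr > 0), length(mass) == length(fmr))
  if (is.null(species)) species <- rep(NA_character_, length(mass))
  data.frame(species = species, mass = mass, fmr = fmr,
             mass_specific_fmr = fmr / mass,
             log10_mass = log10(mass),
             log10_msfmr = log10(fmr / mass),
             stringsAsFactors = FALSE)
}

#' Growth metrics for a compiled table of growth-curve parameters
#'
#' Applies [inflection_metrics()] row-wise to a compilation table with
#' columns `species`, `model`, `A`, `K` (the layout of literature
#' growth-rate compilations).
#'
#' @param curves data frame with columns `species`, `model`, `A`, `K`
#' @return data frame adding `max_rate`, `inflection_mass`, `rgr`,
#'   `log10_rgr`, `log10_A`
#' @export
growth_metrics_table <- function(curves) {
  stopifnot(all(c("species", "model", "A", "K") %in% names(curves)))
  res <- lapply(seq_len(nrow(curves)), function(i)
    inflection_metrics(curves$model[i], curves$A[i], curves$K[i]))
  curves$max_rate <- vapply(res, `[[`, 0, "max_rate")
  curves$inflection_mass <- vapply(res, `[[`, 0, "inflection_mass")
  curves$rgr <- vapply(res, `[[`, 0, "rgr")
  curves$log10_rgr <- vapply(res, `[[`, 0, "log10_rgr")
  curves$log10_A <- vapply(res, `[[`, 0, "log10_A")
  curves
}
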