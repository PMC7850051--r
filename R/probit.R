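## dose_response: probit regression on log10 concentration, LC50 with
## Fieller 95% CI, and between-population comparison by CI overlap.
##
## The model is Phi^-1(p) = alpha + beta * log10(dose), fitted by ML
## (binomial GLM, probit link). LC50 = 10^(-alpha/beta). The CI comes from
## Fieller's theorem on the ratio -alpha/beta; when the deviance exceeds
## the chi-squared 0.95 quantile the variance is inflated by Finney's
## heterogeneity factor (deviance/df) and a t quantile replaces z.

#' Read a dose-response assay table
#'
#' @param path CSV with columns population, concentration, n_exposed,
#'   n_dead (replicate rows allowed).
#' @return data.table validated against the assay invariants.
#' @export
read_assay <- function(path) {
  a <- data.table::fread(path)
  need <- c("population", "concentration", "n_exposed", "n_dead")
  if (!all(need %in% names(a))) {
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  }
  validate_assay(a)
  a
}

validate_assay <- function(a) {
  if (any(a$concentration <= 0)) stop("assay: concentrations must be > 0")
  if (any(a$n_dead < 0 | a$n_dead > a$n_exposed)) {
    stop("assay: need 0 <= n_dead <= n_exposed")
  }
  invisible(a)
}

#' Probit dose-response fit with LC50 and Fieller 95% CI
#'
#' @param assay data.frame with columns concentration (ppm), n_exposed,
#'   n_dead (one population; replicates allowed).
#' @param level confidence level (default 0.95).
#' @param abbott apply Abbott's correction using control mortality given as
#'   a proportion (default NULL: no correction).
#' @return a `probit_fit` object: slope (probits per log10 ppm), intercept,
#'   lc50, ci_low, ci_high (heterogeneity-aware), ci_low_raw, ci_high_raw
#'   (uncorrected), deviance, df, heterogeneity flag.
#' @export
probit_fit <- function(assay, level = 0.95, abbott = NULL) {
  a <- data.table::as.data.table(assay)
  validate_assay(a)
  if (length(unique(a$concentration)) < 2L) {
    stop("probit_fit: need >= 2 distinct concentrations")
  }
  dead <- a$n_dead
  if (!is.null(abbott)) {
    stopifnot(abbott >= 0, abbott < 1)
    dead <- pmax(0, (a$n_dead / a$n_exposed - abbott) / (1 - abbott)) * a$n_exposed
  }
  ## complete separation check on per-concentration totals
  tot <- data.table::data.table(conc = a$concentration, dead = dead,
                                n = a$n_exposed)[
    , .(dead = sum(dead), n = sum(n)), by = conc]
  if (all(tot$dead == 0) || all(tot$dead == tot$n)) {
    stop("probit_fit: all-0% or all-100% mortality; no finite MLE")
  }
  x <- log10(a$concentration)
  fit <- suppressWarnings(
    stats::glm(cbind(dead, a$n_exposed - dead) ~ x,
               family = stats::binomial(link = "probit")))
  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  V <- stats::vcov(fit)
  dev <- stats::deviance(fit)
  df <- fit$df.residual
  het <- df > 0 && dev > stats::qchisq(0.95, df)
  rho <- -alpha / beta
  ci_raw <- fieller_ci(alpha, beta, V, level = level,
                       crit = stats::qnorm(1 - (1 - level) / 2))
  ci <- ci_raw
  if (het) {
    h <- dev / df
    ci <- fieller_ci(alpha, beta, V * h, level = level,
                     crit = stats::qt(1 - (1 - level) / 2, df))
  }
  if (beta <= 0) {
    warning("probit_fit: non-positive slope; LC50 CI undefined")
    ci <- ci_raw <- c(NA_real_, NA_real_)
  }
  structure(list(slope = beta, intercept = alpha, lc50 = 10^rho,
                 ci_low = 10^ci[1], ci_high = 10^ci[2],
                 ci_low_raw = 10^ci_raw[1], ci_high_raw = 10^ci_raw[2],
                 deviance = dev, df = df, heterogeneity = het,
                 level = level),
            class = "probit_fit")
}

## Fieller CI for rho = -alpha/beta on the log10 scale.
fieller_ci <- function(alpha, beta, V, level, crit) {
  rho <- -alpha / beta
  g <- crit^2 * V[2, 2] / beta^2
  if (g >= 1) return(c(-Inf, Inf))    # slope indistinguishable from 0
  ## Var(alpha + rho*beta) expansion with covariance sign for -alpha/beta
  v11 <- V[1, 1]; v12 <- V[1, 2]; v22 <- V[2, 2]
  disc <- v11 + 2 * rho * v12 + rho^2 * v22 -
    g * (v11 - v12^2 / v22)
  if (disc < 0) return(c(NA_real_, NA_real_))
  half <- (crit / abs(beta)) * sqrt(disc)
  centre <- rho + g * v12 / v22   # +v12: cov(-alpha, beta) = -v12
  c(centre - half, centre + half) / (1 - g)
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("<probit_fit> slope %.4f, LC50 %.4g ppm (%.0f%% CI %.4g-%.4g)%s\n",
              x$slope, x$lc50, 100 * x$level, x$ci_low, x$ci_high,
              if (x$heterogeneity) " [heterogeneity-corrected]" else ""))
  invisible(x)
}

#' Compare two LC50 estimates by confidence-interval overlap
#'
#' Populations are called significantly different when their CIs are
#' disjoint. Accepts [probit_fit] objects or any list with `lc50`,
#' `ci_low`, `ci_high` (so intervals from the literature can be compared).
#'
#' @param fitA,fitB fitted dose-response objects or lc50/CI lists.
#' @return list with `significant` (logical; NA when "not assessable"),
#'   `ratio` (lc50_A / lc50_B, the resistance ratio), and `assessable`.
#' @export
compare_lc50 <- function(fitA, fitB) {
  ok <- function(f) {
    !is.null(f$ci_low) && !is.null(f$ci_high) &&
      is.finite(f$ci_low) && is.finite(f$ci_high)
  }
  ratio <- fitA$lc50 / fitB$lc50
  if (!ok(fitA) || !ok(fitB)) {
    return(list(significant = NA, ratio = ratio, assessable = FALSE))
  }
  disjoint <- fitA$ci_high < fitB$ci_low || fitB$ci_high < fitA$ci_low
  list(significant = disjoint, ratio = ratio, assessable = TRUE)
}

#' Fit probit models for every population in an assay table
#'
#' @param assay table with population column (as from [read_assay]).
#' @param ... passed to [probit_fit].
#' @return data.table, one row per population (report-ready).
#' @export
probit_scan <- function(assay, ...) {
  a <- data.table::as.data.table(assay)
  pops <- unique(a$population)
  data.table::rbindlist(lapply(pops, function(p) {
    f <- probit_fit(a[population == p], ...)
    data.table::data.table(population = p, slope = f$slope,
                           intercept = f$intercept, lc50 = f$lc50,
                           ci_low = f$ci_low, ci_high = f$ci_high,
                           deviance = f$deviance,
                           heterogeneity = f$heterogeneity)
  }))
}

#' Simulate a probit dose-response assay
#'
#' Generates mortality counts from a true probit model; used by the
#' synthetic-data pipeline and the parameter-recovery tests. The default
#' design mirrors the bioassay protocol: 5-6 doses, 3 replicates of 20
#' larvae each, mortality scored at a fixed endpoint.
#'
#' @param lc50 true LC50 (ppm).
#' @param slope true probit slope per log10 ppm.
#' @param doses concentrations (ppm); default spans the LC50
#'   geometrically.
#' @param n_per_rep larvae per replicate (default 20).
#' @param reps replicates per dose (default 3).
#' @param population label for the output table.
#' @param seed optional RNG seed.
#' @return assay data.table (population, concentration, n_exposed, n_dead).
#' @export
simulate_assay <- function(lc50, slope, doses = lc50 * 10^seq(-1, 1, length.out = 5),
                           n_per_rep = 20L, reps = 3L,
                           population = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::pnorm(slope * (log10(doses) - log10(lc50)))
  out <- data.table::data.table(
    population = population,
    concentration = rep(doses, each = reps),
    n_exposed = n_per_rep)
  out[, n_dead := stats::rbinom(.N, n_per_rep, rep(p, each = reps))]
  out[]
}
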