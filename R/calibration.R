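# Calibration of the metabolic index phi = pO2 / pO2crit(T, B).
#
# Oxygen demand is modelled as a piecewise Arrhenius law on either side of a
# breakpoint temperature (default 12 degC):
#
#     pO2crit(T, B) = B^n * A_o * exp(E_o / (k_B * T_K))
#
# with branch-specific (A_o, E_o). Each branch is an ordinary least-squares
# fit of ln(pO2crit / B^n) on the Arrhenius coordinate x = 1/(k_B T_K), with
# slope E_o and intercept ln A_o. A negative E_o above the breakpoint and a
# positive E_o below give bidirectional hypoxia tolerance: tolerance is best
# (pO2crit lowest) at the breakpoint. The mass exponent n is fitted by
# alternating temperature- and mass-standardisation.

#' Boltzmann constant in eV per kelvin
#' @export
BOLTZMANN_EV <- 8.617333e-5

#' Arrhenius coordinate 1/(k_B T)
#'
#' @param temp temperature in degrees C; converted as K = degC + 273.15.
#' @return 1/(k_B T) in 1/eV.
#' @examples
#' arrhenius_coordinate(12)  # ~40.70
#' @export
arrhenius_coordinate <- function(temp) {
  if (any(temp <= -273.15)) stop("temperature at or below absolute zero")
  1 / (BOLTZMANN_EV * (temp + 273.15))
}

#' Metabolic-index parameter set
#'
#' Container for a calibrated (or externally supplied) piecewise demand
#' model. `A_o` values are on the kPa scale (the exponentiated regression
#' intercept), `E_o` in eV, `n` dimensionless.
#'
#' Validity checks: predicted pO2crit must be positive over 5-30 degC and
#' the two branches must agree at the breakpoint within
#' `continuity_tol` (relative; default 5%) -- a warning is raised otherwise.
#'
#' @param A_o_upper,E_o_upper intercept scale and slope for temperatures
#'   above the breakpoint.
#' @param A_o_lower,E_o_lower same for temperatures below the breakpoint.
#' @param n mass scaling exponent.
#' @param breakpoint_temp breakpoint, degrees C (default 12).
#' @param diagnostics optional list of fit diagnostics.
#' @param continuity_tol relative branch-mismatch tolerance at the breakpoint.
#' @return object of class `phi_params`.
#' @export
phi_params <- function(A_o_upper, E_o_upper, A_o_lower, E_o_lower, n,
                       breakpoint_temp = 12, diagnostics = NULL,
                       continuity_tol = 0.05) {
  p <- structure(
    list(A_o_upper = A_o_upper, E_o_upper = E_o_upper,
         A_o_lower = A_o_lower, E_o_lower = E_o_lower,
         n = n, breakpoint_temp = breakpoint_temp, k_B = BOLTZMANN_EV,
         diagnostics = diagnostics),
    class = "phi_params")
  tt <- seq(5, 30, by = 0.5)
  pc <- po2crit_predict(p, tt, mass = 1)
  if (any(!is.finite(pc)) || any(pc <= 0)) {
    stop("parameters predict non-positive pO2crit over 5-30 degC")
  }
  bu <- branch_po2crit(p, breakpoint_temp, 1, "upper")
  bl <- branch_po2crit(p, breakpoint_temp, 1, "lower")
  if (abs(bu - bl) / bu > continuity_tol) {
    warning(sprintf(
      "branch pO2crit at the %g degC breakpoint differ by %.1f%% (upper %.3f, lower %.3f kPa)",
      breakpoint_temp, 100 * abs(bu - bl) / bu, bu, bl))
  }
  p
}

branch_po2crit <- function(params, temp, mass, branch) {
  x <- arrhenius_coordinate(temp)
  A <- if (branch == "upper") params$A_o_upper else params$A_o_lower
  E <- if (branch == "upper") params$E_o_upper else params$E_o_lower
  mass^params$n * A * exp(E * x)
}

#' Predicted critical oxygen partial pressure
#'
#' Branch selection: temperatures strictly below the breakpoint use the
#' lower branch; the breakpoint itself and everything above it use the
#' upper branch.
#'
#' @param params a [phi_params()] or [phi_calibrate()] fit.
#' @param temp temperature, degrees C (vectorised).
#' @param mass body mass, kg.
#' @return pO2crit in kPa.
#' @export
po2crit_predict <- function(params, temp, mass = 1) {
  params <- as_phi_params(params)
  up <- branch_po2crit(params, temp, mass, "upper")
  lo <- branch_po2crit(params, temp, mass, "lower")
  ifelse(temp >= params$breakpoint_temp, up, lo)
}

#' The metabolic index
#'
#' phi = pO2 / pO2crit(T, B): the ratio of ambient oxygen supply to the
#' minimum partial pressure sustaining standard metabolism. phi = 1 means the
#' habitat barely supports resting metabolism; at normoxia phi approximates
#' factorial aerobic scope.
#'
#' @param params a [phi_params()] or [phi_calibrate()] fit.
#' @param temp temperature, degrees C.
#' @param po2 ambient oxygen partial pressure, kPa (>= 0).
#' @param mass body mass, kg.
#' @return dimensionless index (vectorised).
#' @export
phi <- function(params, temp, po2, mass = 1) {
  stopifnot(all(po2 >= 0, na.rm = TRUE))
  po2 / po2crit_predict(params, temp, mass)
}

as_phi_params <- function(x) {
  if (inherits(x, "phi_fit")) x$params
  else if (inherits(x, "phi_params")) x
  else stop("expected a phi_params or phi_fit object")
}

check_calibration_data <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("po2crit", "mass", "test_temp") %in% names(data)))
  if (any(data$po2crit <= 0)) stop("po2crit must be positive")
  invisible(data)
}

branch_rows <- function(data, breakpoint) {
  # rows at exactly the breakpoint temperature enter both branch fits
  list(upper = data[data$test_temp >= breakpoint, , drop = FALSE],
       lower = data[data$test_temp <= breakpoint, , drop = FALSE])
}

#' Fit the mass scaling exponent of pO2crit
#'
#' Alternating scheme: (1) provisional branch-specific Arrhenius fits of
#' ln(pO2crit / B^n) on x = 1/(k_B T) at the current n (initially 0);
#' (2) divide pO2crit by its branch's fitted Arrhenius value
#' A_o exp(E_o x) (temperature standardisation; the branch intercept must be
#' included because the two branches sit at very different A_o scales);
#' (3) least-squares fit on logs of the power law standardized-pO2crit ~
#' B^n; repeat until |delta n| < tol.
#'
#' @param data calibration rows (trial_id, po2crit, mass, test_temp, ...).
#' @param breakpoint breakpoint temperature, degrees C.
#' @param tol convergence tolerance on n (default 1e-4).
#' @param max_iter iteration cap (default 20).
#' @return list with `n`, `iterations`, `converged`, and the final power-law
#'   fit summary (`log_intercept`, `r_squared`).
#' @export
fit_mass_exponent <- function(data, breakpoint = 12, tol = 1e-4, max_iter = 20) {
  check_calibration_data(data)
  if (nrow(data) < 10) stop("need at least 10 trials to fit a mass exponent")
  if (max(data$mass) / min(data$mass) < 2) {
    stop("degenerate mass range: need at least a 2-fold spread")
  }
  x <- arrhenius_coordinate(data$test_temp)
  n <- 0
  converged <- FALSE
  pl <- NULL
  for (it in seq_len(max_iter)) {
    std <- data$po2crit / data$mass^n
    br <- branch_rows(transform(data, .y = log(std), .x = x), breakpoint)
    tfac <- numeric(nrow(data))
    for (b in c("upper", "lower")) {
      rows <- br[[b]]
      if (length(unique(rows$test_temp)) < 2) {
        stop("need >= 2 distinct temperatures per branch for the provisional fit")
      }
      fit <- stats::lm(.y ~ .x, data = rows)
      idx <- if (b == "upper") data$test_temp >= breakpoint else data$test_temp < breakpoint
      tfac[idx] <- exp(stats::coef(fit)[1] + stats::coef(fit)[2] * x[idx])
    }
    temp_std <- data$po2crit / tfac
    pl <- stats::lm(log(temp_std) ~ log(data$mass))
    n_new <- unname(stats::coef(pl)[2])
    if (abs(n_new - n) < tol) {
      n <- n_new
      converged <- TRUE
      break
    }
    n <- n_new
  }
  if (!converged) warning("mass-exponent iteration did not converge")
  list(n = n, iterations = it, converged = converged,
       log_intercept = unname(stats::coef(pl)[1]),
       r_squared = summary(pl)$r.squared)
}

#' Fit the piecewise Arrhenius demand model
#'
#' Per-branch ordinary least squares of ln(pO2crit / B^n) on the Arrhenius
#' coordinate; the slope is stored as E_o and the exponentiated intercept as
#' A_o, so that predicted mass-standardised pO2crit(T) = A_o exp(E_o x).
#' Rows at exactly the breakpoint temperature enter both branches. At least
#' two distinct temperatures per branch are required; two groups identify
#' the branch line exactly (the usual design below the breakpoint, e.g.
#' treatments at 8 and 12 degC).
#'
#' @param data calibration rows.
#' @param n mass scaling exponent (from [fit_mass_exponent()], or 0).
#' @param breakpoint breakpoint temperature, degrees C (default 12; fixed,
#'   not searched).
#' @return a [phi_params()] object with per-branch R^2 and residual SD in
#'   `$diagnostics`.
#' @export
fit_piecewise_arrhenius <- function(data, n = 0, breakpoint = 12) {
  check_calibration_data(data)
  br <- branch_rows(data, breakpoint)
  out <- list()
  diag <- list()
  for (b in c("upper", "lower")) {
    rows <- br[[b]]
    if (length(unique(rows$test_temp)) < 2) {
      stop(sprintf("need >= 2 distinct temperatures in the %s branch", b))
    }
    x <- arrhenius_coordinate(rows$test_temp)
    if (stats::sd(x) < 1e-12) stop("zero-variance Arrhenius coordinate")
    y <- log(rows$po2crit / rows$mass^n)
    fit <- stats::lm(y ~ x)
    out[[paste0("A_o_", b)]] <- exp(unname(stats::coef(fit)[1]))
    out[[paste0("E_o_", b)]] <- unname(stats::coef(fit)[2])
    diag[[b]] <- list(r_squared = summary(fit)$r.squared,
                      residual_sd = summary(fit)$sigma,
                      n_trials = nrow(rows))
  }
  phi_params(A_o_upper = out$A_o_upper, E_o_upper = out$E_o_upper,
             A_o_lower = out$A_o_lower, E_o_lower = out$E_o_lower,
             n = n, breakpoint_temp = breakpoint, diagnostics = diag)
}

#' Calibrate the metabolic index from per-individual pO2crit data
#'
#' The top-level fitting function: estimates the mass scaling exponent by the
#' alternating scheme of [fit_mass_exponent()] (unless `n` is supplied), then
#' fits the piecewise Arrhenius demand model with [fit_piecewise_arrhenius()].
#'
#' @param data data.frame with columns po2crit (kPa), mass (kg), test_temp
#'   (degC) and optionally area / sex_stage (see [process_trials()]).
#' @param breakpoint breakpoint temperature, degrees C.
#' @param n fix the mass exponent instead of fitting it (e.g. 0 to disable
#'   mass standardisation).
#' @return an object of class `phi_fit` with components `params`
#'   ([phi_params()]), `mass_fit`, `data`, and `call`; supports `print`,
#'   `summary`, `coef`, `predict` and `plot`.
#' @examples
#' truth <- planted_truth()
#' cohort <- generate_respirometry_cohort(synthetic_config(), truth)
#' cal <- process_trials(cohort$trials)
#' fit <- phi_calibrate(cal)
#' coef(fit)
#' @export
phi_calibrate <- function(data, breakpoint = 12, n = NULL) {
  check_calibration_data(data)
  mass_fit <- NULL
  if (is.null(n)) {
    mass_fit <- fit_mass_exponent(data, breakpoint = breakpoint)
    n <- mass_fit$n
  }
  params <- fit_piecewise_arrhenius(data, n = n, breakpoint = breakpoint)
  structure(list(params = params, mass_fit = mass_fit, data = data,
                 call = match.call()),
            class = "phi_fit")
}

#' @export
print.phi_params <- function(x, ...) {
  cat("Metabolic-index parameters (pO2crit = B^n A_o exp(E_o/(kB T)))\n")
  cat(sprintf("  breakpoint: %g degC; mass exponent n = %.4f\n",
              x$breakpoint_temp, x$n))
  cat(sprintf("  upper branch (T >= %g): A_o = %.6g, E_o = %.4f eV\n",
              x$breakpoint_temp, x$A_o_upper, x$E_o_upper))
  cat(sprintf("  lower branch (T <  %g): A_o = %.6g, E_o = %.4f eV\n",
              x$breakpoint_temp, x$A_o_lower, x$E_o_lower))
  invisible(x)
}

#' @export
print.phi_fit <- function(x, ...) {
  cat("Calibrated metabolic index\n")
  print(x$params)
  if (!is.null(x$mass_fit)) {
    cat(sprintf("  mass exponent fitted in %d iteration(s)%s\n",
                x$mass_fit$iterations,
                if (x$mass_fit$converged) "" else " (not converged)"))
  }
  cat(sprintf("  %d trials, %d distinct temperatures\n",
              nrow(x$data), length(unique(x$data$test_temp))))
  invisible(x)
}

#' @export
coef.phi_fit <- function(object, ...) {
  p <- object$params
  c(A_o_upper = p$A_o_upper, E_o_upper = p$E_o_upper,
    A_o_lower = p$A_o_lower, E_o_lower = p$E_o_lower,
    n = p$n, breakpoint_temp = p$breakpoint_temp)
}

#' @export
summary.phi_fit <- function(object, ...) {
  p <- object$params
  bp <- p$breakpoint_temp
  out <- list(
    coefficients = coef(object),
    diagnostics = p$diagnostics,
    continuity_gap_kpa = abs(branch_po2crit(p, bp, 1, "upper") -
                             branch_po2crit(p, bp, 1, "lower")),
    po2crit_at_breakpoint = po2crit_predict(p, bp),
    n_trials = nrow(object$data))
  class(out) <- "summary.phi_fit"
  out
}

#' @export
print.summary.phi_fit <- function(x, ...) {
  cat("Calibrated metabolic index -- summary\n\ncoefficients:\n")
  print(x$coefficients)
  cat(sprintf("\nbranch continuity gap at breakpoint: %.4f kPa (pO2crit %.3f kPa)\n",
              x$continuity_gap_kpa, x$po2crit_at_breakpoint))
  for (b in names(x$diagnostics)) {
    d <- x$diagnostics[[b]]
    cat(sprintf("%s branch: R^2 = %.3f, residual SD = %.3f (%d trials)\n",
                b, d$r_squared, d$residual_sd, d$n_trials))
  }
  invisible(x)
}

#' Predict from a calibrated metabolic index
#'
#' @param object a `phi_fit`.
#' @param newdata data.frame with `temp` (degC), optionally `mass` (kg,
#'   default 1) and -- for `type = "phi"` -- `po2` (kPa).
#' @param type `"po2crit"` (demand, kPa) or `"phi"` (supply/demand ratio).
#' @param ... unused.
#' @export
predict.phi_fit <- function(object, newdata, type = c("po2crit", "phi"), ...) {
  type <- match.arg(type)
  stopifnot(is.data.frame(newdata), "temp" %in% names(newdata))
  mass <- if ("mass" %in% names(newdata)) newdata$mass else 1
  if (type == "po2crit") {
    po2crit_predict(object, newdata$temp, mass)
  } else {
    if (!"po2" %in% names(newdata)) stop("type = 'phi' needs a po2 column")
    phi(object, newdata$temp, newdata$po2, mass)
  }
}

#' Arrhenius diagnostic plot of a calibrated index
#'
#' Mass-standardised ln(pO2crit) against 1/(k_B T) with the two fitted
#' branches.
#'
#' @param x a `phi_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phi_fit <- function(x, ...) {
  p <- x$params
  d <- x$data
  xx <- arrhenius_coordinate(d$test_temp)
  yy <- log(d$po2crit / d$mass^p$n)
  graphics::plot(xx, yy, xlab = expression(1 / (k[B] * T) ~ (eV^-1)),
                 ylab = expression(ln(p * O[2 * crit] / B^n)), ...)
  xbp <- arrhenius_coordinate(p$breakpoint_temp)
  xs <- seq(min(xx), xbp, length.out = 50)
  graphics::lines(xs, log(p$A_o_upper) + p$E_o_upper * xs, col = "firebrick")
  xs <- seq(xbp, max(xx), length.out = 50)
  graphics::lines(xs, log(p$A_o_lower) + p$E_o_lower * xs, col = "steelblue")
  invisible(x)
}

#' Test for group effects on the pO2crit-temperature relationship
#'
#' Linear model po2crit ~ temp * factor restricted to a temperature range
#' (default 12-24 degC, where the relationship is linear in temperature),
#' with sequential ANOVA F tests for the additive factor effect and its
#' interaction with temperature. Pooling across groups is recommended when
#' neither term is significant at `alpha`.
#'
#' @param data calibration rows.
#' @param factor name of the grouping column ("area" or "sex_stage").
#' @param temp_range inclusive temperature window, degrees C.
#' @param alpha significance level for the pooling recommendation.
#' @return list with the ANOVA table, per-term F and p, and `pool`
#'   (logical recommendation).
#' @export
test_group_effects <- function(data, factor = "area", temp_range = c(12, 24),
                               alpha = 0.05) {
  check_calibration_data(data)
  stopifnot(factor %in% names(data))
  d <- data[data$test_temp >= temp_range[1] & data$test_temp <= temp_range[2], ]
  d$grp <- base::factor(d[[factor]])
  if (nlevels(d$grp) < 2) stop("factor has fewer than 2 levels in the range")
  fit <- stats::lm(po2crit ~ test_temp * grp, data = d)
  an <- stats::anova(fit)
  additive <- an["grp", ]
  interact <- an["test_temp:grp", ]
  list(anova = an,
       additive_F = additive$`F value`, additive_p = additive$`Pr(>F)`,
       interaction_F = interact$`F value`, interaction_p = interact$`Pr(>F)`,
       pool = additive$`Pr(>F)` > alpha && interact$`Pr(>F)` > alpha)
}

#' Read / write metabolic-index parameter files
#'
#' Plain-text DCF (key: value) exchange format consumed by the layer
#' projection stage.
#'
#' @param params a [phi_params()] or `phi_fit`.
#' @param file path.
#' @export
write_phi_params <- function(params, file) {
  p <- as_phi_params(params)
  df <- data.frame(A_o_upper = format(p$A_o_upper, digits = 17),
                   E_o_upper = format(p$E_o_upper, digits = 17),
                   A_o_lower = format(p$A_o_lower, digits = 17),
                   E_o_lower = format(p$E_o_lower, digits = 17),
                   n = format(p$n, digits = 17),
                   breakpoint_temp = format(p$breakpoint_temp, digits = 17))
  write.dcf(df, file)
  invisible(file)
}

#' @rdname write_phi_params
#' @export
read_phi_params <- function(file) {
  d <- as.data.frame(read.dcf(file), stringsAsFactors = FALSE)
  phi_params(A_o_upper = as.numeric(d$A_o_upper),
             E_o_upper = as.numeric(d$E_o_upper),
             A_o_lower = as.numeric(d$A_o_lower),
             E_o_lower = as.numeric(d$E_o_lower),
             n = as.numeric(d$n),
             breakpoint_temp = as.numeric(d$breakpoint_temp))
}
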