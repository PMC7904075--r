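# Estimation of standard (SMR) and maximum (MMR) metabolic rates and the
# critical oxygen level (O2crit / pO2crit) from per-individual respirometry
# traces. A trace holds per-measurement mass-specific metabolic rate paired
# with the mean chamber oxygen saturation, split into routine, post-chase and
# progressive-hypoxia phases.

#' Construct a respirometry trial
#'
#' @param trial_id identifier.
#' @param mass body mass, kg.
#' @param test_temp test temperature, degrees C (the trial runs at the test
#'   temperature, not the holding temperature).
#' @param measurements data.frame with columns `time` (min), `mr`
#'   (mg O2 min^-1 kg^-1), `o2_sat` (% air saturation) and `phase`
#'   (one of "routine", "post_chase", "hypoxia").
#' @param area capture area label (e.g. "TNP", "PE").
#' @param sex_stage sex/stage label ("F", "M", "F/I", "M/I", "unknown").
#' @return an object of class `respirometry_trial`.
#' @export
respirometry_trial <- function(trial_id, mass, test_temp, measurements,
                               area = "unknown", sex_stage = "unknown") {
  stopifnot(is.data.frame(measurements),
            all(c("time", "mr", "o2_sat", "phase") %in% names(measurements)))
  m <- measurements
  if (any(m$mr < 0)) stop("negative metabolic rate")
  if (any(m$o2_sat < 0 | m$o2_sat > 102)) {
    stop("o2_sat outside 0..102 (% air saturation)")
  }
  if (!all(m$phase %in% c("routine", "post_chase", "hypoxia"))) {
    stop("unknown phase label")
  }
  hyp <- m[m$phase == "hypoxia", , drop = FALSE]
  if (nrow(hyp) > 1) {
    hyp <- hyp[order(hyp$time), , drop = FALSE]
    if (any(diff(hyp$o2_sat) > 1e-9)) {
      stop("hypoxia-phase saturations must be non-increasing in time")
    }
  }
  if (sum(m$phase == "routine") < 10) {
    stop("need at least 10 routine-phase measurements")
  }
  structure(
    list(trial_id = trial_id, mass = mass, test_temp = test_temp,
         area = area, sex_stage = sex_stage, measurements = m),
    class = "respirometry_trial")
}

#' @export
print.respirometry_trial <- function(x, ...) {
  cat(sprintf("Respirometry trial %s: %.2f kg at %g degC (%d measurements)\n",
              x$trial_id, x$mass, x$test_temp, nrow(x$measurements)))
  print(table(x$measurements$phase))
  invisible(x)
}

#' Standard metabolic rate from the routine phase
#'
#' SMR is the quantile that assigns the bottom 20% of all pre-chase
#' metabolic-rate measurements, using the linear-interpolation quantile
#' definition (type 7) by default.
#'
#' @param trial a [respirometry_trial()].
#' @param prob quantile level (default 0.2).
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return SMR in mg O2 min^-1 kg^-1.
#' @export
estimate_smr <- function(trial, prob = 0.2, type = 7) {
  mr <- trial$measurements$mr[trial$measurements$phase == "routine"]
  if (length(mr) < 10) stop("need at least 10 routine-phase measurements")
  unname(stats::quantile(mr, probs = prob, type = type))
}

#' Maximum metabolic rate from the post-chase phase
#'
#' @param trial a [respirometry_trial()].
#' @return maximum post-chase metabolic rate, mg O2 min^-1 kg^-1.
#' @export
estimate_mmr <- function(trial) {
  mr <- trial$measurements$mr[trial$measurements$phase == "post_chase"]
  if (length(mr) < 1) stop("no post-chase measurements")
  max(mr)
}

# One-sided p-value for slope > 0; a numerically perfect fit counts as
# significant when the slope is positive (zero residual variance makes the
# usual t undefined).
slope_significant <- function(fit, alpha = 0.05) {
  cf <- stats::coef(fit)
  if (length(cf) < 2 || !is.finite(cf[2]) || cf[2] <= 0) return(FALSE)
  sm <- suppressWarnings(summary(fit))
  if (sm$sigma < 1e-12) return(TRUE)
  tval <- sm$coefficients[2, "t value"]
  p_one <- stats::pt(tval, df = fit$df.residual, lower.tail = FALSE)
  p_one < alpha
}

# An oxyconforming decline passes through the origin (rate proportional to
# saturation); near-SMR points smuggled in from above the true O2crit drag
# the fitted intercept up. A significantly positive intercept therefore
# flags contamination.
intercept_positive <- function(fit, alpha = 0.05) {
  cf <- stats::coef(fit)
  if (length(cf) < 2 || !is.finite(cf[1]) || cf[1] <= 0) return(FALSE)
  sm <- suppressWarnings(summary(fit))
  if (sm$sigma < 1e-12) return(FALSE)
  tval <- sm$coefficients[1, "t value"]
  stats::pt(tval, df = fit$df.residual, lower.tail = FALSE) < alpha
}

r_squared <- function(fit) {
  sm <- suppressWarnings(summary(fit))
  if (sm$sigma < 1e-12) return(1)
  sm$r.squared
}

#' Critical oxygen level from the progressive-hypoxia phase
#'
#' O2crit is the intersection between the SMR line and an ordinary
#' least-squares regression through the hypoxia-phase measurements whose
#' metabolic rate has fallen below SMR (oxyconforming decline). Up to
#' `max_points` of the lowest-saturation sub-SMR points are used (minimum 3).
#'
#' An automated overestimate check replaces the visual inspection used in
#' practice: the regression is refit with only the 4 lowest-saturation
#' points (one more than the minimum needed for a regression) and flagged
#' `adjusted` when the initial fit shows any of (i) a slope not
#' significantly greater than zero (one-sided, alpha = 0.05), (ii)
#' R^2 < 0.5, or (iii) an intercept significantly above zero -- an
#' oxyconforming decline is proportional to saturation, so a positive
#' intercept indicates near-SMR points included from above the true O2crit.
#' `force_adjust` applies the refit unconditionally (manual override).
#'
#' @param trial a [respirometry_trial()].
#' @param smr standard metabolic rate for this trial (from [estimate_smr()]).
#' @param max_points maximum number of regression points (default 15).
#' @param force_adjust force the 4-point refit.
#' @param salinity,baro_kpa passed to [saturation_to_po2()] for the kPa
#'   conversion at the trial's test temperature.
#' @return an object of class `o2crit_result`: list with `smr`, `o2crit_sat`
#'   (%), `po2crit` (kPa), `n_regression_points`, `slope`, `intercept`,
#'   `adjusted`.
#' @export
estimate_o2crit <- function(trial, smr, max_points = 15, force_adjust = FALSE,
                            salinity = 0, baro_kpa = STANDARD_ATM_KPA) {
  stopifnot(smr > 0)
  hyp <- trial$measurements[trial$measurements$phase == "hypoxia", , drop = FALSE]
  if (nrow(hyp) == 0) stop("no hypoxia phase in trial")
  sub <- hyp[hyp$mr < smr, , drop = FALSE]
  if (nrow(sub) < 3) stop("fewer than 3 sub-SMR hypoxia points")
  sub <- sub[order(sub$o2_sat), , drop = FALSE]

  fit_points <- function(k) {
    pts <- sub[seq_len(min(k, nrow(sub))), , drop = FALSE]
    list(pts = pts, fit = stats::lm(mr ~ o2_sat, data = pts))
  }

  intersect_sat <- function(sel) {
    b <- unname(stats::coef(sel$fit)[2])
    a <- unname(stats::coef(sel$fit)[1])
    s <- (smr - a) / b
    list(a = a, b = b, sat = s,
         valid = is.finite(b) && b > 0 && s > 0 && s < 100)
  }
  sel <- fit_points(max_points)
  full <- intersect_sat(sel)
  use <- full
  adjusted <- FALSE
  if (force_adjust || !slope_significant(sel$fit) || r_squared(sel$fit) < 0.5 ||
      intercept_positive(sel$fit)) {
    sel4 <- fit_points(4)
    refit <- intersect_sat(sel4)
    # the refit exists to correct overestimates: adopt it when it is valid
    # and lowers the estimate (or when forced, or the full fit is unusable)
    if (refit$valid && (force_adjust || !full$valid || refit$sat < full$sat)) {
      sel <- sel4
      use <- refit
      adjusted <- TRUE
    }
  }
  if (!is.finite(use$b) || use$b <= 0) {
    stop("non-positive regression slope: trace does not show an ",
         "oxyconforming decline")
  }
  if (!use$valid) {
    stop(sprintf("O2crit estimate %.1f%% outside (0, 100)", use$sat))
  }
  a <- use$a; b <- use$b
  o2crit_sat <- use$sat
  structure(
    list(trial_id = trial$trial_id,
         smr = smr,
         o2crit_sat = o2crit_sat,
         po2crit = saturation_to_po2(o2crit_sat, trial$test_temp,
                                     salinity = salinity, baro_kpa = baro_kpa),
         n_regression_points = nrow(sel$pts),
         slope = b, intercept = a,
         adjusted = adjusted),
    class = "o2crit_result")
}

#' @export
print.o2crit_result <- function(x, ...) {
  cat(sprintf(
    "O2crit: %.2f%% saturation (pO2crit %.3f kPa) at SMR %.3f; %d regression points%s\n",
    x$o2crit_sat, x$po2crit, x$smr, x$n_regression_points,
    if (x$adjusted) " [adjusted to 4]" else ""))
  invisible(x)
}

#' Process a set of trials into a calibration dataset
#'
#' Runs [estimate_smr()] and [estimate_o2crit()] on each trial and assembles
#' the per-individual pO2crit table consumed by [phi_calibrate()].
#'
#' @param trials list of [respirometry_trial()] objects.
#' @param max_points,salinity,baro_kpa passed to [estimate_o2crit()].
#' @param force_adjust character vector of trial ids whose O2crit regression
#'   should be forced to 4 points (manual override).
#' @return data.frame with columns trial_id, po2crit, mass, test_temp, area,
#'   sex_stage, smr, o2crit_sat, n_regression_points, adjusted.
#' @export
process_trials <- function(trials, max_points = 15, salinity = 0,
                           baro_kpa = STANDARD_ATM_KPA, force_adjust = character()) {
  rows <- lapply(trials, function(tr) {
    smr <- estimate_smr(tr)
    res <- estimate_o2crit(tr, smr, max_points = max_points,
                           force_adjust = tr$trial_id %in% force_adjust,
                           salinity = salinity, baro_kpa = baro_kpa)
    data.frame(trial_id = tr$trial_id, po2crit = res$po2crit, mass = tr$mass,
               test_temp = tr$test_temp, area = tr$area, sex_stage = tr$sex_stage,
               smr = smr, o2crit_sat = res$o2crit_sat,
               n_regression_points = res$n_regression_points,
               adjusted = res$adjusted, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diagnostic plot of an O2crit regression
#'
#' @param trial a [respirometry_trial()].
#' @param result the matching [estimate_o2crit()] output.
#' @param ... passed to [graphics::plot()].
#' @export
plot_o2crit <- function(trial, result, ...) {
  m <- trial$measurements
  graphics::plot(m$o2_sat, m$mr, xlab = "O2 (% air saturation)",
                 ylab = expression(MO[2] ~ (mg ~ O[2] ~ min^-1 ~ kg^-1)),
                 col = ifelse(m$phase == "hypoxia", "steelblue", "grey60"), ...)
  graphics::abline(h = result$smr, lty = 2)
  graphics::abline(result$intercept, result$slope, col = "firebrick")
  graphics::abline(v = result$o2crit_sat, lty = 3)
  invisible(NULL)
}

#' Read / write tidy respirometry traces
#'
#' The exchange format is one CSV row per measurement with columns trial_id,
#' mass, test_temp, area, sex_stage, phase, time_min, mr, o2_sat.
#'
#' @param file path to CSV.
#' @return `read_trials_csv`: list of [respirometry_trial()] objects.
#' @export
read_trials_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  lapply(split(d, d$trial_id), function(g) {
    respirometry_trial(
      trial_id = g$trial_id[1], mass = g$mass[1], test_temp = g$test_temp[1],
      area = g$area[1], sex_stage = g$sex_stage[1],
      measurements = data.frame(time = g$time_min, mr = g$mr,
                                o2_sat = g$o2_sat, phase = g$phase))
  })
}

#' @rdname read_trials_csv
#' @param trials list of trials to write.
#' @export
write_trials_csv <- function(trials, file) {
  rows <- lapply(trials, function(tr) {
    m <- tr$measurements
    data.frame(trial_id = tr$trial_id, mass = tr$mass, test_temp = tr$test_temp,
               area = tr$area, sex_stage = tr$sex_stage, phase = m$phase,
               time_min = m$time, mr = m$mr, o2_sat = m$o2_sat,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
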