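# Planted-truth synthetic data: respirometry cohorts, seasonal ocean grids
# and occurrence sets with the statistical structure the analysis assumes,
# so every downstream stage is testable by parameter recovery.

#' Planted ground truth for the synthetic generators
#'
#' Defaults mirror a published calibration for a warm-temperate sparid:
#' upper-branch A_o = 1.55951e9 kPa-scale / E_o = -0.4885 eV, lower-branch
#' E_o = 1.01 eV with A_o derived from branch continuity at the 12 degC
#' breakpoint, mass exponent 0.17, and a suitability threshold phi_crit = 3
#' with a 13-75 m depth window.
#'
#' @param A_o_upper,E_o_upper upper-branch (T >= breakpoint) Arrhenius
#'   intercept scale (kPa at unit exp term) and slope (eV).
#' @param E_o_lower lower-branch slope (eV).
#' @param A_o_lower lower-branch intercept; `NULL` (default) derives it from
#'   continuity at the breakpoint, ln A_lower = ln A_upper +
#'   (E_upper - E_lower) x(breakpoint).
#' @param breakpoint_temp breakpoint, degC.
#' @param mass_exponent_n mass scaling exponent.
#' @param smr_curve,mmr_curve quadratic coefficients (increasing powers) of
#'   mass-specific SMR(T) and MMR(T), mg O2 min-1 kg-1 vs degC.
#' @param phi_crit_true planted suitability threshold (> 1).
#' @param depth_window planted suitable depth window, m below sea level.
#' @param noise_sd_mr relative (multiplicative Gaussian) noise on metabolic
#'   rate measurements.
#' @param seed master seed for all generators.
#' @return object of class `planted_truth`.
#' @export
planted_truth <- function(A_o_upper = 1.55951e9, E_o_upper = -0.4885,
                          E_o_lower = 1.01, A_o_lower = NULL,
                          breakpoint_temp = 12, mass_exponent_n = 0.17,
                          smr_curve = c(0.30, 0.010, 0.0015),
                          mmr_curve = c(1.00, 0.350, -0.0070),
                          phi_crit_true = 3.0, depth_window = c(13, 75),
                          noise_sd_mr = 0.05, seed = 1L) {
  xbp <- arrhenius_coordinate(breakpoint_temp)
  if (is.null(A_o_lower)) {
    A_o_lower <- exp(log(A_o_upper) + (E_o_upper - E_o_lower) * xbp)
  }
  truth <- structure(
    list(A_o_upper = A_o_upper, E_o_upper = E_o_upper,
         A_o_lower = A_o_lower, E_o_lower = E_o_lower,
         breakpoint_temp = breakpoint_temp, mass_exponent_n = mass_exponent_n,
         smr_curve = smr_curve, mmr_curve = mmr_curve,
         phi_crit_true = phi_crit_true, depth_window = depth_window,
         noise_sd_mr = noise_sd_mr, seed = as.integer(seed)),
    class = "planted_truth")
  # invariants
  tt <- seq(5, 30, by = 0.5)
  pu <- A_o_upper * exp(E_o_upper * arrhenius_coordinate(tt))
  pl <- A_o_lower * exp(E_o_lower * arrhenius_coordinate(tt))
  stopifnot(all(pu > 0), all(pl > 0))
  gap <- abs(pu[tt == breakpoint_temp] - pl[tt == breakpoint_temp])
  if (gap / pu[tt == breakpoint_temp] > 0.01) {
    stop("branch pO2crit laws disagree at the breakpoint by more than 1%")
  }
  smr <- eval_quadratic(smr_curve, tt); mmr <- eval_quadratic(mmr_curve, tt)
  if (any(smr <= 0) || any(mmr <= smr)) {
    stop("need 0 < SMR(T) < MMR(T) over 5-30 degC")
  }
  if (phi_crit_true <= 1) stop("phi_crit_true must exceed 1")
  truth
}

#' Metabolic-index parameters implied by a planted truth
#'
#' @param truth a [planted_truth()].
#' @return a [phi_params()] object.
#' @export
truth_params <- function(truth) {
  phi_params(A_o_upper = truth$A_o_upper, E_o_upper = truth$E_o_upper,
             A_o_lower = truth$A_o_lower, E_o_lower = truth$E_o_lower,
             n = truth$mass_exponent_n, breakpoint_temp = truth$breakpoint_temp)
}

#' Configuration of the synthetic study
#'
#' Defaults reproduce the study conditions the generators emulate: five
#' temperature treatments (8-24 degC) with 8 individuals each, specimen
#' masses 0.32-1.55 kg, a 0.25-degree coastal grid with a warm edge (east)
#' and a cool hypoxic upwelling edge (west), monthly layers for a
#' contemporary (2005-2009) and a future (2095-2099) block, and 400 raw
#' occurrence points.
#'
#' @param n_individuals fish per temperature treatment.
#' @param treatment_temps test temperatures, degC.
#' @param mass_range specimen mass range, kg.
#' @param lon_range,lat_range grid extent, degrees.
#' @param resolution grid resolution, degrees (> 0).
#' @param years_contemporary,years_future year blocks.
#' @param n_occurrences raw occurrence points to draw (before cell
#'   deduplication).
#' @param label_noise fraction of occurrence points replaced by draws from
#'   unsuitable cells.
#' @param temp_domain west-to-east bottom-temperature range, degC.
#' @param sat_frac_domain west-to-east dissolved-O2 relative saturation
#'   range: the west sits in a hypoxic upwelling band, saturation reaching
#'   the eastern value at `upwelling_front` (fraction of the west-east
#'   extent) and staying there. Concentration is saturation times the local
#'   solubility, so oxygen declines toward the cool edge.
#' @param upwelling_front where (0-1 of the extent) the saturation ramp
#'   levels off.
#' @param seasonal_amp_temp,seasonal_amp_sat seasonal cycle amplitudes
#'   (degC; saturation fraction), warm-season peak in February, oxygen in
#'   antiphase.
#' @param warming_trend,deox_trend additive future warming (degC) and
#'   deoxygenation (saturation fraction, subtracted).
#' @param spatial_noise_temp,spatial_noise_sat SD of the static spatial
#'   texture fields (identical in both periods).
#' @param salinity uniform salinity, psu.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 8,
                             treatment_temps = c(8, 12, 16, 20, 24),
                             mass_range = c(0.32, 1.55),
                             lon_range = c(15, 25), lat_range = c(-38, -28),
                             resolution = 0.25,
                             years_contemporary = 2005:2009,
                             years_future = 2095:2099,
                             n_occurrences = 400, label_noise = 0,
                             temp_domain = c(8, 25),
                             sat_frac_domain = c(0.35, 1.0),
                             upwelling_front = 0.45,
                             seasonal_amp_temp = 2, seasonal_amp_sat = 0.05,
                             warming_trend = 2.5, deox_trend = 0.08,
                             spatial_noise_temp = 0.3,
                             spatial_noise_sat = 0.02,
                             salinity = 35) {
  stopifnot(resolution > 0, n_individuals >= 1, all(mass_range > 0),
            mass_range[2] >= mass_range[1], n_occurrences >= 1,
            label_noise >= 0, label_noise <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# one respirometry trace from the planted laws
simulate_trial <- function(trial_id, mass, temp, truth, area, sex_stage) {
  ns <- truth$noise_sd_mr
  mnoise <- function(k) 1 + stats::rnorm(k, 0, ns)
  smr_t <- eval_quadratic(truth$smr_curve, temp)
  mmr_t <- eval_quadratic(truth$mmr_curve, temp)
  po2c <- mass^truth$mass_exponent_n *
    (if (temp >= truth$breakpoint_temp)
       truth$A_o_upper * exp(truth$E_o_upper * arrhenius_coordinate(temp))
     else truth$A_o_lower * exp(truth$E_o_lower * arrhenius_coordinate(temp)))
  sat_c <- po2_to_saturation(po2c, temp)
  if (sat_c <= 0 || sat_c >= 100) {
    stop(sprintf("planted critical saturation %.1f%% out of range at %g degC",
                 sat_c, temp))
  }
  # routine: ~20 h of 20-min intermittent-flow cycles; activity noise is
  # half-normal above SMR so the 0.2 quantile sits at SMR
  n_rout <- 60
  rout_mr <- smr_t * (1 + abs(stats::rnorm(n_rout, 0, 2 * ns))) * mnoise(n_rout)
  rout <- data.frame(time = seq(0, by = 20, length.out = n_rout),
                     mr = rout_mr, o2_sat = 97 + stats::runif(n_rout, -2, 2),
                     phase = "routine")
  # post-chase: exponential recovery from MMR
  n_post <- 6
  post_mr <- (smr_t + (mmr_t - smr_t) * exp(-(0:(n_post - 1)) / 3)) * mnoise(n_post)
  post <- data.frame(time = max(rout$time) + 5 * seq_len(n_post),
                     mr = post_mr, o2_sat = 97 + stats::runif(n_post, -2, 2),
                     phase = "post_chase")
  # progressive hypoxia: oxyregulation at SMR above the critical saturation,
  # linear origin-bound decline below it. The fish itself depletes the
  # closed respirometer, so saturation falls at a constant rate while the
  # rate is regulated and geometrically (rate proportional to saturation)
  # once the fish conforms -- measurements cluster below the critical
  # saturation, as in real traces.
  # depletion per 5-min cycle scales with the fish's metabolic rate: constant
  # while the fish regulates at SMR, then proportional to saturation once it
  # conforms; the trial ends ~16 cycles into conformity (signs of stress)
  step <- 2.0 * smr_t / eval_quadratic(truth$smr_curve, 16)
  sats_above <- seq(95, sat_c, by = -step)
  s <- sats_above[length(sats_above)] * (1 - step / sat_c)
  sats_below <- numeric(0)
  while (s >= 1.5 && length(sats_below) < 16) {
    sats_below <- c(sats_below, s)
    s <- s * (1 - step / sat_c)
  }
  sats <- c(sats_above, sats_below)
  hyp_mr <- ifelse(sats > sat_c, smr_t, smr_t * sats / sat_c) * mnoise(length(sats))
  hyp <- data.frame(time = max(post$time) + 5 * seq_along(sats),
                    mr = pmax(hyp_mr, 0), o2_sat = sats, phase = "hypoxia")
  list(trial = respirometry_trial(trial_id, mass, temp,
                                  rbind(rout, post, hyp), area, sex_stage),
       true_smr = smr_t, true_mmr = mmr_t,
       true_o2crit_sat = sat_c, true_po2crit = po2c)
}

#' Generate a synthetic respirometry cohort
#'
#' One trial per individual per temperature treatment, with per-trial truth
#' (SMR, MMR, critical saturation and pO2crit) recorded for recovery tests.
#' Deterministic for a fixed `truth$seed`.
#'
#' @param config a [synthetic_config()].
#' @param truth a [planted_truth()].
#' @param seed overrides `truth$seed`.
#' @return list with `trials` (list of [respirometry_trial()]) and `truth_table`
#'   (data.frame of planted per-trial values).
#' @export
generate_respirometry_cohort <- function(config, truth, seed = truth$seed) {
  set.seed(seed)
  trials <- list(); rows <- list()
  id <- 0
  sexes <- c("F", "M", "F/I", "M/I", "unknown")
  for (temp in config$treatment_temps) {
    for (i in seq_len(config$n_individuals)) {
      id <- id + 1
      mass <- stats::runif(1, config$mass_range[1], config$mass_range[2])
      sim <- simulate_trial(sprintf("T%02d_%02d", round(temp), i), mass, temp,
                            truth,
                            area = if (i %% 2 == 0) "TNP" else "PE",
                            sex_stage = sample(sexes, 1,
                                               prob = c(0.2, 0.25, 0.4, 0.08, 0.07)))
      trials[[id]] <- sim$trial
      rows[[id]] <- data.frame(trial_id = sim$trial$trial_id, mass = mass,
                               test_temp = temp, true_smr = sim$true_smr,
                               true_mmr = sim$true_mmr,
                               true_o2crit_sat = sim$true_o2crit_sat,
                               true_po2crit = sim$true_po2crit,
                               stringsAsFactors = FALSE)
    }
  }
  list(trials = trials, truth_table = do.call(rbind, rows))
}

# static spatial texture shared by the contemporary and future blocks
smooth_field <- function(nla, nlo, sd) {
  if (sd <= 0) return(matrix(0, nla, nlo))
  f <- matrix(stats::rnorm(nla * nlo, 0, sd), nla, nlo)
  # one smoothing pass (3x3 mean) keeps the texture spatially coherent
  g <- f
  for (i in seq_len(nla)) {
    for (j in seq_len(nlo)) {
      g[i, j] <- mean(f[max(1, i - 1):min(nla, i + 1),
                        max(1, j - 1):min(nlo, j + 1)])
    }
  }
  g
}

#' Generate synthetic ocean grids
#'
#' Bottom temperature increases monotonically west to east (warm edge);
#' oxygen concentration declines toward the west (cool hypoxic upwelling
#' edge). A sinusoidal seasonal cycle (warm-season peak in February,
#' oxygen in antiphase) is superposed; the future block adds the configured
#' warming and deoxygenation trends additively. The depth field ramps from
#' ~0 to ~100 m with latitude. Static spatial texture fields are identical
#' in both periods, so future minus contemporary equals the trend exactly.
#'
#' @param config a [synthetic_config()].
#' @param truth a [planted_truth()] (supplies the seed).
#' @param seed overrides `truth$seed`.
#' @return list with elements `contemporary` and `future` (each a list of
#'   `temp`, `conc`, `sal` stacks), and `depth` (static stack, m).
#' @export
generate_environment <- function(config, truth, seed = truth$seed) {
  set.seed(seed + 1L)
  lon <- seq(config$lon_range[1] + config$resolution / 2, config$lon_range[2],
             by = config$resolution)
  lat <- seq(config$lat_range[1] + config$resolution / 2, config$lat_range[2],
             by = config$resolution)
  nlo <- length(lon); nla <- length(lat)
  fr_lon <- matrix((lon - min(lon)) / max(diff(range(lon)), 1e-9),
                   nla, nlo, byrow = TRUE)
  fr_lat <- matrix((lat - min(lat)) / max(diff(range(lat)), 1e-9), nla, nlo)
  t_tex <- smooth_field(nla, nlo, config$spatial_noise_temp)
  s_tex <- smooth_field(nla, nlo, config$spatial_noise_sat)
  t_base <- config$temp_domain[1] +
    fr_lon * diff(config$temp_domain) + t_tex
  sat_base <- config$sat_frac_domain[1] +
    pmin(fr_lon / config$upwelling_front, 1) * diff(config$sat_frac_domain) +
    s_tex
  depth_m <- 2 + 96 * fr_lat + 1.5 * sin(6 * pi * fr_lon)

  block <- function(years, dT, dS) {
    tm <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
    nt <- nrow(tm)
    ta <- array(NA_real_, dim = c(nt, nla, nlo))
    ca <- array(NA_real_, dim = c(nt, nla, nlo))
    for (k in seq_len(nt)) {
      season <- cos(2 * pi * (tm$month[k] - 2) / 12)
      tt <- t_base + dT + config$seasonal_amp_temp * season
      sf <- pmin(pmax(sat_base - dS - config$seasonal_amp_sat * season,
                      0.05), 1.05)
      ta[k, , ] <- tt
      ca[k, , ] <- sf * o2_saturation_concentration(tt, config$salinity)
    }
    list(temp = grid_stack("temperature", "degC", lon, lat, tm, ta),
         conc = grid_stack("o2_concentration", "mmol m-3", lon, lat, tm, ca),
         sal = grid_stack("salinity", "psu", lon, lat, tm,
                          array(config$salinity, dim = c(nt, nla, nlo))))
  }
  list(contemporary = block(config$years_contemporary, 0, 0),
       future = block(config$years_future, config$warming_trend,
                      config$deox_trend),
       depth = grid_stack("depth", "m", lon, lat,
                          data.frame(year = config$years_contemporary[1],
                                     month = 1),
                          array(depth_m, dim = c(1, nla, nlo))))
}

#' Minimum-phi layer and suitability mask implied by a planted truth
#'
#' Shared by [generate_occurrences()] and the end-to-end recovery tests:
#' converts the concentration block to pO2, projects phi at 1 kg, takes the
#' minimum over all monthly slices, and applies the planted phi_crit and
#' depth-window rule.
#'
#' @param env output of [generate_environment()].
#' @param truth a [planted_truth()].
#' @param period `"contemporary"` or `"future"`.
#' @return list with `min_phi` (single-slice stack), `depth` (matrix, m) and
#'   `suitable` (logical matrix).
#' @export
planted_suitability <- function(env, truth, period = "contemporary") {
  blk <- env[[period]]
  po2 <- po2_layers(blk$conc, blk$temp, blk$sal, env$depth)
  ph <- compute_phi_layers(truth_params(truth), blk$temp, po2)
  min_phi <- aggregate_monthly(ph)$min
  dep <- matrix(env$depth$data[1, , ], length(env$depth$lat),
                length(env$depth$lon))
  mp <- matrix(min_phi$data[1, , ], length(min_phi$lat), length(min_phi$lon))
  suitable <- !is.na(mp) & mp >= truth$phi_crit_true &
    dep >= truth$depth_window[1] & dep <= truth$depth_window[2]
  list(min_phi = min_phi, depth = dep, suitable = suitable)
}

#' Generate synthetic occurrence points
#'
#' Presence points are drawn (with replacement, then jittered uniformly
#' within their cell, so several points can share a cell) from cells whose
#' minimum monthly phi is at least the planted phi_crit and whose depth lies
#' in the planted window. A `label_noise` fraction is replaced by draws from
#' unsuitable cells.
#'
#' @param env output of [generate_environment()].
#' @param truth a [planted_truth()].
#' @param config a [synthetic_config()].
#' @param seed overrides `truth$seed`.
#' @return list with `points` (data.frame lon, lat, suitable), `suitable`
#'   mask matrix and the `min_phi` stack used.
#' @export
generate_occurrences <- function(env, truth, config, seed = truth$seed) {
  set.seed(seed + 2L)
  suit <- planted_suitability(env, truth)
  lon <- env$depth$lon; lat <- env$depth$lat
  res <- config$resolution
  good <- which(suit$suitable, arr.ind = TRUE)
  if (nrow(good) == 0) stop("no cell satisfies the planted suitability rule")
  bad <- which(!suit$suitable, arr.ind = TRUE)
  n <- config$n_occurrences
  n_bad <- round(config$label_noise * n)
  pick <- good[sample.int(nrow(good), n - n_bad, replace = TRUE), , drop = FALSE]
  is_suit <- rep(TRUE, n - n_bad)
  if (n_bad > 0) {
    pick <- rbind(pick, bad[sample.int(nrow(bad), n_bad, replace = TRUE), ,
                            drop = FALSE])
    is_suit <- c(is_suit, rep(FALSE, n_bad))
  }
  pts <- data.frame(
    lon = lon[pick[, 2]] + stats::runif(n, -res / 2, res / 2),
    lat = lat[pick[, 1]] + stats::runif(n, -res / 2, res / 2),
    suitable = is_suit)
  list(points = pts, suitable = suit$suitable, min_phi = suit$min_phi)
}
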