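# Shared fixtures: the published parameter set used as a calibration
# oracle, and small hand-built grids/trials.

published_params <- function() {
  phi_params(A_o_upper = 1.55951e9, E_o_upper = -0.4885,
             A_o_lower = 5.109275e-18, E_o_lower = 1.01,
             n = 0.17, breakpoint_temp = 12)
}

# single-slice stack from a lat x lon matrix
make_stack <- function(m, var = "x", units = "1", lon = NULL, lat = NULL,
                       year = 2005, month = 1) {
  nla <- nrow(m); nlo <- ncol(m)
  if (is.null(lon)) lon <- seq(0.5, by = 1, length.out = nlo)
  if (is.null(lat)) lat <- seq(-10.5, by = 1, length.out = nla)
  grid_stack(var, units, lon, lat, data.frame(year = year, month = month),
             array(m, dim = c(1, nla, nlo)))
}

# multi-slice stack from a list of matrices
make_stack_t <- function(mats, var = "x", units = "1") {
  nla <- nrow(mats[[1]]); nlo <- ncol(mats[[1]])
  arr <- array(NA_real_, dim = c(length(mats), nla, nlo))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  grid_stack(var, units, seq(0.5, by = 1, length.out = nlo),
             seq(-10.5, by = 1, length.out = nla),
             data.frame(year = 2005, month = seq_along(mats)), arr)
}

# a piecewise-linear hypoxia trace with an exact analytic intersection
make_linear_trial <- function(smr = 1, slope = 0.02, sat_c = 50,
                              temp = 16, mass = 1) {
  routine <- data.frame(time = 1:12, mr = smr * 1.5, o2_sat = 95,
                        phase = "routine")
  sats <- seq(95, 2, by = -3)
  mr <- ifelse(sats >= sat_c, smr * 1.2, slope * sats)
  hyp <- data.frame(time = 100 + seq_along(sats), mr = mr, o2_sat = sats,
                    phase = "hypoxia")
  respirometry_trial("lin", mass, temp, rbind(routine, hyp))
}
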