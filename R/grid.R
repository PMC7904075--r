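# Gridded monthly environmental and derived layers on a regular lon/lat
# mesh. A grid_stack holds a 3-D array indexed (time, lat, lon) with NA as
# the missing-value mask, plus coordinate vectors and a units attribute.
# Static fields (depth, aggregates) are single-slice stacks.

#' Construct a grid stack
#'
#' @param var variable name.
#' @param units units string (CF-style, e.g. "degC", "mmol m-3", "kPa", "m").
#' @param lon,lat strictly monotone cell-centre coordinate vectors (degrees,
#'   regular spacing).
#' @param time data.frame with integer columns `year` and `month`, one row
#'   per slice.
#' @param data numeric array with dim (nrow(time), length(lat), length(lon)).
#' @return object of class `grid_stack`.
#' @export
grid_stack <- function(var, units, lon, lat, time, data) {
  stopifnot(is.data.frame(time), all(c("year", "month") %in% names(time)))
  if (length(lon) > 1 && !(all(diff(lon) > 0) || all(diff(lon) < 0))) {
    stop("lon must be strictly monotone")
  }
  if (length(lat) > 1 && !(all(diff(lat) > 0) || all(diff(lat) < 0))) {
    stop("lat must be strictly monotone")
  }
  data <- array(data, dim = c(nrow(time), length(lat), length(lon)))
  structure(list(var = var, units = units, lon = lon, lat = lat,
                 time = time, data = data),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("grid_stack '%s' [%s]: %d x %d cells, %d time slice(s)\n",
              x$var, x$units, length(x$lat), length(x$lon), nrow(x$time)))
  cat(sprintf("  lon %.3f..%.3f, lat %.3f..%.3f; %d masked cell-values\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat),
              sum(is.na(x$data))))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lon, b$lon)) && isTRUE(all.equal(a$lat, b$lat))
}

stopifnot_aligned <- function(a, b) {
  if (!same_grid(a, b)) stop("grid stacks are not on the same grid")
  invisible(TRUE)
}

#' Read / write grid stacks as long-format CSV
#'
#' Plain-text exchange format: one row per (year, month, lat, lon) with the
#' cell value (empty for masked cells), and the variable name and units
#' carried in the header columns.
#'
#' @param stack a [grid_stack()].
#' @param file path.
#' @export
write_grid_csv <- function(stack, file) {
  nt <- nrow(stack$time); nla <- length(stack$lat); nlo <- length(stack$lon)
  df <- data.frame(
    var = stack$var, units = stack$units,
    year = rep(stack$time$year, times = nla * nlo),
    month = rep(stack$time$month, times = nla * nlo),
    lat = rep(rep(stack$lat, each = nt), times = nlo),
    lon = rep(stack$lon, each = nt * nla),
    value = as.vector(stack$data))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  tm <- unique(d[, c("year", "month")])
  tm <- tm[order(tm$year, tm$month), , drop = FALSE]
  rownames(tm) <- NULL
  key_t <- match(paste(d$year, d$month), paste(tm$year, tm$month))
  arr <- array(NA_real_, dim = c(nrow(tm), length(lat), length(lon)))
  arr[cbind(key_t, match(d$lat, lat), match(d$lon, lon))] <- d$value
  grid_stack(d$var[1], d$units[1], lon, lat, tm, arr)
}

#' Fill masked coastal cells from valid neighbours
#'
#' Iteratively replaces each masked cell that has at least one valid
#' 8-neighbour (same time slice) with the mean of its valid neighbours,
#' until no such cell remains or `max_iter` passes are done. Originally
#' valid cells are never modified; the operation is idempotent once
#' converged.
#'
#' @param stack a [grid_stack()].
#' @param max_iter maximum number of passes (default 10).
#' @return filled [grid_stack()].
#' @export
fill_coastal_gaps <- function(stack, max_iter = 10) {
  if (all(is.na(stack$data))) {
    warning("all cells masked; nothing to fill")
    return(stack)
  }
  d <- stack$data
  nt <- dim(d)[1]; nla <- dim(d)[2]; nlo <- dim(d)[3]
  for (t in seq_len(nt)) {
    sl <- matrix(d[t, , ], nla, nlo)
    for (it in seq_len(max_iter)) {
      bad <- which(is.na(sl), arr.ind = TRUE)
      if (nrow(bad) == 0) break
      new_vals <- rep(NA_real_, nrow(bad))
      for (k in seq_len(nrow(bad))) {
        i <- bad[k, 1]; j <- bad[k, 2]
        ii <- max(1, i - 1):min(nla, i + 1)
        jj <- max(1, j - 1):min(nlo, j + 1)
        nb <- sl[ii, jj]
        nb <- nb[!is.na(nb)]
        if (length(nb) > 0) new_vals[k] <- mean(nb)
      }
      if (all(is.na(new_vals))) break
      sl[bad] <- new_vals
    }
    d[t, , ] <- sl
  }
  stack$data <- d
  stack
}

#' Refine a grid stack by cell-centre bilinear interpolation
#'
#' Each cell is split into `factor` x `factor` children; values at the new
#' cell centres are bilinearly interpolated from the four surrounding
#' original centres (clamped at the grid edge, so constant fields are
#' reproduced exactly and values stay within the local hull).
#'
#' @param stack a [grid_stack()] on a regularly spaced grid.
#' @param factor integer refinement factor (default 2).
#' @return refined [grid_stack()].
#' @export
resample_bilinear <- function(stack, factor = 2) {
  refine <- function(coord) {
    if (length(coord) < 2) stop("need at least 2 coordinates to resample")
    res <- diff(coord)
    if (max(res) - min(res) > 1e-6 * abs(mean(res))) {
      stop("irregular coordinate spacing")
    }
    step <- mean(res)
    new_step <- step / factor
    offs <- (seq_len(factor) - (factor + 1) / 2) * new_step
    as.vector(t(outer(coord, offs, "+")))
  }
  interp_weights <- function(old, new) {
    # clamped piecewise-linear interpolation weights along one axis
    sgn <- if (old[2] > old[1]) 1 else -1
    o <- sgn * old; x <- sgn * new
    i0 <- findInterval(x, o, rightmost.closed = FALSE)
    i0 <- pmin(pmax(i0, 1), length(o) - 1)
    w <- (x - o[i0]) / (o[i0 + 1] - o[i0])
    w <- pmin(pmax(w, 0), 1)
    list(i0 = i0, w = w)
  }
  lon2 <- refine(stack$lon); lat2 <- refine(stack$lat)
  wlon <- interp_weights(stack$lon, lon2)
  wlat <- interp_weights(stack$lat, lat2)
  nt <- dim(stack$data)[1]
  out <- array(NA_real_, dim = c(nt, length(lat2), length(lon2)))
  for (t in seq_len(nt)) {
    sl <- matrix(stack$data[t, , ], length(stack$lat), length(stack$lon))
    a <- sl[wlat$i0, wlon$i0]
    b <- sl[wlat$i0, wlon$i0 + 1]
    cc <- sl[wlat$i0 + 1, wlon$i0]
    dd <- sl[wlat$i0 + 1, wlon$i0 + 1]
    wx <- matrix(wlon$w, length(lat2), length(lon2), byrow = TRUE)
    wy <- matrix(wlat$w, length(lat2), length(lon2))
    out[t, , ] <- (1 - wy) * ((1 - wx) * a + wx * b) +
      wy * ((1 - wx) * cc + wx * dd)
  }
  grid_stack(stack$var, stack$units, lon2, lat2, stack$time, out)
}

#' Project the metabolic index over gridded layers
#'
#' Cell-wise phi = pO2 / pO2crit(T, B) at a fixed reference mass (default
#' 1 kg: the B^n factor is constant across space and does not affect the
#' distribution model). Masks propagate.
#'
#' @param params a [phi_params()] or `phi_fit`.
#' @param temp_stack temperature stack, degC.
#' @param po2_stack oxygen partial-pressure stack, kPa, on the same grid and
#'   time index.
#' @param mass reference mass, kg.
#' @return phi [grid_stack()] (dimensionless).
#' @export
compute_phi_layers <- function(params, temp_stack, po2_stack, mass = 1) {
  stopifnot_aligned(temp_stack, po2_stack)
  if (nrow(temp_stack$time) != nrow(po2_stack$time)) {
    stop("time indices differ between stacks")
  }
  vals <- phi(params, as.vector(temp_stack$data),
              pmax(as.vector(po2_stack$data), 0), mass = mass)
  grid_stack("phi", "1", temp_stack$lon, temp_stack$lat, temp_stack$time,
             array(vals, dim = dim(temp_stack$data)))
}

#' Convert an oxygen-concentration stack to partial pressure
#'
#' Applies [o2_conc_to_po2()] cell-wise, using the local temperature,
#' salinity and depth (via [pressure_at_depth()] at the cell latitude).
#'
#' @param conc_stack O2 concentration stack, mmol m-3.
#' @param temp_stack temperature stack, degC, same grid/time.
#' @param sal_stack salinity stack (psu), same grid/time, or a scalar.
#' @param depth_stack static depth stack (m below sea level), or scalar 0.
#' @return pO2 [grid_stack()] in kPa.
#' @export
po2_layers <- function(conc_stack, temp_stack, sal_stack = 35, depth_stack = 0) {
  stopifnot_aligned(conc_stack, temp_stack)
  dm <- dim(conc_stack$data)
  sal <- if (inherits(sal_stack, "grid_stack")) sal_stack$data else
    array(sal_stack, dim = dm)
  if (inherits(depth_stack, "grid_stack")) {
    dep <- matrix(depth_stack$data[1, , ], dm[2], dm[3])
  } else {
    dep <- matrix(depth_stack, dm[2], dm[3])
  }
  latm <- matrix(conc_stack$lat, dm[2], dm[3])
  press <- pressure_at_depth(pmax(dep, 0), latm)
  press_full <- aperm(array(press, dim = c(dm[2], dm[3], dm[1])), c(3, 1, 2))
  vals <- o2_conc_to_po2(pmax(as.vector(conc_stack$data), 0),
                         as.vector(temp_stack$data),
                         as.vector(sal), as.vector(press_full))
  grid_stack("po2", "kPa", conc_stack$lon, conc_stack$lat, conc_stack$time,
             array(vals, dim = dm))
}

#' Aggregate monthly slices to min / mean / max layers
#'
#' @param stack a [grid_stack()].
#' @param years optional integer vector restricting the period (e.g.
#'   2005:2009); all slices by default.
#' @return named list of single-slice stacks `min`, `mean`, `max` (time row
#'   is the first year/month of the period).
#' @export
aggregate_monthly <- function(stack, years = NULL) {
  keep <- if (is.null(years)) seq_len(nrow(stack$time)) else
    which(stack$time$year %in% years)
  if (length(keep) == 0) stop("no time slices in the requested period")
  d <- stack$data[keep, , , drop = FALSE]
  one <- function(fun, tag) {
    v <- apply(d, c(2, 3), function(z) {
      if (all(is.na(z))) NA_real_ else fun(z, na.rm = TRUE)
    })
    grid_stack(paste0(tag, "_", stack$var), stack$units, stack$lon, stack$lat,
               stack$time[keep[1], , drop = FALSE],
               array(v, dim = c(1, dim(v))))
  }
  list(min = one(min, "min"), mean = one(mean, "mean"), max = one(max, "max"))
}

#' Depth-clip the analysis domain
#'
#' @param bathy single-slice depth stack (m below sea level, positive down).
#' @param range inclusive depth window, m (default c(0, 100)).
#' @return logical lat x lon matrix (TRUE = inside the domain); warns if
#'   empty.
#' @export
clip_depth_domain <- function(bathy, range = c(0, 100)) {
  dep <- matrix(bathy$data[1, , ], length(bathy$lat), length(bathy$lon))
  mask <- !is.na(dep) & dep >= range[1] & dep <= range[2]
  if (!any(mask)) warning("depth clip leaves an empty domain")
  mask
}

#' Apply a domain mask to a stack
#'
#' @param stack a [grid_stack()].
#' @param mask logical lat x lon matrix from [clip_depth_domain()].
#' @export
apply_domain_mask <- function(stack, mask) {
  d <- stack$data
  for (t in seq_len(dim(d)[1])) {
    sl <- matrix(d[t, , ], dim(d)[2], dim(d)[3])
    sl[!mask] <- NA_real_
    d[t, , ] <- sl
  }
  stack$data <- d
  stack
}

#' Aerobic-scope thermal performance curves
#'
#' Quadratic polynomials for mass-standardised SMR(T) and MMR(T)
#' (mg O2 min^-1 kg^-1 against degC), coefficients in increasing power
#' order c(intercept, linear, quadratic).
#'
#' @param smr_coef,mmr_coef length-3 numeric coefficient vectors.
#' @return object of class `aerobic_scope_curves`.
#' @export
aerobic_scope_curves <- function(smr_coef, mmr_coef) {
  stopifnot(length(smr_coef) == 3, length(mmr_coef) == 3)
  structure(list(smr = smr_coef, mmr = mmr_coef),
            class = "aerobic_scope_curves")
}

eval_quadratic <- function(coef, x) coef[1] + coef[2] * x + coef[3] * x^2

#' Fit aerobic-scope curves from per-trial SMR / MMR estimates
#'
#' @param data data.frame with test_temp, smr, mmr columns (mass-specific
#'   rates).
#' @return an [aerobic_scope_curves()] object.
#' @export
fit_aerobic_scope_curves <- function(data) {
  stopifnot(all(c("test_temp", "smr", "mmr") %in% names(data)))
  fs <- stats::lm(smr ~ test_temp + I(test_temp^2), data = data)
  fm <- stats::lm(mmr ~ test_temp + I(test_temp^2), data = data)
  aerobic_scope_curves(unname(stats::coef(fs)), unname(stats::coef(fm)))
}

#' Absolute and factorial aerobic-scope layers
#'
#' AAS = MMR(T) - SMR(T); FAS = MMR(T) / SMR(T), evaluated cell-wise through
#' the temperature stack. Cells where SMR <= 0 or MMR <= SMR (outside the
#' curves' valid range) are masked.
#'
#' @param curves an [aerobic_scope_curves()].
#' @param temp_stack temperature stack, degC.
#' @return list of two stacks `aas` (mg O2 min-1 kg-1) and `fas`
#'   (dimensionless).
#' @export
aerobic_scope_layers <- function(curves, temp_stack) {
  tt <- as.vector(temp_stack$data)
  smr <- eval_quadratic(curves$smr, tt)
  mmr <- eval_quadratic(curves$mmr, tt)
  bad <- !is.na(smr) & (smr <= 0 | mmr <= smr)
  smr[bad] <- NA_real_; mmr[bad] <- NA_real_
  dm <- dim(temp_stack$data)
  list(
    aas = grid_stack("aas", "mg O2 min-1 kg-1", temp_stack$lon, temp_stack$lat,
                     temp_stack$time, array(mmr - smr, dim = dm)),
    fas = grid_stack("fas", "1", temp_stack$lon, temp_stack$lat,
                     temp_stack$time, array(mmr / smr, dim = dm)))
}
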