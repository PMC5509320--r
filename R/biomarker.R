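## P-wave fiducials and body-surface biomarkers.  The primary biomarker is
## the BSPiM: the per-lead signed time integral of the P-wave between its
## onset (ectopic stimulus) and offset (latest atrial depolarization).

#' P-wave fiducials from the activation map
#'
#' Onset is the ectopic stimulus time; offset is the latest atrial
#' depolarization (stimulus time + max activation time).
#'
#' @param latmap a `lat_map` with finite activation everywhere.
#' @param stim_time stimulus time (ms); defaults to the map's own.
#' @return list of class `fiducials`: `onset`, `offset` (ms).
#' @export
detect_fiducials <- function(latmap, stim_time = latmap$stim_time) {
  if (any(!is.finite(latmap$lat)))
    validation_error("fiducials undefined: unreached nodes present")
  structure(list(onset = stim_time, offset = stim_time + max(latmap$lat)),
            class = "fiducials")
}

## Trapezoidal weights for integrating over [onset, offset] on the sample
## grid, with linear interpolation at the (possibly off-grid) endpoints.
window_columns <- function(times, fid) {
  if (fid$onset < min(times) - 1e-9 || fid$offset > max(times) + 1e-9)
    range_error("fiducial window outside the trace time range")
  sel <- which(times >= fid$onset - 1e-9 & times <= fid$offset + 1e-9)
  list(sel = sel, t = times[sel])
}

#' Body-surface P-wave integral map
#'
#' Signed trapezoidal integral of every lead over the fiducial window;
#' positive and negative lobes cancel.
#'
#' @param bspm a `bspm`.
#' @param fiducials a `fiducials`.
#' @param focus optional focus id stored with the map.
#' @return object of class `bspim_map`: `values` (mV ms), `normalized`
#'   (`NA` until [normalize_set()]), `argmax_lead`, `argmin_lead`, `labels`,
#'   `focus`.
#' @export
pwave_integral <- function(bspm, fiducials, focus = NA_character_) {
  w <- window_columns(bspm$times, fiducials)
  tt <- w$t
  Ve <- bspm$Ve[, w$sel, drop = FALSE]
  if (length(tt) < 2) {
    vals <- numeric(nrow(Ve))
  } else {
    dt <- diff(tt)
    wts <- c(dt / 2, 0) + c(0, dt / 2)
    vals <- as.numeric(Ve %*% wts)
  }
  new_bspim_map(vals, bspm$labels, focus)
}

new_bspim_map <- function(values, labels, focus = NA_character_) {
  ties_max <- which(values == max(values))
  ties_min <- which(values == min(values))
  structure(list(values = values, normalized = rep(NA_real_, length(values)),
                 argmax_lead = min(ties_max), argmin_lead = min(ties_min),
                 labels = labels, focus = focus),
            class = "bspim_map")
}

#' Root-mean-square map over the fiducial window
#' @inheritParams pwave_integral
#' @return numeric per-lead RMS (mV).
#' @export
rms_map <- function(bspm, fiducials) {
  w <- window_columns(bspm$times, fiducials)
  sqrt(rowMeans(bspm$Ve[, w$sel, drop = FALSE]^2))
}

#' Extrema maps over the fiducial window
#' @inheritParams pwave_integral
#' @return list `max`, `min` (per-lead mV).
#' @export
extrema_maps <- function(bspm, fiducials) {
  w <- window_columns(bspm$times, fiducials)
  Ve <- bspm$Ve[, w$sel, drop = FALSE]
  list(max = apply(Ve, 1, max), min = apply(Ve, 1, min))
}

#' Elementwise RMS x integral map
#' @param rms per-lead RMS values.
#' @param integral a `bspim_map` (or numeric vector).
#' @return numeric per-lead product.
#' @export
product_map <- function(rms, integral) {
  v <- if (inherits(integral, "bspim_map")) integral$values else integral
  rms * v
}

#' Full biomarker suite for one focus
#' @inheritParams pwave_integral
#' @return list of class `biomarker_suite`: `integral` (`bspim_map`), `rms`,
#'   `max`, `min`, `rms_x_integral`.
#' @export
biomarker_suite <- function(bspm, fiducials, focus = NA_character_) {
  integral <- pwave_integral(bspm, fiducials, focus)
  r <- rms_map(bspm, fiducials)
  ex <- extrema_maps(bspm, fiducials)
  structure(list(integral = integral, rms = r, max = ex$max, min = ex$min,
                 rms_x_integral = product_map(r, integral), focus = focus),
            class = "biomarker_suite")
}

#' Normalize a set of integral maps by the global range
#'
#' Every value is divided by the largest absolute value over the whole set,
#' so the set-wide maximum magnitude is exactly 1 and relative patterns are
#' preserved within and across maps.
#'
#' @param maps list of `bspim_map`.
#' @return the list with `normalized` filled in.
#' @export
normalize_set <- function(maps) {
  if (length(maps) == 0) parameter_error("empty map set")
  gmax <- max(vapply(maps, function(m) max(abs(m$values)), numeric(1)))
  if (gmax == 0) bspim_error("all-zero map set cannot be normalized",
                             "bspim_normalization_error")
  lapply(maps, function(m) { m$normalized <- m$values / gmax; m })
}

#' Min-to-max dipole-axis summary of an integral map
#'
#' The axis runs from the position of the most negative to the most positive
#' integral value; its class is the dominant torso-frame component
#' (x: leftward/rightward, z: upward/downward).
#'
#' @param map a `bspim_map`.
#' @param leads the `lead_set` the map was computed on.
#' @return list of class `dipole_axis`: `min_pos`, `max_pos`, `direction`,
#'   `class` (one of `"upward"`, `"downward"`, `"leftward"`, `"rightward"`).
#' @export
dipole_axis <- function(map, leads) {
  if (map$argmax_lead == map$argmin_lead)
    bspim_error("flat map: dipole axis degenerate", "bspim_degenerate_axis_error")
  P <- lead_positions(leads)
  mx <- P[map$argmax_lead, ]
  mn <- P[map$argmin_lead, ]
  dir <- mx - mn
  cls <- if (abs(dir[3]) >= abs(dir[1])) {
    if (dir[3] >= 0) "upward" else "downward"
  } else {
    if (dir[1] >= 0) "leftward" else "rightward"
  }
  structure(list(min_pos = mn, max_pos = mx, direction = dir, class = cls),
            class = "dipole_axis")
}
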