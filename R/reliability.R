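#' Reliability-model parameters
#'
#' Constants of the piecewise-linear fits that map a cue condition to an
#' (augmented) mean vector length, and hence to a von Mises concentration.
#' Defaults are the published fits:
#' wind `R = 0.11 s + 0.43` (s in m/s) and light
#' `R = -0.07 phi + 0.80` for elevations up to the 75 degree breakpoint,
#' `R = -1.26 phi + 2.31` above it, with `phi` the elevation in radians.
#' The additive constants `c_wind = 0.133` and `c_light = 0.135` augment R
#' before concentration estimation so that simulated populations match the
#' precision of real animals; the raw (non-augmented) fits describe the
#' behavioural medians themselves.
#'
#' @param wind_slope,wind_intercept wind fit, per m/s.
#' @param light_slope_low,light_intercept_low light fit at or below the
#'   breakpoint, per radian of elevation.
#' @param light_slope_high,light_intercept_high light fit above the breakpoint.
#' @param breakpoint_deg elevation (degrees) separating the two light branches;
#'   the breakpoint itself belongs to the low branch.
#' @param c_wind,c_light additive augmentation constants, `>= 0`.
#' @return object of class `reliability_params`.
#' @export
reliability_params <- function(wind_slope = 0.11, wind_intercept = 0.43,
                               light_slope_low = -0.07,
                               light_intercept_low = 0.80,
                               light_slope_high = -1.26,
                               light_intercept_high = 2.31,
                               breakpoint_deg = 75,
                               c_wind = 0.133, c_light = 0.135) {
  stopifnot(c_wind >= 0, c_light >= 0,
            breakpoint_deg > 0, breakpoint_deg < 90)
  structure(list(wind_slope = wind_slope, wind_intercept = wind_intercept,
                 light_slope_low = light_slope_low,
                 light_intercept_low = light_intercept_low,
                 light_slope_high = light_slope_high,
                 light_intercept_high = light_intercept_high,
                 breakpoint_deg = breakpoint_deg,
                 c_wind = c_wind, c_light = c_light),
            class = "reliability_params")
}

# R is clamped strictly below 1 so the high branch of kappa_fisher stays finite
.clamp_R <- function(R) pmin(pmax(R, 0), 1 - 1e-9)

#' Mean vector length predicted for a wind cue
#'
#' @param speed wind speed in m/s, `>= 0`.
#' @param params a [reliability_params()] object.
#' @param augmented add `c_wind` (the form used for concentration estimation)?
#' @return predicted R, clamped to `[0, 1)`.
#' @examples
#' wind_R(2.5)                    # 0.838
#' wind_R(2.5, augmented = FALSE) # 0.705, the raw fit line
#' @export
wind_R <- function(speed, params = reliability_params(), augmented = TRUE) {
  if (anyNA(speed) || any(speed < 0))
    stop("wind_R(): wind speed must be >= 0 m/s", call. = FALSE)
  R <- params$wind_slope * speed + params$wind_intercept
  if (augmented) R <- R + params$c_wind
  .clamp_R(R)
}

#' Mean vector length predicted for a light (ersatz sun) cue
#'
#' The split-linear fit takes the elevation in radians; precision is roughly
#' flat up to the 75 degree breakpoint and collapses rapidly toward zenith,
#' where an overhead point source carries almost no azimuthal information.
#'
#' @param elevation_deg solar elevation in degrees, in `[0, 90]`.
#' @param params a [reliability_params()] object.
#' @param augmented add `c_light`?
#' @return predicted R, clamped to `[0, 1)`.
#' @examples
#' light_R(45)                    # ~0.880
#' light_R(86, augmented = FALSE) # ~0.419, near the observed median 0.41
#' @export
light_R <- function(elevation_deg, params = reliability_params(),
                    augmented = TRUE) {
  if (anyNA(elevation_deg) || any(elevation_deg < 0) || any(elevation_deg > 90))
    stop("light_R(): elevation must lie in [0, 90] degrees", call. = FALSE)
  phi <- deg2rad(elevation_deg)
  R <- ifelse(elevation_deg <= params$breakpoint_deg,
              params$light_slope_low * phi + params$light_intercept_low,
              params$light_slope_high * phi + params$light_intercept_high)
  if (augmented) R <- R + params$c_light
  .clamp_R(R)
}

#' An experimental cue condition
#'
#' One cell of the cue-conflict design: sun elevation, wind speed, the cue
#' azimuths in the arena frame, and the azimuthal conflict applied to the
#' wind cue (positive = direction of the wind shift).
#'
#' @param light_elevation_deg degrees in `[0, 90]`.
#' @param wind_speed_ms m/s, `>= 0`.
#' @param conflict_deg wind-shift angle in degrees (0, 60 and 120 in the
#'   standard design; any value accepted).
#' @param light_azimuth_deg,wind_azimuth_deg arena azimuths, wrapped to
#'   `[0, 360)`.
#' @return object of class `cue_condition`.
#' @export
cue_condition <- function(light_elevation_deg, wind_speed_ms,
                          conflict_deg = 0,
                          light_azimuth_deg = 0, wind_azimuth_deg = 0) {
  if (light_elevation_deg < 0 || light_elevation_deg > 90)
    stop("cue_condition(): elevation must lie in [0, 90] degrees", call. = FALSE)
  if (wind_speed_ms < 0)
    stop("cue_condition(): wind speed must be >= 0", call. = FALSE)
  structure(list(light_elevation_deg = light_elevation_deg,
                 wind_speed_ms = wind_speed_ms,
                 conflict_deg = conflict_deg,
                 light_azimuth_deg = light_azimuth_deg %% 360,
                 wind_azimuth_deg = wind_azimuth_deg %% 360),
            class = "cue_condition")
}

#' @export
print.cue_condition <- function(x, ...) {
  cat(sprintf("Cue condition: sun %g deg elevation, wind %g m/s, conflict %g deg\n",
              x$light_elevation_deg, x$wind_speed_ms, x$conflict_deg))
  invisible(x)
}

#' Condition identifier string
#' @param cond a [cue_condition()].
#' @return e.g. `"e60_s2.5_c120"`.
#' @export
condition_id <- function(cond) {
  sprintf("e%g_s%g_c%g", cond$light_elevation_deg, cond$wind_speed_ms,
          cond$conflict_deg)
}

#' von Mises concentrations for both cues under a condition
#'
#' Applies the reliability fits with augmentation and converts each R to a
#' concentration with [kappa_fisher()]. These are the weights fed to every
#' integration model.
#'
#' @param cond a [cue_condition()].
#' @param params a [reliability_params()] object.
#' @return named numeric vector `c(kappa_wind, kappa_light)`.
#' @examples
#' condition_kappas(cue_condition(60, 2.5)) # near-parity condition
#' @export
condition_kappas <- function(cond, params = reliability_params()) {
  c(kappa_wind = kappa_fisher(wind_R(cond$wind_speed_ms, params)),
    kappa_light = kappa_fisher(light_R(cond$light_elevation_deg, params)))
}

#' The standard 21-condition cue-conflict grid
#'
#' Elevations 45/60/75/86 degrees at 2.5 m/s and 60/75/86 degrees at
#' 1.25 m/s, each crossed with conflicts of 0, 60 and 120 degrees:
#' 12 + 9 = 21 conditions.
#'
#' @return list of [cue_condition()] objects, named by [condition_id()].
#' @export
conflict_grid <- function() {
  cells <- rbind(
    expand.grid(elev = c(45, 60, 75, 86), speed = 2.5,
                conflict = c(0, 60, 120)),
    expand.grid(elev = c(60, 75, 86), speed = 1.25,
                conflict = c(0, 60, 120)))
  conds <- lapply(seq_len(nrow(cells)), function(i)
    cue_condition(cells$elev[i], cells$speed[i], cells$conflict[i]))
  names(conds) <- vapply(conds, condition_id, character(1))
  conds
}
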