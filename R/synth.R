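# Synthetic exit-angle datasets. Exits are generated by sampling cue beliefs
# and re-integrating per exit (the snapshot model), not by adding fixed noise
# to a bearing - this is what creates the conflict-dependent population
# variance the integration models predict. Truth manifests are written
# separately and are never read by any analysis stage.

#' Synthetic single-cue precision dataset
#'
#' Emulates the precision protocol: per condition level, each beetle takes a
#' menotactic bearing uniform on the circle and produces five exits von Mises
#' distributed about (bearing + cue azimuth); the cue azimuth is then shifted
#' by 180 degrees and five more cue-locked exits follow. Concentrations come
#' from the reliability fits (augmented) unless overridden.
#'
#' @param elevations_deg ersatz-sun elevations to simulate (light cue); use
#'   `NULL` to simulate wind only.
#' @param speeds_ms wind speeds to simulate (wind cue, sun at zenith); `NULL`
#'   for light only.
#' @param n_beetles beetles per condition level (protocol default 20).
#' @param seed integer seed; a fixed seed reproduces the dataset exactly.
#' @param params [reliability_params()].
#' @param kappa_override optional fixed concentration for all levels (used
#'   in degenerate-noise tests).
#' @param base_azimuth_deg cue azimuth for the first five exits.
#' @return list with `exits` (exit table, see [exit_table_schema()]) and
#'   `truth` (list: seed, kappas per level, per-beetle true bearings).
#' @export
generate_reliability_dataset <- function(elevations_deg = c(45, 60, 75, 86),
                                         speeds_ms = NULL,
                                         n_beetles = 20L, seed = 1L,
                                         params = reliability_params(),
                                         kappa_override = NULL,
                                         base_azimuth_deg = 90) {
  set.seed(seed)
  rows <- list(); truth_levels <- list()
  gen_level <- function(cue, level, kappa) {
    bearings <- stats::runif(n_beetles, 0, 360)
    az <- c(rep(base_azimuth_deg, 5), rep((base_azimuth_deg + 180) %% 360, 5))
    recs <- lapply(seq_len(n_beetles), function(b) {
      noise <- rad2deg(sample_von_mises(10L, 0, kappa))
      data.frame(beetle_id = sprintf("%s%g_b%02d", substr(cue, 1, 1), level, b),
                 day = 1L, exit_index = 1:10, phase = "congruent",
                 light_elevation_deg = if (cue == "light") level else 90,
                 wind_speed_ms = if (cue == "wind") level else 0,
                 light_azimuth_deg = if (cue == "light") az else 0,
                 wind_azimuth_deg = if (cue == "wind") az else 0,
                 conflict_deg = 0,
                 exit_bearing_deg = (bearings[b] + az + noise) %% 360,
                 row.names = NULL)
    })
    list(exits = do.call(rbind, recs),
         truth = list(cue = cue, level = level, kappa = kappa,
                      bearings_deg = bearings))
  }
  for (e in elevations_deg) {
    kap <- if (is.null(kappa_override)) kappa_fisher(light_R(e, params))
           else kappa_override
    g <- gen_level("light", e, kap)
    rows[[length(rows) + 1L]] <- g$exits
    truth_levels[[length(truth_levels) + 1L]] <- g$truth
  }
  for (s in speeds_ms) {
    kap <- if (is.null(kappa_override)) kappa_fisher(wind_R(s, params))
           else kappa_override
    g <- gen_level("wind", s, kap)
    rows[[length(rows) + 1L]] <- g$exits
    truth_levels[[length(truth_levels) + 1L]] <- g$truth
  }
  list(exits = do.call(rbind, rows),
       truth = list(kind = "reliability", seed = seed,
                    n_beetles = n_beetles, levels = truth_levels))
}

#' Synthetic cue-conflict dataset from a known generating model
#'
#' Emulates the conflict assay: each beetle holds a persistent intended
#' bearing (uniform on the circle) and exits eight times in the protocol
#' order congruent x3, first conflict, congruent, second conflict,
#' congruent x2, with the 60/120-degree conflict order randomised per
#' beetle. Every exit is produced by drawing fresh cue beliefs (light mean
#' at the light azimuth, wind mean shifted by the active conflict) and
#' integrating them with the generating model; a BVS beetle keeps one bias
#' for its whole session.
#'
#' @param conditions data frame with columns `elev` and `speed`, or `NULL`
#'   for the standard 7 (elevation, speed) pairs of the 21-condition grid.
#' @param model generating model name or [model_config()].
#' @param n_beetles beetles per (elevation, speed) pair (protocol default
#'   30).
#' @param seed integer seed.
#' @param params [reliability_params()].
#' @param kappa_override optional `c(kappa_wind, kappa_light)` override.
#' @param light_azimuth_deg stationary light azimuth.
#' @return list with `exits` (exit table) and `truth` (generating model,
#'   seed, per-beetle bearings and biases).
#' @export
generate_conflict_dataset <- function(conditions = NULL, model = "BVS",
                                      n_beetles = 30L, seed = 1L,
                                      params = reliability_params(),
                                      kappa_override = NULL,
                                      light_azimuth_deg = 0) {
  cfg <- if (inherits(model, "model_config")) model else model_config(model)
  if (is.null(conditions))
    conditions <- rbind(data.frame(elev = c(45, 60, 75, 86), speed = 2.5),
                        data.frame(elev = c(60, 75, 86), speed = 1.25))
  set.seed(seed)
  rows <- list(); truth_beetles <- list()
  for (i in seq_len(nrow(conditions))) {
    elev <- conditions$elev[i]; speed <- conditions$speed[i]
    kap <- if (is.null(kappa_override))
      condition_kappas(cue_condition(elev, speed), params)
    else kappa_override
    # Vectorised over the n_beetles x 8 exits of this condition block.
    bearings <- stats::runif(n_beetles, 0, 360)
    first60 <- stats::runif(n_beetles) < 0.5
    ne <- 8L * n_beetles
    active <- matrix(0, nrow = 8, ncol = n_beetles)
    active[.conflict_positions[1], ] <- ifelse(first60, 60, 120)
    active[.conflict_positions[2], ] <- ifelse(first60, 120, 60)
    bias <- if (cfg$name == "BVS") sample_bias(n_beetles, cfg$sigma_bias)
            else rep(0, n_beetles)
    thw <- wrap_angle(sample_von_mises(ne, 0, kap[[1]]) + deg2rad(c(active)))
    thl <- sample_von_mises(ne, 0, kap[[2]])
    integ <- .integrate_vectorised(cfg$name, thw, thl, kap[[1]], kap[[2]],
                                   cfg$a, rep(bias, each = 8L))
    ids <- sprintf("e%g_s%g_b%03d", elev, speed, seq_len(n_beetles))
    phase <- matrix("congruent", nrow = 8, ncol = n_beetles)
    phase[.conflict_positions[1], ] <- paste0("conflict",
                                              active[.conflict_positions[1], ])
    phase[.conflict_positions[2], ] <- paste0("conflict",
                                              active[.conflict_positions[2], ])
    rows[[length(rows) + 1L]] <- data.frame(
      beetle_id = rep(ids, each = 8L), day = 1L,
      exit_index = rep(1:8, n_beetles), phase = c(phase),
      light_elevation_deg = elev, wind_speed_ms = speed,
      light_azimuth_deg = light_azimuth_deg,
      wind_azimuth_deg = (light_azimuth_deg + c(active)) %% 360,
      conflict_deg = c(active),
      exit_bearing_deg = (rep(bearings, each = 8L) + light_azimuth_deg +
                            rad2deg(integ)) %% 360,
      row.names = NULL)
    for (b in seq_len(n_beetles))
      truth_beetles[[ids[b]]] <- list(bearing_deg = bearings[b],
                                      bias = bias[b],
                                      kappa_wind = unname(kap[[1]]),
                                      kappa_light = unname(kap[[2]]))
  }
  list(exits = do.call(rbind, rows),
       truth = list(kind = "conflict", model = cfg$name, a = cfg$a,
                    sigma_bias = cfg$sigma_bias, seed = seed,
                    beetles = truth_beetles))
}
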