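# Exit-angle tables are plain data frames following the schema in
# exit_table_schema(); all bearings and azimuths are degrees in the arena
# frame, angles become radians only inside the circular primitives.

#' Exit-table column schema
#'
#' @return character vector of required column names for exit-angle tables.
#' @export
exit_table_schema <- function() {
  c("beetle_id", "day", "exit_index", "phase",
    "light_elevation_deg", "wind_speed_ms",
    "light_azimuth_deg", "wind_azimuth_deg", "conflict_deg",
    "exit_bearing_deg")
}

.assert_exit_table <- function(exits) {
  miss <- setdiff(exit_table_schema(), names(exits))
  if (length(miss))
    stop("exit table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(exits)
}

#' Normalise exit bearings to the orientation cue
#'
#' Subtracts the per-exit azimuth of the reference cue from each exit
#' bearing, wrapping to `(-180, 180]`. Because the azimuth is taken per exit,
#' the 180-degree mid-session cue shift of the precision protocol is undone
#' and all ten exits of a beetle become comparable; a cue-locked beetle has
#' ten identical normalized exits.
#'
#' @param exits exit table (see [exit_table_schema()]).
#' @param cue which cue's azimuth to normalise against: the light cue is the
#'   stationary reference in the conflict assay.
#' @return `exits` with a `normalized_deg` column added.
#' @export
normalize_exits <- function(exits, cue = c("light", "wind")) {
  .assert_exit_table(exits)
  cue <- match.arg(cue)
  az <- exits[[paste0(cue, "_azimuth_deg")]]
  if (anyNA(az))
    stop("normalize_exits(): missing cue azimuth in some record", call. = FALSE)
  exits$normalized_deg <- wrap_deg(exits$exit_bearing_deg - az)
  exits
}

#' Per-beetle resultant summaries from normalised exits
#'
#' @param exits_norm output of [normalize_exits()].
#' @return data frame with one row per (beetle_id, day): `n_exits`, `R`,
#'   `mean_deg`, `circ_sd_deg`.
#' @export
beetle_resultants <- function(exits_norm) {
  if (is.null(exits_norm$normalized_deg))
    stop("beetle_resultants(): run normalize_exits() first", call. = FALSE)
  sp <- split(exits_norm, list(exits_norm$beetle_id, exits_norm$day),
              drop = TRUE)
  do.call(rbind, lapply(sp, function(d) {
    rs <- mean_resultant(deg2rad(d$normalized_deg))
    data.frame(beetle_id = d$beetle_id[1], day = d$day[1],
               n_exits = rs$n, R = rs$R,
               mean_deg = rad2deg(rs$mean_angle),
               circ_sd_deg = rad2deg(rs$circ_sd),
               row.names = NULL)
  }))
}

#' Orientation screen for single-cue precision data
#'
#' A beetle whose ten normalised exits are not significantly different from
#' uniform (Rayleigh p above `alpha`) is deemed unable to orient and is
#' excluded from the tactic-behaviour analysis (its R still enters the
#' precision medians).
#'
#' @param normalized_deg the beetle's normalised exits (degrees).
#' @param alpha significance level.
#' @param n_required protocol exit count (10).
#' @return `TRUE` if oriented (kept), `FALSE` if excluded.
#' @export
reliability_screen <- function(normalized_deg, alpha = 0.05,
                               n_required = 10L) {
  if (length(normalized_deg) != n_required)
    stop("reliability_screen(): expected ", n_required, " exits, got ",
         length(normalized_deg), call. = FALSE)
  rayleigh_test(deg2rad(normalized_deg))$p.value <= alpha
}

#' Menotaxis versus taxis classification of a condition group
#'
#' Rayleigh test on the population of per-beetle mean normalised bearings:
#' a uniform population (p > alpha) means each animal held an arbitrary
#' bearing relative to the cue (menotaxis); a directed population (p <=
#' alpha) indicates a shared preference toward/away from the cue (taxis).
#'
#' @param mean_bearings_deg per-beetle mean normalised bearings (degrees),
#'   at least two.
#' @param alpha significance level.
#' @return list with `classification` (`"menotaxis"` or `"taxis"`), `p`,
#'   `n`.
#' @export
menotaxis_test <- function(mean_bearings_deg, alpha = 0.05) {
  if (length(mean_bearings_deg) < 2L)
    stop("menotaxis_test(): need at least two beetles", call. = FALSE)
  ht <- rayleigh_test(deg2rad(mean_bearings_deg))
  list(classification = if (ht$p.value > alpha) "menotaxis" else "taxis",
       p = ht$p.value, n = length(mean_bearings_deg))
}

# Protocol constants for one conflict session: 8 exits, conflicts at
# positions 4 and 6, congruent elsewhere.
.conflict_positions <- c(4L, 6L)

.session_order <- function(session) {
  session[order(session$exit_index), , drop = FALSE]
}

.validate_conflict_session <- function(session) {
  session <- .session_order(session)
  if (nrow(session) != 8L)
    stop("conflict session must have 8 exits, got ", nrow(session),
         call. = FALSE)
  ph <- session$phase
  if (!all(ph[.conflict_positions] %in% c("conflict60", "conflict120")) ||
      length(unique(ph[.conflict_positions])) != 2L ||
      !all(ph[-.conflict_positions] == "congruent"))
    stop("conflict session must follow congruent x3, conflict, congruent, ",
         "conflict, congruent x2 with one 60 and one 120 degree conflict",
         call. = FALSE)
  session
}

#' Bearing-recovery screen for a conflict session
#'
#' A beetle is retained only if its six congruent exits are significantly
#' directed (Rayleigh p below 0.1), i.e. it reliably recovered its bearing
#' whenever the cues were returned to their original positions.
#'
#' @param session the 8 exits of one (beetle, day) conflict session.
#' @param alpha elimination threshold: drop when p >= `alpha`.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
conflict_screen <- function(session, alpha = 0.1) {
  session <- .validate_conflict_session(session)
  cong <- session[session$phase == "congruent", , drop = FALSE]
  rayleigh_test(deg2rad(cong$exit_bearing_deg))$p.value < alpha
}

#' Signed change in heading between two consecutive exits
#'
#' `wrap(after - before)` in `(-180, 180]` degrees; with the package's
#' azimuth convention a positive change is in the direction of the applied
#' wind shift.
#'
#' @param before_deg,after_deg consecutive exit bearings (degrees).
#' @return signed change(s) in degrees.
#' @examples
#' change_in_heading(350, 10) # +20
#' @export
change_in_heading <- function(before_deg, after_deg) {
  wrap_deg(after_deg - before_deg)
}

#' Changes in heading from one conflict session
#'
#' Extracts the three protocol changes: 0-degree control (first to second
#' congruent exit) and, for each conflict exit, the change from the
#' immediately preceding congruent exit.
#'
#' @param session the 8 exits of one (beetle, day) session.
#' @return data frame with `conflict_deg` (0, 60, 120) and `change_deg`.
#' @export
session_changes <- function(session) {
  session <- .validate_conflict_session(session)
  b <- session$exit_bearing_deg
  out <- data.frame(
    conflict_deg = c(0,
                     ifelse(session$phase[4] == "conflict60", 60, 120),
                     ifelse(session$phase[6] == "conflict60", 60, 120)),
    change_deg = c(change_in_heading(b[1], b[2]),
                   change_in_heading(b[3], b[4]),
                   change_in_heading(b[5], b[6])))
  out[order(out$conflict_deg), , drop = FALSE]
}

#' Circular summary of a set of heading changes
#'
#' @param changes_deg per-beetle changes in heading (degrees), `n >= 2`.
#' @return list with `n`, `mean_deg`, `circ_sd_deg`, `R`, `rayleigh_p`.
#' @export
summarize_condition <- function(changes_deg) {
  if (length(changes_deg) < 2L)
    stop("summarize_condition(): need at least two changes", call. = FALSE)
  th <- deg2rad(changes_deg)
  rs <- mean_resultant(th)
  list(n = rs$n,
       mean_deg = rad2deg(rs$mean_angle),
       circ_sd_deg = rad2deg(rs$circ_sd),
       R = rs$R,
       rayleigh_p = rayleigh_test(th)$p.value)
}

#' Single-cue precision analysis pipeline
#'
#' For each condition level (elevation for the light cue, speed for wind):
#' normalises each beetle's ten exits to the cue azimuth, computes per-beetle
#' R, applies the orientation screen, classifies the oriented population as
#' menotactic or tactic, and reports median R with IQR over *all* beetles
#' (screened-out individuals still contribute to precision, matching the
#' published analysis). Quantiles use linear interpolation between order
#' statistics.
#'
#' @param exits exit table for single-cue sessions.
#' @param cue `"light"` or `"wind"`.
#' @param alpha screen significance level.
#' @param n_exits protocol exits per beetle (10).
#' @return list with `summary` (one row per condition level: `level`, `n`,
#'   `n_oriented`, `median_R`, `IQR_low`, `IQR_high`, `taxis_p`,
#'   `classification`, `note`) and `beetles` (per-beetle resultants with
#'   `oriented` flag).
#' @export
analyze_reliability <- function(exits, cue = c("light", "wind"),
                                alpha = 0.05, n_exits = 10L) {
  cue <- match.arg(cue)
  exits <- normalize_exits(exits, cue)
  level_col <- if (cue == "light") "light_elevation_deg" else "wind_speed_ms"
  sp <- split(exits, exits[[level_col]])
  beetles <- list(); rows <- list()
  for (lv in names(sp)) {
    res <- beetle_resultants(sp[[lv]])
    res$oriented <- vapply(split(sp[[lv]], sp[[lv]]$beetle_id),
                           function(d) reliability_screen(d$normalized_deg,
                                                          alpha,
                                                          n_exits),
                           logical(1))[as.character(res$beetle_id)]
    res$level <- as.numeric(lv)
    beetles[[lv]] <- res
    men <- if (sum(res$oriented) >= 2)
      menotaxis_test(res$mean_deg[res$oriented], alpha)
    else list(classification = NA_character_, p = NA_real_)
    q <- stats::quantile(res$R, c(0.25, 0.5, 0.75), type = 7)
    rows[[lv]] <- data.frame(level = as.numeric(lv), n = nrow(res),
                             n_oriented = sum(res$oriented),
                             median_R = unname(q[2]),
                             IQR_low = unname(q[1]), IQR_high = unname(q[3]),
                             taxis_p = men$p,
                             classification = men$classification,
                             note = "", row.names = NULL)
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(summary$level), , drop = FALSE]
  rownames(summary) <- NULL
  list(summary = summary, beetles = do.call(rbind, beetles))
}

#' Cue-conflict analysis pipeline
#'
#' Groups exits into (beetle, day) sessions, applies the bearing-recovery
#' screen, extracts each keeper's three changes in heading, and pools them
#' into the (elevation, speed, conflict) condition cells used for model
#' evaluation.
#'
#' @param exits exit table for conflict sessions.
#' @param alpha recovery-screen threshold (drop when congruent Rayleigh
#'   p >= alpha).
#' @return list with `changes_by_condition` (named list of degree vectors,
#'   keyed by [condition_id()]), `summary` (per-cell circular statistics),
#'   `n_total` (post-screen datum count), `n_sessions_kept`,
#'   `n_sessions_dropped`.
#' @export
analyze_conflict <- function(exits, alpha = 0.1) {
  .assert_exit_table(exits)
  sessions <- split(exits, list(exits$beetle_id, exits$day), drop = TRUE)
  changes <- list()
  kept <- 0L; dropped <- 0L
  for (s in sessions) {
    if (!conflict_screen(s, alpha)) { dropped <- dropped + 1L; next }
    kept <- kept + 1L
    ch <- session_changes(s)
    for (i in seq_len(nrow(ch))) {
      cid <- condition_id(cue_condition(s$light_elevation_deg[1],
                                        s$wind_speed_ms[1],
                                        ch$conflict_deg[i]))
      changes[[cid]] <- c(changes[[cid]], ch$change_deg[i])
    }
  }
  summary <- do.call(rbind, lapply(names(changes), function(cid) {
    sm <- summarize_condition(changes[[cid]])
    data.frame(condition = cid, n = sm$n, mean_deg = sm$mean_deg,
               circ_sd_deg = sm$circ_sd_deg, R = sm$R,
               rayleigh_p = sm$rayleigh_p, row.names = NULL)
  }))
  list(changes_by_condition = changes, summary = summary,
       n_total = sum(lengths(changes)),
       n_sessions_kept = kept, n_sessions_dropped = dropped)
}

#' Individual precision in a sustained conflict series
#'
#' For the individual-precision protocol (ten exits per conflict level) this
#' computes each beetle's R per level and the median/IQR across beetles.
#'
#' @param exits exit table where `phase` encodes the conflict level and each
#'   (beetle, phase) group holds that beetle's exits under the level.
#' @param by column distinguishing the levels (default `"phase"`).
#' @return data frame: `level`, `n_beetles`, `median_R`, `IQR_low`,
#'   `IQR_high`.
#' @export
individual_precision <- function(exits, by = "phase") {
  .assert_exit_table(exits)
  exits <- normalize_exits(exits, "light")
  sp <- split(exits, exits[[by]])
  do.call(rbind, lapply(names(sp), function(lv) {
    Rs <- vapply(split(sp[[lv]], sp[[lv]]$beetle_id),
                 function(d) mean_resultant(deg2rad(d$normalized_deg))$R,
                 numeric(1))
    q <- stats::quantile(Rs, c(0.25, 0.5, 0.75), type = 7)
    data.frame(level = lv, n_beetles = length(Rs), median_R = unname(q[2]),
               IQR_low = unname(q[1]), IQR_high = unname(q[3]),
               row.names = NULL)
  }))
}
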