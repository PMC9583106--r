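test_that("normalize_exits subtracts the per-exit cue azimuth", {
  ds <- generate_reliability_dataset(elevations_deg = 60, n_beetles = 2,
                                     seed = 4)
  ex <- normalize_exits(ds$exits, "light")
  expect_true(all(ex$normalized_deg > -180 & ex$normalized_deg <= 180))

  # hand-built records: 90 at azimuth 90 -> 0; 10 at azimuth 350 -> +20
  row <- ds$exits[1:2, ]
  row$exit_bearing_deg <- c(90, 10)
  row$light_azimuth_deg <- c(90, 350)
  expect_equal(normalize_exits(row, "light")$normalized_deg, c(0, 20))

  # protocol round trip: a cue-locked beetle has identical normalized exits
  # through the 180-degree azimuth shift
  locked <- generate_reliability_dataset(elevations_deg = 45, n_beetles = 3,
                                         seed = 6, kappa_override = 1e9)
  nl <- normalize_exits(locked$exits, "light")
  for (d in split(nl, nl$beetle_id)) {
    expect_lt(diff(range(d$normalized_deg)), 0.05)
    expect_gt(mean_resultant(deg2rad(d$normalized_deg))$R, 0.999999)
  }

  bad <- ds$exits; bad$light_azimuth_deg[3] <- NA
  expect_error(normalize_exits(bad, "light"), "azimuth")
})

test_that("reliability screen keeps oriented beetles and matches Rayleigh
           power", {
  expect_true(reliability_screen(rep(37, 10)))
  expect_false(reliability_screen(seq(0, 324, by = 36)))
  expect_error(reliability_screen(rep(0, 7)), "expected 10")

  # kappa = 2 beetles are excluded at the complement of Rayleigh power at
  # n = 10 (measured operating characteristic ~0.93 keep rate)
  set.seed(55)
  kept <- mean(replicate(500,
    reliability_screen(rad2deg(sample_von_mises(10, 0, 2)))))
  expect_gt(kept, 0.85)
  expect_lt(kept, 0.99)
  # and kappa = 0 beetles are kept at roughly the alpha rate
  set.seed(56)
  kept0 <- mean(replicate(500,
    reliability_screen(rad2deg(sample_von_mises(10, 0, 0)))))
  expect_lt(kept0, 0.12)
})

test_that("menotaxis_test separates arbitrary from shared bearings", {
  set.seed(9)
  expect_equal(menotaxis_test(stats::runif(20, -180, 180))$classification,
               "menotaxis")
  expect_equal(menotaxis_test(stats::runif(20, -10, 10))$classification,
               "taxis")
  expect_error(menotaxis_test(5), "two beetles")

  # anemotaxis power: means ~ VM(0, kappa = 1.5), n = 14 beetles
  set.seed(10)
  hits <- mean(replicate(100, {
    m <- rad2deg(sample_von_mises(14, 0, 1.5))
    menotaxis_test(m)$classification == "taxis"
  }))
  expect_gt(hits, 0.7)
})

test_that("conflict_screen enforces bearing recovery on the six congruent
           exits", {
  keep <- make_session(c(10, 12, 8, 70, 11, 130, 9, 10))
  expect_true(conflict_screen(keep))
  drop <- make_session(c(0, 60, 120, 33, 180, 99, 240, 300))
  expect_false(conflict_screen(drop))

  # protocol violations are rejected
  expect_error(conflict_screen(keep[-1, ]), "8 exits")
  bad <- keep; bad$phase[4] <- "congruent"
  expect_error(conflict_screen(bad), "congruent x3")
  bad2 <- keep; bad2$phase[6] <- "conflict60" # duplicate conflict level
  expect_error(conflict_screen(bad2), "congruent x3")

  # operating characteristic: kappa = 4 keepers vs kappa = 0 non-keepers
  set.seed(12)
  rate <- function(k) mean(replicate(300, {
    b <- rad2deg(sample_von_mises(8, 0, k))
    conflict_screen(make_session(b))
  }))
  expect_gt(rate(4), 0.9)
  expect_lt(rate(0), 0.25)
})

test_that("change_in_heading wraps the consecutive-exit difference", {
  expect_equal(change_in_heading(350, 10), 20)
  expect_equal(change_in_heading(10, 350), -20)
  expect_equal(change_in_heading(123, 123), 0)
  expect_equal(change_in_heading(90, 270), 180)

  # a perfect wind-follower shows the full shift
  s <- make_session(c(0, 0, 0, 60, 0, 120, 0, 0))
  ch <- session_changes(s)
  expect_equal(ch$change_deg[ch$conflict_deg == 0], 0)
  expect_equal(ch$change_deg[ch$conflict_deg == 60], 60)
  expect_equal(ch$change_deg[ch$conflict_deg == 120], 120)

  # conflict order is read from the phases, not assumed
  s2 <- make_session(c(5, 5, 5, 125, 5, 65, 5, 5), conflicts = c(120, 60))
  ch2 <- session_changes(s2)
  expect_equal(ch2$change_deg[ch2$conflict_deg == 120], 120)
  expect_equal(ch2$change_deg[ch2$conflict_deg == 60], 60)
})

test_that("summarize_condition recovers distribution parameters", {
  expect_error(summarize_condition(5), "two changes")
  all0 <- summarize_condition(rep(0, 12))
  expect_equal(all0$mean_deg, 0)
  expect_equal(all0$circ_sd_deg, 0)
  expect_lt(all0$rayleigh_p, 1e-4)

  set.seed(30)
  sm <- summarize_condition(rad2deg(sample_von_mises(27, deg2rad(60), 2)))
  expect_equal(sm$mean_deg, 60, tolerance = 25)
  expect_equal(sm$n, 27)
  expect_gt(sm$R, 0.4)
})

test_that("analyze_conflict pools per-session changes into condition cells
           and is frame-invariant", {
  ds <- generate_conflict_dataset(conditions = data.frame(elev = c(45, 60),
                                                          speed = 2.5),
                                  model = "NVS", n_beetles = 25, seed = 14)
  an <- analyze_conflict(ds$exits)
  expect_equal(an$n_sessions_kept + an$n_sessions_dropped, 50)
  expect_equal(an$n_total, 3L * an$n_sessions_kept)
  expect_setequal(names(an$changes_by_condition),
                  c("e45_s2.5_c0", "e45_s2.5_c60", "e45_s2.5_c120",
                    "e60_s2.5_c0", "e60_s2.5_c60", "e60_s2.5_c120"))
  expect_true(all(an$summary$n >= 2))

  # rotating the whole arena frame leaves every change untouched
  rot <- ds$exits
  rot$exit_bearing_deg <- (rot$exit_bearing_deg + 77) %% 360
  rot$light_azimuth_deg <- (rot$light_azimuth_deg + 77) %% 360
  rot$wind_azimuth_deg <- (rot$wind_azimuth_deg + 77) %% 360
  an_rot <- analyze_conflict(rot)
  expect_equal(an_rot$changes_by_condition, an$changes_by_condition,
               tolerance = 1e-9)
})

test_that("analyze_reliability reports medians, IQRs and classification", {
  ds <- generate_reliability_dataset(elevations_deg = c(45, 86),
                                     n_beetles = 20, seed = 18)
  an <- analyze_reliability(ds$exits, cue = "light")
  expect_equal(an$summary$level, c(45, 86))
  expect_equal(an$summary$n, c(20, 20))
  expect_true(all(an$summary$IQR_low <= an$summary$median_R))
  expect_true(all(an$summary$median_R <= an$summary$IQR_high))
  # precision falls with elevation
  expect_gt(an$summary$median_R[1], an$summary$median_R[2])
  # uniform intended bearings: menotaxis at both levels
  expect_true(all(an$summary$classification == "menotaxis"))
})

test_that("individual_precision summarises per-phase beetle R values", {
  # build a 10-exits-per-phase series from the generator pieces
  set.seed(20)
  rows <- list()
  for (b in 1:8) {
    bearing <- stats::runif(1, 0, 360)
    for (ph in c("congruent", "conflict60", "conflict120")) {
      noise <- rad2deg(sample_von_mises(10, 0, 8))
      rows[[length(rows) + 1L]] <- data.frame(
        beetle_id = sprintf("b%d", b), day = 1L, exit_index = 1:10,
        phase = ph, light_elevation_deg = 60, wind_speed_ms = 2.5,
        light_azimuth_deg = 0, wind_azimuth_deg = 0,
        conflict_deg = switch(ph, congruent = 0, conflict60 = 60, 120),
        exit_bearing_deg = (bearing + noise) %% 360)
    }
  }
  ip <- individual_precision(do.call(rbind, rows))
  expect_equal(nrow(ip), 3)
  expect_equal(ip$n_beetles, rep(8, 3))
  expect_true(all(ip$median_R > 0.8))
})
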