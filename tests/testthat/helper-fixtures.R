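# Shared fixture builders. Everything is generated in code; no stored data.

# One valid conflict session (8 exits) with explicit bearings.
make_session <- function(bearings, conflicts = c(60, 120), beetle = "b1",
                         elev = 60, speed = 2.5, day = 1L) {
  stopifnot(length(bearings) == 8L)
  phase <- rep("congruent", 8)
  phase[c(4, 6)] <- paste0("conflict", conflicts)
  active <- numeric(8)
  active[c(4, 6)] <- conflicts
  data.frame(beetle_id = beetle, day = day, exit_index = 1:8, phase = phase,
             light_elevation_deg = elev, wind_speed_ms = speed,
             light_azimuth_deg = 0, wind_azimuth_deg = active %% 360,
             conflict_deg = active, exit_bearing_deg = bearings %% 360)
}

# Uniform PMF over nb bins (no Laplace smoothing needed: every bin occupied).
uniform_pmf <- function(bw = 5) {
  centers <- seq(-180 + bw / 2, 180 - bw / 2, by = bw)
  bin_to_pmf(centers, bw, laplace = FALSE)
}

# A PMF with hand-set masses, for likelihood arithmetic tests.
manual_pmf <- function(mass, bw = 5) {
  stopifnot(length(mass) == 360 / bw, abs(sum(mass) - 1) < 1e-9)
  left <- seq(-180, 180 - bw, by = bw)
  structure(data.frame(bin_left_deg = left, bin_right_deg = left + bw,
                       mass = mass),
            class = c("population_pmf", "data.frame"))
}
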