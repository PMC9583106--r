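#' Simulation configuration
#'
#' @param n_sim simulated population size per (model, condition); the
#'   benchmark value is 1e6, tests scale down to 1e4-1e5.
#' @param bin_width_deg histogram bin width in degrees; must divide 360.
#' @param seed integer seed for the whole simulation run.
#' @param share_samples if `TRUE` (default) the von Mises cue samples for a
#'   condition are drawn once and reused by every model, minimising sampling
#'   noise in model comparisons.
#' @param a,sigma_bias model parameters passed to NVS/BVS.
#' @param params [reliability_params()] used to derive concentrations.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_sim = 1e6, bin_width_deg = 5, seed = 1L,
                              share_samples = TRUE, a = 53,
                              sigma_bias = sqrt(0.000303),
                              params = reliability_params()) {
  stopifnot(n_sim >= 1, 360 %% bin_width_deg == 0)
  structure(list(n_sim = as.integer(n_sim), bin_width_deg = bin_width_deg,
                 seed = as.integer(seed), share_samples = share_samples,
                 a = a, sigma_bias = sigma_bias, params = params),
            class = "simulation_config")
}

# One condition's worth of raw cue samples in the canonical frame (light
# azimuth = 0): aligned means for the initial integration, wind mean shifted
# by +conflict for the conflict integration. Draw order is fixed so a given
# seed always yields the same samples.
.draw_condition_samples <- function(n, conflict_rad, kappa_wind, kappa_light) {
  list(wind_init = sample_von_mises(n, 0, kappa_wind),
       light_init = sample_von_mises(n, 0, kappa_light),
       wind_conf = sample_von_mises(n, conflict_rad, kappa_wind),
       light_conf = sample_von_mises(n, 0, kappa_light))
}

# Apply one model to pre-drawn samples; returns changes in heading (radians).
.changes_from_samples <- function(model, smp, kappa_wind, kappa_light,
                                  a, bias = NULL) {
  init <- .integrate_vectorised(model, smp$wind_init, smp$light_init,
                                kappa_wind, kappa_light, a, bias)
  conf <- .integrate_vectorised(model, smp$wind_conf, smp$light_conf,
                                kappa_wind, kappa_light, a, bias)
  wrap_angle(conf - init)
}

#' Change in heading of one simulated individual
#'
#' Samples both cues with aligned means, integrates; samples both cues again
#' with the wind mean shifted by the conflict angle (fresh, independent
#' draws), integrates; returns the wrapped difference (conflict minus
#' initial), positive in the direction of the wind shift. For BVS one bias
#' is drawn per individual and reused across both steps.
#'
#' @param model model name or [model_config()].
#' @param cond a [cue_condition()].
#' @param kappas optional `c(kappa_wind, kappa_light)` override; defaults to
#'   [condition_kappas()].
#' @param params [reliability_params()].
#' @return change in heading, degrees in `(-180, 180]`.
#' @export
simulate_individual_change <- function(model, cond, kappas = NULL,
                                       params = reliability_params()) {
  cfg <- if (inherits(model, "model_config")) model else model_config(model)
  if (is.null(kappas)) kappas <- condition_kappas(cond, params)
  smp <- .draw_condition_samples(1L, deg2rad(cond$conflict_deg),
                                 kappas[[1]], kappas[[2]])
  bias <- if (cfg$name == "BVS") sample_bias(1L, cfg$sigma_bias) else NULL
  rad2deg(.changes_from_samples(cfg$name, smp, kappas[[1]], kappas[[2]],
                                cfg$a, bias))
}

#' Simulate a population of changes in heading
#'
#' `n_sim` independent individuals under one (model, condition) pair.
#' Deterministic for a fixed `config$seed`.
#'
#' @param model model name.
#' @param cond a [cue_condition()].
#' @param config a [simulation_config()].
#' @return numeric vector of changes in heading (degrees, `(-180, 180]`).
#' @export
simulate_population <- function(model, cond, config = simulation_config()) {
  set.seed(config$seed)
  kap <- condition_kappas(cond, config$params)
  smp <- .draw_condition_samples(config$n_sim, deg2rad(cond$conflict_deg),
                                 kap[[1]], kap[[2]])
  model <- if (inherits(model, "model_config")) model$name else model
  bias <- if (model == "BVS") sample_bias(config$n_sim, config$sigma_bias)
          else NULL
  rad2deg(.changes_from_samples(model, smp, kap[[1]], kap[[2]],
                                config$a, bias))
}

#' Bin changes in heading into a normalized probability mass function
#'
#' Histograms a population of heading changes over half-open, right-closed
#' bins anchored at multiples of the bin width covering `(-180, 180]`
#' (72 bins at the default 5 degrees) and normalises. With
#' `laplace = TRUE` one pseudo-count is added to every bin before
#' normalising, so no bin has zero mass and downstream log-likelihoods stay
#' finite; this is the form used as a model's likelihood function.
#'
#' @param changes_deg changes in heading (degrees); wrapped internally.
#' @param bin_width_deg bin width; must divide 360.
#' @param laplace add 1 pseudo-count per bin before normalising?
#' @param model,condition optional labels stored on the result.
#' @return object of class `population_pmf`: data frame with
#'   `bin_left_deg`, `bin_right_deg`, `mass`, plus attributes `model`,
#'   `condition_id` and `n`.
#' @export
bin_to_pmf <- function(changes_deg, bin_width_deg = 5, laplace = TRUE,
                       model = NA_character_, condition = NA_character_) {
  if (length(changes_deg) < 1L)
    stop("bin_to_pmf(): no data to bin", call. = FALSE)
  stopifnot(360 %% bin_width_deg == 0)
  nb <- as.integer(360 / bin_width_deg)
  x <- wrap_deg(changes_deg) # (-180, 180]
  idx <- pmax(1L, as.integer(ceiling((x + 180) / bin_width_deg)))
  counts <- tabulate(idx, nbins = nb)
  mass <- if (laplace) (counts + 1) / (sum(counts) + nb)
          else counts / sum(counts)
  left <- seq(-180, 180 - bin_width_deg, by = bin_width_deg)
  structure(data.frame(bin_left_deg = left,
                       bin_right_deg = left + bin_width_deg,
                       mass = mass),
            model = model, condition_id = condition,
            n = length(changes_deg),
            class = c("population_pmf", "data.frame"))
}

# Map wrapped degree values to PMF bin indices (shared with the likelihood).
.pmf_bin_index <- function(x_deg, bin_width_deg) {
  x <- wrap_deg(x_deg)
  pmax(1L, as.integer(ceiling((x + 180) / bin_width_deg)))
}

#' Simulate PMFs for every model and condition
#'
#' Runs the Monte-Carlo simulator over a model list and a condition grid,
#' producing one normalized PMF per (model, condition). When
#' `config$share_samples` is on (default) the cue samples for each condition
#' are drawn once and reused across models, so models are compared on
#' identical noise realisations. Seeding is global: the run is a pure
#' function of `config$seed` and the grid order.
#'
#' @param models character vector of model names.
#' @param conditions list of [cue_condition()]s, e.g. [conflict_grid()].
#' @param config a [simulation_config()].
#' @return nested list `pmfs[[model]][[condition_id]]` of `population_pmf`
#'   objects.
#' @export
run_condition_grid <- function(models = names(model_n_params()),
                               conditions = conflict_grid(),
                               config = simulation_config()) {
  if (length(conditions) < 1L)
    stop("run_condition_grid(): empty condition list", call. = FALSE)
  if (is.null(names(conditions)))
    names(conditions) <- vapply(conditions, condition_id, character(1))
  set.seed(config$seed)
  out <- stats::setNames(
    lapply(models, function(m) vector("list", length(conditions))), models)
  for (m in models) names(out[[m]]) <- names(conditions)

  for (cid in names(conditions)) {
    cond <- conditions[[cid]]
    kap <- condition_kappas(cond, config$params)
    if (config$share_samples) {
      smp <- .draw_condition_samples(config$n_sim,
                                     deg2rad(cond$conflict_deg),
                                     kap[[1]], kap[[2]])
      bias <- if ("BVS" %in% models)
        sample_bias(config$n_sim, config$sigma_bias) else NULL
      for (m in models) {
        ch <- .changes_from_samples(m, smp, kap[[1]], kap[[2]], config$a,
                                    if (m == "BVS") bias else NULL)
        out[[m]][[cid]] <- bin_to_pmf(rad2deg(ch), config$bin_width_deg,
                                      model = m, condition = cid)
      }
    } else {
      for (m in models) {
        smp <- .draw_condition_samples(config$n_sim,
                                       deg2rad(cond$conflict_deg),
                                       kap[[1]], kap[[2]])
        bias <- if (m == "BVS")
          sample_bias(config$n_sim, config$sigma_bias) else NULL
        ch <- .changes_from_samples(m, smp, kap[[1]], kap[[2]], config$a, bias)
        out[[m]][[cid]] <- bin_to_pmf(rad2deg(ch), config$bin_width_deg,
                                      model = m, condition = cid)
      }
    }
  }
  out
}
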