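#' A sampled cue belief
#'
#' The instantaneous percept of one cue: a sampled direction `theta`
#' (radians, wrapped) and the concentration `kappa` of the noise distribution
#' it was drawn from. Every integration model maps two beliefs to one heading.
#'
#' @param theta sampled direction (radians).
#' @param kappa concentration, `>= 0`.
#' @return object of class `cue_belief`.
#' @export
cue_belief <- function(theta, kappa) {
  if (length(kappa) != 1L || kappa < 0)
    stop("cue_belief(): kappa must be a single value >= 0", call. = FALSE)
  structure(list(theta = wrap_angle(theta), kappa = kappa),
            class = "cue_belief")
}

#' Model names and free-parameter counts
#'
#' The five integration strategies compared by the package, with the number
#' of fitted parameters each carries into AIC/BIC: WTA, WAM and WVS have
#' none; NVS fits the sigmoid steepness `a`; BVS fits `a` and the bias SD.
#'
#' @return named integer vector.
#' @export
model_n_params <- function() {
  c(WTA = 0L, WAM = 0L, WVS = 0L, NVS = 1L, BVS = 2L)
}

#' Integration-model configuration
#'
#' @param name one of `"WTA"`, `"WAM"`, `"WVS"`, `"NVS"`, `"BVS"`.
#' @param a sigmoid steepness for NVS/BVS; default 53, the grid-search
#'   maximum-likelihood value.
#' @param sigma_bias SD of the per-individual weight bias for BVS; default
#'   `sqrt(0.000303) ~ 0.0174` - a deliberately narrow prior, so most
#'   individuals are effectively unbiased and bias only matters where the
#'   cue weights are near parity.
#' @return object of class `model_config` with `n_params` filled from
#'   [model_n_params()].
#' @export
model_config <- function(name, a = 53, sigma_bias = sqrt(0.000303)) {
  name <- match.arg(name, names(model_n_params()))
  stopifnot(a > 0, sigma_bias >= 0)
  structure(list(name = name, a = a, sigma_bias = sigma_bias,
                 n_params = unname(model_n_params()[name])),
            class = "model_config")
}

#' Reliability-proportional normalized weights
#'
#' `w_wind = kappa_wind / (kappa_wind + kappa_light)` and its complement;
#' the optimal weighting for von Mises cues.
#'
#' @param kappa_wind,kappa_light concentrations with a positive sum.
#' @return named vector `c(w_wind, w_light)` summing to 1.
#' @export
normalized_weights <- function(kappa_wind, kappa_light) {
  s <- kappa_wind + kappa_light
  if (any(s <= 0))
    stop("normalized_weights(): both concentrations are zero", call. = FALSE)
  c(w_wind = kappa_wind / s, w_light = kappa_light / s)
}

#' Sigmoid weight adjustment
#'
#' `g(x; a) = 1 / (1 + exp(-a * (x - 0.5)))`: fixes 0.5, is strictly
#' increasing, and for large `a` pushes any weight advantage toward total
#' dominance - the mechanism that turns the optimal vector sum into a
#' pseudo-winner-take-all (NVS) while still letting the weaker cue
#' contribute.
#'
#' @param x weight(s); any real value accepted (BVS passes shifted weights).
#' @param a steepness, `> 0`.
#' @return adjusted weight(s) in `(0, 1)`.
#' @export
sigmoid_adjust <- function(x, a = 53) {
  if (a <= 0) stop("sigmoid_adjust(): a must be > 0", call. = FALSE)
  1 / (1 + exp(-a * (x - 0.5)))
}

# Core vector-sum heading: theta_wind + atan2(sin(theta_light - theta_wind),
# ratio + cos(theta_light - theta_wind)) with ratio = w_wind / w_light.
# This is the angular component of the sum of polar vectors
# (theta_wind, w_wind) + (theta_light, w_light); only the weight ratio
# matters. The atan2(0, 0) degeneracy (equal weights, 180 deg apart) is
# resolved as a zero offset, i.e. theta_wind.
.vector_sum_angle <- function(theta_wind, theta_light, ratio) {
  d <- theta_light - theta_wind
  s <- sin(d)
  c0 <- ratio + cos(d)
  off <- atan2(s, c0)
  # equal weights at an exact 180-degree conflict: the sum vector vanishes
  # (up to rounding in sin(pi)); resolve the offset as 0, i.e. theta_wind
  off[abs(s) < 1e-9 & abs(c0) < 1e-9] <- 0
  wrap_angle(theta_wind + off)
}

#' Winner-take-all integration
#'
#' Returns the sampled azimuth of the cue with the larger concentration;
#' exact ties (measure zero under Monte-Carlo noise) are broken by a fair
#' coin from the current RNG stream.
#'
#' @param wind,light [cue_belief()] objects.
#' @return integrated heading (radians).
#' @export
integrate_wta <- function(wind, light) {
  if (wind$kappa > light$kappa) return(wind$theta)
  if (light$kappa > wind$kappa) return(light$theta)
  if (stats::runif(1) < 0.5) wind$theta else light$theta
}

#' Weighted arithmetic mean integration
#'
#' The classical linear weighted average `w_wind * theta_wind +
#' w_light * theta_light`, computed on the raw angle values in the canonical
#' frame without wrapping them first. This is deliberately the "wrong"
#' operation for circular data - averaging headings either side of the
#' +/-180 degree cut gives a heading pointing the opposite way - and the
#' pathology is preserved because the model is included precisely to test
#' that linear averaging fails on angular cues. Consequently WAM is
#' frame-dependent: the package's canonical frame places the light azimuth
#' at 0 with angles in `(-pi, pi]`.
#'
#' @param wind,light [cue_belief()] objects.
#' @return integrated heading (radians, wrapped for downstream use).
#' @export
integrate_wam <- function(wind, light) {
  w <- normalized_weights(wind$kappa, light$kappa)
  wrap_angle(w[["w_wind"]] * wind$theta + w[["w_light"]] * light$theta)
}

#' Optimal weighted vector sum integration
#'
#' Interprets each belief as a polar vector with length equal to its weight
#' and returns the direction of their sum. With reliability-proportional
#' weights this is the Bayes-optimal combination of von Mises cues; it
#' behaves like the arithmetic mean at small conflicts and like
#' winner-take-all at large conflicts with unequal weights.
#'
#' @param wind,light [cue_belief()] objects.
#' @param weights optional `c(w_wind, w_light)`; defaults to
#'   [normalized_weights()] of the beliefs' concentrations. `w_light = 0`
#'   returns `theta_wind` (the vector-sum limit).
#' @return integrated heading (radians).
#' @export
integrate_wvs <- function(wind, light, weights = NULL) {
  if (is.null(weights))
    weights <- normalized_weights(wind$kappa, light$kappa)
  w_w <- weights[[1]]; w_l <- weights[[2]]
  if (w_l <= 0) return(wind$theta)
  .vector_sum_angle(wind$theta, light$theta, w_w / w_l)
}

#' Non-optimal (sigmoid-adjusted) vector sum integration
#'
#' Normalized weights are passed through [sigmoid_adjust()] before the
#' vector sum, shrinking the region of weight space where both cues matter.
#' Equal concentrations reproduce the optimal sum exactly (g fixes 0.5);
#' as `a` grows NVS tends to winner-take-all on non-tied inputs.
#'
#' @param wind,light [cue_belief()] objects.
#' @param a sigmoid steepness.
#' @return integrated heading (radians).
#' @export
integrate_nvs <- function(wind, light, a = 53) {
  w <- normalized_weights(wind$kappa, light$kappa)
  .vector_sum_angle(wind$theta, light$theta,
                    sigmoid_adjust(w[["w_wind"]], a) /
                      sigmoid_adjust(w[["w_light"]], a))
}

#' Biased non-optimal vector sum integration
#'
#' As [integrate_nvs()], but the normalized wind weight is shifted by `-b`
#' and the light weight by `+b` before sigmoid adjustment, where `b` is a
#' per-individual bias drawn once per animal (and reused across the initial
#' and conflict integrations) from `Normal(0, sigma_bias)`. Positive `b`
#' biases the individual toward the light cue. Shifted weights may leave
#' `[0, 1]`; they are passed to the sigmoid unclamped, which maps all reals
#' into `(0, 1)`.
#'
#' @param wind,light [cue_belief()] objects.
#' @param a sigmoid steepness.
#' @param bias_b the individual's bias (supply the same value for both
#'   integration steps of one individual).
#' @return integrated heading (radians).
#' @seealso [sample_bias()] to draw per-individual biases.
#' @export
integrate_bvs <- function(wind, light, a = 53, bias_b = 0) {
  w <- normalized_weights(wind$kappa, light$kappa)
  .vector_sum_angle(wind$theta, light$theta,
                    sigmoid_adjust(w[["w_wind"]] - bias_b, a) /
                      sigmoid_adjust(w[["w_light"]] + bias_b, a))
}

#' Draw per-individual weight biases
#'
#' @param n number of individuals.
#' @param sigma_bias SD of the zero-mean Gaussian bias distribution.
#' @return numeric vector of biases.
#' @export
sample_bias <- function(n, sigma_bias = sqrt(0.000303)) {
  stats::rnorm(n, 0, sigma_bias)
}

#' Integrate two cue beliefs under a named model
#'
#' Dispatcher over the five strategies; the per-model functions document the
#' mathematics.
#'
#' @param model model name or [model_config()].
#' @param wind,light [cue_belief()] objects.
#' @param bias_b individual bias (BVS only).
#' @return integrated heading (radians).
#' @export
integrate_cues <- function(model, wind, light, bias_b = 0) {
  cfg <- if (inherits(model, "model_config")) model else model_config(model)
  switch(cfg$name,
         WTA = integrate_wta(wind, light),
         WAM = integrate_wam(wind, light),
         WVS = integrate_wvs(wind, light),
         NVS = integrate_nvs(wind, light, cfg$a),
         BVS = integrate_bvs(wind, light, cfg$a, bias_b))
}

# Vectorised model application used by the simulator: theta_* are equal-length
# sample vectors, kappas scalars, bias a vector (BVS) or NULL. Returns the
# integrated heading for each individual. WTA's tie branch draws one coin per
# individual to keep RNG consumption deterministic.
.integrate_vectorised <- function(model, theta_wind, theta_light,
                                  kappa_wind, kappa_light,
                                  a = 53, bias = NULL) {
  switch(model,
    WTA = {
      if (kappa_wind > kappa_light) theta_wind
      else if (kappa_light > kappa_wind) theta_light
      else ifelse(stats::runif(length(theta_wind)) < 0.5, theta_wind, theta_light)
    },
    WAM = {
      w <- normalized_weights(kappa_wind, kappa_light)
      wrap_angle(w[["w_wind"]] * theta_wind + w[["w_light"]] * theta_light)
    },
    WVS = {
      w <- normalized_weights(kappa_wind, kappa_light)
      .vector_sum_angle(theta_wind, theta_light, w[["w_wind"]] / w[["w_light"]])
    },
    NVS = {
      w <- normalized_weights(kappa_wind, kappa_light)
      .vector_sum_angle(theta_wind, theta_light,
                        sigmoid_adjust(w[["w_wind"]], a) /
                          sigmoid_adjust(w[["w_light"]], a))
    },
    BVS = {
      if (is.null(bias))
        stop("BVS requires a bias vector", call. = FALSE)
      w <- normalized_weights(kappa_wind, kappa_light)
      .vector_sum_angle(theta_wind, theta_light,
                        sigmoid_adjust(w[["w_wind"]] - bias, a) /
                          sigmoid_adjust(w[["w_light"]] + bias, a))
    },
    stop("unknown model: ", model, call. = FALSE))
}
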