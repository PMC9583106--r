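#' Wrap angles to the principal interval
#'
#' Maps an angle (radians) to its representative in `(-pi, pi]`. All internal
#' computation in beetlecue is done in radians on this interval; degrees appear
#' only at the file/CLI boundary.
#'
#' @param x numeric vector of angles in radians. Must be finite.
#' @return numeric vector congruent to `x` modulo `2*pi`, in `(-pi, pi]`.
#' @examples
#' wrap_angle(2 * pi)      # 0
#' wrap_angle(-3 * pi / 2) # pi/2
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("wrap_angle(): angles must be finite numeric values", call. = FALSE)
  w <- x - 2 * pi * floor(x / (2 * pi)) # [0, 2*pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Degree/radian conversion
#'
#' Helpers used at the I/O boundary; degree output is wrapped to `(-180, 180]`.
#' @param deg,rad angles in degrees / radians.
#' @return converted angles.
#' @export
deg2rad <- function(deg) deg * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(rad) rad * 180 / pi

#' Wrap an angular difference in degrees to (-180, 180]
#'
#' Degree-native (no radian round trip), so exact bin-edge values such as
#' -175 stay exact.
#' @param deg angle(s) in degrees.
#' @return wrapped degrees.
#' @export
wrap_deg <- function(deg) {
  w <- deg %% 360
  ifelse(w > 180, w - 360, w)
}

#' von Mises probability density
#'
#' Density of the von Mises distribution
#' `f(x; mu, kappa) = exp(kappa * cos(x - mu)) / (2 * pi * I0(kappa))`,
#' the circular analogue of the normal distribution; `kappa` plays the role of
#' an inverse variance and is the "reliability" of a directional cue.
#' Evaluated with exponentially scaled Bessel functions so large `kappa`
#' does not overflow.
#'
#' @param x numeric vector of angles (radians).
#' @param mu mean direction (radians).
#' @param kappa concentration, `>= 0`. `kappa = 0` gives the circular uniform
#'   density `1/(2*pi)`.
#' @return densities, same length as `x`.
#' @export
von_mises_pdf <- function(x, mu = 0, kappa = 1) {
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 0)
    stop("von_mises_pdf(): kappa must be a single finite value >= 0",
         call. = FALSE)
  exp(kappa * (cos(x - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Draws `n` angles using the Best-Fisher (1979) wrapped-Cauchy rejection
#' scheme, vectorised over rejections. Uses R's global RNG stream, so results
#' are reproducible under `set.seed()`. `kappa = 0` falls back to uniform
#' sampling on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, `>= 0`.
#' @return `n` angles in `(-pi, pi]`.
#' @examples
#' set.seed(1)
#' th <- sample_von_mises(1000, mu = pi / 4, kappa = 2)
#' mean_resultant(th)$R # close to besselI(2,1)/besselI(2,0) ~ 0.698
#' @export
sample_von_mises <- function(n, mu = 0, kappa = 1) {
  if (length(n) != 1L || n < 1) stop("sample_von_mises(): n must be >= 1",
                                     call. = FALSE)
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 0)
    stop("sample_von_mises(): kappa must be a single finite value >= 0",
         call. = FALSE)
  n <- as.integer(n)
  # below ~1e-6 the rejection constants degenerate numerically and the
  # distribution is uniform to within total variation ~kappa anyway
  if (kappa < 1e-6) return(wrap_angle(stats::runif(n, -pi, pi)))

  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)

  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    if (any(ok)) {
      u3 <- stats::runif(sum(ok))
      out[need[ok]] <- sign(u3 - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      need <- need[!ok]
    }
  }
  wrap_angle(out + mu)
}

#' Resultant-vector summary of circular data
#'
#' Computes the mean resultant vector of a set of angles: its direction (the
#' circular mean), its length `R` in `[0, 1]` (1 = all angles identical,
#' 0 = perfectly balanced), and the circular standard deviation
#' `sqrt(-2 * log(R))`. `R` is the precision statistic used throughout the
#' exit-angle analyses.
#'
#' @param angles numeric vector of angles (radians), length `>= 1`.
#' @return object of class `resultant_summary`: list with `mean_angle`
#'   (radians, `(-pi, pi]`), `R`, `n`, and `circ_sd` (radians; `Inf`, flagged
#'   via `undefined_sd`, when `R` is numerically 0).
#' @export
mean_resultant <- function(angles) {
  if (length(angles) < 1L)
    stop("mean_resultant(): need at least one angle", call. = FALSE)
  if (anyNA(angles) || any(!is.finite(angles)))
    stop("mean_resultant(): angles must be finite", call. = FALSE)
  n <- length(angles)
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  R <- min(sqrt(C^2 + S^2), 1)
  undefined <- R < .Machine$double.eps
  structure(
    list(mean_angle = if (undefined) NA_real_ else wrap_angle(atan2(S, C)),
         R = R, n = n,
         circ_sd = if (undefined) Inf else sqrt(-2 * log(max(R, .Machine$double.xmin))),
         undefined_sd = undefined),
    class = "resultant_summary")
}

#' @export
print.resultant_summary <- function(x, ...) {
  cat(sprintf("Resultant summary: n = %d, R = %.4f, mean = %.1f deg, circ SD = %.1f deg\n",
              x$n, x$R,
              if (is.na(x$mean_angle)) NA else rad2deg(x$mean_angle),
              rad2deg(x$circ_sd)))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniform on the circle against a
#' unimodal alternative, using `Z = n * R^2`. The p-value uses the standard
#' large-sample series refinement
#' `p = exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)]`,
#' clamped into `(0, 1]` (the series can dip microscopically below zero for
#' large `Z`). A significant result indicates a directed sample; in the
#' menotaxis analyses a *non*-significant population of mean bearings is the
#' menotactic signature.
#'
#' @param angles numeric vector of angles (radians), `n >= 2`.
#' @return object of class `htest` with `statistic` (Z), `p.value`,
#'   `estimate` (R) and `parameter` (n).
#' @export
rayleigh_test <- function(angles) {
  if (length(angles) < 2L)
    stop("rayleigh_test(): need at least two angles", call. = FALSE)
  rs <- mean_resultant(angles)
  n <- rs$n
  Z <- n * rs$R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 1e-300), 1)
  structure(
    list(statistic = c(Z = Z), p.value = p,
         estimate = c(R = rs$R), parameter = c(n = n),
         method = "Rayleigh test of circular uniformity",
         data.name = deparse(substitute(angles))),
    class = "htest")
}

#' Fisher's approximation of the von Mises concentration
#'
#' Estimates the concentration `kappa` from a mean vector length `R` by the
#' three-branch approximation (Fisher 1993):
#' \itemize{
#'   \item `R < 0.53`: `2R + R^3 + (5/6) R^5`
#'   \item `R >= 0.85`: `1 / (2(1-R) - (1-R)^2 - (1-R)^3)`
#'   \item otherwise: `-0.4 + 1.39 R + 0.43 / (1 - R)`
#' }
#' The middle branch is sometimes misprinted as a product `0.43 * (1 - R)`;
#' that rendering is non-monotone and disagrees grossly with the maximum
#' likelihood inversion, but is available for audit via
#' `literal_third_branch = TRUE`.
#'
#' @param R mean vector length(s) in `[0, 1)`.
#' @param literal_third_branch if `TRUE`, use the misprinted
#'   `0.43 * (1 - R)` product in the middle branch (audit only).
#' @return estimated concentration(s) `>= 0`.
#' @seealso [kappa_ml()] for the maximum-likelihood inversion it approximates.
#' @export
kappa_fisher <- function(R, literal_third_branch = FALSE) {
  if (anyNA(R) || any(R < 0) || any(R >= 1))
    stop("kappa_fisher(): R must lie in [0, 1)", call. = FALSE)
  mid <- if (literal_third_branch)
    -0.4 + 1.39 * R + 0.43 * (1 - R)
  else
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  k <- ifelse(R < 0.53,
              2 * R + R^3 + (5 / 6) * R^5,
              ifelse(R >= 0.85,
                     1 / (2 * (1 - R) - (1 - R)^2 - (1 - R)^3),
                     mid))
  pmax(k, 0)
}

#' Maximum-likelihood concentration from a mean vector length
#'
#' Inverts `A(kappa) = I1(kappa)/I0(kappa) = R` by bracketed root finding
#' (tolerance `1e-10`). Serves as the exact oracle against which
#' [kappa_fisher()] is validated; the approximation is preferred in the hot
#' simulation path because it is branch-free and fast.
#'
#' @param R mean vector length(s) in `[0, 1)`.
#' @param tol root-finding tolerance.
#' @return concentration(s).
#' @export
kappa_ml <- function(R, tol = 1e-10) {
  if (anyNA(R) || any(R < 0) || any(R >= 1))
    stop("kappa_ml(): R must lie in [0, 1)", call. = FALSE)
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  one <- function(r) {
    if (r < 1e-12) return(0)
    upper <- max(2, 2 / (1 - r))
    while (A(upper) < r) upper <- upper * 2
    stats::uniroot(function(k) A(k) - r, c(1e-12, upper), tol = tol)$root
  }
  vapply(R, one, numeric(1))
}
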