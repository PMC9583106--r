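test_that("normalized weights and sigmoid adjustment", {
  expect_equal(normalized_weights(2, 2), c(w_wind = 0.5, w_light = 0.5))
  w <- normalized_weights(2.05, 2)
  expect_equal(unname(w), c(0.50617284, 0.49382716), tolerance = 1e-7)
  expect_equal(unname(normalized_weights(3, 0)), c(1, 0))
  expect_error(normalized_weights(0, 0), "zero")

  expect_equal(sigmoid_adjust(0.5, 53), 0.5)
  expect_equal(sigmoid_adjust(0.6, 53), 0.99503320, tolerance = 1e-7)
  x <- seq(-0.2, 1.2, by = 0.05)
  expect_equal(sigmoid_adjust(x, 53) + sigmoid_adjust(1 - x, 53),
               rep(1, length(x)), tolerance = 1e-12)
  expect_true(all(diff(sigmoid_adjust(x, 53)) > 0))
  expect_error(sigmoid_adjust(0.5, a = -1), "a must")
})

test_that("winner-take-all picks the heavier cue and breaks ties fairly", {
  w <- cue_belief(1.0, 3); l <- cue_belief(-1.0, 2)
  expect_equal(integrate_wta(w, l), 1.0)
  expect_equal(integrate_wta(cue_belief(1, 1), cue_belief(-1, 2)), -1)

  set.seed(7)
  picks <- replicate(4000, integrate_wta(cue_belief(1, 2), cue_belief(-1, 2)))
  expect_equal(mean(picks == 1), 0.5, tolerance = 0.03)
})

test_that("WAM is a raw linear average with the documented circular pathology", {
  eq <- function(a, b) list(cue_belief(deg2rad(a), 1), cue_belief(deg2rad(b), 1))
  b <- eq(0, 120)
  expect_equal(rad2deg(integrate_wam(b[[1]], b[[2]])), 60, tolerance = 1e-9)
  # weights 2/3 vs 1/3 on 0 and 90 degrees
  expect_equal(rad2deg(integrate_wam(cue_belief(0, 2),
                                     cue_belief(deg2rad(90), 1))),
               30, tolerance = 1e-9)
  # the 0-vs-360 pathology, expressed in the canonical (-180, 180] frame:
  # headings just either side of the cut average to ~0 instead of ~180
  p <- eq(170, -170)
  expect_equal(rad2deg(integrate_wam(p[[1]], p[[2]])), 0, tolerance = 1e-9)
  # hence WAM is not rotation-equivariant
  d <- deg2rad(30)
  r <- eq(170 + 30 - 360, -170 + 30) # same inputs rotated then wrapped
  expect_false(isTRUE(all.equal(
    wrap_angle(integrate_wam(r[[1]], r[[2]]) - d),
    integrate_wam(p[[1]], p[[2]]))))
})

test_that("WVS is the polar vector sum", {
  # equal weights bisect any separation exactly
  for (sep in c(10, 60, 120, 179)) {
    w <- cue_belief(0, 2); l <- cue_belief(deg2rad(sep), 2)
    expect_equal(rad2deg(integrate_wvs(w, l)), sep / 2, tolerance = 1e-10)
  }
  # dominance limit
  expect_equal(integrate_wvs(cue_belief(0.5, 1), cue_belief(-2, 1),
                             weights = c(1, 0)), 0.5)
  expect_equal(integrate_wvs(cue_belief(0.5, 1), cue_belief(-2, 1),
                             weights = c(0.999999, 0.000001)),
               0.5, tolerance = 1e-4)
  # illustration values: kappa_wind = 2.05, kappa_light = 2, 120-deg conflict
  out <- integrate_wvs(cue_belief(deg2rad(120), 2.05), cue_belief(0, 2))
  expect_equal(rad2deg(out), 61.22498864, tolerance = 1e-6)
  # equals the explicit vector sum of (theta, W) polar vectors
  w <- normalized_weights(2.05, 2)
  vx <- w[["w_wind"]] * cos(deg2rad(120)) + w[["w_light"]] * 1
  vy <- w[["w_wind"]] * sin(deg2rad(120))
  expect_equal(out, atan2(vy, vx), tolerance = 1e-12)
  # degenerate antipodal equal-weight case resolves to theta_wind
  expect_equal(integrate_wvs(cue_belief(0, 1), cue_belief(pi, 1)), 0)
})

test_that("WVS matches WAM at small conflicts and WTA at large weight ratios", {
  # small conflict, unequal weights: agreement to o(delta)
  w <- cue_belief(0, 2); l <- cue_belief(deg2rad(5), 1)
  expect_equal(rad2deg(integrate_wvs(w, l)), rad2deg(integrate_wam(w, l)),
               tolerance = 0.01)
  # large ratio, large conflict: near the dominant cue
  w2 <- cue_belief(0, 50); l2 <- cue_belief(deg2rad(120), 1)
  expect_lt(abs(rad2deg(integrate_wvs(w2, l2))), 2)
})

test_that("NVS reduces to WVS at parity and to WTA as a grows", {
  w <- cue_belief(deg2rad(40), 2); l <- cue_belief(deg2rad(-30), 2)
  expect_equal(integrate_nvs(w, l, a = 53), integrate_wvs(w, l),
               tolerance = 1e-12)

  # kappa ratio 1.5 (adjusted weight ratio ~200:1): within 1 degree of the
  # stronger cue even at a 120-degree conflict
  w3 <- cue_belief(0, 3); l3 <- cue_belief(deg2rad(120), 2)
  expect_lt(abs(rad2deg(integrate_nvs(w3, l3, a = 53))), 1)
  # kappa ratio 1.2 gives a ~4.7 degree pull, not <1 (g ratio ~11:1)
  w4 <- cue_belief(0, 2.4); l4 <- cue_belief(deg2rad(120), 2)
  expect_equal(abs(rad2deg(integrate_nvs(w4, l4, a = 53))), 4.66,
               tolerance = 0.05)

  # a -> infinity: winner-take-all on non-tied inputs
  set.seed(3)
  for (i in 1:25) {
    kw <- stats::runif(1, 0.5, 5); kl <- stats::runif(1, 0.5, 5)
    if (abs(kw - kl) < 0.05) next
    tw <- stats::runif(1, -pi, pi); tl <- stats::runif(1, -pi, pi)
    wb <- cue_belief(tw, kw); lb <- cue_belief(tl, kl)
    expect_equal(integrate_nvs(wb, lb, a = 1e4), integrate_wta(wb, lb),
                 tolerance = 1e-6)
  }
  # a -> 0+: adjusted weights flatten toward parity, i.e. the equal-weight sum
  wb <- cue_belief(0, 4); lb <- cue_belief(deg2rad(100), 1)
  expect_equal(integrate_nvs(wb, lb, a = 1e-8),
               integrate_wvs(wb, lb, weights = c(0.5, 0.5)),
               tolerance = 1e-6)
})

test_that("BVS bias shifts weight between the cues", {
  w <- cue_belief(deg2rad(35), 2.2); l <- cue_belief(deg2rad(-80), 1.7)
  expect_equal(integrate_bvs(w, l, a = 53, bias_b = 0),
               integrate_nvs(w, l, a = 53), tolerance = 1e-12)

  # equal kappas, positive bias pulls toward the light cue
  we <- cue_belief(0, 2); le <- cue_belief(deg2rad(90), 2)
  mid <- rad2deg(integrate_bvs(we, le, bias_b = 0))
  plus <- rad2deg(integrate_bvs(we, le, bias_b = 0.05))
  minus <- rad2deg(integrate_bvs(we, le, bias_b = -0.05))
  expect_equal(mid, 45, tolerance = 1e-9)
  expect_gt(plus, 60)
  expect_lt(minus, 30)
})

test_that("all integrators are rotation-equivariant except WAM, and exact at
           zero conflict", {
  set.seed(17)
  for (i in 1:15) {
    kw <- stats::runif(1, 0.5, 5); kl <- stats::runif(1, 0.5, 5)
    tw <- stats::runif(1, -pi, pi); tl <- stats::runif(1, -pi, pi)
    delta <- stats::runif(1, -pi, pi)
    b <- stats::rnorm(1, 0, 0.0174)
    for (m in c("WVS", "NVS", "BVS")) {
      base <- integrate_cues(m, cue_belief(tw, kw), cue_belief(tl, kl),
                             bias_b = b)
      rot <- integrate_cues(m, cue_belief(wrap_angle(tw + delta), kw),
                            cue_belief(wrap_angle(tl + delta), kl),
                            bias_b = b)
      expect_equal(wrap_angle(rot - delta - base), 0, tolerance = 1e-9)
    }
    if (abs(kw - kl) > 1e-6) {
      base <- integrate_wta(cue_belief(tw, kw), cue_belief(tl, kl))
      rot <- integrate_wta(cue_belief(wrap_angle(tw + delta), kw),
                           cue_belief(wrap_angle(tl + delta), kl))
      expect_equal(wrap_angle(rot - delta - base), 0, tolerance = 1e-9)
    }
    # zero conflict: every model returns the common direction exactly
    for (m in c("WTA", "WAM", "WVS", "NVS", "BVS"))
      expect_equal(integrate_cues(m, cue_belief(tw, kw), cue_belief(tw, kl),
                                  bias_b = b), tw, tolerance = 1e-12)
  }
})

test_that("model_config validates names and parameter counts", {
  expect_equal(model_config("BVS")$n_params, 2L)
  expect_equal(model_config("NVS")$n_params, 1L)
  expect_equal(model_config("WVS")$n_params, 0L)
  expect_equal(model_config("BVS")$sigma_bias^2, 0.000303, tolerance = 1e-12)
  expect_error(model_config("XYZ"))
})
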