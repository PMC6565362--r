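# Tuning characterization and ideal-observer analyses: preferred
# directions, congruent/opposite/intermediate structure, ROC statistics,
# cumulative-Gaussian fits, combined thresholds and the decision boundary.

test_that("preferred direction is the rate-weighted circular mean", {
  probes <- seq(-160, 180, by = 20)
  curve <- exp(2 * cos(pi / 180 * (probes - 60)))
  expect_equal(preferred_direction(curve, probes), 60, tolerance = 1e-9)
  # skewed synthetic curve against the brute-force complex sum
  skew <- curve + 0.3 * exp(1.5 * cos(pi / 180 * (probes + 40)))
  v <- sum(skew * exp(1i * pi / 180 * probes))
  expect_equal(preferred_direction(skew, probes), Arg(v) * 180 / pi,
               tolerance = 1e-10)
  expect_error(preferred_direction(rep(2, length(probes)), probes),
               "undefined")
})

test_that("congruent and opposite neurons have 0 and 180 degree offsets", {
  p <- fixture_params()
  probes <- seq(-150, 180, by = 30)
  s1 <- tuning_sweep(p, probes, "cue1", alpha1 = 0.8, alpha2 = 0.8,
                     duration = 15, burn_in = 15, seed = 61)
  s2 <- tuning_sweep(p, probes, "cue2", alpha1 = 0.8, alpha2 = 0.8,
                     duration = 15, burn_in = 15, seed = 62)
  neuron <- which.min(abs(theta_grid(p) + 90))
  # congruent neuron prefers the same direction under either cue
  pc1 <- preferred_direction(tuning_curve(s1, "m1c", neuron))
  pc2 <- preferred_direction(tuning_curve(s2, "m1c", neuron))
  expect_lt(abs(wrap_angle(pc1 - pc2)), 15)
  expect_lt(abs(wrap_angle(pc1 - (-90))), 15)
  # opposite neuron shifts by half the period
  po1 <- preferred_direction(tuning_curve(s1, "m1o", neuron))
  po2 <- preferred_direction(tuning_curve(s2, "m1o", neuron))
  expect_lt(abs(abs(wrap_angle(po1 - po2)) - 180), 15)
})

test_that("zero-disparity combined cues enhance congruent and suppress opposite cells", {
  p <- fixture_params()
  probes <- seq(-150, 180, by = 30)
  args <- list(p = p, probes = probes, alpha1 = 0.5, alpha2 = 0.5,
               duration = 15, burn_in = 15)
  s1 <- do.call(tuning_sweep, c(args, list(condition = "cue1", seed = 63)))
  s2 <- do.call(tuning_sweep, c(args, list(condition = "cue2", seed = 64)))
  sb <- do.call(tuning_sweep, c(args, list(condition = "both", seed = 65)))
  neuron <- which.min(abs(theta_grid(p) + 90))
  peak <- function(sw, gr) max(sw$rates[neuron, , gr])
  expect_gt(peak(sb, "m1c"), max(peak(s1, "m1c"), peak(s2, "m1c")))
  expect_lt(peak(sb, "m1o"), peak(s1, "m1o"))  # direct cue is cue 1
})

test_that("preferred-direction differences split congruent from opposite", {
  p <- fixture_params()
  h <- pref_diff_histogram(p, probes = seq(-120, 180, by = 60),
                           alpha = 0.8, duration = 12, burn_in = 12,
                           seed = 66)
  cong <- h$diff[h$group == "m1c"]
  oppo <- h$diff[h$group == "m1o"]
  expect_true(all(cong < 30))
  expect_true(all(oppo > 150))
  # with jitter on, intermediate neurons appear
  pj <- fixture_params(jitter = list(on = TRUE, scale = 0.9, seed = 5L))
  hj <- pref_diff_histogram(pj, probes = seq(-120, 180, by = 60),
                            alpha = 0.8, duration = 12, burn_in = 12,
                            seed = 66)
  expect_gt(sum(hj$diff > 30 & hj$diff < 150), 0)
  expect_gt(hj$counts[["intermediate"]] + hj$counts[["congruent"]] +
              hj$counts[["opposite"]], 0)
})

test_that("ROC fraction matches the closed-form Gaussian oracle", {
  expect_equal(roc_fraction(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_fraction(c(5, 6, 7), c(1, 2, 3)), 1)
  # hand-counted pairs: (1,1)=.5 (1,2)=0 (1,3)=0 (2,1)=1 (2,2)=.5 (2,3)=0
  expect_equal(roc_fraction(c(1, 2), c(1, 2, 3)), 2 / 6)
  # closed form: AUC of two unit-variance Gaussians d' apart = Phi(d'/sqrt(2))
  set.seed(71)
  for (dprime in c(0.5, 1, 2)) {
    a <- rnorm(3000, dprime); b <- rnorm(3000)
    expect_equal(roc_fraction(a, b), pnorm(dprime / sqrt(2)),
                 tolerance = 0.03)
  }
})

test_that("cumulative-Gaussian fit recovers parameters", {
  x <- seq(-32, 32, by = 4)
  fit <- fit_neurometric(x, pnorm(x / 5))
  expect_equal(unname(coef(fit)["sigma"]), 5, tolerance = 1e-5)
  expect_equal(unname(coef(fit)["mu"]), 0, tolerance = 1e-4)
  expect_equal(fit$threshold, unname(coef(fit)["sigma"]))
  expect_equal(predict(fit, 0), pnorm(0, coef(fit)["mu"], coef(fit)["sigma"]),
               ignore_attr = TRUE)
  # flat fractions are flagged as unidentifiable
  flat <- fit_neurometric(x, rep(0.5, length(x)))
  expect_true(any(grepl("unidentifiable", flat$flag)))
  # noisy recovery across replicates stays centered on the true sigma
  set.seed(72)
  sig_hat <- replicate(60, {
    fr <- pnorm(x / 8) + rnorm(length(x), 0, 0.03)
    fit_neurometric(x, pmin(pmax(fr, 0), 1))$threshold
  })
  expect_equal(mean(sig_hat), 8, tolerance = 0.15)
})

test_that("combined-threshold prediction follows the optimal-combination rule", {
  expect_equal(predict_combined_threshold(1, 1), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(predict_combined_threshold(3, 4), 2.4, tolerance = 1e-12)
  expect_equal(predict_combined_threshold(2, 1e9), 2, tolerance = 1e-6)
  expect_lte(predict_combined_threshold(3, 4), 3)
  expect_error(predict_combined_threshold(0, 1), "sigma")
})

test_that("decision boundary interpolates the weighted crossing", {
  d <- seq(10, 170, by = 10)
  rc <- cos(pi * d / 360)^2
  ro <- sin(pi * d / 360)^2
  expect_equal(decision_boundary(d, rc, ro), 90, tolerance = 1e-9)
  expect_gt(decision_boundary(d, rc, ro, w_cong = 2, w_oppo = 1), 90)
  expect_lt(decision_boundary(d, rc, ro, w_cong = 1, w_oppo = 2), 90)
  expect_error(decision_boundary(d, rc + 2, ro), "no crossing")
})

test_that("rate-disparity curves are complementary and opposite neurons discriminate finer", {
  p <- fixture_params()
  neuron <- which.min(abs(theta_grid(p) - 90))
  tt <- disparity_trials(p, disparities = seq(-32, 32, by = 8),
                         n_trials = 10, alpha1 = 0.25, alpha2 = 0.8,
                         neurons = neuron, duration = 10, burn_in = 12,
                         seed = 81)
  # opposite rates vary with disparity much more than congruent rates
  slope <- function(gr) {
    d <- tt[tt$group == gr, ]
    coef(lm(rate ~ disparity, d))[2]
  }
  expect_gt(abs(slope("m1o")), 2 * abs(slope("m1c")))
  fo <- neurometric_from_trials(tt, neuron, "m1o")
  fc <- neurometric_from_trials(tt, neuron, "m1c")
  expect_lt(fo$threshold, fc$threshold)
  # neurometric points are anti-symmetric about 0.5 by construction
  pts <- fo$points
  expect_equal(pts$fraction[pts$disparity == 8] +
                 pts$fraction[pts$disparity == -8], 1, tolerance = 1e-12)
})

test_that("combined-cue heading threshold improves on single cues", {
  cfg <- fixture_config("heading_roc")
  res <- run_experiment(cfg)
  thr <- res$thresholds
  cong <- thr[thr$group == "m1c", ]
  s1 <- cong$threshold[cong$condition == "cue1"]
  s2 <- cong$threshold[cong$condition == "cue2"]
  sb <- cong$threshold[cong$condition == "both"]
  expect_lte(sb, min(s1, s2) * 1.15)   # at worst marginally above
  pred <- res$combined_prediction
  expect_equal(pred$measured[pred$group == "m1c"],
               pred$predicted[pred$group == "m1c"], tolerance = 0.6)
})
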