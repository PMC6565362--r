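# Single-neuron characterization and ideal-observer analyses: tuning
# curves under the three cueing conditions, preferred directions and the
# congruent/intermediate/opposite histogram, trial-rate tables across cue
# disparities, ROC fractions, cumulative-Gaussian neurometric fits
# (classic least-squares model objects), combined-threshold prediction and
# the integration-vs-segregation decision boundary.

#' Tuning curves from probe-direction sweeps
#'
#' Sweeps the cue direction(s) over a probe grid and, for each probe, runs
#' one long trial and time-averages the equilibrium rates, yielding the
#' tuning curve of every neuron simultaneously. Conditions: \code{"cue1"}
#' or \code{"cue2"} sweep a single cue; \code{"both"} sweeps both cues at
#' the same direction (zero disparity).
#'
#' @param p a \code{\link{cann_params}}.
#' @param probes probe directions in degrees (default the neuron grid
#'   coarsened to 20-degree steps).
#' @param condition cueing condition.
#' @param alpha1,alpha2 cue intensities (U0 units).
#' @param duration,burn_in sampled epoch and transient per probe (tau).
#' @param seed integer; probe k uses seed \code{seed + k}.
#' @return object of class \code{"tuning_sweep"}: \code{rates} and
#'   \code{sd}, arrays \code{N x length(probes) x 4} (neuron, probe,
#'   group), plus \code{probes}, \code{theta}, \code{condition}.
#' @export
tuning_sweep <- function(p, probes = seq(-160, 180, by = 20),
                         condition = c("cue1", "cue2", "both"),
                         alpha1 = 0.35, alpha2 = 0.35,
                         duration = 50, burn_in = 30, seed = 1L) {
  condition <- match.arg(condition)
  probes <- wrap_angle(probes)
  rates <- array(NA_real_, c(p$N, length(probes), 4),
                 dimnames = list(NULL, NULL, .GROUPS))
  sds <- rates
  for (k in seq_along(probes)) {
    cues <- switch(condition,
      cue1 = list(cue_stimulus(probes[k], alpha1, 1)),
      cue2 = list(cue_stimulus(probes[k], alpha2, 2)),
      both = list(cue_stimulus(probes[k], alpha1, 1),
                  cue_stimulus(probes[k], alpha2, 2)))
    tr <- simulate_cann(p, cues, duration = duration, burn_in = burn_in,
                        seed = seed + k)
    rates[, k, ] <- tr$rate_mean
    sds[, k, ] <- tr$rate_sd
  }
  structure(list(rates = rates, sd = sds, probes = probes,
                 theta = theta_grid(p), condition = condition,
                 params = p, seed = seed),
            class = "tuning_sweep")
}

#' Extract one neuron's tuning curve from a sweep
#'
#' @param sweep a \code{\link{tuning_sweep}}.
#' @param group group name ("m1c", "m1o", "m2c", "m2o").
#' @param neuron neuron index (position on \code{\link{theta_grid}}).
#' @return object of class \code{"tuning_curve"} with \code{probe},
#'   \code{rate}, \code{sd}, and metadata.
#' @export
tuning_curve <- function(sweep, group, neuron) {
  stopifnot(inherits(sweep, "tuning_sweep"), group %in% .GROUPS)
  structure(list(probe = sweep$probes,
                 rate = sweep$rates[neuron, , group],
                 sd = sweep$sd[neuron, , group],
                 neuron = neuron, group = group,
                 pref_grid = sweep$theta[neuron],
                 condition = sweep$condition),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("tuning curve: neuron %d (%s, grid %g deg), condition %s, %d probes\n",
              x$neuron, x$group, x$pref_grid, x$condition, length(x$probe)))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  o <- order(x$probe)
  graphics::plot(x$probe[o], x$rate[o], type = "b", pch = 16,
                 xlab = "cue direction (deg)", ylab = "mean rate (Hz)", ...)
  graphics::arrows(x$probe[o], x$rate[o] - x$sd[o], x$probe[o],
                   x$rate[o] + x$sd[o], angle = 90, code = 3, length = 0.02,
                   col = "grey50")
  invisible(x)
}

#' Preferred direction of a tuning curve
#'
#' Circular mean of the probe angles weighted by firing rate (the
#' population vector of the tuning curve).
#'
#' @param curve a \code{\link{tuning_curve}}, or a rate vector with probe
#'   angles in \code{probes}.
#' @param probes probe angles when \code{curve} is a bare vector.
#' @return preferred direction in degrees.
#' @export
preferred_direction <- function(curve, probes = NULL) {
  if (inherits(curve, "tuning_curve")) {
    rates <- curve$rate; probes <- curve$probe
  } else rates <- curve
  population_vector(rates, probes)
}

#' Cross-cue preferred-direction differences
#'
#' Runs single-cue tuning sweeps under cue 1 and cue 2 and returns, for
#' every neuron of the requested module, the absolute circular difference
#' between its two preferred directions. With perfect reciprocal wiring the
#' differences concentrate at 0 (congruent group) and 180 degrees (opposite
#' group); with jitter on, intermediate neurons appear in between. The
#' classification bands (congruent < 60, intermediate 60-120, opposite
#' > 120 degrees) are a reporting convention only; the raw differences are
#' always returned.
#'
#' @param p a \code{\link{cann_params}} (set \code{jitter$on = TRUE} to
#'   model imperfect reciprocal connectivity).
#' @param module module to characterize (1 or 2).
#' @param probes,alpha,duration,burn_in,seed sweep settings (see
#'   \code{\link{tuning_sweep}}).
#' @return object of class \code{"pref_diff"}: \code{diff} (absolute
#'   differences in [0, 180], one per neuron, congruent then opposite
#'   group), \code{group}, and the band \code{counts}.
#' @export
pref_diff_histogram <- function(p, module = 1,
                                probes = seq(-150, 180, by = 30),
                                alpha = 0.8, duration = 50, burn_in = 30,
                                seed = 1L) {
  s1 <- tuning_sweep(p, probes, "cue1", alpha1 = alpha, alpha2 = alpha,
                     duration = duration, burn_in = burn_in, seed = seed)
  s2 <- tuning_sweep(p, probes, "cue2", alpha1 = alpha, alpha2 = alpha,
                     duration = duration, burn_in = burn_in,
                     seed = seed + 1000L)
  grs <- if (module == 1) c("m1c", "m1o") else c("m2c", "m2o")
  dd <- unlist(lapply(grs, function(gr) {
    vapply(seq_len(p$N), function(j) {
      p1 <- preferred_direction(s1$rates[j, , gr], probes)
      p2 <- preferred_direction(s2$rates[j, , gr], probes)
      abs(wrap_angle(p1 - p2))
    }, numeric(1))
  }))
  counts <- c(congruent = sum(dd < 60), intermediate = sum(dd >= 60 & dd <= 120),
              opposite = sum(dd > 120))
  structure(list(diff = dd, group = rep(grs, each = p$N), counts = counts,
                 module = module),
            class = "pref_diff")
}

#' @export
print.pref_diff <- function(x, ...) {
  cat(sprintf("preferred-direction differences, module %d (%d neurons)\n",
              x$module, length(x$diff)))
  print(x$counts)
  invisible(x)
}

#' @export
plot.pref_diff <- function(x, ...) {
  graphics::hist(x$diff, breaks = seq(0, 180, by = 15),
                 xlab = "|preferred direction difference| (deg)",
                 main = sprintf("module %d", x$module), ...)
  invisible(x)
}

#' Trial firing rates across cue disparities
#'
#' The cue-disparity discrimination protocol: the mean of the two cues is
#' fixed at 0 (\code{x1 + x2 = 0}) while the disparity \code{x1 - x2}
#' sweeps a symmetric grid (default -32 to 32 degrees in steps of 4). For
#' each disparity, \code{n_trials} independent trials are run and each
#' neuron's time-averaged equilibrium rate recorded.
#'
#' @param p a \code{\link{cann_params}}.
#' @param disparities disparity grid (degrees), symmetric about 0.
#' @param n_trials trials per disparity (default 30).
#' @param alpha1,alpha2 cue intensities (U0 units).
#' @param neurons neuron indices to record (default all).
#' @param condition cueing condition: \code{"both"} (default) presents the
#'   two cues at \code{x1 = d/2}, \code{x2 = -d/2}; \code{"cue1"} /
#'   \code{"cue2"} present a single cue at its respective direction.
#' @param duration,burn_in per-trial epoch (tau).
#' @param seed base seed; trial t of disparity k uses
#'   \code{seed + 1000 k + t}.
#' @return data.frame with columns \code{disparity}, \code{trial},
#'   \code{neuron}, \code{group}, \code{rate}.
#' @export
disparity_trials <- function(p, disparities = seq(-32, 32, by = 4),
                             n_trials = 30, alpha1 = 0.25, alpha2 = 0.8,
                             neurons = seq_len(p$N),
                             condition = c("both", "cue1", "cue2"),
                             duration = 20, burn_in = 20, seed = 1L) {
  condition <- match.arg(condition)
  if (max(abs(wrap_angle(disparities) + wrap_angle(rev(disparities)))) > 1e-9)
    stop("disparity grid must be symmetric about 0")
  out <- vector("list", length(disparities) * n_trials)
  i <- 0
  for (k in seq_along(disparities)) {
    d <- disparities[k]
    x1 <- d / 2; x2 <- -d / 2
    cues <- switch(condition,
      both = list(cue_stimulus(x1, alpha1, 1), cue_stimulus(x2, alpha2, 2)),
      cue1 = list(cue_stimulus(x1, alpha1, 1)),
      cue2 = list(cue_stimulus(x2, alpha2, 2)))
    for (t in seq_len(n_trials)) {
      tr <- simulate_cann(p, cues, duration = duration, burn_in = burn_in,
                          seed = seed + 1000L * k + t)
      i <- i + 1
      out[[i]] <- data.frame(disparity = d, trial = t,
                             neuron = rep(neurons, times = 4),
                             group = rep(.GROUPS, each = length(neurons)),
                             rate = c(tr$rate_mean[neurons, ]))
    }
  }
  do.call(rbind, out)
}

#' ROC fraction for two trial-rate distributions
#'
#' Area under the ROC curve of the two empirical distributions: the
#' probability that a draw from \code{dist_a} exceeds a draw from
#' \code{dist_b}, ties counted half. Used as the fraction of correct
#' discriminations by an ideal observer of a single neuron.
#'
#' @param dist_a,dist_b numeric trial rates, at least 2 each.
#' @return fraction in [0, 1].
#' @examples
#' roc_fraction(c(5, 6, 7), c(1, 2, 3))  # 1
#' @export
roc_fraction <- function(dist_a, dist_b) {
  if (length(dist_a) < 2 || length(dist_b) < 2)
    stop("need at least 2 trials per distribution")
  cmp <- outer(dist_a, dist_b, ">") + 0.5 * outer(dist_a, dist_b, "==")
  mean(cmp)
}

#' Fit a cumulative-Gaussian neurometric function
#'
#' Least-squares fit of \code{Phi((x - mu) / sigma)} to (stimulus, ROC
#' fraction) points; the fitted \code{sigma} is the neuronal discrimination
#' threshold. Unweighted least squares with \code{sigma > 0} enforced by an
#' exp-parameterization; multiple starting widths are tried and the best
#' residual kept. A fit is flagged unidentifiable when the fractions never
#' cross away from 0.5 (flat neurometric function).
#'
#' @param x stimulus values (e.g. cue disparities, degrees), >= 4 points
#'   spanning both sides of the 0.5 fraction.
#' @param fraction ROC fractions in [0, 1].
#' @return object of class \code{"neurometric_fit"} with \code{coefficients}
#'   (mu, sigma), \code{threshold} (= sigma), \code{fitted},
#'   \code{residuals}, \code{converged}, \code{flag}.
#' @examples
#' x <- seq(-30, 30, 5)
#' fit_neurometric(x, pnorm(x / 5))
#' @export
fit_neurometric <- function(x, fraction) {
  stopifnot(length(x) == length(fraction), length(x) >= 4)
  if (any(fraction < 0 | fraction > 1)) stop("fractions must lie in [0, 1]")
  flag <- NULL
  if (max(abs(fraction - 0.5)) < 1e-3)
    flag <- "flat neurometric function: sigma unidentifiable"
  obj <- function(par) {
    sum((fraction - stats::pnorm(x, mean = par[1], sd = exp(par[2])))^2)
  }
  span <- diff(range(x))
  best <- NULL
  for (s0 in span * c(0.05, 0.15, 0.5, 1.5)) {
    fit <- stats::optim(c(stats::median(x), log(s0)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  converged <- best$convergence == 0
  if (!converged) flag <- c(flag, "optimizer did not converge")
  mu <- best$par[1]; sigma <- exp(best$par[2])
  fitted <- stats::pnorm(x, mu, sigma)
  structure(list(coefficients = c(mu = mu, sigma = sigma),
                 threshold = sigma, fitted = fitted,
                 residuals = fraction - fitted, x = x, fraction = fraction,
                 rss = best$value, converged = converged, flag = flag),
            class = "neurometric_fit")
}

#' @export
print.neurometric_fit <- function(x, ...) {
  cat(sprintf("cumulative-Gaussian neurometric fit: mu = %.4g, sigma (threshold) = %.4g\n",
              x$coefficients["mu"], x$coefficients["sigma"]))
  if (!is.null(x$flag)) cat("  flagged:", paste(x$flag, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.neurometric_fit <- function(object, ...) object$coefficients

#' @export
predict.neurometric_fit <- function(object, newdata = object$x, ...) {
  stats::pnorm(newdata, object$coefficients["mu"], object$coefficients["sigma"])
}

#' @export
residuals.neurometric_fit <- function(object, ...) object$residuals

#' @export
plot.neurometric_fit <- function(x, ...) {
  graphics::plot(x$x, x$fraction, pch = 16,
                 xlab = "stimulus (deg)", ylab = "fraction 'x1 > x2'",
                 ylim = c(0, 1), ...)
  xx <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xx, predict(x, xx), col = "#b2182b")
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Neurometric function of one neuron from a trial table
#'
#' Builds the ROC fraction per disparity (each disparity's trial rates
#' against the pooled reference at the zero-disparity condition or the
#' mirrored condition, see \code{ref}) and fits the cumulative Gaussian.
#' For the standard construction, the fraction at disparity d is the ROC
#' value of the rates at +d against the rates at -d (the ideal observer
#' judging "x1 > x2"), which is anti-symmetric about 0.5.
#'
#' @param trials data.frame from \code{\link{disparity_trials}}.
#' @param neuron,group neuron selector.
#' @param ref reference construction: \code{"mirror"} compares +d against
#'   -d (cue-disparity task); \code{"zero"} compares each probe against the
#'   distribution at 0 (heading task; the reference distribution is the
#'   0-degree trial set).
#' @param increasing logical: TRUE when the neuron's rate increases with
#'   the discriminated variable, so larger rates vote for "larger than
#'   reference"; set FALSE for a decreasing rate-disparity curve. Default
#'   resolves by the sign of the fitted slope.
#' @return a \code{\link{fit_neurometric}} object with the points attached.
#' @export
neurometric_from_trials <- function(trials, neuron, group,
                                    ref = c("mirror", "zero"),
                                    increasing = NULL) {
  ref <- match.arg(ref)
  tt <- trials[trials$neuron == neuron & trials$group == group, ]
  ds <- sort(unique(tt$disparity))
  rate_at <- function(d) tt$rate[tt$disparity == d]
  slope <- stats::coef(stats::lm(rate ~ disparity, tt))[2]
  if (is.null(increasing)) increasing <- slope >= 0
  frac <- vapply(ds, function(d) {
    a <- rate_at(d)
    b <- if (ref == "mirror") rate_at(-d) else rate_at(0)
    f <- roc_fraction(a, b)
    if (increasing) f else 1 - f
  }, numeric(1))
  fit <- fit_neurometric(ds, frac)
  fit$points <- data.frame(disparity = ds, fraction = frac)
  fit$neuron <- neuron; fit$group <- group
  fit
}

#' Predicted combined-cue discrimination threshold
#'
#' Optimal (Gaussian) combination of two single-cue thresholds:
#' \code{sigma1 sigma2 / sqrt(sigma1^2 + sigma2^2)}, never larger than the
#' smaller of the two.
#'
#' @param sigma1,sigma2 single-cue thresholds, > 0.
#' @return predicted combined threshold.
#' @examples
#' predict_combined_threshold(3, 4)  # 2.4
#' @export
predict_combined_threshold <- function(sigma1, sigma2) {
  stopifnot(sigma1 > 0, sigma2 > 0)
  sigma1 * sigma2 / sqrt(sigma1^2 + sigma2^2)
}

#' Integration-vs-segregation decision boundary
#'
#' The disparity at which the weighted congruent-neuron rate curve crosses
#' the weighted opposite-neuron curve:
#' \code{W_cong * r_c(D) = W_oppo * r_o(D)}. With equal weights and the
#' complementary rate curves of the network this sits at 90 degrees;
#' increasing \code{W_cong / W_oppo} moves it upward. Found by linear
#' interpolation of the sign change of the weighted difference.
#'
#' @param disparity disparity grid in (0, 180), increasing.
#' @param r_c,r_o congruent (decreasing) and opposite (increasing) rate
#'   statistics on the grid.
#' @param w_cong,w_oppo readout weights.
#' @return crossing disparity in degrees.
#' @examples
#' d <- seq(10, 170, 10)
#' decision_boundary(d, cos(pi * d / 360)^2, sin(pi * d / 360)^2)  # 90
#' @export
decision_boundary <- function(disparity, r_c, r_o, w_cong = 1, w_oppo = 1) {
  stopifnot(length(disparity) == length(r_c), length(r_c) == length(r_o),
            !is.unsorted(disparity), w_cong > 0, w_oppo > 0)
  f <- w_cong * r_c - w_oppo * r_o
  s <- which(f[-length(f)] >= 0 & f[-1] < 0)
  if (!length(s)) stop("no crossing of the weighted rate curves on the grid")
  i <- s[1]
  disparity[i] + f[i] * (disparity[i + 1] - disparity[i]) / (f[i] - f[i + 1])
}
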