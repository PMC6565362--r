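# Population-vector readout and the Bayesian-optimality bookkeeping built
# on it: distribution estimates from bump-position series, vector-sum
# predictions for combined-cue estimates of congruent and opposite neurons,
# real-time recovery of the direct-cue estimate from joint activity, and a
# circular R^2 for recovery sweeps.

#' Population-vector readout of a rate profile
#'
#' Decodes the bump position as the angle of the complex sum
#' \code{arg[sum_theta r(theta) exp(i theta)]}. Equivariant: shifting the
#' profile shifts the decoded angle by the same amount.
#'
#' @param rates nonnegative firing rates over the preferred-direction grid.
#' @param theta preferred directions in degrees (defaults to a uniform grid
#'   of \code{length(rates)} angles).
#' @return decoded angle in degrees in (-180, 180].
#' @examples
#' th <- theta_grid(36)
#' population_vector(exp(3 * cos(pi / 180 * (th - 40))), th)
#' @export
population_vector <- function(rates, theta = theta_grid(length(rates))) {
  stopifnot(length(rates) == length(theta))
  if (any(rates < 0)) stop("rates must be nonnegative")
  th <- deg2rad(theta)
  cx <- sum(rates * cos(th)); sx <- sum(rates * sin(th))
  if (sqrt(cx^2 + sx^2) <= 1e-10 * max(sum(rates), 1))
    stop("population vector undefined: zero or uniform rate profile")
  wrap_angle(rad2deg(atan2(sx, cx)))
}

#' Distribution estimate from a bump-position series
#'
#' Treats the per-sample decoded positions as draws from the posterior the
#' population encodes: the circular mean over samples is the estimate's
#' mean and the sample mean resultant length maps through the inverse
#' resultant to its concentration.
#'
#' @param z_series decoded angles in degrees (NAs dropped), at least 100
#'   samples.
#' @param source optional tag (e.g. group and cue condition) carried along
#'   for bookkeeping.
#' @return object of class \code{"population_estimate"}: \code{mean},
#'   \code{kappa}, \code{n_samples}, \code{source}, \code{mu_defined}.
#' @export
estimate_distribution <- function(z_series, source = NULL) {
  z <- z_series[is.finite(z_series)]
  if (length(z) < 100) stop("need at least 100 samples")
  e <- circ_estimate(z)
  structure(list(mean = e$mu, kappa = e$kappa, n_samples = e$n,
                 mu_defined = e$mu_defined, source = source),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("population estimate%s: mean %s deg, kappa %.5g (n = %d)\n",
              if (is.null(x$source)) "" else paste0(" [", x$source, "]"),
              if (x$mu_defined) sprintf("%.3f", x$mean) else "undefined",
              x$kappa, x$n_samples))
  invisible(x)
}

as_vm <- function(e) {
  stopifnot(inherits(e, "population_estimate"))
  von_mises(if (e$mu_defined) e$mean else 0, e$kappa,
            mu_defined = e$mu_defined)
}

as_pop_estimate <- function(d, n_samples, source = NULL) {
  structure(list(mean = d$mu, kappa = d$kappa, n_samples = n_samples,
                 mu_defined = d$mu_defined, source = source),
            class = "population_estimate")
}

#' Predicted combined-cue estimate of congruent neurons
#'
#' Optimal integration predicts that the combined-cue estimate of a group
#' equals the vector sum of its two single-cue estimates:
#' \code{kappa_pred exp(i z_pred) = sum_l kappa(z|x_l) exp(i <z|x_l>)}.
#'
#' @param e1,e2 \code{\link{estimate_distribution}} results for the same
#'   group under cue 1 alone and cue 2 alone.
#' @return a \code{population_estimate} (n_samples is the minimum of the
#'   inputs').
#' @export
predict_integration <- function(e1, e2) {
  d <- vm_product(as_vm(e1), as_vm(e2))
  as_pop_estimate(d, min(e1$n_samples, e2$n_samples), "predicted integration")
}

#' Predicted combined-cue estimate of opposite neurons
#'
#' Two equivalent forms of the segregation prediction: the vector
#' difference of the congruent single-cue estimates (direct minus indirect),
#' or the vector sum of the opposite group's own single-cue estimates
#' (whose indirect-cue estimate already sits at the antipode). Both are
#' implemented; they agree identically because the opposite group's
#' indirect-cue vector is the negation of the congruent one's.
#'
#' @param e_direct,e_indirect \code{\link{estimate_distribution}} results
#'   under the direct cue alone and the indirect cue alone, from congruent
#'   neurons (\code{from = "congruent"}) or from the opposite neurons
#'   themselves (\code{from = "opposite"}).
#' @param from which single-cue estimates are supplied.
#' @return a \code{population_estimate}.
#' @export
predict_disparity <- function(e_direct, e_indirect,
                              from = c("congruent", "opposite")) {
  from <- match.arg(from)
  d <- if (from == "congruent")
    vm_ratio(as_vm(e_direct), as_vm(e_indirect))
  else
    vm_product(as_vm(e_direct), as_vm(e_indirect))
  as_pop_estimate(d, min(e_direct$n_samples, e_indirect$n_samples),
                  "predicted disparity")
}

#' Real-time recovery of the direct-cue estimate
#'
#' Under combined cues, the posterior given the direct cue alone is
#' recovered per time step from the joint activity of the congruent and
#' opposite groups of a module: each group contributes a vector whose angle
#' is its decoded bump position and whose length is its summed firing rate
#' (the summed rate encodes the concentration in a probabilistic population
#' code); the recovered estimate is the angle of the vector sum.
#'
#' @param z_c,z_o decoded positions (degrees) of the congruent and opposite
#'   group, per time step.
#' @param rsum_c,rsum_o summed firing rates of the two groups, per step.
#' @return recovered angles in degrees; NA where the two vectors cancel
#'   (undefined direction).
#' @export
recover_direct_cue <- function(z_c, rsum_c, z_o, rsum_o) {
  stopifnot(length(z_c) == length(z_o), length(z_c) == length(rsum_c),
            length(z_o) == length(rsum_o))
  zc <- deg2rad(z_c); zo <- deg2rad(z_o)
  x <- rsum_c * cos(zc) + rsum_o * cos(zo)
  y <- rsum_c * sin(zc) + rsum_o * sin(zo)
  len <- sqrt(x^2 + y^2)
  out <- wrap_angle(rad2deg(atan2(y, x)))
  out[len <= 1e-10 * pmax(rsum_c + rsum_o, 1)] <- NA_real_
  out
}

#' Coefficient of determination for recovered vs reference angles
#'
#' R^2 of recovered means against reference means across conditions, with
#' circular data handled by unwrapping: residuals about the identity line
#' are wrapped to (-180, 180], and total variation is measured after
#' centering the reference angles on their circular mean.
#'
#' @param recovered,reference angle vectors in degrees, equal length >= 3.
#' @return R^2 (can be negative for a predictor worse than the reference
#'   mean; reported as computed).
#' @export
recovery_r2 <- function(recovered, reference) {
  stopifnot(length(recovered) == length(reference), length(reference) >= 3)
  ok <- is.finite(recovered) & is.finite(reference)
  recovered <- recovered[ok]; reference <- reference[ok]
  if (length(reference) < 3) stop("fewer than 3 finite pairs")
  res <- wrap_angle(recovered - reference)
  ctr <- circ_estimate(reference)
  cen <- wrap_angle(reference - if (ctr$mu_defined) ctr$mu else 0)
  tot <- cen - mean(cen)
  1 - sum(res^2) / sum(tot^2)
}

#' Single-cue and combined-cue estimates for one condition
#'
#' Convenience wrapper running the three cueing conditions (cue 1 alone,
#' cue 2 alone, both) with a common parameter set and decoding the
#' requested group's estimates, as used by the optimality analyses.
#'
#' @param p a \code{\link{cann_params}}.
#' @param x1,x2 cue directions (degrees).
#' @param alpha1,alpha2 cue intensities in U0 units.
#' @param group which group to decode (e.g. "m1c", "m1o").
#' @param duration,burn_in,stride,seed passed to
#'   \code{\link{simulate_cann}}; the three conditions use seeds
#'   \code{seed}, \code{seed + 1}, \code{seed + 2}.
#' @return list with \code{single1}, \code{single2}, \code{combined}
#'   population estimates and the three traces (invisible in the list as
#'   \code{traces}).
#' @export
cueing_conditions <- function(p, x1, x2, alpha1, alpha2, group = "m1c",
                              duration = 150, burn_in = 50, stride = 1L,
                              seed = 1L) {
  c1 <- cue_stimulus(x1, alpha1, 1)
  c2 <- cue_stimulus(x2, alpha2, 2)
  tr1 <- simulate_cann(p, list(c1), duration, burn_in, stride, seed)
  tr2 <- simulate_cann(p, list(c2), duration, burn_in, stride, seed + 1L)
  tr12 <- simulate_cann(p, list(c1, c2), duration, burn_in, stride, seed + 2L)
  list(single1 = estimate_distribution(tr1$z[, group], paste(group, "| cue 1")),
       single2 = estimate_distribution(tr2$z[, group], paste(group, "| cue 2")),
       combined = estimate_distribution(tr12$z[, group],
                                        paste(group, "| both cues")),
       traces = list(cue1 = tr1, cue2 = tr2, both = tr12))
}
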