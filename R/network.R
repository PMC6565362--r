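# The decentralized two-module continuous attractor network: parameter
# container, connectivity kernels, feedforward drive, divisive
# normalization, and the stochastic Euler integration front end (the inner
# loop lives in src/cann.cpp; an R reference step is kept here for
# cross-checking).
#
# Group layout used throughout: columns 1..4 of N x 4 matrices are
# module 1 congruent, module 1 opposite, module 2 congruent,
# module 2 opposite ("m1c", "m1o", "m2c", "m2o").

.GROUPS <- c("m1c", "m1o", "m2c", "m2o")

# Critical recurrent strength J_c for the default geometry (N = 180, a = 3,
# omega = 3e-4, J_int = 0.5), determined by bisection on bump persistence
# after input offset (see critical_jc); frozen here so that default
# parameter sets are self-contained.
.JC_DEFAULT <- 0.014094

#' Network parameter set
#'
#' Bundles all structural constants of the two-module network. Defaults are
#' the documented operating point: \code{N = 180} neurons per group,
#' connection width \code{a = 3} (about 40-degree tuning), divisive
#' normalization \code{omega = 3e-4} with inhibition sharing
#' \code{J_int = 0.5} (these set the ~50 Hz firing-rate saturation),
#' recurrent strength \code{J_rc = 0.3 J_c} and reciprocal strength
#' \code{J_rp = 0.5 J_rc}, background input \code{I_b = 1}, Fano factor
#' \code{F = 0.5}, time constant \code{tau = 1} (dimensionless) and Euler
#' step \code{dt = 0.01 tau}.
#'
#' \code{J_c} is the minimal recurrent strength at which a module holds a
#' persistent activity bump after feedforward input is removed. It enters
#' only as the unit in which \code{J_rc} and the input scale \code{U_0} are
#' expressed. The default is the package's frozen bisection estimate for the
#' default geometry; \code{\link{critical_jc}} re-estimates it empirically
#' for any parameter set.
#'
#' Population sums in the dynamics are expressed relative to the reference
#' grid of 180 neurons (sums carry weight \code{180/N}), so the printed
#' \code{omega} and the saturation rate are preserved when \code{N} is
#' changed for faster, coarser simulations.
#'
#' @param N neurons per group, \code{>= 8}.
#' @param a connection width (von Mises concentration of all kernels).
#' @param omega divisive-normalization magnitude.
#' @param J_int inhibition-pool sharing coefficient in (0, 1].
#' @param J_rc_ratio recurrent strength as a fraction of \code{J_c}.
#' @param J_rp_ratio reciprocal strength as a fraction of \code{J_rc}; must
#'   be < 1 (reciprocal coupling is always weaker than recurrent).
#' @param J_c critical recurrent strength; default is the frozen estimate
#'   for the default geometry.
#' @param I_b background input mean.
#' @param fano Fano factor of feedforward and background noise.
#' @param tau synaptic time constant (dimensionless 1).
#' @param dt Euler step, \code{<= 0.1 tau}.
#' @param jitter reciprocal-connection randomization: a list
#'   \code{list(on = FALSE, scale = 0.9, seed = 1L)}. When on, every
#'   receiving neuron's incoming reciprocal row gains a randomly directed
#'   von Mises bump of connections with the same width as the structured
#'   kernel and amplitude \code{Uniform(0, scale)} times its peak —
#'   coherent mistargeting of the same order as the connections. This
#'   models imperfect cross-module wiring and produces intermediate
#'   neurons (cross-cue preferred-direction differences strictly between
#'   0 and 180 degrees).
#' @return an object of class \code{"cann_params"}.
#' @examples
#' p <- cann_params()
#' p$J_rc / p$J_c   # 0.3
#' @export
cann_params <- function(N = 180L, a = 3, omega = 3e-4, J_int = 0.5,
                        J_rc_ratio = 0.3, J_rp_ratio = 0.5,
                        J_c = .JC_DEFAULT, I_b = 1, fano = 0.5,
                        tau = 1, dt = 0.01,
                        jitter = list(on = FALSE, scale = 0.9, seed = 1L)) {
  N <- as.integer(N)
  stopifnot(N >= 8, a > 0, omega > 0, J_int > 0, J_int <= 1,
            I_b >= 0, fano >= 0, tau > 0, dt > 0, dt <= 0.1 * tau,
            J_c > 0, J_rc_ratio > 0)
  if (J_rp_ratio >= 1)
    stop("J_rp must be smaller than J_rc (J_rp_ratio < 1)")
  jit <- utils::modifyList(list(on = FALSE, scale = 0.9, seed = 1L), jitter)
  p <- list(N = N, a = a, omega = omega, J_int = J_int,
            J_c = J_c, J_rc = J_rc_ratio * J_c,
            J_rp = J_rp_ratio * J_rc_ratio * J_c,
            J_rc_ratio = J_rc_ratio, J_rp_ratio = J_rp_ratio,
            I_b = I_b, fano = fano, tau = tau, dt = dt, jitter = jit)
  class(p) <- "cann_params"
  p
}

#' @export
print.cann_params <- function(x, ...) {
  cat("two-module CANN parameters\n")
  cat(sprintf("  N = %d per group, a = %g, omega = %g, J_int = %g\n",
              x$N, x$a, x$omega, x$J_int))
  cat(sprintf("  J_c = %.6g, J_rc = %.3g J_c, J_rp = %.3g J_rc\n",
              x$J_c, x$J_rc_ratio, x$J_rp_ratio))
  cat(sprintf("  I_b = %g, Fano = %g, tau = %g, dt = %g tau\n",
              x$I_b, x$fano, x$tau, x$dt / x$tau))
  cat(sprintf("  U_0 = %.4g; reciprocal jitter %s\n", u0_scale(x),
              if (x$jitter$on) sprintf("on (scale %g, seed %d)",
                                       x$jitter$scale, x$jitter$seed)
              else "off"))
  invisible(x)
}

#' Preferred-direction grid of the network
#'
#' Neurons tile (-180, 180] uniformly: \code{theta_i = -180 + i * 360 / N},
#' \code{i = 1..N} (so +180 is on the grid and -180 is not).
#'
#' @param p a \code{\link{cann_params}} object (or an integer N).
#' @return angles in degrees, length N.
#' @export
theta_grid <- function(p) {
  N <- if (inherits(p, "cann_params")) p$N else as.integer(p)
  -180 + (1:N) * 360 / N
}

#' Synaptic input scale U0
#'
#' The height of the synaptic bump a neuronal group can hold at the critical
#' coupling: \code{U0 = J_c * exp(a/2) / (2 pi omega (1 + J_int) I0(a/2))}.
#' Cue intensities \code{alpha} are expressed as multiples of U0 so that the
#' documented range [0.3, 1.5] U0 spans the super-linear through the nearly
#' saturated part of the input-rate transfer.
#'
#' @param p a \code{\link{cann_params}} object.
#' @return U0 in synaptic-input units.
#' @export
u0_scale <- function(p) {
  stopifnot(inherits(p, "cann_params"))
  p$J_c * exp(p$a / 2) /
    (2 * pi * p$omega * (1 + p$J_int) * besselI(p$a / 2, 0))
}

#' Connectivity kernels
#'
#' Builds the three N x N weight matrices: the recurrent kernel within a
#' group, \code{W_rc(th, th') = J_rc exp(a cos(th - th')) / (2 pi I0(a))};
#' the cross-module reciprocal kernel between congruent neurons (same form
#' with \code{J_rp}); and between opposite neurons the same profile offset
#' by 180 degrees, so an opposite neuron is wired most strongly to the
#' neuron preferring the antipodal direction in the other module. With
#' jitter on, reciprocal weights are perturbed multiplicatively (see
#' \code{\link{cann_params}}) under the jitter seed, leaving the global RNG
#' state untouched.
#'
#' @param p a \code{\link{cann_params}} object.
#' @return list of class \code{"cann_kernels"} with \code{W_rc},
#'   \code{W_rp_c}, \code{W_rp_o}, and \code{theta}.
#' @export
build_kernels <- function(p) {
  stopifnot(inherits(p, "cann_params"))
  th <- deg2rad(theta_grid(p))
  dd <- outer(th, th, "-")
  base <- exp(p$a * cos(dd)) / (2 * pi * besselI(p$a, 0, expon.scaled = TRUE)) *
    exp(-p$a)
  W_rc <- p$J_rc * base
  W_rp_c <- p$J_rp * base
  W_rp_o <- p$J_rp * exp(p$a * cos(dd + pi)) /
    (2 * pi * besselI(p$a, 0, expon.scaled = TRUE)) * exp(-p$a)
  if (isTRUE(p$jitter$on)) {
    # imperfect cross-module wiring: each receiving neuron's incoming
    # reciprocal row gains a randomly directed von Mises bump of the same
    # profile, with amplitude up to `scale` times the structured kernel.
    # The perturbation is coherent across a row (mistargeted arbor), which
    # is what lets preferred directions drift into the intermediate band;
    # i.i.d. per-connection noise averages out in the population vector.
    os <- .Random.seed_save()
    set.seed(p$jitter$seed)
    N <- p$N
    base_row <- function(peak_scale, psi, amp) {
      sweep_rows <- amp * peak_scale *
        exp(p$a * (cos(outer(psi, th, "-")) - 1))
      sweep_rows
    }
    for (nm in c("W_rp_c", "W_rp_o")) {
      psi <- stats::runif(N, -pi, pi)
      amp <- stats::runif(N, 0, p$jitter$scale)
      peak <- p$J_rp * exp(p$a) / (2 * pi * besselI(p$a, 0))
      assign(nm, get(nm) + base_row(peak, psi, amp))
    }
    .Random.seed_restore(os)
  }
  structure(list(W_rc = W_rc, W_rp_c = W_rp_c, W_rp_o = W_rp_o,
                 theta = theta_grid(p)),
            class = "cann_kernels")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' One cue stimulus
#'
#' @param direction cue direction in degrees, wrapped to (-180, 180].
#' @param alpha intensity in multiples of \code{\link{u0_scale}}; controls
#'   the cue's reliability.
#' @param module which module (1 or 2) receives the cue as its direct
#'   feedforward input.
#' @param on logical; an "off" cue contributes no cue drive (background
#'   input is always present).
#' @return an object of class \code{"cue_stimulus"}.
#' @examples
#' cue_stimulus(-30, 0.35, module = 1)
#' @export
cue_stimulus <- function(direction, alpha, module, on = TRUE) {
  stopifnot(alpha >= 0, module %in% c(1, 2))
  structure(list(direction = wrap_angle(direction), alpha = alpha,
                 module = as.integer(module), on = isTRUE(on)),
            class = "cue_stimulus")
}

#' @export
print.cue_stimulus <- function(x, ...) {
  cat(sprintf("cue to module %d: direction %g deg, alpha = %g U0%s\n",
              x$module, x$direction, x$alpha, if (x$on) "" else " (off)"))
  invisible(x)
}

#' Mean feedforward profile of a cue
#'
#' \code{I_ff(theta) = alpha U0 exp[a (cos(theta - x) - 1) / 2]}: a von
#' Mises-shaped hill of input peaking at the cue direction with peak value
#' \code{alpha U0} and falling to \code{alpha U0 exp(-a)} at the antipode.
#'
#' @param p a \code{\link{cann_params}}.
#' @param cue a \code{\link{cue_stimulus}} (or NULL / off cue for zero
#'   drive).
#' @return numeric vector of length N over \code{\link{theta_grid}}.
#' @export
ff_mean <- function(p, cue) {
  if (is.null(cue) || !cue$on || cue$alpha == 0) return(numeric(p$N))
  th <- deg2rad(theta_grid(p) - cue$direction)
  cue$alpha * u0_scale(p) * exp(p$a * (cos(th) - 1) / 2)
}

#' Sample noisy feedforward drive
#'
#' Draws the stochastic feedforward input received by one module over
#' \code{n_steps} Euler steps: mean cue profile plus multiplicative cue
#' noise with variance \code{F * I_ff} per unit time (shared between the
#' congruent and opposite group of the module), plus background mean
#' \code{I_b} with its own noise of variance \code{F * I_b} (independent per
#' group). White-noise terms are scaled by \code{1/sqrt(dt)} per step so the
#' variance integrated over unit time matches the delta-correlated
#' covariance.
#'
#' This R-level generator mirrors the compiled simulation loop and exists
#' for statistical checks of the noise scaling.
#'
#' @param p a \code{\link{cann_params}}.
#' @param cue a \code{\link{cue_stimulus}}.
#' @param n_steps number of Euler steps to draw.
#' @return list with \code{I_c}, \code{I_o} (\code{n_steps x N} inputs to
#'   the congruent and opposite group) and \code{mean} (the noise-free
#'   profile including background).
#' @export
feedforward_drive <- function(p, cue, n_steps) {
  m <- ff_mean(p, cue)
  N <- p$N
  amp_cue <- sqrt(p$fano * m / p$dt)
  amp_bg <- sqrt(p$fano * p$I_b / p$dt)
  xi <- matrix(stats::rnorm(n_steps * N), n_steps, N)
  cue_part <- sweep(xi, 2, amp_cue, "*")
  base <- matrix(m + p$I_b, n_steps, N, byrow = TRUE)
  I_c <- base + cue_part +
    amp_bg * matrix(stats::rnorm(n_steps * N), n_steps, N)
  I_o <- base + cue_part +
    amp_bg * matrix(stats::rnorm(n_steps * N), n_steps, N)
  list(I_c = I_c, I_o = I_o, mean = m + p$I_b)
}

#' Divisive normalization
#'
#' Converts synaptic inputs to firing rates through the rectified-square
#' nonlinearity with divisive inhibition:
#' \code{r = [u]+^2 / (1 + omega D)}, where the inhibition pool of each
#' group sums its own squared rectified input plus \code{J_int} times the
#' other-type pool in the same module:
#' \code{D_mn = sum [u_mn]+^2 + J_int sum [u_mn']+^2} (sums weighted by
#' \code{180/N} on coarser grids).
#'
#' @param u \code{N x 4} matrix of synaptic inputs, columns
#'   \code{m1c, m1o, m2c, m2o}.
#' @param p a \code{\link{cann_params}}.
#' @return list with \code{r} (\code{N x 4} firing rates, Hz) and \code{D}
#'   (length-4 inhibition-pool activities).
#' @export
divisive_normalize <- function(u, p) {
  stopifnot(is.matrix(u), ncol(u) == 4, nrow(u) == p$N)
  g <- 180 / p$N
  up <- pmax(u, 0)
  S <- colSums(up^2)
  mate <- c(2, 1, 4, 3)
  D <- g * (S + p$J_int * S[mate])
  r <- sweep(up^2, 2, 1 + p$omega * D, "/")
  colnames(r) <- .GROUPS
  names(D) <- .GROUPS
  list(r = r, D = D)
}

#' One Euler step of the network (R reference implementation)
#'
#' Deterministic single-step update used to verify the compiled loop and to
#' study fixed points: combines recurrent input, reciprocal input from the
#' other module (congruent groups coupled by the congruent kernel, opposite
#' groups by the offset kernel, never across types) and the provided drive.
#'
#' @param u \code{N x 4} synaptic-input matrix.
#' @param kernels a \code{\link{build_kernels}} result.
#' @param drive \code{N x 4} matrix of external input (feedforward +
#'   background), noise-free.
#' @param p a \code{\link{cann_params}}.
#' @return updated \code{N x 4} synaptic-input matrix.
#' @export
step_cann <- function(u, kernels, drive, p) {
  g <- 180 / p$N
  r <- divisive_normalize(u, p)$r
  rec <- g * (kernels$W_rc %*% r)
  rp <- cbind(g * (kernels$W_rp_c %*% r[, 3]), g * (kernels$W_rp_o %*% r[, 4]),
              g * (kernels$W_rp_c %*% r[, 1]), g * (kernels$W_rp_o %*% r[, 2]))
  un <- u + (-u + rec + rp + drive) * p$dt / p$tau
  if (any(!is.finite(un))) stop("network state diverged (non-finite)")
  dimnames(un) <- dimnames(u)
  un
}

#' Simulate the two-module network
#'
#' Integrates the stochastic network dynamics with the Euler-Maruyama
#' scheme, discards a burn-in transient, and records per-sample decoded bump
#' positions (population vector), summed and peak rates per group, and
#' time-averaged rate/input profiles. Identical seeds give identical traces.
#'
#' @param p a \code{\link{cann_params}}.
#' @param cues list of \code{\link{cue_stimulus}} objects (at most one per
#'   module); empty list for spontaneous activity.
#' @param duration sampled epoch length in units of tau (default 500,
#'   i.e. 5e4 samples at dt = 0.01 and stride 1).
#' @param burn_in discarded transient in units of tau (default 50).
#' @param stride keep every \code{stride}-th step (default 1).
#' @param seed integer seed for the noise stream; \code{NULL} continues the
#'   current RNG state.
#' @param init optional \code{N x 4} initial synaptic input (e.g. the
#'   \code{u_final} of a previous trace); defaults to zeros.
#' @param cue_noise,bg_noise switches for the two noise sources; switching
#'   one off does not alter the draws used by the other.
#' @return an object of class \code{"cann_trace"}: \code{z} (n x 4 decoded
#'   angles, degrees; NA where a group's activity carries no direction),
#'   \code{rate_sum}, \code{rate_peak} (n x 4), \code{rate_mean},
#'   \code{rate_sd}, \code{u_mean}, \code{u_final} (N x 4), \code{theta},
#'   plus the parameters, cues and seed needed to reproduce the run.
#' @examples
#' \donttest{
#' p <- cann_params(N = 36)
#' tr <- simulate_cann(p, list(cue_stimulus(-30, 0.35, 1)),
#'                     duration = 50, seed = 1)
#' summary(tr)
#' }
#' @export
simulate_cann <- function(p, cues = list(), duration = 500, burn_in = 50,
                          stride = 1L, seed = NULL, init = NULL,
                          cue_noise = TRUE, bg_noise = TRUE) {
  stopifnot(inherits(p, "cann_params"))
  if (inherits(cues, "cue_stimulus")) cues <- list(cues)
  mods <- vapply(cues, function(cu) cu$module, integer(1))
  if (anyDuplicated(mods)) stop("at most one cue per module")
  cue1 <- if (any(mods == 1)) cues[[which(mods == 1)]] else NULL
  cue2 <- if (any(mods == 2)) cues[[which(mods == 2)]] else NULL
  ker <- build_kernels(p)
  g <- 180 / p$N
  if (is.null(init)) init <- matrix(0, p$N, 4)
  stopifnot(nrow(init) == p$N, ncol(init) == 4)
  n_burn <- as.integer(round(burn_in / p$dt))
  n_sample <- as.integer(round(duration / p$dt / stride))
  if (!is.null(seed)) set.seed(seed)
  out <- cann_run_cpp(init, g * ker$W_rc, g * ker$W_rp_c, g * ker$W_rp_o,
                      ff_mean(p, cue1), ff_mean(p, cue2),
                      p$I_b, p$fano, p$dt, p$tau, p$omega, p$J_int, g,
                      n_burn, n_sample, as.integer(stride),
                      cue_noise, bg_noise)
  z <- rad2deg(out$z)
  colnames(z) <- colnames(out$rate_sum) <- colnames(out$rate_peak) <- .GROUPS
  colnames(out$rate_mean) <- colnames(out$rate_sd) <- .GROUPS
  colnames(out$u_mean) <- colnames(out$u_final) <- .GROUPS
  structure(list(z = z, rate_sum = out$rate_sum, rate_peak = out$rate_peak,
                 rate_mean = out$rate_mean, rate_sd = out$rate_sd,
                 u_mean = out$u_mean, u_final = out$u_final,
                 theta = ker$theta, params = p, cues = cues, seed = seed,
                 duration = duration, burn_in = burn_in, stride = stride,
                 n_samples = out$n_samples),
            class = "cann_trace")
}

#' @export
print.cann_trace <- function(x, ...) {
  cat(sprintf("CANN trace: %d samples (dt = %g tau, stride %d, burn-in %g tau)\n",
              x$n_samples, x$params$dt, x$stride, x$burn_in))
  for (cu in x$cues)
    cat(sprintf("  cue to module %d at %g deg, alpha = %g U0\n",
                cu$module, cu$direction, cu$alpha))
  if (!length(x$cues)) cat("  no cues (background only)\n")
  cat(sprintf("  seed %s\n", if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

#' @export
summary.cann_trace <- function(object, ...) {
  est <- lapply(.GROUPS, function(gr) {
    zz <- object$z[, gr]
    zz <- zz[is.finite(zz)]
    if (length(zz) >= 2) circ_estimate(zz) else NULL
  })
  names(est) <- .GROUPS
  peak <- apply(object$rate_mean, 2, max)
  cat("decoded bump positions (population vector over samples):\n")
  for (gr in .GROUPS) {
    e <- est[[gr]]
    if (is.null(e) || !e$mu_defined)
      cat(sprintf("  %s: undefined (no directional activity)\n", gr))
    else
      cat(sprintf("  %s: mean %8.3f deg, kappa %8.3g, peak rate %6.2f Hz\n",
                  gr, e$mu, e$kappa, peak[[gr]]))
  }
  invisible(est)
}

#' @export
plot.cann_trace <- function(x, which = c("profile", "position"), ...) {
  which <- match.arg(which)
  cols <- c(m1c = "#2166ac", m1o = "#b2182b", m2c = "#67a9cf",
            m2o = "#ef8a62")
  if (which == "profile") {
    graphics::matplot(x$theta, x$rate_mean, type = "l", lty = 1,
                      col = cols, xlab = "preferred direction (deg)",
                      ylab = "mean rate (Hz)", ...)
    graphics::legend("topright", legend = .GROUPS, col = cols, lty = 1,
                     bty = "n", cex = 0.8)
  } else {
    tt <- seq_len(nrow(x$z)) * x$params$dt * x$stride
    graphics::matplot(tt, x$z, type = "l", lty = 1, col = cols,
                      xlab = "time (tau)", ylab = "decoded position (deg)",
                      ...)
  }
  invisible(x)
}

#' Critical recurrent strength by bisection
#'
#' Estimates \code{J_c}, the minimal recurrent strength at which a single
#' module (congruent and opposite group with shared inhibition, reciprocal
#' connections absent) holds a persistent activity bump after feedforward
#' input is switched off. Noise-free integration from a seeded bump; the
#' bump is called persistent when its peak synaptic input stays above
#' \code{tol_u} after \code{settle} time constants.
#'
#' @param p a \code{\link{cann_params}} (its \code{J_c}/\code{J_rc} are
#'   ignored; geometry and normalization parameters are used).
#' @param lower,upper initial bracket for the search.
#' @param settle integration time (units of tau) after input offset.
#' @param rel_tol relative bisection tolerance.
#' @param tol_u persistence threshold on peak synaptic input.
#' @return estimated critical strength.
#' @export
critical_jc <- function(p, lower = 1e-4, upper = 0.1, settle = 200,
                        rel_tol = 1e-3, tol_u = 1e-2) {
  stopifnot(inherits(p, "cann_params"))
  g <- 180 / p$N
  th <- deg2rad(theta_grid(p))
  bump <- exp(p$a * (cos(th) - 1) / 2)
  persists <- function(J) {
    q <- p
    q$J_rc <- J
    q$J_rp <- 0
    ker <- build_kernels(q)
    # seed a generous bump in both groups of module 1 and iterate noise-free
    u <- cbind(50 * bump, 50 * bump, 0 * bump, 0 * bump)
    n <- as.integer(round(settle / p$dt))
    u <- cann_run_cpp(u, g * ker$W_rc, g * ker$W_rp_c, g * ker$W_rp_o,
                      numeric(p$N), numeric(p$N), 0, 0, p$dt, p$tau,
                      p$omega, p$J_int, g, n, 1L, 1L, FALSE, FALSE)$u_final
    max(u[, 1]) > tol_u
  }
  while (!persists(upper)) upper <- upper * 2
  while (persists(lower)) lower <- lower / 2
  while ((upper - lower) / upper > rel_tol) {
    mid <- (upper + lower) / 2
    if (persists(mid)) upper <- mid else lower <- mid
  }
  (upper + lower) / 2
}
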