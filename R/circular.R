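# Circular-statistics primitives: von Mises distributions treated as 2-D
# vectors (angle = mean, length = concentration), the mean resultant length
# A(kappa) and its inverse, and sample-based estimation of circular
# parameters. Angles are degrees in (-180, 180] at the API boundary and
# radians internally.

#' @useDynLib mscann, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# kappa assigned when every sample coincides (resultant length
# numerically 1); documented cap, see ?circ_estimate
.KAPPA_CAP <- 1e8

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @examples
#' wrap_angle(c(-180, 180, 270, 540))
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Von Mises distribution as a classed object
#'
#' Constructs a von Mises distribution on the circle with mean direction
#' \code{mu} (degrees) and concentration \code{kappa}. \code{kappa = 0} is
#' the uniform circular distribution; its mean direction is undefined and the
#' object carries \code{mu_defined = FALSE} so downstream code must branch
#' deliberately rather than propagate a meaningless angle.
#'
#' @param mu mean direction in degrees; wrapped to (-180, 180].
#' @param kappa concentration, dimensionless, \code{>= 0}.
#' @param mu_defined logical; set \code{FALSE} for the uniform case.
#' @return an object of class \code{"von_mises"} with fields \code{mu},
#'   \code{kappa}, \code{mu_defined}.
#' @examples
#' von_mises(20, 50)
#' von_mises(0, 0)   # uniform; mu flagged undefined
#' @export
von_mises <- function(mu, kappa, mu_defined = kappa > 0) {
  stopifnot(length(mu) == 1, length(kappa) == 1, is.finite(mu))
  if (!is.finite(kappa) || kappa < 0)
    stop("kappa must be finite and >= 0 (use a large sentinel for infinity)")
  structure(list(mu = if (mu_defined) unname(wrap_angle(mu)) else NA_real_,
                 kappa = unname(kappa), mu_defined = isTRUE(mu_defined)),
            class = "von_mises")
}

#' @export
print.von_mises <- function(x, ...) {
  if (x$mu_defined)
    cat(sprintf("von Mises: mu = %.4f deg, kappa = %.6g\n", x$mu, x$kappa))
  else
    cat(sprintf("von Mises: uniform (kappa = %.3g, mu undefined)\n", x$kappa))
  invisible(x)
}

#' @export
format.von_mises <- function(x, ...) {
  if (x$mu_defined) sprintf("VM(%.3f deg, %.4g)", x$mu, x$kappa)
  else sprintf("VM(uniform, kappa=%.3g)", x$kappa)
}

#' Von Mises probability density
#'
#' Density of a \code{\link{von_mises}} distribution evaluated at angles in
#' degrees. The density is expressed per degree, so that integrating over
#' one period (-180, 180] in degrees gives 1. \code{kappa = 0} returns the
#' uniform density 1/360 everywhere.
#'
#' @param theta angles in degrees (vectorized).
#' @param d a \code{von_mises} object.
#' @return densities, 1/degree.
#' @examples
#' d <- von_mises(0, 2)
#' integrate(vm_pdf, -180, 180, d = d)$value  # 1
#' @export
vm_pdf <- function(theta, d) {
  stopifnot(inherits(d, "von_mises"))
  if (d$kappa == 0) return(rep(1 / 360, length(theta)))
  th <- deg2rad(theta - d$mu)
  # exponentially scaled Bessel keeps large kappa finite
  log_i0 <- log(besselI(d$kappa, 0, expon.scaled = TRUE)) + d$kappa
  exp(d$kappa * cos(th) - log(2 * pi) - log_i0) * pi / 180
}

#' Mean resultant length A(kappa) of a von Mises distribution
#'
#' \code{A(kappa) = I1(kappa)/I0(kappa)}, the expected length of the unit
#' vector average of von Mises samples. Strictly increasing from
#' \code{A(0) = 0} towards 1 as \code{kappa} grows; it converts between the
#' concentration and dispersion parameterizations of circular spread.
#'
#' @param kappa concentration(s), \code{>= 0} (vectorized).
#' @return mean resultant length(s) in \code{[0, 1)}.
#' @examples
#' resultant_length(c(0, 2, 50))
#' @export
resultant_length <- function(kappa) {
  if (any(!is.finite(kappa) & kappa > 0)) stop("kappa must be finite")
  if (any(kappa < 0)) stop("kappa must be >= 0")
  r <- numeric(length(kappa))
  pos <- kappa > 0
  k <- kappa[pos]
  # scaled ratio is stable for all kappa; asymptotic tail for very large
  # kappa where besselI underflow/overflow would bite
  big <- k > 1e5
  rk <- numeric(length(k))
  rk[!big] <- besselI(k[!big], 1, expon.scaled = TRUE) /
    besselI(k[!big], 0, expon.scaled = TRUE)
  kb <- k[big]
  rk[big] <- 1 - 1 / (2 * kb) - 1 / (8 * kb^2) - 1 / (8 * kb^3)
  r[pos] <- rk
  r
}

#' Inverse of the mean resultant length
#'
#' Recovers the concentration \code{kappa} such that
#' \code{resultant_length(kappa) = r}. No closed form exists; the root is
#' bracketed and solved by \code{\link[stats]{uniroot}} to tolerance 1e-10.
#' Resultant lengths numerically indistinguishable from 1 map to the
#' documented concentration cap (1e8).
#'
#' @param r mean resultant length(s) in \code{[0, 1)} (vectorized).
#' @return concentration(s) \code{>= 0}.
#' @examples
#' inv_resultant(resultant_length(5))  # 5
#' @export
inv_resultant <- function(r) {
  if (any(r < 0 | r >= 1)) stop("r must lie in [0, 1)")
  vapply(r, function(ri) {
    if (ri == 0) return(0)
    if (ri >= 1 - 1e-9) return(.KAPPA_CAP)
    # Banerjee-style starting guess brackets the root generously
    k0 <- ri * (2 - ri^2) / (1 - ri^2)
    lo <- max(k0 / 4, 1e-12)
    hi <- max(k0 * 4, 1e-6)
    while (resultant_length(lo) > ri) lo <- lo / 4
    while (resultant_length(hi) < ri) hi <- hi * 4
    stats::uniroot(function(k) resultant_length(k) - ri, c(lo, hi),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Cartesian vector embedding of a von Mises distribution
#'
#' A von Mises distribution maps to the 2-D vector
#' \code{kappa * (cos mu, sin mu)}; products and ratios of von Mises
#' densities correspond to sums and differences of these vectors.
#'
#' @param d a \code{von_mises} object.
#' @return numeric vector \code{c(x, y)}.
#' @seealso \code{\link{vec_to_vm}}
#' @export
vm_to_vec <- function(d) {
  stopifnot(inherits(d, "von_mises"))
  if (!d$mu_defined) return(c(x = 0, y = 0))
  mu <- deg2rad(d$mu)
  c(x = d$kappa * cos(mu), y = d$kappa * sin(mu))
}

#' Von Mises distribution from its Cartesian embedding
#'
#' @param v numeric vector \code{c(x, y)}.
#' @param tol vectors shorter than \code{tol} are treated as exact
#'   cancellation and return the uniform distribution with the undefined-mu
#'   flag set.
#' @return a \code{von_mises} object.
#' @export
vec_to_vm <- function(v, tol = 1e-12) {
  kappa <- sqrt(sum(v^2))
  if (kappa < tol) return(von_mises(0, 0, mu_defined = FALSE))
  von_mises(rad2deg(atan2(v[2], v[1])), kappa)
}

#' Product of two von Mises densities
#'
#' The (renormalized) product of two von Mises densities is again von Mises;
#' in the vector picture it is the vector sum. This is the elementary
#' operation of optimal cue integration for circular variables:
#' \code{kappa_hat * exp(i mu_hat) = kappa1 * exp(i mu1) + kappa2 * exp(i mu2)}.
#' Exact cancellation (antipodal means, equal concentrations) returns the
#' uniform distribution with the undefined-mu flag.
#'
#' @param d1,d2 \code{von_mises} objects.
#' @return a \code{von_mises} object.
#' @examples
#' vm_product(von_mises(0, 50), von_mises(90, 50))  # mu 45, kappa 50*sqrt(2)
#' @export
vm_product <- function(d1, d2) {
  vec_to_vm(vm_to_vec(d1) + vm_to_vec(d2))
}

#' Ratio of two von Mises densities
#'
#' The ratio corresponds to vector subtraction, equivalently the product
#' with the second mean shifted by 180 degrees (since
#' \code{-cos(t) = cos(t - 180)}). This is the elementary operation of cue
#' segregation: the disparity between two circular estimates.
#'
#' @param d1,d2 \code{von_mises} objects.
#' @return a \code{von_mises} object.
#' @examples
#' vm_ratio(von_mises(0, 50), von_mises(20, 25))
#' @export
vm_ratio <- function(d1, d2) {
  # implemented literally as the 180-degree-shifted product so the two
  # forms are bitwise identical
  if (!d2$mu_defined) return(vm_product(d1, d2))
  vm_product(d1, von_mises(d2$mu + 180, d2$kappa))
}

#' Estimate circular mean and concentration from angle samples
#'
#' Computes the circular sample mean \code{arg(sum exp(i z) / n)} and maps
#' the sample mean resultant length through \code{\link{inv_resultant}} to a
#' concentration. When all samples coincide the resultant is numerically 1
#' and kappa saturates at the documented cap (1e8); a zero resultant
#' (e.g. perfectly uniform samples) returns kappa 0 with the undefined-mean
#' flag.
#'
#' @param samples angles in degrees, length \code{>= 2}.
#' @return a list of class \code{"circ_estimate"} with \code{mu} (degrees),
#'   \code{kappa}, \code{r} (sample mean resultant length), and \code{n}.
#' @examples
#' set.seed(1)
#' circ_estimate(rnorm(500, mean = 37, sd = 5))
#' @export
circ_estimate <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 samples")
  z <- deg2rad(samples)
  cx <- mean(cos(z)); sx <- mean(sin(z))
  r <- min(sqrt(cx^2 + sx^2), 1)
  if (r < 1e-12) {
    out <- list(mu = NA_real_, kappa = 0, r = r, n = length(samples),
                mu_defined = FALSE)
  } else {
    out <- list(mu = wrap_angle(rad2deg(atan2(sx, cx))),
                kappa = if (r >= 1 - 1e-9) .KAPPA_CAP else inv_resultant(r),
                r = r, n = length(samples), mu_defined = TRUE)
  }
  class(out) <- "circ_estimate"
  out
}

#' @export
print.circ_estimate <- function(x, ...) {
  cat(sprintf("circular estimate (n = %d): mu = %s deg, kappa = %.6g\n",
              x$n, if (x$mu_defined) sprintf("%.4f", x$mu) else "undefined",
              x$kappa))
  invisible(x)
}

#' Draw random angles from a von Mises distribution
#'
#' Best-of-breed rejection sampler (wrapped-Cauchy envelope,
#' Best & Fisher construction) used for parameter-recovery checks and for
#' building synthetic angle series.
#'
#' @param n number of draws.
#' @param d a \code{von_mises} object (kappa 0 gives uniform draws).
#' @return angles in degrees in (-180, 180].
#' @export
rvon_mises <- function(n, d) {
  stopifnot(inherits(d, "von_mises"))
  k <- d$kappa
  if (k == 0) return(wrap_angle(stats::runif(n, -180, 180)))
  mu <- deg2rad(d$mu)
  a <- 1 + sqrt(1 + 4 * k^2)
  b <- (a - sqrt(2 * a)) / (2 * k)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + rr * z) / (rr + z)
    cc <- k * (rr - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap_angle(rad2deg(out))
}
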