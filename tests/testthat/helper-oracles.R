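# Independent oracles used across the suite.

# Mean resultant length by direct numerical quadrature of the trigonometric
# moment ratio (independent of besselI).
quad_resultant <- function(k) {
  num <- integrate(function(t) cos(t) * exp(k * (cos(t) - 1)), -pi, pi,
                   rel.tol = 1e-13)$value
  den <- integrate(function(t) exp(k * (cos(t) - 1)), -pi, pi,
                   rel.tol = 1e-13)$value
  num / den
}

# Frozen oracle values (computed with quad_resultant and plain vector
# arithmetic before the implementation existed):
#   A(2)                       = 0.697774657964
#   A(10)                      = 0.948599825955
#   kappa_2s at (50, 50)       = 25.2566038992   root of A(k) = A(50)^2
#   integrated posterior, x1 = 0, x2 = 20 deg, kappa1 = kappa2 = kappa_s = 50:
#       mean  6.6820468510 deg, kappa 74.2377294342
#   disparity distribution, same setting:
#       mean -18.2044550275 deg, kappa 27.6505263874
ORACLE <- list(
  A2 = 0.697774657964,
  A10 = 0.948599825955,
  k2s_50_50 = 25.2566038992,
  fig_int = c(mu = 6.6820468510, kappa = 74.2377294342),
  fig_disp = c(mu = -18.2044550275, kappa = 27.6505263874)
)

# Small fixture network used throughout the unit tests.
fixture_params <- function(...) cann_params(N = 36L, ...)

expect_angle_equal <- function(a, b, tol = 1e-8) {
  expect_lt(abs(mscann::wrap_angle(a - b)), tol)
}
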