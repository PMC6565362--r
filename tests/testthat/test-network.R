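# Network construction and dynamics: parameter validation, kernels, input
# scale, feedforward noise statistics, divisive normalization, Euler step
# consistency, determinism, equivariance and bump geometry. Simulations use
# the N = 36 fixture grid.

test_that("parameter validation enforces the documented constraints", {
  expect_error(cann_params(dt = 0.2), "dt")
  expect_error(cann_params(N = 4), "N")
  expect_error(cann_params(J_int = 0), "J_int")
  expect_error(cann_params(J_rp_ratio = 1), "smaller than J_rc")
  p <- fixture_params()
  expect_equal(p$J_rc, 0.3 * p$J_c)
  expect_equal(p$J_rp, 0.5 * p$J_rc)
})

test_that("U0 follows the closed form and its scalings", {
  p <- cann_params()
  direct <- p$J_c * exp(p$a / 2) /
    (2 * pi * p$omega * (1 + p$J_int) * besselI(p$a / 2, 0))
  expect_equal(u0_scale(p), direct, tolerance = 1e-12)
  expect_equal(u0_scale(cann_params(J_c = 2 * p$J_c)), 2 * u0_scale(p),
               tolerance = 1e-12)
  expect_equal(u0_scale(cann_params(omega = 2 * p$omega)), u0_scale(p) / 2,
               tolerance = 1e-12)
})

test_that("kernels have the documented profile, symmetry and offset", {
  p <- fixture_params()
  ker <- build_kernels(p)
  peak <- p$J_rc * exp(p$a) / (2 * pi * besselI(p$a, 0))
  expect_equal(max(ker$W_rc), peak, tolerance = 1e-12)
  expect_equal(unname(diag(ker$W_rc)), rep(peak, p$N), tolerance = 1e-12)
  expect_equal(ker$W_rc, t(ker$W_rc), tolerance = 1e-12)
  # circulant: identical row sums
  expect_lt(diff(range(rowSums(ker$W_rc))), 1e-12)
  # opposite kernel is the congruent kernel offset by 180 degrees
  shift <- p$N / 2
  idx <- c((shift + 1):p$N, 1:shift)
  expect_equal(ker$W_rp_o, ker$W_rp_c[, idx], tolerance = 1e-14,
               ignore_attr = TRUE)
  # peak of the opposite kernel sits at the antipode with J_rp scale
  peak_o <- p$J_rp * exp(p$a) / (2 * pi * besselI(p$a, 0))
  i0 <- which.min(abs(ker$theta - 0)); i180 <- which.min(abs(ker$theta - 180))
  expect_equal(ker$W_rp_o[i0, i180], peak_o, tolerance = 1e-12)
  expect_equal(max(ker$W_rp_o[i0, ]), peak_o, tolerance = 1e-12)
})

test_that("reciprocal jitter is seeded, multiplicative and RNG-isolated", {
  p <- fixture_params(jitter = list(on = TRUE, scale = 0.5, seed = 9L))
  set.seed(123); before <- .Random.seed
  k1 <- build_kernels(p)
  expect_identical(.Random.seed, before)     # global RNG untouched
  k2 <- build_kernels(p)
  expect_identical(k1$W_rp_c, k2$W_rp_c)     # same jitter seed, same kernels
  p2 <- fixture_params(jitter = list(on = TRUE, scale = 0.5, seed = 10L))
  expect_false(identical(build_kernels(p2)$W_rp_c, k1$W_rp_c))
  base <- build_kernels(fixture_params())
  # added component is nonnegative and bounded by scale times the peak
  added <- k1$W_rp_c - base$W_rp_c
  peak <- max(base$W_rp_c)
  expect_true(all(added >= -1e-15))
  expect_true(all(added <= 0.5 * peak + 1e-12))
  expect_identical(k1$W_rc, base$W_rc)       # recurrent kernel not jittered
})

test_that("feedforward mean profile peaks at the cue with the right tails", {
  p <- fixture_params()
  cue <- cue_stimulus(40, 0.7, 1)
  m <- ff_mean(p, cue)
  th <- theta_grid(p)
  U0 <- u0_scale(p)
  expect_equal(m[which.min(abs(th - 40))], 0.7 * U0, tolerance = 1e-12)
  expect_equal(m[which.min(abs(th + 140))], 0.7 * U0 * exp(-p$a),
               tolerance = 1e-12)
  expect_identical(ff_mean(p, cue_stimulus(40, 0, 1)), numeric(p$N))
  expect_identical(ff_mean(p, NULL), numeric(p$N))
})

test_that("feedforward noise realizes the configured Fano factor", {
  p <- fixture_params()
  set.seed(21)
  cue <- cue_stimulus(0, 0.8, 1)
  dr <- feedforward_drive(p, cue, n_steps = 1e4)
  m <- ff_mean(p, cue)
  hot <- which(m > 0.2 * max(m))
  # cue-part variance relative to mean, integrated over time, gives F
  fano_hat <- vapply(hot, function(i) {
    var(dr$I_c[, i]) * p$dt / (m[i] + p$I_b)
  }, numeric(1))
  # background adds F*Ib to the numerator and Ib to the mean, so the ratio
  # still estimates F
  expect_equal(median(fano_hat), p$fano, tolerance = 0.05)
  # cue noise is shared between congruent and opposite groups: the
  # cue-associated part of I_c and I_o is identical, backgrounds differ
  resid <- (dr$I_c - dr$I_o)
  expect_gt(var(c(resid)), 0)  # backgrounds independent
  pk <- which.max(m)
  cue_c <- sweep(dr$I_c, 2, m + p$I_b)[, pk]
  cue_o <- sweep(dr$I_o, 2, m + p$I_b)[, pk]
  # shared cue noise makes the two inputs strongly correlated at the bump
  expect_gt(cor(cue_c, cue_o), 0.7)
})

test_that("divisive normalization rectifies, squares and pools", {
  p <- fixture_params()
  # all-nonpositive input gives zero rates
  u <- matrix(-abs(rnorm(p$N * 4)), p$N, 4)
  expect_true(all(divisive_normalize(u, p)$r == 0))
  # omega -> 0 limit: pure rectified square
  p0 <- p; p0$omega <- 0
  u <- matrix(rnorm(p$N * 4), p$N, 4)
  expect_equal(divisive_normalize(u, p0)$r, pmax(u, 0)^2,
               tolerance = 1e-12, ignore_attr = TRUE)
  # single active group with uniform input: closed-form bound
  h <- 30
  u <- cbind(rep(h, p$N), 0, 0, 0)
  out <- divisive_normalize(u, p)
  g <- 180 / p$N
  expect_equal(unname(out$r[1, 1]), h^2 / (1 + p$omega * g * p$N * h^2),
               tolerance = 1e-12)
  expect_equal(unname(out$D["m1o"]), g * p$J_int * p$N * h^2,
               tolerance = 1e-12)
  # inhibition pools satisfy the defining sum at every step
  u <- matrix(rnorm(p$N * 4, 1), p$N, 4)
  out <- divisive_normalize(u, p)
  S <- colSums(pmax(u, 0)^2)
  expect_equal(unname(out$D), g * (S + p$J_int * S[c(2, 1, 4, 3)]),
               tolerance = 1e-12)
})

test_that("compiled step equals the R reference step exactly", {
  p <- fixture_params()
  ker <- build_kernels(p)
  set.seed(31)
  u0 <- matrix(rnorm(p$N * 4, 1, 0.5), p$N, 4)
  ffv <- ff_mean(p, cue_stimulus(0, 0.5, 1))
  drive <- cbind(ffv + p$I_b, ffv + p$I_b, rep(p$I_b, p$N), rep(p$I_b, p$N))
  uR <- step_cann(u0, ker, drive, p)
  g <- 180 / p$N
  uC <- mscann:::cann_run_cpp(u0, g * ker$W_rc, g * ker$W_rp_c,
                              g * ker$W_rp_o, ffv, numeric(p$N), p$I_b, 0,
                              p$dt, p$tau, p$omega, p$J_int, g,
                              0L, 1L, 1L, FALSE, FALSE)$u_final
  expect_equal(uC, unname(uR), tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("zero state with zero drive is a fixed point", {
  p <- fixture_params()
  ker <- build_kernels(p)
  u <- matrix(0, p$N, 4)
  expect_identical(step_cann(u, ker, matrix(0, p$N, 4), p), u)
})

test_that("noise-free dynamics converge to a stationary bump", {
  p <- fixture_params()
  cues <- list(cue_stimulus(0, 0.5, 1), cue_stimulus(0, 0.5, 2))
  tr <- simulate_cann(p, cues, duration = 1, burn_in = 100,
                      cue_noise = FALSE, bg_noise = FALSE)
  ker <- build_kernels(p)
  ff1 <- ff_mean(p, cues[[1]]); ff2 <- ff_mean(p, cues[[2]])
  drive <- cbind(ff1 + p$I_b, ff1 + p$I_b, ff2 + p$I_b, ff2 + p$I_b)
  un <- step_cann(tr$u_final, ker, drive, p)
  residual <- max(abs(un - tr$u_final)) / p$dt
  expect_lt(residual, 1e-6)
  # bump exists and peaks at the cue
  expect_gt(max(tr$rate_mean[, "m1c"]), 1)
  expect_equal(tr$theta[which.max(tr$rate_mean[, "m1c"])], 0,
               tolerance = 1e-9)
})

test_that("simulation is deterministic given the seed", {
  p <- fixture_params()
  cues <- list(cue_stimulus(-30, 0.35, 1))
  a <- simulate_cann(p, cues, duration = 5, burn_in = 2, seed = 99)
  b <- simulate_cann(p, cues, duration = 5, burn_in = 2, seed = 99)
  expect_identical(a$z, b$z)
  expect_identical(a$rate_mean, b$rate_mean)
  expect_identical(a$u_final, b$u_final)
  d <- simulate_cann(p, cues, duration = 5, burn_in = 2, seed = 100)
  expect_false(identical(a$z, d$z))
})

test_that("dynamics are rotation-equivariant and module-symmetric", {
  p <- fixture_params()
  shift_deg <- 40                       # 4 grid steps on the fixture grid
  shift <- shift_deg / (360 / p$N)
  t0 <- simulate_cann(p, list(cue_stimulus(0, 0.5, 1)), duration = 2,
                      burn_in = 40, cue_noise = FALSE, bg_noise = FALSE)
  t1 <- simulate_cann(p, list(cue_stimulus(shift_deg, 0.5, 1)), duration = 2,
                      burn_in = 40, cue_noise = FALSE, bg_noise = FALSE)
  for (gr in c("m1c", "m1o", "m2c", "m2o")) {
    rolled <- t0$rate_mean[((seq_len(p$N) - shift - 1) %% p$N) + 1, gr]
    expect_equal(t1$rate_mean[, gr], rolled, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # module symmetry: cue to module 2 mirrors cue to module 1
  t2 <- simulate_cann(p, list(cue_stimulus(0, 0.5, 2)), duration = 2,
                      burn_in = 40, cue_noise = FALSE, bg_noise = FALSE)
  expect_equal(t2$rate_mean[, c("m2c", "m2o", "m1c", "m1o")],
               t0$rate_mean[, c("m1c", "m1o", "m2c", "m2o")],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("opposite-group bumps sit at the cue antipode in the other module", {
  p <- fixture_params()
  tr <- simulate_cann(p, list(cue_stimulus(-30, 0.5, 1)), duration = 2,
                      burn_in = 50, cue_noise = FALSE, bg_noise = FALSE)
  expect_equal(population_vector(tr$rate_mean[, "m1c"], tr$theta), -30,
               tolerance = 1)
  expect_equal(population_vector(tr$rate_mean[, "m1o"], tr$theta), -30,
               tolerance = 1)
  expect_equal(population_vector(tr$rate_mean[, "m2c"], tr$theta), -30,
               tolerance = 1)
  expect_equal(population_vector(tr$rate_mean[, "m2o"], tr$theta), 150,
               tolerance = 1)
  # no winner-take-all: every group keeps a nonzero bump
  expect_true(all(apply(tr$rate_mean, 2, max) > 0.5))
})

test_that("decoded bumps agree across grid resolutions", {
  cues <- list(cue_stimulus(-30, 0.5, 1), cue_stimulus(10, 0.5, 2))
  z <- lapply(c(36L, 90L), function(N) {
    tr <- simulate_cann(cann_params(N = N), cues, duration = 2,
                        burn_in = 50, cue_noise = FALSE, bg_noise = FALSE)
    vapply(c("m1c", "m1o", "m2c", "m2o"), function(gr)
      population_vector(tr$rate_mean[, gr], tr$theta), numeric(1))
  })
  expect_equal(z[[1]], z[[2]], tolerance = 1.5)
})

test_that("critical coupling matches the frozen default estimate", {
  p <- fixture_params()
  jc <- critical_jc(p, lower = 0.005, upper = 0.05, settle = 80,
                    rel_tol = 5e-3)
  expect_equal(jc, 0.014094, tolerance = 0.05)
})

test_that("state divergence is reported with a diagnostic", {
  p <- fixture_params()
  ker <- build_kernels(p)
  g <- 180 / p$N
  u0 <- matrix(1e200, p$N, 4)
  expect_error(
    mscann:::cann_run_cpp(u0, g * ker$W_rc, g * ker$W_rp_c, g * ker$W_rp_o,
                          numeric(p$N), numeric(p$N), p$I_b, 0, p$dt, p$tau,
                          p$omega, p$J_int, g, 10L, 1L, 1L, FALSE, FALSE),
    "diverged")
})
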