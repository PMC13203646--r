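test_that("scaled-linear schedule hits its endpoints with sqrt-beta affine in t", {
  s <- make_schedule(1000L, 0.0015, 0.0195)
  expect_equal(s$beta[1], 0.0015)
  expect_equal(s$beta[1000], 0.0195)
  d2 <- diff(diff(sqrt(s$beta)))
  expect_lt(max(abs(d2)), 1e-12)
  # invariants
  expect_true(all(diff(s$beta) >= 0))
  expect_true(all(s$beta > 0 & s$beta < 1))
  expect_true(all(diff(s$alpha_bar) < 0))
  expect_equal(s$alpha_bar, cumprod(s$alpha), tolerance = 1e-15)
  expect_equal(s$alpha_bar[1], s$alpha[1])

  s1 <- make_schedule(1L, 0.0015, 0.0195)
  expect_equal(s1$beta, 0.0015)
  expect_error(make_schedule(10, 0.5, 0.2), "beta")
  expect_error(make_schedule(10, 0, 0.1), "beta")
})

test_that("forward corruption follows the closed-form marginal", {
  s <- make_schedule(50L, 0.008, 0.20)
  set.seed(31)
  z0 <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  eps0 <- array(0, dim(z0))
  expect_equal(forward_sample(z0, 10, eps0, s), sqrt(s$alpha_bar[10]) * z0)
  eps <- array(rnorm(length(z0)), dim(z0))
  expect_equal(forward_sample(array(0, dim(z0)), 25, eps, s),
               sqrt(1 - s$alpha_bar[25]) * eps)
  expect_error(forward_sample(z0, 0, eps, s), "timestep")
  expect_error(forward_sample(z0, 51, eps, s), "timestep")
})

test_that("variance is preserved for unit-variance signals at every tested t", {
  s <- make_schedule(50L, 0.008, 0.20)
  n <- 1e5
  se_band <- 3 * sqrt(2 / (n - 1))
  set.seed(32)
  for (t in c(1, 10, 25, 50)) {
    zt <- forward_sample(rnorm(n), t, rnorm(n), s)
    expect_lt(abs(var(zt) - 1), se_band)
  }
})

test_that("training loss is the plain MSE", {
  expect_equal(training_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(training_loss(c(1, 2) + 1, c(1, 2)), 1)
  expect_equal(training_loss(c(0, 0), c(1, 3)), 5)
  expect_error(training_loss(c(1, 2), c(1, 2, 3)), "shape")
})

test_that("the posterior-mean chain inverts the forward mean process exactly", {
  set.seed(33)
  z0 <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  for (T_steps in c(10L, 50L)) {
    s <- make_schedule(T_steps, 0.008, 0.20)
    # single-step identity at t = 1 with the oracle predictor
    eps <- array(rnorm(length(z0)), dim(z0))
    z1 <- forward_sample(z0, 1, eps, s)
    orac1 <- (z1 - sqrt(s$alpha_bar[1]) * z0) / sqrt(1 - s$alpha_bar[1])
    expect_equal(reverse_step_printed(z1, 1, orac1, s), z0, tolerance = 1e-10)
    # full chain with the oracle predictor eps(z_t) telescopes back to z0
    z <- sqrt(s$alpha_bar[T_steps]) * z0
    for (t in seq(T_steps, 1)) {
      orac <- (z - sqrt(s$alpha_bar[t]) * z0) /
        sqrt(1 - s$alpha_bar[t])
      z <- reverse_step_printed(z, t, orac, s)
    }
    expect_lt(max(abs(z - z0)) / max(abs(z0)), 1e-8)
  }
  # eps_pred = 0 is a pure rescale
  s <- make_schedule(10L, 0.008, 0.20)
  zt <- array(rnorm(8), c(2, 2, 2, 1))
  expect_equal(reverse_step_printed(zt, 5, array(0, dim(zt)), s),
               zt / sqrt(s$alpha[5]))
})

test_that("ancestral step reduces to the mean form and bounds its variance", {
  s <- make_schedule(50L, 0.008, 0.20)
  set.seed(34)
  zt <- array(rnorm(24), c(2, 2, 2, 3))
  ep <- array(rnorm(24), dim(zt))
  nz <- array(rnorm(24), dim(zt))
  expect_identical(reverse_step_ancestral(zt, 1, ep, s, nz),
                   reverse_step_printed(zt, 1, ep, s))
  expect_equal(reverse_step_ancestral(zt, 30, ep, s, array(0, dim(zt))),
               reverse_step_printed(zt, 30, ep, s))
  beta_tilde <- c(0, (1 - s$alpha_bar[-s$T]) / (1 - s$alpha_bar[-1]) *
                    s$beta[-1])
  expect_true(all(beta_tilde <= s$beta + 1e-15))
})

test_that("condition assembly respects geometry and the chosen mode", {
  const_ct <- array(0.3, c(32, 32, 16))
  cond <- make_condition(const_ct, c(8, 8, 4))
  expect_identical(dim(cond), c(8L, 8L, 4L, 1L))
  expect_true(all(abs(cond - 0.3) < 1e-12))
  # full-profile bookkeeping: 96x96x64 -> 24x24x16
  big <- array(0, c(96, 96, 64))
  expect_identical(dim(make_condition(big, c(24, 24, 16)))[1:3],
                   c(24L, 24L, 16L))
  set.seed(35)
  ct <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  expect_identical(make_condition(ct, c(8, 8, 4)),
                   make_condition(ct, c(8, 8, 4)))
  v <- local({ set.seed(36); vae_init(c(8, 16, 16), 3) })
  ce <- make_condition(ct, c(8, 8, 4), "encoder", v)
  expect_identical(dim(ce), c(8L, 8L, 4L, 3L))
  expect_error(make_condition(ct, c(8, 8, 4), "encoder"), "stage-I")
})

test_that("PET sampling is seeded-deterministic and mode-sensitive", {
  set.seed(37)
  vae <- vae_init(c(8, 16, 16), 3)
  dn <- denoiser_init(c(8, 16, 16), 3, 3, 16, 4)
  dn$params$conv_out$w[] <- rnorm(length(dn$params$conv_out$w), sd = 0.05)
  s <- make_schedule(5L, 0.008, 0.20)
  ct <- volume3d(array(runif(16 * 16 * 16, -1, 1), c(16, 16, 16)), c(6, 6, 12),
                 "RAS", "normalized-CT")
  a <- sample_pet(dn, ct, s, vae, mode = "ancestral", seed = 99,
                  cond_mode = "encoder")
  b <- sample_pet(dn, ct, s, vae, mode = "ancestral", seed = 99,
                  cond_mode = "encoder")
  expect_identical(unclass(a), unclass(b))
  expect_true(all(a >= 0))
  expect_identical(vol_modality(a), "PET-SUV")
  p <- sample_pet(dn, ct, s, vae, mode = "printed", seed = 99,
                  cond_mode = "encoder")
  expect_false(identical(unclass(a), unclass(p)))
})
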