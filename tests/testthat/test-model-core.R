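# Agent-level rules: saturation kernel, moderated likelihood, behavior
# draw, saturating intention update.

test_that("saturation kernel vanishes at the bounds and peaks at 0.5", {
  expect_identical(saturation(0), 0)
  expect_identical(saturation(1), 0)
  expect_identical(saturation(0.5), 1)
  expect_equal(saturation(0.25), 0.75)
  # symmetric about 0.5
  I <- seq(0, 0.5, by = 0.01)
  expect_equal(saturation(I), saturation(1 - I))
  expect_error(saturation(1.01), "intention")
  expect_error(saturation(-0.2), "intention")
})

test_that("behavior likelihood follows the moderated form and its contract", {
  p <- model_params(beta_env = 0.2)
  # neutral perception: identity with intention
  expect_identical(behavior_likelihood(0.5, 0, p), 0.5)
  # moderation vanishes at the intention bound even at maximal beta
  expect_identical(behavior_likelihood(1, -1, model_params(beta_env = 0.25)), 1)
  expect_equal(behavior_likelihood(0.5, 1, p), 0.7)
  # defensive clamp outside the admissible beta range
  expect_warning(p_big <- model_params(beta_env = 0.4), "beta_env")
  expect_equal(suppressWarnings(behavior_likelihood(0.25, -1, p_big)), 0)
  expect_warning(behavior_likelihood(0.25, -1, p_big), "monotone")
  expect_error(behavior_likelihood(1.5, 0, p), "intention")
  expect_error(behavior_likelihood(0.5, 2, p), "perceived_env")
})

test_that("behavior draws are exact at the bounds and unbiased in the middle", {
  expect_identical(draw_behavior(rep(0, 100)), rep(0L, 100))
  expect_identical(draw_behavior(rep(1, 100)), rep(1L, 100))
  set.seed(42)
  m <- mean(draw_behavior(rep(0.5, 10000)))
  expect_lt(abs(m - 0.5), 3 * sqrt(0.25 / 10000))
  set.seed(7); a <- draw_behavior(rep(0.3, 50))
  set.seed(7); b <- draw_behavior(rep(0.3, 50))
  expect_identical(a, b)
})

test_that("intention update moves toward the social target without overshoot", {
  p <- model_params(w_self = 1, w_net = 1, w_com = 1, lam = 0.1)
  # absorbing bounds regardless of social input
  expect_identical(update_intention(0, 1, 1, 1, p), 0)
  expect_identical(update_intention(1, 0, 0, 0, p), 1)
  # fixed point at T = I
  expect_equal(update_intention(0.5, 1, 0.5, 0.25,
                                model_params(w_self = 1, w_net = 2,
                                             w_com = 2, lam = 0.5)), 0.5)
  # derived example: T = 1, lam = 0.1, sat(0.5) = 1
  expect_equal(update_intention(0.5, 1, 1, 1, p), 0.55)
  # contraction toward target, property over random cases
  set.seed(101)
  for (i in 1:200) {
    pars <- random_params()
    I <- stats::runif(1); b <- stats::rbinom(1, 1, 0.5)
    ne <- stats::runif(1); ce <- stats::runif(1)
    w <- pars$w_self + pars$w_net + pars$w_com
    target <- (pars$w_self * b + pars$w_net * ne + pars$w_com * ce) / w
    I2 <- update_intention(I, b, ne, ce, pars)
    expect_true(I2 >= 0 && I2 <= 1)
    expect_lte(abs(I2 - target), abs(I - target) + 1e-12)
    if (abs(target - I) > 1e-12) {
      expect_identical(sign(I2 - I), sign(target - I))
    }
  }
})

test_that("degenerate social weights are rejected", {
  expect_error(model_params(w_self = 0, w_net = 0, w_com = 0), "social weights")
  expect_error(model_params(lam = 0), "lam")
  expect_error(model_params(lam = 1.2), "lam")
  expect_error(model_params(w_net = -1), "w_net")
})
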