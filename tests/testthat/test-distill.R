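# Distillation math: softening, clamping, binary KL, per-teacher and
# averaged losses, and the penalized total.

test_that("soften applies temperature to teacher logits only", {
  expect_equal(soften(0, 5, "teacher"), 0.5)
  expect_equal(soften(0, 5, "student"), 0.5)
  expect_equal(soften(2, 2, "teacher"), 1 / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(soften(2, 2, "student"), 1 / (1 + exp(-2)), tolerance = 1e-9)
  expect_lt(abs(soften(2, 1e6, "teacher") - 0.5), 1e-5)
  expect_error(soften(1, 0), "temperature")
})

test_that("clamp_probs bounds values and leaves the interior alone", {
  eps <- 1e-7
  expect_equal(clamp_probs(0, eps), eps)
  expect_equal(clamp_probs(1, eps), 1 - eps)
  expect_equal(clamp_probs(0.5, eps), 0.5)
  x <- seq(0, 1, by = 0.05)
  cx <- clamp_probs(x, eps)
  expect_true(all(cx >= eps & cx <= 1 - eps))
  inside <- x > eps & x < 1 - eps
  expect_equal(cx[inside], x[inside])
})

test_that("kl_binary matches the closed-form oracle and is asymmetric", {
  expect_equal(kl_binary(0.75, 0.5), kl_ref(0.75, 0.5), tolerance = 1e-12)
  expect_equal(kl_binary(0.75, 0.5), 0.130812, tolerance = 1e-6)
  expect_equal(kl_binary(0.5, 0.75), 0.143841, tolerance = 1e-6)
  expect_gt(abs(kl_binary(0.75, 0.5) - kl_binary(0.5, 0.75)), 1e-3)
  p <- random_prob_map(49, 9)
  expect_equal(kl_binary(p, p), p * 0)
})

test_that("kl_binary is non-negative on a dense clamped grid", {
  g <- seq(1e-7, 1 - 1e-7, length.out = 101)
  grid <- expand.grid(pt = g, ps = g)
  v <- kl_binary(grid$pt, grid$ps)
  expect_true(all(v >= -1e-12))
  expect_true(all(is.finite(v)))
})

test_that("distillation_loss reduces correctly", {
  cfg <- distill_config(temperature = 1)
  z <- matrix(rnorm(64), 8)
  expect_lt(distillation_loss(z, z, cfg), 1e-10)
  # single pixel: z_t = ln 3 at T = 1 -> p_t = 0.75 vs p_s = 0.5
  expect_equal(distillation_loss(matrix(log(3)), matrix(0), cfg),
               0.130812, tolerance = 1e-6)
  set.seed(4)
  for (i in 1:20) {
    zt <- matrix(rnorm(25, sd = 3), 5)
    zs <- matrix(rnorm(25, sd = 3), 5)
    expect_gte(distillation_loss(zt, zs, distill_config(temperature = runif(1, 0.5, 8))), 0)
  }
  expect_error(distillation_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("distillation_loss is invariant under joint spatial permutation", {
  set.seed(11)
  zt <- matrix(rnorm(36), 6); zs <- matrix(rnorm(36), 6)
  perm <- sample(36)
  zt2 <- zt; zt2[] <- zt[perm]
  zs2 <- zs; zs2[] <- zs[perm]
  cfg <- distill_config()
  expect_equal(distillation_loss(zt2, zs2, cfg), distillation_loss(zt, zs, cfg),
               tolerance = 1e-12)
})

test_that("high-temperature limit approaches the uniform teacher", {
  set.seed(12)
  zt <- matrix(rnorm(64, sd = 2), 8)
  zs <- matrix(rnorm(64, sd = 2), 8)
  hi <- distillation_loss(zt, zs, distill_config(temperature = 1e6))
  unif <- mean(kl_binary(clamp_probs(matrix(0.5, 8, 8)), clamp_probs(sigmoid(zs))))
  expect_equal(hi, unif, tolerance = 1e-4)
})

test_that("avg_distillation_loss is the arithmetic mean", {
  expect_equal(avg_distillation_loss(0.7), 0.7)
  expect_equal(avg_distillation_loss(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(avg_distillation_loss(rep(0.42, 3)), 0.42)
  expect_error(avg_distillation_loss(numeric(0)), "at least one")
})

test_that("total_student_loss follows the penalized weighting", {
  cfg <- distill_config(alpha = 0.5, penalty = 1)
  expect_equal(total_student_loss(0.2, 0.4, cfg)$total, 0.3)
  cfg10 <- distill_config(alpha = 0.5, penalty = 10)
  expect_equal(total_student_loss(0.2, 0.4, cfg10)$total, 0.1 + 2.0)
  expect_equal(total_student_loss(0.2, 99, distill_config(alpha = 1))$total, 0.2)
  expect_equal(total_student_loss(99, 0.4, distill_config(alpha = 0))$total, 0.4)
  # linearity in each argument
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1); h <- runif(1); s <- runif(2, 1, 3)
    cfg <- distill_config(alpha = runif(1), penalty = 1 + runif(1) * 19)
    expect_equal(total_student_loss(s[1] * a, s[2] * h, cfg)$total,
                 cfg$alpha * s[1] * a + (1 - cfg$alpha) * cfg$penalty * s[2] * h,
                 tolerance = 1e-12)
  }
})

test_that("distill_config validates its fields", {
  expect_error(distill_config(temperature = 0), "temperature")
  expect_error(distill_config(alpha = 1.2), "alpha")
  expect_error(distill_config(epsilon = 0.7), "epsilon")
  expect_error(distill_config(penalty = 0.5), "penalty")
  expect_error(distill_config(teacher_roles = character(0)), "teacher")
})

test_that("distillation gradient matches finite differences", {
  set.seed(21)
  zt <- matrix(rnorm(16, sd = 2), 4)
  zs <- matrix(rnorm(16, sd = 2), 4)
  for (cfg in list(distill_config(temperature = 3),
                   distill_config(temperature = 2, scale_student = TRUE))) {
    g <- vesselkd:::distillation_grad(zt, zs, cfg)
    for (j in c(2, 9)) {
      zp <- zs; zp[j] <- zp[j] + 1e-6
      zm <- zs; zm[j] <- zm[j] - 1e-6
      num <- (distillation_loss(zt, zp, cfg) - distillation_loss(zt, zm, cfg)) / 2e-6
      expect_equal(g[j], num, tolerance = 1e-5)
    }
  }
})
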