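# Loss zoo: frozen hand-computed values, reduction identities, and
# finite-difference checks of the analytic gradients.

test_that("bce_loss matches closed-form values", {
  expect_equal(bce_loss(matrix(0.5), matrix(1)), log(2), tolerance = 1e-9)
  y <- random_mask(100, seed = 2)
  expect_equal(bce_loss(matrix(0.5, 10, 10), y), log(2), tolerance = 1e-9)
  # perfect prediction after clamping is ~0
  expect_lt(bce_loss(y, y), 1e-5)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("dice and soft-dice match hand-computed sums", {
  p <- c(1, 1, 0, 0); y <- c(1, 0, 1, 0)
  expect_equal(dice_loss(p, y, smooth = 1), 1 - 3 / 5)
  # soft variant: denominator sum(p^2) + sum(y^2) + 1 = 2 + 2 + 1
  expect_equal(soft_dice_loss(p, y, smooth = 1), 1 - 3 / 5)
  p2 <- c(0.5, 0.5); y2 <- c(1, 0)
  expect_equal(soft_dice_loss(p2, y2, smooth = 1),
               1 - (2 * 0.5 + 1) / (0.5 + 1 + 1))
  expect_equal(dice_loss(y, y, smooth = 1), 0)
  expect_equal(dice_loss(numeric(4) , numeric(4), smooth = 1), 0)
})

test_that("tversky matches direct substitution and reduces to dice", {
  # soft counts TP = 1, FP = 1, FN = 1
  p <- c(1, 1, 0); y <- c(1, 0, 1)
  expect_equal(tversky_loss(p, y, 0.7, 0.3, smooth = 1), 1 - 2 / 3,
               tolerance = 1e-9)
  # with additive smoothing s the symmetric Tversky equals Dice at smooth
  # 2s (multiply numerator and denominator by 2); at s = 0 they coincide
  expect_equal(tversky_loss(p, y, 0.5, 0.5, smooth = 1),
               dice_loss(p, y, smooth = 2), tolerance = 1e-12)
  expect_equal(tversky_loss(p, y, 0.5, 0.5, smooth = 0),
               dice_loss(p, y, smooth = 0), tolerance = 1e-12)
  expect_equal(tversky_loss(y, y), 0)
})

test_that("focal loss closed form and gamma = 0 reduction", {
  expect_equal(focal_loss(matrix(0.5), matrix(1), gamma = 2),
               0.25 * log(2), tolerance = 1e-9)
  expect_lt(focal_loss(matrix(c(0, 1)), matrix(c(0, 1)), gamma = 2), 1e-5)
})

test_that("reduction identities hold on 100 random maps", {
  for (s in 1:100) {
    p <- random_prob_map(36, seed = s)
    y <- random_mask(36, seed = s + 1000)
    expect_equal(tversky_loss(p, y, 0.5, 0.5, smooth = 0),
                 dice_loss(p, y, smooth = 0), tolerance = 1e-12)
    expect_equal(tversky_loss(p, y, 0.5, 0.5, smooth = 1),
                 dice_loss(p, y, smooth = 2), tolerance = 1e-12)
    expect_equal(focal_loss(p, y, gamma = 0), bce_loss(p, y), tolerance = 1e-12)
    expect_equal(focal_tversky_loss(p, y, gamma = 1),
                 tversky_loss(p, y), tolerance = 1e-12)
  }
})

test_that("composites equal the sum of their separately computed parts", {
  p <- matrix(c(1, 1, 0, 0), 2); y <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(dice_bce_loss(p, y), bce_loss(p, y) + dice_loss(p, y))
  expect_equal(combined_loss(p, y), dice_bce_loss(p, y))
  expect_equal(combo_loss(p, y, w = 1), bce_loss(p, y))
  expect_equal(combo_loss(p, y, w = 0), dice_loss(p, y))
  expect_equal(combo_loss(p, y, w = 0.3),
               0.3 * bce_loss(p, y) + 0.7 * dice_loss(p, y))
})

test_that("all losses are >= 0, ~0 at p = y, and permutation invariant", {
  handles <- lapply(vesselkd:::LOSS_NAMES, make_loss)
  for (s in 1:20) {
    p <- random_prob_map(49, seed = s)
    y <- random_mask(49, seed = s + 500)
    set.seed(s + 900)
    perm <- sample(length(p))
    pp <- p; pp[] <- p[perm]
    yy <- y; yy[] <- y[perm]
    for (h in handles) {
      v <- h$fn(p, y)
      expect_gte(v, 0)
      expect_true(is.finite(v))
      expect_equal(h$fn(pp, yy), v, tolerance = 1e-12)
      expect_lt(h$fn(y, y), 1e-4)
    }
    # finite at exact 0/1 probabilities after clamping
    for (h in handles) expect_true(is.finite(h$fn(y, 1 - y)))
  }
})

test_that("analytic gradients match finite differences", {
  for (nm in vesselkd:::LOSS_NAMES) {
    h <- make_loss(nm)
    set.seed(42)
    p <- matrix(runif(16, 0.05, 0.95), 4)
    y <- matrix(rbinom(16, 1, 0.5), 4)
    g <- h$grad(p, y)
    eps <- 1e-6
    for (j in c(1, 7, 16)) {
      pp <- p; pp[j] <- pp[j] + eps
      pm <- p; pm[j] <- pm[j] - eps
      num <- (h$fn(pp, y) - h$fn(pm, y)) / (2 * eps)
      expect_equal(g[j], num, tolerance = 1e-4,
                   label = sprintf("%s grad[%d]", nm, j))
    }
  }
})

test_that("make_loss dispatches and rejects unknown names", {
  h <- make_loss("DiceBCELoss")
  p <- random_prob_map(25, 3); y <- random_mask(25, 4)
  expect_equal(h$fn(p, y), dice_bce_loss(p, y))
  expect_equal(make_loss("BCE")$fn(p, y), bce_loss(p, y))
  expect_error(make_loss("FooLoss"), "DiceLoss.*FocalTverskyLoss")
  expect_error(loss_config(combo_weight = 2), "combo_weight")
  expect_error(loss_config(tversky_alpha = -1, tversky_beta = 0), "positive")
})
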