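test_that("adaptive fusion weights live on the simplex and renormalize", {
  v <- c(1, 2); t_ <- c(3, 4); a <- c(5, 6)
  eq <- adaptiveWeightedFusion(v, t_, a, logits = c(0, 0, 0))
  expect_equal(unname(eq$weights), rep(1 / 3, 3))
  expect_equal(eq$fused, (v + t_ + a) / 3)
  # masking one modality renormalizes over the remaining two
  two <- adaptiveWeightedFusion(v, t_, NULL, logits = c(0, 0, 0))
  expect_equal(unname(two$weights), c(0.5, 0.5, 0))
  expect_equal(sum(two$weights), 1)
  # identical features: fused equals them for any weights
  set.seed(1)
  idf <- adaptiveWeightedFusion(v, v, v, logits = rnorm(3))
  expect_equal(idf$fused, v, tolerance = 1e-12)
  expect_error(adaptiveWeightedFusion(NULL, NULL, NULL), "no available")
  # random logits stay on the simplex
  for (i in 1:20) {
    w <- adaptiveWeightedFusion(v, t_, a, logits = rnorm(3))$weights
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("cross-modal fusion gates and bounds as specified", {
  d <- 3L
  v <- c(1, -1, 2); t_ <- c(0, 1, 1); a <- c(2, 2, -1)
  zero <- list(W_alpha = matrix(0, 2, 2 * d), b_alpha = c(0, 0),
               W_psi = matrix(0, d, 2 * d), b_psi = rep(0, d))
  out <- crossModalFuse(v, t_, a, zero)
  expect_equal(out$alpha, c(0.5, 0.5))
  expect_equal(out$F_vt, (v + t_) / 2)
  expect_equal(out$F_joint, rep(0, d))
  set.seed(6)
  rnd <- list(W_alpha = matrix(rnorm(2 * 2 * d), 2), b_alpha = rnorm(2),
              W_psi = matrix(rnorm(d * 2 * d), d), b_psi = rnorm(d))
  out2 <- crossModalFuse(v, t_, a, rnd)
  expect_true(all(out2$F_joint > -1 & out2$F_joint < 1))
  expect_equal(sum(out2$alpha), 1, tolerance = 1e-12)
  expect_error(crossModalFuse(v, t_, c(1, 2), rnd), "equal length")
})

test_that("the alignment loss counts ordered pairs of normalized features", {
  f <- c(0.2, -0.7, 1.1)
  expect_equal(alignmentLoss(list(f, f, f)), 0)
  expect_equal(alignmentLoss(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))), 12)
  # invariant to positive rescaling of any feature
  g <- c(1, 2, 2)
  base <- alignmentLoss(list(f, g))
  expect_equal(alignmentLoss(list(5 * f, g)), base, tolerance = 1e-12)
  expect_equal(alignmentLoss(list(f, 0.1 * g)), base, tolerance = 1e-12)
  expect_error(alignmentLoss(list(f)), "at least two")
  expect_error(alignmentLoss(list(f, c(0, 0, 0))), "zero vector")
})

test_that("attention reweighting produces a simplex over feature dimensions", {
  d <- 4L
  fj <- c(1, -2, 0.5, 3)
  zero <- list(W_a = matrix(0, d, d), b_a = rep(0, d))
  out <- attentionReweight(fj, zero)
  expect_equal(out$alpha, rep(1 / d, d))
  expect_equal(out$F_attn, fj / d)
  set.seed(8)
  rnd <- list(W_a = matrix(rnorm(d * d), d), b_a = rnorm(d))
  out2 <- attentionReweight(fj, rnd)
  expect_true(all(out2$alpha >= 0))
  expect_equal(sum(out2$alpha), 1, tolerance = 1e-6)
  # a dominant bias concentrates the attention there
  conc <- attentionReweight(fj, list(W_a = matrix(0, d, d),
                                     b_a = c(50, 0, 0, 0)))
  expect_gt(conc$alpha[1], 1 - 1e-12)
})

test_that("the risk head is bounded and monotone in its bias", {
  params <- list(W_s = rep(0, 5), b_s = 0)
  out <- riskScore(rep(1, 3), rep(1, 2), params)
  expect_equal(out$score, 0)
  expect_equal(out$probability, 0.5)
  set.seed(9)
  for (i in 1:20) {
    p <- list(W_s = rnorm(5), b_s = rnorm(1))
    pr <- riskScore(rnorm(3), rnorm(2), p)$probability
    expect_true(pr > plogis(-1) && pr < plogis(1))
  }
  ps <- vapply(c(-2, 0, 2), function(b)
    riskScore(rep(0.3, 3), rep(0.1, 2), list(W_s = rep(1, 5), b_s = b))$probability, 1)
  expect_true(all(diff(ps) > 0))
})

test_that("the focal risk loss matches its printed form", {
  expect_equal(focalRiskLoss(0.9, 1, 2), 0.01 * (-log(0.9)), tolerance = 1e-9)
  expect_equal(focalRiskLoss(0.9, 0, 2), 0.81 * (-log(0.1)), tolerance = 1e-9)
  # gamma = 0 reduces exactly to binary cross-entropy on a grid
  grid <- expand.grid(P = seq(0.01, 0.99, length.out = 50), y = c(0, 1))
  expect_equal(focalRiskLoss(grid$P, grid$y, 0), bceLoss(grid$P, grid$y),
               tolerance = 1e-9)
  expect_error(focalRiskLoss(0.5, 1, -1), "gamma")
})

test_that("the recurrent unit is bounded and contracts to a fixed point", {
  d <- 2L; h <- 3L
  zero <- list(W_h = matrix(0, h, h), W_x = matrix(0, h, d), b_h = rep(0, h),
               W_o = rep(0, h), b_o = 0)
  st <- recurrentStep(rep(0, h), rep(0, d), zero)
  expect_equal(st$H, rep(0, h))
  expect_equal(st$y, 0.5)
  set.seed(10)
  params <- list(W_h = matrix(rnorm(h * h, 0, 0.2), h),   # contraction
                 W_x = matrix(rnorm(h * d, 0, 0.3), h),
                 b_h = rnorm(h, 0, 0.1), W_o = rnorm(h), b_o = 0.2)
  x <- c(0.5, -1)
  H <- rep(0, h)
  for (i in 1:200) {
    st <- recurrentStep(H, x, params)
    expect_true(all(abs(st$H) < 1))
    Hnew <- st$H
    if (i > 1 && max(abs(Hnew - H)) < 1e-12) break
    H <- Hnew
  }
  # converged to a fixed point of the update
  expect_equal(recurrentStep(H, x, params)$H, H, tolerance = 1e-10)
})

test_that("hierarchical combination is linear in each argument", {
  a <- matrix(1:4, 2); b <- matrix(5:8, 2)
  expect_equal(hierarchicalCombine(a, b, 1, 0), a)
  expect_equal(hierarchicalCombine(a, a, 0.5, 0.5), a)
  expect_equal(hierarchicalCombine(2 * a, b, 0.3, 0.7),
               2 * hierarchicalCombine(a, b, 0.3, 0) +
                 hierarchicalCombine(a * 0, b, 0, 0.7))
  expect_error(hierarchicalCombine(a, matrix(1:6, 2), 1, 1), "identical shape")
})

test_that("the benchmark configuration activates no extension unit", {
  expect_identical(activeExtensions(modelConfig(), trainConfig()), character(0))
  expect_identical(activeExtensions(tinyModelConfig(), tinyTrainConfig()),
                   character(0))
})
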