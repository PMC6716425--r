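# The composite loss: w_D * E_i[(-ln Dice_i)^gamma] + w_C * E_x[-ln p_l(x)].

test_that("soft Dice matches direct summation oracles", {
  sh <- c(4, 4, 2)
  truth <- array(0L, sh)
  truth[1:4] <- 1L  # 4 voxels of label 1
  # probs assign p_1 = 1 on exactly 2 of them: Dice = 2*2/(4+2) = 2/3
  probs <- array(0, dim = c(sh, 2))
  probs[, , , 1] <- 1
  p1 <- array(0, sh); p1[1:2] <- 1
  probs[, , , 2] <- p1
  probs[, , , 1] <- 1 - p1
  expect_equal(dice_per_label(probs, truth, 1L), 2 / 3, tolerance = 1e-6)

  # perfect one-hot overlap -> 1; disjoint nonempty -> 0
  oh <- one_hot(truth, 2)
  expect_equal(dice_per_label(oh, truth, 1L), 1, tolerance = 1e-6)
  flipped <- array(0L, sh); flipped[5:8] <- 1L
  expect_equal(dice_per_label(one_hot(flipped, 2), truth, 1L), 0,
               tolerance = 1e-5)
})

test_that("composite loss vanishes on perfect predictions and scales with weights", {
  set.seed(31)
  sh <- c(6, 5, 4)
  truth <- array(sample(0:3, prod(sh), TRUE), sh)
  oh <- one_hot(truth, 4)
  lc <- loss_config(include_background = TRUE)
  expect_equal(composite_loss(oh, truth, lc), 0, tolerance = 1e-4)

  probs <- random_probs(sh, 4, seed = 8)
  l1 <- composite_loss(probs, truth, loss_config(0.8, 0.2, 0.3))
  l2 <- composite_loss(probs, truth, loss_config(1.6, 0.4, 0.3))
  expect_equal(l2, 2 * l1, tolerance = 1e-10)
  expect_gt(l1, 0)
})

test_that("loss equals 1.0 when every Dice_i and p_l(x) equal exp(-1) at the reference weights", {
  # constructed field: p on the truth channel = e^-1 everywhere; off-truth
  # mass per channel tuned so that Dice_i = e^-1 exactly
  sh <- c(10, 10, 10)
  N <- prod(sh); t <- N / 2
  truth <- array(rep(0:1, each = t), sh)
  e1 <- exp(-1)
  off <- t * (1 - e1) / (N - t)  # per-voxel off-truth mass
  probs <- array(0, dim = c(sh, 2))
  probs[, , , 1] <- ifelse(truth == 0, e1, off)
  probs[, , , 2] <- ifelse(truth == 1, e1, off)
  expect_equal(dice_per_label(probs, truth, 0L), e1, tolerance = 1e-5)
  expect_equal(dice_per_label(probs, truth, 1L), e1, tolerance = 1e-5)
  lc <- loss_config(w_D = 0.8, w_C = 0.2, gamma = 0.3,
                    include_background = TRUE)
  expect_equal(composite_loss(probs, truth, lc), 1.0, tolerance = 1e-4)
})

test_that("analytic loss gradient matches central finite differences", {
  set.seed(17)
  sh <- c(4, 4, 3)
  truth <- array(sample(0:2, prod(sh), TRUE), sh)
  probs <- random_probs(sh, 3, seed = 5)
  lc <- loss_config(0.8, 0.2, 0.3)
  g <- composite_loss_grad(probs, truth, lc)
  h <- 1e-6
  idx <- sample(length(probs), 50)
  for (k in idx) {
    up <- probs; up[k] <- up[k] + h
    dn <- probs; dn[k] <- dn[k] - h
    fd <- (composite_loss(up, truth, lc) -
             composite_loss(dn, truth, lc)) / (2 * h)
    expect_equal(g[k], fd, tolerance = 1e-4)
  }
})

test_that("dice is invariant under a joint voxel permutation", {
  set.seed(23)
  sh <- c(5, 4, 3)
  truth <- array(sample(0:2, prod(sh), TRUE), sh)
  probs <- random_probs(sh, 3, seed = 2)
  perm <- sample(prod(sh))
  truth_p <- array(as.vector(truth)[perm], sh)
  probs_p <- probs
  for (c in 1:3) probs_p[, , , c] <- array(as.vector(probs[, , , c])[perm], sh)
  for (i in 0:2) {
    expect_equal(dice_per_label(probs_p, truth_p, i),
                 dice_per_label(probs, truth, i), tolerance = 1e-12)
  }
})

test_that("degenerate label/probability combinations stay finite", {
  sh <- c(3, 3, 3)
  truth <- array(0L, sh)  # label 1 absent
  probs <- array(0, dim = c(sh, 2))
  probs[, , , 1] <- 1     # and p_1 = 0 everywhere: 0/0 Dice
  d <- dice_per_label(probs, truth, 1L)
  expect_true(is.finite(d))
  expect_equal(d, 1, tolerance = 1e-5)  # empty vs empty: smoothed to 1
  l <- composite_loss(probs, truth, loss_config())
  expect_true(is.finite(l))
})
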