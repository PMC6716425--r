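test_that("network output is a valid probability field of the right shape", {
  cfg <- segnet_config(channels = c(2, 3), layers = 1, n_labels = 4,
                       input_roi = c(8, 8, 8))
  net <- build_segnet(cfg, seed = 3)
  x <- array(stats::rnorm(8^3), dim = c(8, 8, 8, 1))
  fw <- pdstriatum:::segnet_forward(net, x)
  expect_equal(dim(fw$logits[[1]]), c(8, 8, 8, 4))
  probs <- softmax_probs(fw$logits[[1]])
  expect_true(all(is.finite(probs)))
  expect_true(all(probs >= 0 & probs <= 1))
  sums <- apply(probs, 1:3, sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-12)
  # auxiliary deep-supervision head at the coarser level
  expect_equal(dim(fw$logits[[2]]), c(4, 4, 4, 4))
})

test_that("parameter count grows with width and the ROI contract is enforced", {
  n1 <- n_params(build_segnet(segnet_config(channels = c(2, 4),
                                            input_roi = c(8, 8, 8)), 1))
  n2 <- n_params(build_segnet(segnet_config(channels = c(4, 4),
                                            input_roi = c(8, 8, 8)), 1))
  expect_gt(n2, n1)
  expect_error(segnet_config(channels = c(2, 4, 8), input_roi = c(10, 10, 10)),
               "divisible")
  expect_error(pdstriatum:::crop_roi(array(0, c(8, 8, 8)), c(16, 16, 16)),
               "axis")
})

test_that("whole-network analytic gradients match finite differences", {
  cfg <- segnet_config(channels = c(2, 3), layers = 2, n_labels = 3,
                       input_roi = c(8, 8, 8))
  net <- build_segnet(cfg, seed = 4)
  set.seed(6)
  x <- array(stats::rnorm(8^3), dim = c(8, 8, 8, 1))
  truth <- array(sample(0:2, 8^3, TRUE), dim = c(8, 8, 8))
  lc <- loss_config()
  total_loss <- function(net) {
    fw <- pdstriatum:::segnet_forward(net, x)
    sum(vapply(seq_len(cfg$depth), function(l) {
      tl <- pdstriatum:::subsample_labels(truth, l)
      cfg$deep_supervision_weights[l] *
        composite_loss(softmax_probs(fw$logits[[l]]), tl, lc)
    }, numeric(1)))
  }
  fw <- pdstriatum:::segnet_forward(net, x)
  gl <- lapply(seq_len(cfg$depth), function(l) {
    tl <- pdstriatum:::subsample_labels(truth, l)
    cfg$deep_supervision_weights[l] *
      pdstriatum:::composite_loss_logits(fw$logits[[l]], tl, lc)$grad
  })
  grads <- pdstriatum:::segnet_backward(net, fw$cache, gl)
  h <- 1e-5
  set.seed(7)
  for (nm in sample(names(net$params), 12)) {
    k <- sample(length(net$params[[nm]]), 1)
    up <- net; up$params[[nm]][k] <- up$params[[nm]][k] + h
    dn <- net; dn$params[[nm]][k] <- dn$params[[nm]][k] - h
    fd <- (total_loss(up) - total_loss(dn)) / (2 * h)
    expect_equal(grads[[nm]][k], fd, tolerance = 1e-4)
  }
})

test_that("training is deterministic and inert at zero learning rate", {
  cfg <- small_exact_config()
  s <- generate_subject(cfg, "NL", "t", seed = 2)
  scfg <- segnet_config(channels = c(2, 4), layers = 1, n_labels = 8,
                        input_roi = c(16, 16, 16))
  net <- build_segnet(scfg, seed = 1)
  f0 <- train_segnet(net, list(s), epochs = 3, lr = 0, seed = 5,
                     augment = FALSE)
  expect_equal(diff(range(f0$loss)), 0, tolerance = 1e-12)
  f1 <- train_segnet(net, list(s), epochs = 3, lr = 1e-3, seed = 5,
                     augment = TRUE)
  f2 <- train_segnet(net, list(s), epochs = 3, lr = 1e-3, seed = 5,
                     augment = TRUE)
  expect_identical(f1$loss, f2$loss)
  expect_lt(f1$loss[3], f1$loss[1])
})

test_that("predictions only contain dictionary labels and break ties low", {
  cfg <- segnet_config(channels = c(2, 3), layers = 1, n_labels = 8,
                       input_roi = c(8, 8, 8))
  net <- build_segnet(cfg, seed = 2)
  # zero out the final head so every label is tied: argmax must pick 0
  net$params[["head1.w"]][] <- 0
  net$params[["head1.b"]][] <- 0
  mr <- image_volume(array(stats::rnorm(12^3), c(12, 12, 12)),
                     spacing = c(1, 1, 1))
  pred <- predict_segnet(net, mr)
  expect_true(all(pred$data == 0L))
  net2 <- build_segnet(cfg, seed = 2)
  pred2 <- predict_segnet(net2, mr)
  expect_true(all(pred2$data %in% 0:7))
})

test_that("hard DSC evaluation matches voxel-count oracles", {
  lab <- function(arr) label_map(arr, c(1, 1, 1), c(0, 0, 0))
  truth <- array(0L, c(6, 6, 6))
  truth[2:5, 2:5, 2:3] <- 1L  # a 2-voxel-thick slab, 32 voxels
  pred <- array(0L, c(6, 6, 6))
  pred[2:5, 2:5, 2] <- 1L     # half-eroded: 16 voxels, all inside truth
  d <- evaluate_dsc(lab(pred), lab(truth), labels = c(caudate_R = 1L))
  expect_equal(unname(d), 2 * 16 / (16 + 32), tolerance = 1e-12)
  expect_equal(unname(evaluate_dsc(lab(truth), lab(truth),
                                   labels = c(x = 1L))), 1)
  empty <- array(0L, c(6, 6, 6))
  expect_equal(unname(evaluate_dsc(lab(empty), lab(truth),
                                   labels = c(x = 1L))), 0)
  expect_error(evaluate_dsc(lab(empty),
                            label_map(array(0L, c(5, 5, 5)),
                                      c(1, 1, 1), c(0, 0, 0))),
               "grids differ")
})

test_that("checkpoints survive a JSON save/load round-trip", {
  cfg <- segnet_config(channels = c(2, 3), layers = 1, n_labels = 4,
                       input_roi = c(8, 8, 8))
  net <- build_segnet(cfg, seed = 9)
  path <- withr::local_tempfile(fileext = ".json.gz")
  save_segnet(net, path)
  net2 <- load_segnet(path)
  x <- array(stats::rnorm(8^3), dim = c(8, 8, 8, 1))
  f1 <- pdstriatum:::segnet_forward(net, x)$logits[[1]]
  f2 <- pdstriatum:::segnet_forward(net2, x)$logits[[1]]
  expect_equal(f1, f2, tolerance = 1e-12)
})
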