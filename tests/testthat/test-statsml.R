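# Synthetic feature tables built directly (no imaging) keep these tests fast.
make_table <- function(n_pd = 20, n_nl = 20, shift = NULL, sd_shift = 0,
                       seed = 1) {
  set.seed(seed)
  n <- n_pd + n_nl
  X <- matrix(stats::rnorm(n * 90), n, 90,
              dimnames = list(NULL, feature_names()))
  groups <- c(rep("PD", n_pd), rep("NL", n_nl))
  if (!is.null(shift)) X[groups == "PD", shift] <- X[groups == "PD", shift] +
      sd_shift
  out <- data.frame(id = sprintf("s%02d", seq_len(n)), group = groups, X,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

test_that("per-feature Welch t-tests agree with stats::t.test", {
  tab <- make_table(15, 9, shift = feature_names()[1:4], sd_shift = 1.5,
                    seed = 3)
  sel <- select_features(tab, alpha = 0.01)
  X <- tab[, feature_names()]
  for (f in feature_names()[c(1, 2, 40, 90)]) {
    ref <- stats::t.test(X[tab$group == "NL", f], X[tab$group == "PD", f])
    expect_equal(unname(sel$p_values[f]), ref$p.value, tolerance = 1e-12)
  }
  expect_length(select_features(tab, alpha = 0)$selected, 0)
})

test_that("an extreme shifted feature is always selected; zero-variance ones are excluded", {
  tab <- make_table(20, 20, shift = "putamen_R_sub3_mean_SOR",
                    sd_shift = 10, seed = 7)
  sel <- select_features(tab)
  expect_true("putamen_R_sub3_mean_SOR" %in% sel$selected)
  tab$caudate_R_volume <- 5
  expect_warning(sel2 <- select_features(tab), "zero variance")
  expect_true(is.na(sel2$p_values["caudate_R_volume"]))
  expect_false("caudate_R_volume" %in% sel2$selected)
})

test_that("type-I error of the selection is calibrated at alpha under the null", {
  # both groups identical; fraction of features passing p < 0.01 across
  # replicates must approach 0.01 (group sizes mirror the 49/18 design)
  alpha <- 0.01
  reps <- 400
  frac <- vapply(seq_len(reps), function(r) {
    tab <- make_table(49, 18, seed = 1000 + r)
    length(select_features(tab, alpha)$selected) / 90
  }, numeric(1))
  expect_lt(abs(mean(frac) - alpha), 0.005)
})

test_that("the linear SVM separates separable groups and rejects constants", {
  tab <- make_table(12, 12, shift = feature_names()[1:5], sd_shift = 8,
                    seed = 2)
  model <- train_svm(tab, feature_names()[1:5])
  expect_equal(mean(predict(model, tab) == tab$group), 1)
  tab2 <- make_table(8, 8, seed = 3)
  tab2[[feature_names()[1]]] <- 1
  expect_error(train_svm(tab2, feature_names()[1]), "constant")
  expect_error(train_svm(tab, character(0)), "no selected features")
})

test_that("leave-n-out bookkeeping holds and separable cohorts classify perfectly", {
  tab <- make_table(20, 12, shift = feature_names()[1:6], sd_shift = 6,
                    seed = 5)
  cv1 <- leave_n_out_cv(tab, n = 1)
  expect_equal(cv1$acc_mean, 1)
  expect_equal(cv1$wrong_mean, 0)
  expect_equal(cv1$n_partitions, nrow(tab))
  cv3 <- leave_n_out_cv(tab, n = 3, n_partitions = 40, seed = 2)
  expect_equal(cv3$wrong_mean, 3 * (1 - cv3$acc_mean), tolerance = 1e-12)
  expect_true(cv3$acc_mean >= 0 && cv3$acc_mean <= 1)
})

test_that("label permutation drives CV accuracy to chance (no leakage)", {
  # with leakage, selecting on all rows before CV would inflate accuracy
  # well above the majority-class rate even for pure noise
  tab <- make_table(18, 12, seed = 11)
  set.seed(99)
  tab$group <- sample(tab$group)
  cv <- leave_n_out_cv(tab, n = 1)
  expect_lt(cv$acc_mean, 0.75)  # majority class = 0.6; allow noise
})

test_that("random-forest importances are normalised and track informative features", {
  tab <- make_table(25, 25, shift = c("putamen_R_sub3_mean_SOR",
                                      "putamen_L_sub3_mean_SOR"),
                    sd_shift = 5, seed = 13)
  imp <- rf_importance(tab, seed = 1, ntree = 150)
  expect_equal(sum(imp$per_feature), 1, tolerance = 1e-9)
  expect_equal(nrow(imp$by_statistic), 7)
  top <- names(sort(imp$per_feature, decreasing = TRUE))[1:2]
  expect_setequal(top, c("putamen_R_sub3_mean_SOR",
                         "putamen_L_sub3_mean_SOR"))
  # pure-noise features stay near zero
  expect_lt(max(imp$per_feature[!names(imp$per_feature) %in% top]), 0.05)
  imp2 <- rf_importance(tab, seed = 1, include_volume = FALSE, ntree = 60)
  expect_equal(nrow(imp2$by_statistic), 6)
  expect_false("volume" %in% imp2$by_statistic$statistic)
  imp3 <- rf_importance(tab, seed = 1, ntree = 150)
  expect_identical(imp$per_feature, imp3$per_feature)
})

test_that("comparing an arm with itself yields identical curves and p = 1", {
  tab <- make_table(16, 10, shift = feature_names()[1:4], sd_shift = 6,
                    seed = 17)
  cmp <- compare_arms(tab, tab, ns = 1:3, n_partitions = 25, seed = 5)
  expect_equal(cmp$wrong_a, cmp$wrong_b, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_arms(tab, tab[nrow(tab):1, ], ns = 1),
               "same subjects")
})

test_that("transfer accuracy trains on one arm and scores another", {
  a <- make_table(15, 10, shift = feature_names()[1:4], sd_shift = 7,
                  seed = 19)
  b <- a
  noise <- matrix(stats::rnorm(nrow(a) * 90, sd = 0.05), nrow(a), 90)
  b[, feature_names()] <- b[, feature_names()] + noise
  expect_equal(transfer_accuracy(a, b), 1)
})

test_that("importance maps paint subregions and leave the background at zero", {
  cfg <- small_exact_config()
  s <- generate_subject(cfg, "NL", "m", seed = 21)
  fv <- extract_features(s$pet, s$labels_pet_space, s$labels_mr_space,
                         seed = 2)
  imp <- stats::setNames(rep(1 / 90, 90), feature_names())
  m <- importance_map(s$labels_pet_space, attr(fv, "partitions"), imp)
  expect_true(all(m$data[s$labels_pet_space$data == 0] == 0))
  sar_vox <- s$labels_pet_space$data %in% 1:6
  expect_true(all(m$data[sar_vox] > 0))
  vals <- unique(round(m$data[sar_vox], 12))
  expect_equal(length(vals), 1)  # equal importances: constant over units
  # concentrating importance on posterior putamen features peaks there
  imp2 <- stats::setNames(rep(0, 90), feature_names())
  imp2[grep("putamen_._sub3", feature_names())] <- 0.5
  m2 <- importance_map(s$labels_pet_space, attr(fv, "partitions"), imp2)
  expect_equal(max(m2$data), max(m2$data[s$labels_pet_space$data %in% c(3, 4)]))
  expect_true(all(m2$data[s$labels_pet_space$data %in% c(1, 2, 5, 6)] == 0))
})
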