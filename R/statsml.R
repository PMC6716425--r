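# Feature significance testing, SVM classification with leave-n-out
# cross-validation, and random-forest importance.
#
# No SVM or random-forest package exists in this stack, so both are
# implemented here: a deterministic L2-regularised squared-hinge linear SVM
# fitted by BFGS, and a compact Gini-impurity CART forest used only for its
# impurity importances.

group_levels <- function(groups) {
  lv <- sort(unique(groups))
  if (length(lv) != 2)
    stop("exactly two groups required, got: ", paste(lv, collapse = ", "))
  # conventionally NL/PD; PD (or the second level) is coded +1
  if (all(c("NL", "PD") %in% lv)) c("NL", "PD") else lv
}

# Vectorised two-sided Welch t-test per column (unequal variances; the
# emulated cohort is 49 vs 18, so pooling would be inappropriate).
welch_t_columns <- function(X, groups) {
  lv <- group_levels(groups)
  A <- X[groups == lv[1], , drop = FALSE]
  B <- X[groups == lv[2], , drop = FALSE]
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 subjects for a t-test")
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2, stats::var); v2 <- apply(B, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- NA_real_  # zero variance in both groups: undefined
  list(t = t, p = p, df = df)
}

#' Select significant features by per-feature Welch t-tests
#'
#' Two-sample two-sided Welch t-test per feature; features with p < alpha
#' are selected (no multiple-testing correction, matching the raw
#' alpha = 0.01 screening the pipeline is built around).
#'
#' @param table a [feature_table()].
#' @param alpha significance level (default 0.01).
#' @return list with `selected` (feature names), `p_values` (named, NA for
#'   zero-variance features, which are excluded with a warning), and
#'   `alpha`.
#' @export
select_features <- function(table, alpha = 0.01) {
  X <- feature_matrix(table)
  res <- welch_t_columns(X, table$group)
  if (anyNA(res$p))
    warning("feature(s) with zero variance in both groups excluded: ",
            paste(colnames(X)[is.na(res$p)], collapse = ", "))
  sel <- colnames(X)[!is.na(res$p) & res$p < alpha]
  list(selected = sel, p_values = stats::setNames(res$p, colnames(X)),
       alpha = alpha)
}

# ---- linear SVM ----------------------------------------------------------

#' Train a linear SVM on selected features
#'
#' L2-regularised squared-hinge linear SVM (C = 1 by default), features
#' standardised by the training statistics; fitted by BFGS from a zero
#' start, hence deterministic.
#'
#' @param table a [feature_table()] already restricted to the features in
#'   `features` (or the full table plus a `features` subset).
#' @param features feature names to use (default: all 90).
#' @param C soft-margin cost.
#' @return An `svm_model` with a [predict()][predict.svm_model] method.
#' @export
train_svm <- function(table, features = feature_names(), C = 1) {
  if (length(features) < 1) stop("no selected features to train on")
  X <- as.matrix(table[, features, drop = FALSE])
  lv <- group_levels(table$group)
  y <- ifelse(table$group == lv[2], 1, -1)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(sd == 0))
    stop("constant feature(s) after selection: ",
         paste(features[sd == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, mu), 2, sd, `/`)
  p <- ncol(Xs)
  obj <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    m <- 1 - y * (Xs %*% w + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  grad <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    m <- as.vector(1 - y * (Xs %*% w + b))
    act <- m > 0
    gw <- w - 2 * C * colSums((y * m * act) * Xs)
    gb <- -2 * C * sum(y * m * act)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(w = fit$par[1:p], b = fit$par[p + 1], mu = mu, sd = sd,
                 features = features, levels = lv, C = C),
            class = "svm_model")
}

#' Predict group labels with a trained SVM
#' @param object an `svm_model`.
#' @param newdata a [feature_table()] (or data.frame with the model's
#'   feature columns).
#' @param ... unused.
#' @return character vector of predicted group labels.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sd, `/`)
  f <- as.vector(Xs %*% object$w + object$b)
  ifelse(f >= 0, object$levels[2], object$levels[1])
}

# ---- leave-n-out cross-validation ---------------------------------------

make_partitions <- function(n_subjects, n, n_partitions, seed, groups) {
  if (n == 1) return(as.list(seq_len(n_subjects)))
  with_seed(seed, {
    lapply(seq_len(n_partitions), function(i) {
      for (try in 1:100) {
        held <- sample.int(n_subjects, n)
        if (length(unique(groups[-held])) == 2) return(held)
      }
      stop("could not draw a held-out set keeping both groups in training")
    })
  })
}

#' Leave-n-out cross-validation of the selection + SVM pipeline
#'
#' For n = 1, exact leave-one-out over all subjects; for n > 1, repeated
#' random held-out subsets (default 200 partitions). Feature selection and
#' standardisation are refit inside each training split, so no information
#' leaks from held-out subjects. When selection returns no feature in a
#' fold, the single lowest-p feature is used so every fold still predicts.
#'
#' @param table a [feature_table()].
#' @param n held-out subjects per partition (1 <= n <= subjects - 2).
#' @param alpha selection level inside each fold.
#' @param n_partitions random partitions when n > 1.
#' @param seed partition RNG seed.
#' @param partitions optional precomputed list of held-out index vectors
#'   (shared across arms by [compare_arms()]).
#' @return A `cv_result`: list with `n`, `acc_mean`, `wrong_mean`,
#'   `n_partitions`, `seed`, and per-partition accuracies `acc`.
#' @export
leave_n_out_cv <- function(table, n = 1, alpha = 0.01, n_partitions = 200,
                           seed = 1L, partitions = NULL) {
  ns <- nrow(table)
  stopifnot(n >= 1, n <= ns - 2)
  if (is.null(partitions))
    partitions <- make_partitions(ns, n, n_partitions, seed, table$group)
  acc <- vapply(partitions, function(held) {
    train <- table[-held, , drop = FALSE]
    test <- table[held, , drop = FALSE]
    sel <- suppressWarnings(select_features(train, alpha))
    feats <- sel$selected
    if (length(feats) == 0) {
      ok <- !is.na(sel$p_values)
      feats <- names(which.min(sel$p_values[ok]))
    }
    # guard: drop features constant in this training split
    const <- vapply(feats, function(f) stats::sd(train[[f]]) == 0,
                    logical(1))
    feats <- feats[!const]
    if (length(feats) == 0) return(NA_real_)
    model <- train_svm(train, feats)
    mean(predict(model, test) == test$group)
  }, numeric(1))
  acc <- acc[!is.na(acc)]
  structure(list(n = n, acc_mean = mean(acc),
                 wrong_mean = mean(n * (1 - acc)),
                 n_partitions = length(acc), seed = seed, acc = acc),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> leave-%d-out: acc %.4f, wrong %.3f (%d partitions)\n",
              x$n, x$acc_mean, x$wrong_mean, x$n_partitions))
  invisible(x)
}

# ---- random forest importance -------------------------------------------

gini_best_split <- function(x, y01) {
  o <- order(x)
  xs <- x[o]; ys <- y01[o]
  n <- length(ys)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  split_ok <- which(diff(xs) > 0)
  if (length(split_ok) == 0) return(NULL)
  nl <- split_ok
  nr <- n - nl
  l1 <- cum1[split_ok]
  r1 <- tot1 - l1
  gini <- function(cnt1, cnt) {
    p <- cnt1 / cnt
    1 - p^2 - (1 - p)^2
  }
  g_parent <- gini(tot1, n)
  gain <- g_parent - (nl / n) * gini(l1, nl) - (nr / n) * gini(r1, nr)
  bi <- which.max(gain)
  if (gain[bi] <= 1e-12) return(NULL)
  list(threshold = (xs[split_ok[bi]] + xs[split_ok[bi] + 1]) / 2,
       gain = gain[bi] * n)  # node-size-weighted impurity decrease
}

grow_tree_importance <- function(X, y01, mtry, importance) {
  stack <- list(seq_len(nrow(X)))
  p <- ncol(X)
  while (length(stack)) {
    idx <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(idx) < 2 || all(y01[idx] == y01[idx][1])) next
    feats <- sample.int(p, mtry)
    best <- NULL; best_f <- NA
    for (f in feats) {
      sp <- gini_best_split(X[idx, f], y01[idx])
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best)) next
    importance[best_f] <- importance[best_f] + best$gain
    left <- idx[X[idx, best_f] <= best$threshold]
    right <- idx[X[idx, best_f] > best$threshold]
    stack[[length(stack) + 1]] <- left
    stack[[length(stack) + 1]] <- right
  }
  importance
}

#' Random-forest feature importance
#'
#' Bagged CART forest (Gini impurity, `mtry = floor(sqrt(p))`, 500 trees)
#' whose impurity decreases are accumulated per feature and normalised to
#' sum 1, then aggregated per statistic kind (mean, median, 3rd quantile,
#' 1st quantile, maximum, minimum, and volume when included) by summing the
#' member features.
#'
#' @param table a [feature_table()].
#' @param seed RNG seed.
#' @param include_volume include the 6 volume features.
#' @param ntree trees in the forest.
#' @return list with `per_feature` (named importances summing to 1) and
#'   `by_statistic` (data.frame: statistic, importance; 7 rows with volume,
#'   6 without).
#' @export
rf_importance <- function(table, seed = 1L, include_volume = TRUE,
                          ntree = 500L) {
  group_levels(table$group)  # validates two groups
  feats <- feature_names()
  if (!include_volume) feats <- feats[!grepl("_volume$", feats)]
  X <- as.matrix(table[, feats, drop = FALSE])
  y01 <- as.integer(table$group == group_levels(table$group)[2])
  p <- ncol(X)
  mtry <- max(1L, floor(sqrt(p)))
  imp <- stats::setNames(numeric(p), feats)
  with_seed(seed, {
    for (b in seq_len(ntree)) {
      boot <- sample.int(nrow(X), replace = TRUE)
      imp <- grow_tree_importance(X[boot, , drop = FALSE], y01[boot],
                                  mtry, imp)
    }
  })
  if (sum(imp) > 0) imp <- imp / sum(imp)
  stat_of <- function(f) {
    if (grepl("_volume$", f)) return("volume")
    sub("^.*_(max|min|median|q1|q3|mean)_SOR$", "\\1", f)
  }
  kinds <- vapply(feats, stat_of, character(1))
  agg <- tapply(imp, kinds, sum)
  pretty <- c(mean = "mean", median = "median", q3 = "3rd quantile",
              q1 = "1st quantile", max = "maximum", min = "minimum",
              volume = "volume")
  ord <- intersect(names(pretty), names(agg))
  by_stat <- data.frame(statistic = unname(pretty[ord]),
                        importance = unname(agg[ord]))
  list(per_feature = imp, by_statistic = by_stat)
}

# ---- comparative experiment drivers -------------------------------------

#' Compare two pipeline arms on identical CV partitions
#'
#' Evaluates both arms' feature tables with leave-n-out CV over a grid of
#' n, sharing the exact same held-out partitions (same seed), then runs a
#' paired t-test across n on the mean wrong-prediction counts.
#'
#' @param table_a,table_b [feature_table()]s of the two arms, same subjects
#'   in the same order.
#' @param ns grid of held-out counts n.
#' @param alpha selection level.
#' @param n_partitions partitions per n (> 1).
#' @param seed shared partition seed.
#' @return list with `cv_a`, `cv_b` (lists of `cv_result` per n),
#'   `p_value` (paired t-test on wrong_mean across n; 1 when the arms are
#'   identical on every n), and `ns`.
#' @export
compare_arms <- function(table_a, table_b, ns = 1:5, alpha = 0.01,
                         n_partitions = 100, seed = 1L) {
  if (nrow(table_a) != nrow(table_b) ||
      !identical(table_a$group, table_b$group))
    stop("arms must cover the same subjects in the same order")
  run <- function(tbl) {
    lapply(ns, function(n) {
      parts <- make_partitions(nrow(tbl), n, n_partitions, seed + n,
                               tbl$group)
      leave_n_out_cv(tbl, n, alpha, seed = seed + n, partitions = parts)
    })
  }
  cv_a <- run(table_a)
  cv_b <- run(table_b)
  wa <- vapply(cv_a, `[[`, numeric(1), "wrong_mean")
  wb <- vapply(cv_b, `[[`, numeric(1), "wrong_mean")
  d <- wa - wb
  p <- if (all(d == 0) || stats::sd(d) == 0) {
    1  # identical arms: no evidence of difference by construction
  } else stats::t.test(wa, wb, paired = TRUE)$p.value
  list(cv_a = cv_a, cv_b = cv_b, p_value = p, ns = ns,
       wrong_a = wa, wrong_b = wb)
}

#' Cross-arm transfer accuracy
#'
#' Trains the selection + SVM pipeline on one arm's full feature table and
#' tests it on another arm's features of the same subjects (e.g. train on
#' manual-label features, test on automatic-segmentation features).
#'
#' @param train_table,test_table [feature_table()]s, same subjects.
#' @param alpha selection level.
#' @return accuracy in `[0, 1]`.
#' @export
transfer_accuracy <- function(train_table, test_table, alpha = 0.01) {
  sel <- suppressWarnings(select_features(train_table, alpha))
  feats <- sel$selected
  if (length(feats) == 0)
    feats <- names(which.min(sel$p_values[!is.na(sel$p_values)]))
  model <- train_svm(train_table, feats)
  mean(predict(model, test_table) == test_table$group)
}

#' Voxelwise subregion importance map
#'
#' Assigns each subregion (and whole pallidum) the summed importance of its
#' six SOR features, painting a piecewise-constant volume for heatmap
#' export; background voxels are 0.
#'
#' @param labels PET-space [label_map()] with the SARs.
#' @param partitions named list of [subdivide_region()] results for the
#'   caudates and putamens (as attached to a `feature_vector`).
#' @param importances named per-feature importances (from
#'   [rf_importance()]).
#' @return an [image_volume()] on the label grid.
#' @export
importance_map <- function(labels, partitions, importances) {
  out <- array(0, dim = dim(labels$data))
  units <- feature_region_units()
  for (un in names(units)) {
    u <- units[[un]]
    fnames <- paste0(un, "_", FEATURE_STATS, "_SOR")
    w <- sum(importances[fnames], na.rm = TRUE)
    vox <- if (is.na(u$sub)) {
      which(labels$data == labels$labels[[u$region]])
    } else {
      p <- partitions[[u$region]]
      if (is.null(p)) stop("missing partition for ", u$region)
      p$voxels[p$assignment == u$sub]
    }
    out[vox] <- w
  }
  image_volume(out, labels$spacing, labels$origin, "other")
}
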