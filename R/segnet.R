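# Deeply supervised residual 3D encoder-decoder for striatal segmentation.
#
# The encoder captures context with residual blocks and 2x max-pooling; the
# decoder restores resolution with nearest-neighbour upsampling and skip
# concatenations; a 1x1x1 convolution + softmax head sits on every decoder
# level (the coarsest head on the bottleneck), and each head is scored with
# the composite loss against stride-subsampled truth. All forward/backward
# passes are hand-derived on top of the Rcpp convolution kernels, since no
# deep-learning framework is available in this stack.

#' Segmentation network configuration
#'
#' Each resolution level is a residual block described by (n, k, r):
#' channel count, convolution layer count, and dropout probability.
#'
#' @param channels per-level channel counts `n` (length = depth, >= 2).
#' @param layers per-level convolution counts `k` (recycled).
#' @param dropout per-level dropout probabilities `r` in `[0,1]` (recycled).
#' @param n_labels output classes (background + 6 SARs + occipital = 8).
#' @param input_roi cubic crop size in voxels; must be divisible by
#'   `2^(depth-1)`. The full-scale reference value is 96; the package
#'   default is a desk-scale 32.
#' @param deep_supervision_weights per-level loss weights (level 1 = full
#'   resolution); default `1/2^(level-1)`, normalised to sum 1.
#' @param blur_sd SD (voxels) of the Gaussian-blur input augmentation.
#' @return A `segnet_config` object.
#' @export
segnet_config <- function(channels = c(8, 16, 32), layers = 1,
                          dropout = 0, n_labels = 8L,
                          input_roi = c(32, 32, 32),
                          deep_supervision_weights = NULL,
                          blur_sd = 0.5) {
  depth <- length(channels)
  stopifnot(depth >= 2, all(channels >= 1), n_labels >= 2,
            length(input_roi) == 3L)
  layers <- rep_len(layers, depth)
  dropout <- rep_len(dropout, depth)
  stopifnot(all(layers >= 1), all(dropout >= 0), all(dropout <= 1))
  div <- 2^(depth - 1)
  if (any(input_roi %% div != 0))
    stop("input_roi must be divisible by 2^(depth-1) = ", div)
  if (is.null(deep_supervision_weights))
    deep_supervision_weights <- 1 / 2^(seq_len(depth) - 1)
  stopifnot(length(deep_supervision_weights) == depth,
            all(deep_supervision_weights >= 0),
            any(deep_supervision_weights > 0))
  deep_supervision_weights <-
    deep_supervision_weights / sum(deep_supervision_weights)
  structure(list(channels = as.integer(channels),
                 layers = as.integer(layers), dropout = dropout,
                 depth = depth, n_labels = as.integer(n_labels),
                 input_roi = as.integer(input_roi),
                 deep_supervision_weights = deep_supervision_weights,
                 blur_sd = blur_sd),
            class = "segnet_config")
}

# ---- parameter initialisation -------------------------------------------

he_conv <- function(k, cin, cout) {
  array(stats::rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
        dim = c(k, k, k, cin, cout))
}

block_param_names <- function(prefix, cin, cout, k_layers) {
  p <- list()
  for (i in seq_len(k_layers)) {
    ci <- if (i == 1) cin else cout
    p[[paste0(prefix, ".conv", i, ".w")]] <- c(3L, ci, cout)
    p[[paste0(prefix, ".conv", i, ".b")]] <- cout
    p[[paste0(prefix, ".norm", i, ".g")]] <- cout
    p[[paste0(prefix, ".norm", i, ".b")]] <- cout
  }
  if (cin != cout) {
    p[[paste0(prefix, ".short.w")]] <- c(1L, cin, cout)
    p[[paste0(prefix, ".short.b")]] <- cout
  }
  p
}

block_in_channels <- function(cfg, which, level) {
  ch <- cfg$channels
  if (which == "enc") {
    if (level == 1) 1L else ch[level - 1]
  } else {
    ch[level + 1] + ch[level]  # upsampled deeper features + skip
  }
}

#' Build (initialise) a segmentation network
#'
#' @param cfg a [segnet_config()].
#' @param seed RNG seed for the He weight initialisation.
#' @return A `segnet` object: the config plus a flat named parameter list.
#' @export
build_segnet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "segnet_config"))
  shapes <- list()
  for (l in seq_len(cfg$depth)) {
    shapes <- c(shapes, block_param_names(
      paste0("enc", l), block_in_channels(cfg, "enc", l),
      cfg$channels[l], cfg$layers[l]))
  }
  for (l in seq_len(cfg$depth - 1)) {
    shapes <- c(shapes, block_param_names(
      paste0("dec", l), block_in_channels(cfg, "dec", l),
      cfg$channels[l], cfg$layers[l]))
  }
  for (l in seq_len(cfg$depth)) {
    shapes[[paste0("head", l, ".w")]] <- c(1L, cfg$channels[l], cfg$n_labels)
    shapes[[paste0("head", l, ".b")]] <- cfg$n_labels
  }
  # conv weights He-initialised; biases 0, norm gains 1, norm biases 0
  params <- with_seed(seed, {
    out <- list()
    for (nm in names(shapes)) {
      s <- shapes[[nm]]
      out[[nm]] <- if (length(s) == 3) {
        he_conv(s[1], s[2], s[3])
      } else if (grepl("\\.g$", nm)) rep(1, s) else rep(0, s)
    }
    out
  })
  structure(list(cfg = cfg, params = params), class = "segnet")
}

#' Number of trainable parameters
#' @param net a `segnet`.
#' @return integer count.
#' @export
n_params <- function(net) sum(vapply(net$params, length, integer(1)))

#' @export
print.segnet <- function(x, ...) {
  cat(sprintf("<segnet> depth %d, channels %s, %d labels, %s ROI, %d params\n",
              x$cfg$depth, paste(x$cfg$channels, collapse = "/"),
              x$cfg$n_labels, paste(x$cfg$input_roi, collapse = "x"),
              n_params(x)))
  invisible(x)
}

# ---- primitive layers (forward + backward) ------------------------------

conv_f <- function(x, w, b) {
  conv3d_forward_blas(x, w, b, dim(x), dim(w))
}
conv_b <- function(x, w, gy) {
  conv3d_backward_blas(x, w, gy, dim(x), dim(w))
}

INORM_EPS <- 1e-5

inorm_f <- function(x, g, b) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4])
  m <- colMeans(xm)
  v <- colMeans(xm^2) - m^2
  sd_inv <- 1 / sqrt(v + INORM_EPS)
  xhat <- sweep(sweep(xm, 2, m), 2, sd_inv, `*`)
  y <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  list(y = array(y, d), cache = list(xhat = xhat, sd_inv = sd_inv, d = d))
}

inorm_b <- function(gy, g, cache) {
  d <- cache$d
  gym <- matrix(gy, ncol = d[4])
  xhat <- cache$xhat
  gg <- colSums(gym * xhat)
  gb <- colSums(gym)
  gxhat <- sweep(gym, 2, g, `*`)
  m1 <- colMeans(gxhat)
  m2 <- colMeans(gxhat * xhat)
  gx <- sweep(sweep(gxhat, 2, m1) - sweep(xhat, 2, m2, `*`),
              2, cache$sd_inv, `*`)
  list(gx = array(gx, d), gg = gg, gb = gb)
}

# ---- residual block ------------------------------------------------------

res_block_f <- function(x, prefix, params, k_layers, r, train, cfg) {
  cache <- list(x = x, layers = vector("list", k_layers), prefix = prefix,
                k_layers = k_layers)
  h <- x
  for (i in seq_len(k_layers)) {
    w <- params[[paste0(prefix, ".conv", i, ".w")]]
    b <- params[[paste0(prefix, ".conv", i, ".b")]]
    z <- conv_f(h, w, b)
    nf <- inorm_f(z, params[[paste0(prefix, ".norm", i, ".g")]],
                  params[[paste0(prefix, ".norm", i, ".b")]])
    a <- pmax(nf$y, 0)
    cache$layers[[i]] <- list(h_in = h, z = z, norm = nf$cache,
                              relu_mask = nf$y > 0)
    h <- a
  }
  has_short <- !is.null(params[[paste0(prefix, ".short.w")]])
  if (has_short) {
    short <- conv_f(x, params[[paste0(prefix, ".short.w")]],
                    params[[paste0(prefix, ".short.b")]])
  } else short <- x
  y <- h + short
  cache$has_short <- has_short
  if (train && r > 0) {
    mask <- (stats::runif(length(y)) >= r) / (1 - r)
    y <- y * mask
    cache$drop_mask <- mask
  }
  list(y = y, cache = cache)
}

res_block_b <- function(gy, cache, params, grads) {
  prefix <- cache$prefix
  if (!is.null(cache$drop_mask)) gy <- gy * cache$drop_mask
  # shortcut branch
  if (cache$has_short) {
    wnm <- paste0(prefix, ".short.w")
    bb <- conv_b(cache$x, params[[wnm]], gy)
    gx <- bb$gx
    grads[[wnm]] <- grads[[wnm]] + bb$gw
    grads[[paste0(prefix, ".short.b")]] <-
      grads[[paste0(prefix, ".short.b")]] + bb$gb
  } else gx <- gy
  # main branch, reversed
  gh <- gy
  for (i in rev(seq_len(cache$k_layers))) {
    lc <- cache$layers[[i]]
    ga <- gh * lc$relu_mask
    nb <- inorm_b(ga, params[[paste0(prefix, ".norm", i, ".g")]], lc$norm)
    grads[[paste0(prefix, ".norm", i, ".g")]] <-
      grads[[paste0(prefix, ".norm", i, ".g")]] + nb$gg
    grads[[paste0(prefix, ".norm", i, ".b")]] <-
      grads[[paste0(prefix, ".norm", i, ".b")]] + nb$gb
    wnm <- paste0(prefix, ".conv", i, ".w")
    cb <- conv_b(lc$h_in, params[[wnm]], nb$gx)
    grads[[wnm]] <- grads[[wnm]] + cb$gw
    grads[[paste0(prefix, ".conv", i, ".b")]] <-
      grads[[paste0(prefix, ".conv", i, ".b")]] + cb$gb
    gh <- cb$gx
  }
  gx <- gx + gh
  list(gx = gx, grads = grads)
}

# ---- full network forward / backward ------------------------------------

segnet_forward <- function(net, x, train = FALSE) {
  cfg <- net$cfg
  p <- net$params
  D <- cfg$depth
  enc_out <- vector("list", D)
  enc_cache <- vector("list", D)
  pool_cache <- vector("list", D)
  cur <- x
  for (l in seq_len(D)) {
    rb <- res_block_f(cur, paste0("enc", l), p, cfg$layers[l],
                      cfg$dropout[l], train, cfg)
    enc_out[[l]] <- rb$y
    enc_cache[[l]] <- rb$cache
    if (l < D) {
      mp <- maxpool2_forward_cpp(enc_out[[l]], dim(enc_out[[l]]))
      pool_cache[[l]] <- list(argmax = mp$argmax, xdim = dim(enc_out[[l]]))
      cur <- mp$y
    }
  }
  dec_out <- vector("list", D)
  dec_cache <- vector("list", D)
  dec_out[[D]] <- enc_out[[D]]
  for (l in rev(seq_len(D - 1))) {
    up <- upsample2_forward_cpp(dec_out[[l + 1]], dim(dec_out[[l + 1]]))
    cat4 <- abind4(up, enc_out[[l]])
    rb <- res_block_f(cat4, paste0("dec", l), p, cfg$layers[l],
                      cfg$dropout[l], train, cfg)
    dec_out[[l]] <- rb$y
    dec_cache[[l]] <- list(block = rb$cache, up_dim = dim(dec_out[[l + 1]]),
                           n_up = dim(up)[4], cat_in = cat4)
  }
  logits <- vector("list", D)
  head_cache <- vector("list", D)
  for (l in seq_len(D)) {
    w <- p[[paste0("head", l, ".w")]]
    logits[[l]] <- conv_f(dec_out[[l]], w, p[[paste0("head", l, ".b")]])
    head_cache[[l]] <- dec_out[[l]]
  }
  list(logits = logits,
       cache = list(enc_cache = enc_cache, pool_cache = pool_cache,
                    dec_cache = dec_cache, head_cache = head_cache,
                    enc_dims = lapply(enc_out, dim)))
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

segnet_backward <- function(net, cache, g_logits) {
  cfg <- net$cfg
  p <- net$params
  D <- cfg$depth
  grads <- lapply(p, function(x) array(0, dim = dim(x) %||% length(x)))
  for (nm in names(grads)) {
    if (is.null(dim(p[[nm]]))) grads[[nm]] <- rep(0, length(p[[nm]]))
  }
  g_dec <- vector("list", D)
  # heads
  for (l in seq_len(D)) {
    if (is.null(g_logits[[l]])) next
    wnm <- paste0("head", l, ".w")
    hb <- conv_b(cache$head_cache[[l]], p[[wnm]], g_logits[[l]])
    grads[[wnm]] <- grads[[wnm]] + hb$gw
    grads[[paste0("head", l, ".b")]] <-
      grads[[paste0("head", l, ".b")]] + hb$gb
    g_dec[[l]] <- accum(g_dec[[l]], hb$gx)
  }
  g_enc <- vector("list", D)
  # decoder blocks, fine -> coarse
  for (l in seq_len(D - 1)) {
    if (is.null(g_dec[[l]])) next
    dc <- cache$dec_cache[[l]]
    rb <- res_block_b(g_dec[[l]], dc$block, p, grads)
    grads <- rb$grads
    g_cat <- rb$gx
    n_up <- dc$n_up
    g_up <- g_cat[, , , seq_len(n_up), drop = FALSE]
    g_skip <- g_cat[, , , n_up + seq_len(dim(g_cat)[4] - n_up),
                    drop = FALSE]
    g_enc[[l]] <- accum(g_enc[[l]], g_skip)
    g_dec[[l + 1]] <- accum(g_dec[[l + 1]],
                            upsample2_backward_cpp(g_up, dc$up_dim))
  }
  g_enc[[D]] <- accum(g_enc[[D]], g_dec[[D]])
  # encoder blocks, coarse -> fine
  for (l in rev(seq_len(D))) {
    if (is.null(g_enc[[l]])) next
    rb <- res_block_b(g_enc[[l]], cache$enc_cache[[l]], p, grads)
    grads <- rb$grads
    if (l > 1) {
      pc <- cache$pool_cache[[l - 1]]
      g_enc[[l - 1]] <- accum(g_enc[[l - 1]],
                              maxpool2_backward_cpp(pc$argmax, rb$gx,
                                                    pc$xdim))
    }
  }
  grads
}

accum <- function(a, b) if (is.null(a)) b else a + b
`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- data preparation ----------------------------------------------------

# Crop a cubic ROI; center defaults to the foreground-label centroid (train)
# or the volume center (inference).
crop_roi <- function(vol_data, roi, center_vox = NULL) {
  sh <- dim(vol_data)
  if (any(roi > sh))
    stop("ROI of ", paste(roi, collapse = "x"),
         " does not fit inside volume of ", paste(sh, collapse = "x"),
         " (axis ", which(roi > sh)[1], ")")
  if (is.null(center_vox)) center_vox <- (sh + 1) / 2
  start <- round(center_vox - roi / 2)
  start <- pmin(pmax(start, 1), sh - roi + 1)
  idx <- Map(function(s, n) seq(s, length.out = n), start, roi)
  list(data = vol_data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       start = start)
}

label_centroid_vox <- function(lab_data) {
  fg <- which(lab_data > 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("no labeled voxels in ROI: cannot centre the crop")
  colMeans(fg)
}

normalize_roi <- function(x) {
  s <- stats::sd(x)
  if (s == 0) s <- 1
  (x - mean(x)) / s
}

subsample_labels <- function(lab_data, level) {
  if (level == 1) return(lab_data)
  by <- 2^(level - 1)
  lab_data[seq(1, dim(lab_data)[1], by = by),
           seq(1, dim(lab_data)[2], by = by),
           seq(1, dim(lab_data)[3], by = by), drop = FALSE]
}

gaussian_blur3 <- function(x3d, sd) {
  if (sd <= 0) return(x3d)
  g1 <- stats::dnorm(-1:1, sd = sd)
  g1 <- g1 / sum(g1)
  k <- outer(outer(g1, g1), g1)
  dim(k) <- c(3, 3, 3, 1, 1)
  x4 <- array(x3d, dim = c(dim(x3d), 1))
  out <- conv3d_forward_cpp(x4, k, 0, dim(x4), dim(k))
  array(out, dim = dim(x3d))
}

# ---- training ------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

prepare_training_case <- function(subject, roi) {
  mr <- subject$mr
  lab <- subject$labels_mr_space %||% subject$labels
  ctr <- label_centroid_vox(lab$data)
  cm <- crop_roi(mr$data, roi, ctr)
  cl <- crop_roi(lab$data, roi, ctr)
  list(x = array(normalize_roi(cm$data), dim = c(roi, 1)),
       truth = cl$data)
}

#' Train the segmentation network
#'
#' Full-volume (single ROI crop per subject) Adam training with the
#' composite loss applied at every deep-supervision head against
#' stride-subsampled truth. Gaussian-blur input augmentation is applied
#' with probability 0.5 when `augment = TRUE`.
#'
#' @param net a `segnet` from [build_segnet()].
#' @param subjects list of `synthetic_subject`s, or lists with `mr`
#'   ([image_volume()]) and `labels` ([label_map()]).
#' @param loss_cfg a [loss_config()].
#' @param epochs passes over the subjects (>= 1).
#' @param lr Adam learning rate (reference recipe: 1e-3).
#' @param seed RNG seed (augmentation + dropout); fixed seed gives an
#'   identical trajectory.
#' @param augment enable Gaussian-blur augmentation.
#' @param stop_dice optional early-stop: stop once the hard training Dice
#'   over foreground labels exceeds this value.
#' @param stop_metric aggregate for the early-stop check: `"mean"` or
#'   `"min"` over foreground labels.
#' @param check_every epochs between early-stop checks.
#' @param verbose print per-epoch losses.
#' @return list with the trained `net` and the per-epoch mean `loss`
#'   trajectory (class `segnet_fit`).
#' @export
train_segnet <- function(net, subjects, loss_cfg = loss_config(),
                         epochs = 10, lr = 1e-3, seed = 1L,
                         augment = TRUE, stop_dice = NULL,
                         stop_metric = c("mean", "min"),
                         check_every = 10L, verbose = FALSE) {
  stopifnot(inherits(net, "segnet"), epochs >= 1, length(subjects) >= 1)
  stop_metric <- match.arg(stop_metric)
  cfg <- net$cfg
  roi <- cfg$input_roi
  cases <- lapply(subjects, prepare_training_case, roi = roi)
  for (cs in cases) {
    if (!any(cs$truth > 0)) stop("training case has no labeled voxels")
  }
  truths <- lapply(cases, function(cs) {
    lapply(seq_len(cfg$depth), function(l) subsample_labels(cs$truth, l))
  })
  state <- adam_init(net$params)
  traj <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ep_loss <- 0
      for (ci in seq_along(cases)) {
        x <- cases[[ci]]$x
        if (augment && stats::runif(1) < 0.5) {
          x3 <- gaussian_blur3(x[, , , 1], cfg$blur_sd)
          x <- array(x3, dim = dim(x))
        }
        fw <- segnet_forward(net, x, train = TRUE)
        g_logits <- vector("list", cfg$depth)
        loss <- 0
        for (l in seq_len(cfg$depth)) {
          wl <- cfg$deep_supervision_weights[l]
          if (wl == 0) next
          ll <- composite_loss_logits(fw$logits[[l]], truths[[ci]][[l]],
                                      loss_cfg)
          loss <- loss + wl * ll$value
          g_logits[[l]] <- wl * ll$grad
        }
        grads <- segnet_backward(net, fw$cache, g_logits)
        if (lr > 0) {
          st <- adam_step(net$params, grads, state, lr)
          net$params <- st$params
          state <- st$state
        }
        ep_loss <- ep_loss + loss
      }
      traj[ep] <- ep_loss / length(cases)
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, traj[ep]))
      if (!is.null(stop_dice) && ep %% check_every == 0) {
        agg <- if (stop_metric == "mean") mean else min
        dsc <- agg(vapply(seq_along(cases), function(ci) {
          fw <- segnet_forward(net, cases[[ci]]$x, train = FALSE)
          pred <- hard_labels(fw$logits[[1]])
          agg(hard_dice_table(pred, cases[[ci]]$truth,
                              seq_len(cfg$n_labels - 1L)))
        }, numeric(1)))
        if (dsc >= stop_dice) break
      }
    }
  })
  structure(list(net = net, loss = traj), class = "segnet_fit")
}

hard_labels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[4])
  array(max.col(m, ties.method = "first") - 1L, dim = d[1:3])
}

#' Segment an MR volume
#'
#' Crops the configured ROI (volume centre unless `roi_center` is given),
#' z-normalises it, runs the network, and argmaxes the full-resolution head
#' (ties broken toward the lowest label code). Voxels outside the ROI are
#' background.
#'
#' @param net trained `segnet` (or a `segnet_fit`).
#' @param mr an [image_volume()].
#' @param roi_center optional ROI centre in voxel coordinates (1-based).
#' @return a [label_map()] on the MR grid.
#' @export
predict_segnet <- function(net, mr, roi_center = NULL) {
  if (inherits(net, "segnet_fit")) net <- net$net
  stopifnot(inherits(net, "segnet"), inherits(mr, "image_volume"))
  roi <- net$cfg$input_roi
  cr <- crop_roi(mr$data, roi, roi_center)
  x <- array(normalize_roi(cr$data), dim = c(roi, 1))
  fw <- segnet_forward(net, x, train = FALSE)
  pred_roi <- hard_labels(fw$logits[[1]])
  out <- array(0L, dim = dim(mr$data))
  idx <- Map(function(s, n) seq(s, length.out = n), cr$start, roi)
  out[idx[[1]], idx[[2]], idx[[3]]] <- pred_roi
  label_map(out, mr$spacing, mr$origin)
}

hard_dice_table <- function(pred_data, truth_data, label_codes) {
  vapply(label_codes, function(i) {
    a <- pred_data == i
    b <- truth_data == i
    if (!any(a) && !any(b)) return(1)
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))
}

#' Hard Dice similarity coefficients between two label maps
#'
#' @param pred,truth [label_map()]s on the same grid (or a list of such
#'   pairs via `cohort`).
#' @param labels named label codes to score (default the six SARs).
#' @return named numeric DSC per region; for `evaluate_dsc_cohort`, a
#'   data.frame with per-region mean and SD across subjects.
#' @export
evaluate_dsc <- function(pred, truth, labels = sar_labels()[sar_names()]) {
  if (!same_grid(pred, truth)) stop("prediction and truth grids differ")
  stats::setNames(hard_dice_table(pred$data, truth$data, labels),
                  names(labels))
}

#' @rdname evaluate_dsc
#' @param pairs list of `list(pred =, truth =)` pairs.
#' @export
evaluate_dsc_cohort <- function(pairs,
                                labels = sar_labels()[sar_names()]) {
  tab <- t(vapply(pairs, function(p) evaluate_dsc(p$pred, p$truth, labels),
                  numeric(length(labels))))
  data.frame(region = names(labels), mean_dsc = colMeans(tab),
             sd_dsc = apply(tab, 2, stats::sd), row.names = NULL)
}

# ---- checkpointing -------------------------------------------------------

#' Save / load a segmentation network as a single JSON archive
#'
#' Parameters are stored as flat numeric arrays with the config embedded,
#' gzip-compressed. Text-based so checkpoints survive source-only transport.
#'
#' @param net a `segnet` (or `segnet_fit`).
#' @param path file path (`.json.gz` suggested).
#' @return `load_segnet` returns the `segnet`.
#' @export
save_segnet <- function(net, path) {
  if (inherits(net, "segnet_fit")) net <- net$net
  obj <- list(cfg = unclass(net$cfg),
              params = lapply(net$params, function(x) {
                list(dim = dim(x) %||% length(x), values = as.vector(x))
              }))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  obj <- jsonlite::fromJSON(paste(readLines(con), collapse = ""),
                            simplifyVector = TRUE)
  cfg <- do.call(segnet_config, obj$cfg[c("channels", "layers", "dropout",
                                          "n_labels", "input_roi",
                                          "deep_supervision_weights",
                                          "blur_sd")])
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) > 1) array(p$values, dim = p$dim) else p$values
  })
  structure(list(cfg = cfg, params = params), class = "segnet")
}
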