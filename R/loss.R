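# Composite segmentation loss: L = w_D * E_i[(-ln Dice_i)^gamma]
#                                 + w_C * E_x[-ln p_l(x)].
#
# The Dice expectation runs over the label set (foreground only by default:
# the loss exists to protect small structures, and background overlap would
# swamp it); the cross-entropy expectation runs over ROI voxels. Soft Dice
# is smoothed with eps in numerator and denominator, and probabilities are
# clamped to [1e-7, 1] inside logs, so the loss is finite everywhere.

DICE_EPS <- 1e-6
PROB_EPS <- 1e-7

#' Composite loss configuration
#'
#' @param w_D weight of the Dice term (default 0.8).
#' @param w_C weight of the cross-entropy term (default 0.2).
#' @param gamma exponent on -ln(Dice) (default 0.3); values below 1 boost
#'   the gradient for labels that are already mostly right, which favours
#'   the small striatal structures.
#' @param include_background whether label 0 enters the Dice expectation.
#' @return A `loss_config` object.
#' @export
loss_config <- function(w_D = 0.8, w_C = 0.2, gamma = 0.3,
                        include_background = FALSE) {
  stopifnot(w_D >= 0, w_C >= 0, w_D + w_C > 0, gamma > 0)
  structure(list(w_D = w_D, w_C = w_C, gamma = gamma,
                 include_background = include_background),
            class = "loss_config")
}

# probs: 4D array (nx,ny,nz,L); channel c holds p for label code c-1.
check_probs_truth <- function(probs, truth) {
  tdata <- if (inherits(truth, "label_map")) truth$data else truth
  pd <- dim(probs)
  stopifnot(length(pd) == 4L)
  if (!identical(as.integer(pd[1:3]), as.integer(dim(tdata))))
    stop("probability grid and truth grid differ: ",
         paste(pd[1:3], collapse = "x"), " vs ",
         paste(dim(tdata), collapse = "x"))
  tdata
}

#' Soft Dice coefficient of one label
#'
#' `2 * sum_x d_il(x) p_i(x) / sum_x (d_il(x) + p_i(x))`, where `d_il` is
#' the Kronecker delta of the ground truth, computed on the probabilities
#' directly (no thresholding) with an eps-smoothed ratio.
#'
#' @param probs 4D probability array (`nx, ny, nz, n_labels`), channel
#'   `c` holding label code `c - 1`.
#' @param truth [label_map()] or integer array on the same grid.
#' @param label integer label code.
#' @return scalar in `[0, 1]`.
#' @export
dice_per_label <- function(probs, truth, label) {
  tdata <- check_probs_truth(probs, truth)
  if (label < 0 || label >= dim(probs)[4])
    stop("label ", label, " outside the probability channels")
  p <- probs[, , , label + 1L]
  d <- tdata == label
  (2 * sum(p[d]) + DICE_EPS) / (sum(d) + sum(p) + DICE_EPS)
}

dice_label_set <- function(cfg, n_labels) {
  if (cfg$include_background) 0:(n_labels - 1L) else seq_len(n_labels - 1L)
}

#' Composite Dice + cross-entropy loss
#'
#' @param probs 4D probability array (see [dice_per_label()]).
#' @param truth [label_map()] or integer array on the same grid.
#' @param cfg a [loss_config()].
#' @return nonnegative scalar; 0 iff the prediction is exactly the one-hot
#'   truth (up to the eps smoothing).
#' @export
composite_loss <- function(probs, truth, cfg = loss_config()) {
  tdata <- check_probs_truth(probs, truth)
  L <- dim(probs)[4]
  lab_set <- dice_label_set(cfg, L)
  dice <- vapply(lab_set, function(i) dice_per_label(probs, tdata, i),
                 numeric(1))
  l_dice <- mean((-log(pmin(dice, 1)))^cfg$gamma)
  pl <- pmax(prob_at_truth(probs, tdata), PROB_EPS)
  l_ce <- mean(-log(pl))
  cfg$w_D * l_dice + cfg$w_C * l_ce
}

prob_at_truth <- function(probs, tdata) {
  nvox <- prod(dim(tdata))
  probs[seq_len(nvox) + nvox * as.vector(tdata)]
}

#' Analytic gradient of the composite loss w.r.t. the probabilities
#'
#' @inheritParams composite_loss
#' @return array shaped like `probs` with `dL/dp_i(x)`.
#' @export
composite_loss_grad <- function(probs, truth, cfg = loss_config()) {
  tdata <- check_probs_truth(probs, truth)
  L <- dim(probs)[4]
  nvox <- prod(dim(tdata))
  g <- array(0, dim = dim(probs))
  tvec <- as.vector(tdata)
  lab_set <- dice_label_set(cfg, L)
  nF <- length(lab_set)
  for (i in lab_set) {
    p <- probs[, , , i + 1L]
    d <- as.numeric(tdata == i)
    num <- 2 * sum(p * d) + DICE_EPS
    den <- sum(d) + sum(p) + DICE_EPS
    D <- num / den
    u <- max(-log(min(D, 1)), 1e-6)  # clamp: u^(gamma-1) blows up at D = 1
    dLdD <- cfg$w_D / nF * cfg$gamma * u^(cfg$gamma - 1) * (-1 / D)
    dDdp <- (2 * d * den - num) / den^2
    g[, , , i + 1L] <- g[, , , i + 1L] + dLdD * dDdp
  }
  # cross-entropy: only the truth channel at each voxel contributes
  pl <- prob_at_truth(probs, tdata)
  idx <- seq_len(nvox) + nvox * tvec
  gce <- ifelse(pl > PROB_EPS, -cfg$w_C / (nvox * pmax(pl, PROB_EPS)), 0)
  g[idx] <- g[idx] + gce
  g
}

#' Softmax over the label channel of a logits array
#' @param logits 4D array (`nx, ny, nz, n_labels`).
#' @return probability array of the same shape (channels sum to 1).
#' @export
softmax_probs <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[4])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), dim = d)
}

# Loss and gradient w.r.t. logits (softmax chain rule), used in training.
composite_loss_logits <- function(logits, truth, cfg = loss_config()) {
  probs <- softmax_probs(logits)
  val <- composite_loss(probs, truth, cfg)
  gp <- composite_loss_grad(probs, truth, cfg)
  d <- dim(probs)
  P <- matrix(probs, ncol = d[4])
  G <- matrix(gp, ncol = d[4])
  gz <- P * (G - rowSums(G * P))
  list(value = val, grad = array(gz, dim = d), probs = probs)
}
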