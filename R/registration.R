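# Multimodal rigid/affine registration with label propagation.
#
# Cross-modal similarity is normalised mutual information (NMI, 32 bins,
# first-order Parzen binning so the surface is smooth), optimised by a
# gradient-free Nelder-Mead simplex over a 3-level pyramid (x4 / x2 / x1
# block-mean downsampling). Everything is deterministic: fixed
# initialisation, no stochastic sampling.

# Matrix mapping 0-based fixed-grid voxel indices to continuous 0-based
# moving-grid indices, through world space and the world transform
# moving -> fixed (we sample the moving image at T^-1 of fixed points).
index_map <- function(transform_world, fixed_grid, moving_grid) {
  S_f <- diag(4)
  diag(S_f)[1:3] <- fixed_grid$spacing
  S_f[1:3, 4] <- fixed_grid$origin
  S_m <- diag(4)
  diag(S_m)[1:3] <- moving_grid$spacing
  S_m[1:3, 4] <- moving_grid$origin
  Minv <- solve(transform_matrix(transform_world))
  solve(S_m) %*% Minv %*% S_f
}

entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalised mutual information between two intensity samples
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` from a joint histogram with linear
#' (first-order Parzen) binning; 1 for independent images, up to 2 for a
#' deterministic relationship.
#'
#' @param a,b numeric vectors of paired samples.
#' @param bins histogram bins per axis (default 32).
#' @return scalar NMI.
#' @export
nmi <- function(a, b, bins = 32L) {
  H <- joint_hist_linear_cpp(a, b, bins, min(a), max(a), min(b), max(b))
  P <- H / sum(H)
  hj <- entropy(as.vector(P))
  if (hj == 0) return(2)
  (entropy(rowSums(P)) + entropy(colSums(P))) / hj
}

# Otsu's threshold on a 256-bin histogram: used to restrict the similarity
# to foreground (head) voxels of the fixed image, since the large noisy
# background otherwise dilutes the rotational information in the histogram.
otsu_threshold <- function(x, bins = 256L) {
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = bins + 1),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Correlation ratio eta^2-complement of the moving intensities given the
# binned fixed intensities: within-bin variance / total variance (lower is
# better). For tissue-wise monotone MR/PET relationships it is considerably
# smoother than NMI at the sub-degree scale, so it drives the final polish.
similarity_cr <- function(moving, fixed, transform, bins = 32L,
                          fixed_mask = NULL) {
  M <- index_map(transform, grid_of(fixed), grid_of(moving))
  rs <- resample_trilinear_cpp(moving$data, dim(moving$data), M,
                               dim(fixed$data), 0)
  keep <- rs$inside
  if (!is.null(fixed_mask)) keep <- keep & fixed_mask
  if (sum(keep) < 64) return(Inf)
  f <- as.vector(fixed$data)[keep]
  m <- as.vector(rs$values)[keep]
  b <- cut(f, bins, labels = FALSE)
  wvar <- sum(tapply(m, b, function(z) length(z) * stats::var(z)),
              na.rm = TRUE)
  wvar / (length(m) * stats::var(m))
}

# NMI of moving resampled through `transform` onto the fixed grid; only
# voxels inside the moving volume and (optionally) above the fixed-image
# foreground mask contribute.
similarity_nmi <- function(moving, fixed, transform, bins = 32L,
                           fixed_mask = NULL) {
  M <- index_map(transform, grid_of(fixed), grid_of(moving))
  rs <- resample_trilinear_cpp(moving$data, dim(moving$data), M,
                               dim(fixed$data), 0)
  keep <- rs$inside
  if (!is.null(fixed_mask)) keep <- keep & fixed_mask
  if (sum(keep) < 64) return(-Inf)
  nmi(as.vector(fixed$data)[keep], as.vector(rs$values)[keep], bins)
}

downsample_volume <- function(vol, times) {
  data <- vol$data
  spacing <- vol$spacing
  origin <- vol$origin
  for (i in seq_len(times)) {
    data <- downsample2_mean_cpp(data, dim(data))
    # block mean of voxels at o and o+s has centre o + s/2; spacing doubles
    origin <- origin + spacing / 2
    spacing <- spacing * 2
  }
  image_volume(data, spacing, origin, vol$modality)
}

default_reg_opts <- function() {
  list(bins = 32L, levels = c(4L, 2L, 1L), maxit = c(400L, 400L, 300L),
       rot_step = 2, trans_step = 4)
}

check_nonconstant <- function(vol, what) {
  if (max(vol$data) - min(vol$data) <= 0)
    stop("degenerate (constant) ", what, " image: registration undefined")
}

# Each pyramid level is lightly Gaussian-smoothed (1 voxel SD): trilinear
# resampling of noisy voxels otherwise roughens the NMI surface at the
# sub-degree scale the optimiser needs to resolve.
pyramid <- function(vol, levels, smooth_sd = 1) {
  lapply(levels, function(f) {
    v <- if (f == 1) vol else downsample_volume(vol, round(log2(f)))
    if (smooth_sd > 0) v$data <- gaussian_blur3(v$data, smooth_sd)
    v
  })
}

#' Rigid registration of a moving onto a fixed image
#'
#' Maximises NMI over the 6 rigid parameters (rotations in deg, translations
#' in mm; rotation centre = fixed-image physical centre) with Nelder-Mead on
#' a 3-level multi-resolution pyramid. Deterministic given `opts`.
#'
#' @param moving,fixed [image_volume()]s (typically MR and PET of one
#'   subject). Both must be nonconstant.
#' @param opts list overriding `bins`, `levels`, `maxit`; see source.
#' @param init optional initial [rigid_transform()].
#' @return list with `transform` ([rigid_transform()] moving to fixed),
#'   `similarity` (final NMI), and `converged` (logical; `FALSE` flags that
#'   the finest-level simplex hit its iteration cap).
#' @export
register_rigid <- function(moving, fixed, opts = list(), init = NULL) {
  check_nonconstant(moving, "moving")
  check_nonconstant(fixed, "fixed")
  o <- utils::modifyList(default_reg_opts(), opts)
  center <- fixed$origin + (dim(fixed$data) - 1) * fixed$spacing / 2
  par <- if (is.null(init)) rep(0, 6) else
    c(init$rotations, init$translations)
  mov_pyr <- pyramid(moving, o$levels)
  fix_pyr <- pyramid(fixed, o$levels)
  masks <- lapply(fix_pyr, function(v)
    as.vector(v$data) > otsu_threshold(as.vector(v$data)))
  converged <- TRUE
  scale6 <- c(rep(o$rot_step, 3), rep(o$trans_step, 3))
  nlev <- length(o$levels)
  for (li in seq_along(o$levels)) {
    fn6 <- function(p) {
      tr <- rigid_transform(p[1:3], p[4:6], center)
      -similarity_nmi(mov_pyr[[li]], fix_pyr[[li]], tr, o$bins, masks[[li]])
    }
    if (li == 1 && nlev > 1) {
      # the coarsest level carries almost no rotation information in these
      # small volumes: solve the translation first, rotation fixed
      fn3 <- function(t3) fn6(c(par[1:3], t3))
      res <- stats::optim(par[4:6], fn3, method = "Nelder-Mead",
                          control = list(maxit = o$maxit[1],
                                         parscale = rep(o$trans_step, 3),
                                         reltol = 1e-8))
      par[4:6] <- res$par
      next
    }
    if (li == 2 && is.null(init)) {
      # global rotation sweep: NMI is multimodal in rotation at the degree
      # scale, so seed the simplex from the best of a coarse grid
      grid <- as.matrix(expand.grid(r1 = seq(-6, 6, 2), r2 = seq(-6, 6, 2),
                                    r3 = seq(-6, 6, 2)))
      vals <- apply(grid, 1, function(r) fn6(c(r, par[4:6])))
      par[1:3] <- grid[which.min(vals), ]
    }
    res <- stats::optim(par, fn6, method = "Nelder-Mead",
                        control = list(maxit = o$maxit[li],
                                       parscale = scale6, reltol = 1e-8))
    par <- res$par
    if (li == nlev) {
      # coordinate-descent polish: 1D line searches travel the shallow
      # valley (rotation about the near-symmetric head axis) that collapses
      # the simplex. The polish objective is the correlation ratio, which
      # is markedly smoother than NMI at the sub-degree scale.
      fn_cr <- function(p) {
        tr <- rigid_transform(p[1:3], p[4:6], center)
        similarity_cr(mov_pyr[[li]], fix_pyr[[li]], tr, o$bins, masks[[li]])
      }
      for (sweep in 1:3) {
        for (j in 1:6) {
          opt1 <- stats::optimize(function(v) {
            p <- par; p[j] <- v; fn_cr(p)
          }, lower = par[j] - 2, upper = par[j] + 2, tol = 1e-3)
          par[j] <- opt1$minimum
        }
      }
      converged <- res$convergence == 0
    }
  }
  tr <- rigid_transform(par[1:3], par[4:6], center)
  # reported similarity is evaluated on the same smoothed/masked full-
  # resolution pair the optimiser saw, so nested refinements are comparable
  sim <- similarity_nmi(mov_pyr[[nlev]], fix_pyr[[nlev]], tr, o$bins,
                        masks[[nlev]])
  if (!converged)
    warning("rigid registration hit the iteration cap; returning best found")
  list(transform = tr, similarity = sim, converged = converged)
}

#' Affine refinement following a pre-rigid registration
#'
#' Optimises the 12 affine parameters (3x3 linear part + translation)
#' starting from `init`, with the same NMI/Nelder-Mead machinery on the two
#' finest pyramid levels. Used by the single-modality arm to fit a PET
#' template to a subject PET.
#'
#' @param moving,fixed [image_volume()]s.
#' @param init a [rigid_transform()] (typically from [register_rigid()]).
#' @param opts list as in [register_rigid()].
#' @return list with `transform` ([affine_transform()]), `similarity`,
#'   `converged`.
#' @export
register_affine <- function(moving, fixed, init = NULL, opts = list()) {
  check_nonconstant(moving, "moving")
  check_nonconstant(fixed, "fixed")
  o <- utils::modifyList(default_reg_opts(), opts)
  o$levels <- o$levels[o$levels <= 2]
  o$maxit <- rep_len(max(o$maxit) * 3L, length(o$levels))
  if (is.null(init)) init <- rigid_transform()
  M0 <- transform_matrix(init)
  par <- c(as.vector(M0[1:3, 1:3]), M0[1:3, 4])
  mov_pyr <- pyramid(moving, o$levels)
  fix_pyr <- pyramid(fixed, o$levels)
  masks <- lapply(fix_pyr, function(v)
    as.vector(v$data) > otsu_threshold(as.vector(v$data)))
  converged <- TRUE
  for (li in seq_along(o$levels)) {
    fn <- function(p) {
      A <- matrix(p[1:9], 3, 3)
      if (abs(det(A)) < 1e-6) return(Inf)
      tr <- affine_transform(A, p[10:12])
      -similarity_nmi(mov_pyr[[li]], fix_pyr[[li]], tr, o$bins, masks[[li]])
    }
    res <- stats::optim(par, fn, method = "Nelder-Mead",
                        control = list(maxit = o$maxit[li],
                                       parscale = c(rep(0.05, 9),
                                                    rep(o$trans_step, 3)),
                                       reltol = 1e-9))
    par <- res$par
    if (li == length(o$levels)) {
      # correlation-ratio coordinate polish, as in the rigid stage; the
      # 12-parameter simplex reliably under-recovers scale otherwise
      fn_cr <- function(p) {
        A <- matrix(p[1:9], 3, 3)
        if (abs(det(A)) < 1e-6) return(Inf)
        similarity_cr(mov_pyr[[li]], fix_pyr[[li]],
                      affine_transform(A, p[10:12]), o$bins, masks[[li]])
      }
      for (sweep in 1:3) {
        for (j in 1:12) {
          half <- if (j <= 9) 0.06 else 2.5
          opt1 <- stats::optimize(function(v) {
            p <- par; p[j] <- v; fn_cr(p)
          }, lower = par[j] - half, upper = par[j] + half, tol = 1e-4)
          par[j] <- opt1$minimum
        }
      }
      converged <- res$convergence == 0
    }
  }
  tr <- affine_transform(matrix(par[1:9], 3, 3), par[10:12])
  nf <- length(o$levels)
  sim <- similarity_nmi(mov_pyr[[nf]], fix_pyr[[nf]], tr, o$bins,
                        masks[[nf]])
  if (!converged)
    warning("affine registration hit the iteration cap; returning best found")
  list(transform = tr, similarity = sim, converged = converged)
}

#' Propagate a label map through a spatial transform
#'
#' Nearest-neighbour resampling of `labels` onto `target_grid` through
#' `transform` (which maps label space to target space). Intensity is never
#' interpolated across label boundaries.
#'
#' @param labels a [label_map()].
#' @param transform a spatial transform (label space -> target space).
#' @param target_grid grid descriptor (or an [image_volume()] /
#'   [label_map()]).
#' @return a [label_map()] on the target grid; warns when a label present in
#'   the input maps entirely outside the target grid.
#' @export
propagate_labels <- function(labels, transform, target_grid) {
  if (!is.null(target_grid$data)) target_grid <- grid_of(target_grid)
  M <- index_map(transform, target_grid, grid_of(labels))
  out <- resample_nearest_cpp(labels$data, dim(labels$data), M,
                              as.integer(target_grid$shape), 0L)
  res <- label_map(array(out, dim = target_grid$shape),
                   target_grid$spacing, target_grid$origin,
                   labels = labels$labels)
  lost <- setdiff(setdiff(unique(as.vector(labels$data)), 0L),
                  unique(as.vector(res$data)))
  if (length(lost)) {
    nm <- names(labels$labels)[match(lost, labels$labels)]
    warning("label(s) mapped outside the target grid (now empty): ",
            paste(nm, collapse = ", "))
  }
  res
}

#' Translation / rotation error between two rigid transforms
#'
#' Used to score registration recovery against a phantom's known
#' misalignment: the rotation error is the angle of the relative rotation,
#' the translation error the norm of the displacement difference at the
#' rotation centre.
#'
#' @param a,b [rigid_transform()]s.
#' @return list with `rotation_deg` and `translation_mm`.
#' @export
rigid_error <- function(a, b) {
  Ra <- rotation_matrix(a$rotations)
  Rb <- rotation_matrix(b$rotations)
  Rrel <- Ra %*% t(Rb)
  ang <- acos(pmin(1, pmax(-1, (sum(diag(Rrel)) - 1) / 2))) * 180 / pi
  pa <- apply_transform(a, a$center)
  pb <- apply_transform(b, a$center)
  list(rotation_deg = ang, translation_mm = sqrt(sum((pa - pb)^2)))
}
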