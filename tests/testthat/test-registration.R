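test_that("registering an image to itself returns the identity", {
  cfg <- small_exact_config()
  s <- generate_subject(cfg, "NL", "a", seed = 3)
  reg <- suppressWarnings(register_rigid(s$pet, s$pet))
  expect_lt(max(abs(reg$transform$rotations)), 0.1)
  expect_lt(max(abs(reg$transform$translations)), 0.1)

  aff <- suppressWarnings(register_affine(s$pet, s$pet,
                                          init = rigid_transform()))
  expect_lt(max(abs(aff$transform$matrix - diag(3))), 0.03)
  expect_lt(max(abs(aff$transform$translations)), 0.5)
})

test_that("optimised similarity is at least the identity-transform similarity", {
  cfg <- small_config()
  s <- generate_subject(cfg, "PD", "b", seed = 11)
  reg <- suppressWarnings(register_rigid(s$mr, s$pet))
  id_sim <- pdstriatum:::similarity_nmi(
    s$mr, s$pet, rigid_transform(),
    fixed_mask = as.vector(s$pet$data) >
      pdstriatum:::otsu_threshold(as.vector(s$pet$data)))
  expect_gte(reg$similarity, id_sim)
})

test_that("degenerate constant images are rejected", {
  flat <- image_volume(array(1, c(8, 8, 8)))
  bumpy <- image_volume(array(stats::rnorm(512), c(8, 8, 8)))
  expect_error(register_rigid(flat, bumpy), "constant")
  expect_error(register_rigid(bumpy, flat), "constant")
})

test_that("affine registration recovers an isotropic scale within 2%", {
  cfg <- small_exact_config()
  s <- generate_subject(cfg, "NL", "t", seed = 5)
  # scaled copy of the PET as the moving template (world-space scaling
  # about the volume centre, which is the origin here)
  scale <- 1.1
  tpl <- s$pet
  tpl$spacing <- s$pet$spacing * scale
  tpl$origin <- s$pet$origin * scale
  rig <- suppressWarnings(register_rigid(tpl, s$pet))
  aff <- suppressWarnings(register_affine(tpl, s$pet, rig$transform))
  # mapping template -> subject must shrink by 1/scale
  sv <- det(aff$transform$matrix)^(1 / 3)
  expect_equal(sv, 1 / scale, tolerance = 0.02)
  expect_gte(aff$similarity, rig$similarity - 1e-6)
})

test_that("label propagation is exact for identity and integer shifts", {
  cfg <- small_exact_config()
  s <- generate_subject(cfg, "NL", "p", seed = 8)
  lab <- s$labels_pet_space
  same <- propagate_labels(lab, rigid_transform(), lab)
  expect_identical(same$data, lab$data)

  # pure one-voxel translation on the matched grid shifts labels exactly
  shift <- rigid_transform(translations = c(lab$spacing[1], 0, 0))
  moved <- suppressWarnings(propagate_labels(lab, shift, lab))
  expect_identical(moved$data[2:dim(lab$data)[1], , ],
                   lab$data[seq_len(dim(lab$data)[1] - 1), , ])
  expect_true(all(moved$data %in% unique(as.vector(lab$data))))
})

test_that("propagation round-trip agrees away from region boundaries", {
  cfg <- small_config()
  s <- generate_subject(cfg, "NL", "r", seed = 13)
  lab <- s$labels_pet_space
  tr <- rigid_transform(c(3, -4, 2), c(2.5, -1.5, 3), center = c(0, 0, 0))
  fwd <- suppressWarnings(propagate_labels(lab, tr, lab))
  back <- suppressWarnings(propagate_labels(fwd, invert_transform(tr), lab))
  fg <- lab$data > 0 | back$data > 0
  agreement <- mean(lab$data[fg] == back$data[fg])
  expect_gte(agreement, 0.95)
})

test_that("labels lost outside the target grid raise a warning", {
  lab <- label_map(array(c(rep(0L, 63), 1L), c(4, 4, 4)),
                   spacing = c(1, 1, 1), origin = c(0, 0, 0))
  far <- rigid_transform(translations = c(100, 0, 0))
  expect_warning(propagate_labels(lab, far, lab), "outside the target")
})
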