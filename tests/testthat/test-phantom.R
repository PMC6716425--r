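test_that("generated subjects honour the configured uptake exactly when noise-free", {
  cfg <- exact_config()
  s <- generate_subject(cfg, "NL", "nl1", seed = 1)
  lab <- s$labels_pet_space$data
  dict <- sar_labels()
  for (r in sar_names()) {
    expect_equal(mean(s$pet$data[lab == dict[[r]]]),
                 unname(cfg$uptake_nl[[r]]), tolerance = 1e-12)
  }
  expect_equal(mean(s$pet$data[lab == dict[["occipital"]]]),
               cfg$occipital_uptake, tolerance = 1e-12)

  # zero PD effect: PD means equal NL means exactly
  cfg0 <- exact_config()
  cfg0$pd_effect[] <- 0
  pd <- generate_subject(cfg0, "PD", "pd1", seed = 1)
  expect_identical(pd$pet$data, s$pet$data)

  # whole-putamen mean SOR = (3 - 1)/1 = 2 by direct voxel averaging
  put <- s$pet$data[lab %in% dict[c("putamen_R", "putamen_L")]]
  occ <- s$pet$data[lab == dict[["occipital"]]]
  expect_equal((mean(put) - mean(occ)) / mean(occ), 2, tolerance = 1e-12)
})

test_that("subjects are bit-identical under a fixed (config, seed) pair", {
  cfg <- phantom_config()
  a <- generate_subject(cfg, "NL", "x", seed = 7)
  b <- generate_subject(cfg, "NL", "x", seed = 7)
  expect_identical(a$mr$data, b$mr$data)
  expect_identical(a$pet$data, b$pet$data)
  expect_identical(a$labels_mr_space$data, b$labels_mr_space$data)
  expect_identical(a$true_transform, b$true_transform)
})

test_that("PD uptake reduction is monotone in pd_effect and strongest posteriorly", {
  base <- exact_config()
  lab <- generate_subject(base, "NL", "n", seed = 3)$labels_pet_space$data
  putamen_mean <- function(effect) {
    cfg <- exact_config()
    cfg$pd_effect[c("putamen_R", "putamen_L")] <- effect
    s <- generate_subject(cfg, "PD", "p", seed = 3)
    mean(s$pet$data[lab %in% sar_labels()[c("putamen_R", "putamen_L")]])
  }
  m <- vapply(c(0, 0.2, 0.4, 0.6), putamen_mean, numeric(1))
  expect_true(all(diff(m) < 0))

  # anterior-posterior gradient: posterior putamen is more reduced
  cfg <- exact_config()
  s <- generate_subject(cfg, "PD", "p", seed = 3)
  coords <- voxel_coordinates(s$labels_pet_space)
  put <- lab == sar_labels()[["putamen_R"]]
  y <- coords[put, 2]
  v <- s$pet$data[put]
  ant <- v[y > stats::median(y)]
  post <- v[y <= stats::median(y)]
  expect_gt(mean(ant), mean(post))
})

test_that("gold-standard labels partition the declared regions", {
  cfg <- phantom_config()
  s <- generate_subject(cfg, "PD", "p", seed = 5)
  lab <- s$labels_mr_space$data
  expect_setequal(unique(as.vector(lab)), unname(sar_labels()))
  # partition is implicit (single integer per voxel); check every SAR is
  # nonempty and geometry errors trigger on overlap
  for (code in sar_labels()[sar_names()]) expect_gt(sum(lab == code), 0)
  bad <- phantom_config()
  bad$region_geometry$caudate_R$center <- bad$region_geometry$putamen_R$center
  expect_error(generate_subject(bad, "NL", "x", seed = 1), "overlap")
})

test_that("a grid too small for the anatomy raises a geometry error", {
  cfg <- phantom_config(grid_shape = c(8, 8, 8), voxel_spacing = c(1, 1, 1),
                        pet_shape = c(6, 6, 6), pet_spacing = c(2, 2, 2))
  expect_error(generate_subject(cfg, "NL", "x", seed = 1),
               "grid too small")
})

test_that("cohorts have the requested composition and are reproducible", {
  cfg <- small_config()
  co <- generate_cohort(cfg, n_pd = 4, n_nl = 3, seed = 9)
  expect_length(co, 7)
  expect_equal(sum(vapply(co, `[[`, character(1), "group") == "PD"), 4)
  co2 <- generate_cohort(cfg, n_pd = 4, n_nl = 3, seed = 9)
  expect_identical(lapply(co, `[[`, "pet"), lapply(co2, `[[`, "pet"))
  only_nl <- generate_cohort(cfg, n_pd = 0, n_nl = 3, seed = 1)
  expect_length(only_nl, 3)
  expect_true(all(vapply(only_nl, `[[`, character(1), "group") == "NL"))
})

test_that("cohorts round-trip through NIfTI files and the manifest", {
  dir <- withr::local_tempdir()
  cfg <- small_config()
  co <- generate_cohort(cfg, n_pd = 1, n_nl = 1, seed = 4)
  manifest_path <- write_cohort(co, dir)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  expect_equal(nrow(manifest), 2)
  mr <- read_nifti(manifest$mr_path[1], modality = "MR")
  expect_equal(mr$data, co[[1]]$mr$data, tolerance = 1e-6)
  expect_equal(mr$spacing, co[[1]]$mr$spacing, tolerance = 1e-6)
  lab <- read_nifti(manifest$labels_path[1], as_labels = TRUE)
  expect_identical(lab$data, co[[1]]$labels_mr_space$data)
  side <- jsonlite::read_json(file.path(dirname(manifest$mr_path[1]),
                                        "subject.json"),
                              simplifyVector = TRUE)
  expect_equal(unlist(side$true_transform$rotations),
               co[[1]]$true_transform$rotations, tolerance = 1e-9)
})
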