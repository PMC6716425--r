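test_that("region statistics match hand-computed values", {
  vol <- image_volume(array(c(1, 2, 3, 4, rep(0, 4)), c(2, 2, 2)))
  st <- region_statistics(vol, 1:4)
  expect_equal(unname(st["max"]), 4)
  expect_equal(unname(st["min"]), 1)
  expect_equal(unname(st["median"]), 2.5)
  expect_equal(unname(st["mean"]), 2.5)
  expect_equal(unname(st["q1"]), 1.75)  # linear interpolation, type 7
  expect_equal(unname(st["q3"]), 3.25)
  cvol <- image_volume(array(7, c(2, 2, 2)))
  expect_true(all(region_statistics(cvol, 1:8) == 7))
  expect_true(st["q1"] <= st["median"] && st["median"] <= st["q3"])
  expect_error(region_statistics(vol, integer(0), "putamen_R"), "putamen_R")
})

test_that("SOR is the reference-normalised difference and scale invariant", {
  expect_equal(sor(2, 1), 1)
  expect_equal(sor(3, 1), 2)
  expect_equal(sor(5, 5), 0)
  lambda <- 3.7
  expect_equal(sor(lambda * 2.4, lambda * 1.2), sor(2.4, 1.2),
               tolerance = 1e-12)
  expect_error(sor(1, 0), "nonpositive")
})

test_that("region volume is voxel count times voxel volume", {
  arr <- array(0L, c(10, 10, 10))
  arr[1:100] <- 1L
  lab <- label_map(arr, spacing = c(1, 1, 1))
  expect_equal(region_volume(lab, 1L), 100)
  lab2 <- label_map(arr, spacing = c(2, 1.5, 1))
  expect_equal(region_volume(lab2, 1L), 300)
  expect_warning(v0 <- region_volume(lab, 5L), "absent")
  expect_equal(v0, 0)
})

test_that("k-means subdivision recovers separated blobs and orders them anterior to posterior", {
  arr <- array(0L, c(6, 30, 6))
  arr[3:4, 2:4, 3:4] <- 1L    # posterior blob (low y)
  arr[3:4, 14:16, 3:4] <- 1L  # middle
  arr[3:4, 26:28, 3:4] <- 1L  # anterior (high y)
  lab <- label_map(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   labels = c(background = 0L, caudate_R = 1L))
  part <- subdivide_region(lab, 1L, k = 3, seed = 4)
  expect_s3_class(part, "sub_region_partition")
  # blobs recovered exactly: assignment constant within each blob
  coords <- voxel_coordinates(lab)[part$voxels, ]
  blob <- cut(coords[, 2], c(-1, 10, 20, 40), labels = FALSE)
  expect_equal(length(unique(paste(blob, part$assignment))), 3)
  # index 1 = most anterior
  expect_equal(unname(part$assignment[which.max(coords[, 2])]), 1L)
  expect_equal(unname(part$assignment[which.min(coords[, 2])]), 3L)
  # partition property and determinism
  expect_setequal(part$voxels, which(arr == 1L))
  part2 <- subdivide_region(lab, 1L, k = 3, seed = 4)
  expect_identical(part$assignment, part2$assignment)
  expect_error(subdivide_region(lab, 2L), "empty")
  tiny <- label_map(array(c(1L, 1L, rep(0L, 6)), c(2, 2, 2)),
                    labels = c(background = 0L, caudate_R = 1L))
  expect_error(subdivide_region(tiny, 1L, k = 3), "fewer")
})

test_that("extract_features emits exactly the canonical 90-feature vector", {
  cfg <- small_exact_config()
  s <- generate_subject(cfg, "NL", "s1", seed = 6)
  fv <- extract_features(s$pet, s$labels_pet_space, s$labels_mr_space,
                         seed = 1, id = "s1", group = "NL")
  expect_length(fv, 90)
  expect_identical(names(fv), feature_names())
  expect_equal(sum(grepl("_SOR$", names(fv))), 84)
  expect_equal(sum(grepl("_volume$", names(fv))), 6)
  expect_true(all(fv[grepl("_volume$", names(fv))] > 0))
  # noise-free world: whole-putamen mean SOR equals the configured contrast
  # (3 - 1)/1 on every putamen subregion mean
  put_means <- fv[grep("putamen_._sub._mean_SOR", names(fv))]
  expect_equal(unname(put_means), rep(2, 6), tolerance = 1e-12)
})

test_that("SOR features are scale invariant and volumes ignore PET entirely", {
  cfg <- small_exact_config()
  s <- generate_subject(cfg, "NL", "s1", seed = 6)
  fv <- extract_features(s$pet, s$labels_pet_space, s$labels_mr_space,
                         seed = 3)
  pet2 <- s$pet
  pet2$data <- pet2$data * 4.2
  fv2 <- extract_features(pet2, s$labels_pet_space, s$labels_mr_space,
                          seed = 3)
  expect_equal(as.numeric(fv2), as.numeric(fv), tolerance = 1e-10)
  # constant PET: every SOR is 0
  pet3 <- s$pet
  pet3$data[] <- 2
  fv3 <- extract_features(pet3, s$labels_pet_space, s$labels_mr_space,
                          seed = 3)
  expect_equal(unname(as.numeric(fv3[grepl("_SOR$", names(fv3))])),
               rep(0, 84), tolerance = 1e-12)
})

test_that("subregion indices correspond across subjects with shared geometry", {
  cfg <- small_exact_config()
  a <- generate_subject(cfg, "NL", "a", seed = 1)
  b <- generate_subject(cfg, "PD", "b", seed = 2)
  pa <- subdivide_region(a$labels_pet_space, 3L, seed = 5)
  pb <- subdivide_region(b$labels_pet_space, 3L, seed = 9)
  # subregion 3 has the most posterior centroid in both
  expect_lt(pa$centroids[3, 2], pa$centroids[1, 2])
  expect_lt(pb$centroids[3, 2], pb$centroids[1, 2])
  expect_equal(pa$centroids, pb$centroids, tolerance = 1e-9)
})

test_that("missing reference or empty SARs are reported by name", {
  cfg <- small_exact_config()
  s <- generate_subject(cfg, "NL", "s", seed = 6)
  noocc <- s$labels_pet_space
  noocc$data[noocc$data == 7L] <- 0L
  expect_error(extract_features(s$pet, noocc, s$labels_mr_space),
               "occipital")
  nopall <- s$labels_pet_space
  nopall$data[nopall$data == 5L] <- 0L
  expect_error(extract_features(s$pet, nopall, s$labels_mr_space),
               "pallidum_R")
})

test_that("feature tables round-trip through CSV", {
  cfg <- small_exact_config()
  s <- generate_subject(cfg, "NL", "s1", seed = 6)
  fv <- extract_features(s$pet, s$labels_pet_space, s$labels_mr_space,
                         seed = 1, id = "s1", group = "NL")
  tab <- feature_table(list(fv))
  expect_s3_class(tab, "feature_table")
  expect_equal(ncol(tab), 92)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(as.numeric(back[1, feature_names()]),
               as.numeric(tab[1, feature_names()]), tolerance = 1e-12)
})
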