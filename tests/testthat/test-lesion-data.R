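test_that("lesion volume scales with voxel count and voxel size", {
  geom2 <- test_geom(c(10L, 10L, 10L), vox = 2)
  les <- lesion_from_idx(c(10, 10, 10), 1:125)
  expect_equal(compute_volume_ml(les, geom2), 1.0)  # 125 x 0.008 ml
  expect_equal(compute_volume_ml(array(0, c(10, 10, 10)), geom2), 0.0)
  geom1 <- test_geom(c(10L, 10L, 10L), vox = 1)
  expect_equal(compute_volume_ml(lesion_from_idx(c(10, 10, 10), 5), geom1),
               0.001)
  expect_error(compute_volume_ml(array(0.4, c(10, 10, 10)), geom2),
               "binary")
})

test_that("volume is additive over disjoint lesions", {
  geom <- test_geom(c(10L, 10L, 10L))
  a <- lesion_from_idx(c(10, 10, 10), 1:40)
  b <- lesion_from_idx(c(10, 10, 10), 301:420)
  expect_equal(compute_volume_ml(a, geom) + compute_volume_ml(b, geom),
               compute_volume_ml(pmin(a + b, 1), geom))
})

test_that("load_cohort assembles masks and behavior in table order", {
  dir <- withr::local_tempdir()
  geom <- test_geom(c(8L, 8L, 8L))
  shp <- c(8, 8, 8)
  lesions <- list(a = lesion_from_idx(shp, 1:10),
                  b = lesion_from_idx(shp, 5:30),
                  c = lesion_from_idx(shp, 100:140))
  for (nm in names(lesions))
    write_volume(lesions[[nm]], geom, file.path(dir, paste0(nm, ".nii.gz")))
  write.csv(data.frame(subject_id = c("b", "a", "c"), score = c(2, 0, 5),
                       mrs = c(1, 0, 3)),
            file.path(dir, "behavior.csv"), row.names = FALSE)
  co <- load_cohort(file.path(dir, paste0(c("a", "b", "c"), ".nii.gz")),
                    file.path(dir, "behavior.csv"))
  expect_s3_class(co, "lesion_cohort")
  expect_identical(co$subjects, c("b", "a", "c"))  # table order
  expect_equal(co$behavior, c(2, 0, 5))
  expect_equal(co$volumes_ml,
               c(26, 10, 41) * geom$voxel_volume_ml, ignore_attr = TRUE)
  expect_equal(co$covariates$mrs, c(1, 0, 3))
})

test_that("load_cohort rejects mismatched geometry, ids and non-binary data", {
  dir <- withr::local_tempdir()
  geom8 <- test_geom(c(8L, 8L, 8L))
  write_volume(lesion_from_idx(c(8, 8, 8), 1:10), geom8,
               file.path(dir, "s1.nii.gz"))
  write_volume(lesion_from_idx(c(8, 8, 8), 1:20), geom8,
               file.path(dir, "s2.nii.gz"))
  write_volume(lesion_from_idx(c(6, 6, 6), 1:10), test_geom(c(6L, 6L, 6L)),
               file.path(dir, "s3.nii.gz"))
  tab3 <- data.frame(subject_id = c("s1", "s2", "s3"), score = 1:3)
  write.csv(tab3, file.path(dir, "b3.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(dir, c("s1.nii.gz", "s2.nii.gz",
                                            "s3.nii.gz")),
                           file.path(dir, "b3.csv")),
               "geometry mismatch.*s3")
  write.csv(data.frame(subject_id = c("s1", "s2", "ghost"), score = 1:3),
            file.path(dir, "bg.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(dir, c("s1.nii.gz", "s2.nii.gz")),
                           file.path(dir, "bg.csv")),
               "ghost")
  # interpolation dust is snapped; clearly non-binary values are rejected
  dusty <- lesion_from_idx(c(8, 8, 8), 1:10)
  dusty[1] <- 0.3
  dusty[2] <- 0.8
  write_volume(dusty, geom8, file.path(dir, "s4.nii.gz"))
  write.csv(data.frame(subject_id = "s4", score = 1),
            file.path(dir, "b4.csv"), row.names = FALSE)
  co <- load_cohort(file.path(dir, "s4.nii.gz"), file.path(dir, "b4.csv"))
  expect_equal(sum(co$lesions[[1]]), 9)  # 0.3 -> 0, 0.8 -> 1
  bad <- lesion_from_idx(c(8, 8, 8), 1:10)
  bad[3] <- 1.5
  write_volume(bad, geom8, file.path(dir, "s5.nii.gz"))
  write.csv(data.frame(subject_id = "s5", score = 1),
            file.path(dir, "b5.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "s5.nii.gz"),
                           file.path(dir, "b5.csv")),
               "outside \\[0, 1\\]")
})

test_that("analysis mask equals brute-force overlap counting", {
  co <- random_cohort(n = 20, seed = 42)
  counts <- array(0L, dim = co$geometry$shape)
  for (L in co$lesions) counts <- counts + L  # independent loop
  for (mo in c(1L, 3L, 5L)) {
    mask <- build_analysis_mask(co, mo)
    expect_identical(mask$mask, counts >= mo)
    expect_identical(mask$column_index, which(counts >= mo))
  }
  # min_overlap = 1 is the union of all lesions
  expect_identical(build_analysis_mask(co, 1L)$mask, counts >= 1L)
})

test_that("a voxel shared by exactly all subjects survives its threshold", {
  shp <- c(6, 6, 6)
  shared <- 111L
  lesions <- list(lesion_from_idx(shp, c(shared, 1, 2)),
                  lesion_from_idx(shp, c(shared, 30, 31)),
                  lesion_from_idx(shp, c(shared, 200)))
  co <- lesion_cohort(lesions, c(1, 2, 3), test_geom(c(6L, 6L, 6L)))
  mask <- build_analysis_mask(co, 3L)
  expect_identical(mask$column_index, shared)
  expect_error(build_analysis_mask(co, 4L), "between 1 and")
  disjoint <- list(lesion_from_idx(shp, 1:3), lesion_from_idx(shp, 10:12))
  co2 <- lesion_cohort(disjoint, c(1, 2), test_geom(c(6L, 6L, 6L)))
  expect_error(build_analysis_mask(co2, 2L), "empty")
})

test_that("subjects lesioned only outside the mask are excluded", {
  shp <- c(8, 8, 8)
  core <- 200:220
  lesions <- c(
    lapply(1:46, function(i) lesion_from_idx(shp, c(core, i))),
    lapply(c(1, 5, 9, 13), function(i) lesion_from_idx(shp, 400 + i)))
  co <- lesion_cohort(lesions, seq_along(lesions), test_geom(c(8L, 8L, 8L)))
  mask <- build_analysis_mask(co, 10L)
  res <- exclude_nonoverlapping_subjects(co, mask)
  expect_identical(res$excluded, sprintf("s%03d", 47:50))
  expect_length(res$cohort$subjects, 46)
  expect_equal(res$cohort$behavior, 1:46)
  # when everyone overlaps, nothing changes
  res2 <- exclude_nonoverlapping_subjects(res$cohort, mask)
  expect_length(res2$excluded, 0)
  expect_identical(res2$cohort$subjects, res$cohort$subjects)
})

test_that("flatten maps lesion status to mask columns and round-trips", {
  shp <- c(6, 6, 6)
  lesions <- list(lesion_from_idx(shp, c(10, 20, 30)),
                  lesion_from_idx(shp, c(10, 20)),
                  lesion_from_idx(shp, c(20, 30, 40)))
  co <- lesion_cohort(lesions, 1:3, test_geom(c(6L, 6L, 6L)))
  mask <- build_analysis_mask(co, 2L)  # voxels 10, 20, 30
  expect_identical(mask$column_index, c(10L, 20L, 30L))
  X <- flatten_cohort(co, mask)
  expect_equal(dim(X), c(3L, 3L))
  expect_equal(X[2, ], c(1, 1, 0), ignore_attr = TRUE)
  expect_true(all(colSums(X) >= mask$min_overlap))
  for (i in 1:3) {
    vol <- unflatten_to_volume(X[i, ], mask)
    expect_equal(vol[mask$column_index],
                 co$lesions[[i]][mask$column_index])
    expect_true(all(vol[-mask$column_index] == 0))
  }
})

test_that("flatten round-trips on random cohorts", {
  co <- random_cohort(n = 15, seed = 7)
  mask <- build_analysis_mask(co, 4L)
  X <- flatten_cohort(co, mask)
  expect_equal(ncol(X), length(mask$column_index))
  expect_true(all(colSums(X) >= 4))
  for (i in c(1, 8, 15))
    expect_equal(unflatten_to_volume(X[i, ], mask)[mask$mask],
                 co$lesions[[i]][mask$mask])
})
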