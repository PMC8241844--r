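test_that("identical config and seed give bit-identical cohorts", {
  cfg <- fast_config(n_subjects = 12, seed = 5)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$lesions, g2$cohort$lesions)
  expect_identical(g1$cohort$behavior, g2$cohort$behavior)
  expect_identical(g1$truth, g2$truth)
  n1 <- generate_null_cohort(cfg)
  n2 <- generate_null_cohort(cfg)
  expect_identical(n1$behavior, n2$behavior)
  expect_identical(n1$lesions, n2$lesions)
})

test_that("subject k is reproducible independent of cohort size", {
  g_small <- generate_cohort(fast_config(n_subjects = 5, seed = 9))
  g_big <- generate_cohort(fast_config(n_subjects = 11, seed = 9))
  expect_identical(g_small$cohort$lesions, g_big$cohort$lesions[1:5])
})

test_that("zero effect, zero volume effect, zero noise gives constant scores", {
  cfg <- fast_config(n_subjects = 10, seed = 3, effect_size = 0,
                     volume_effect = 0, noise_sd = 0, intercept = 2.2)
  g <- generate_cohort(cfg)
  expect_true(all(g$cohort$behavior == 2))  # round-half-up(2.2) = 2
})

test_that("observed scores respect the configured range", {
  cfg <- fast_config(n_subjects = 40, seed = 21, effect_size = 30,
                     noise_sd = 8)
  g <- generate_cohort(cfg)
  expect_true(all(g$cohort$behavior >= 0 & g$cohort$behavior <= 10))
  cfg2 <- fast_config(n_subjects = 20, seed = 21, score_range = c(0L, 6L))
  expect_true(all(generate_cohort(cfg2)$cohort$behavior <= 6))
})

test_that("score is non-decreasing in damage at zero noise and volume effect", {
  cfg <- fast_config(n_subjects = 50, seed = 13, volume_effect = 0,
                     noise_sd = 0, effect_size = 6)
  g <- generate_cohort(cfg)
  ord <- order(g$truth$damage_fraction)
  expect_true(all(diff(g$cohort$behavior[ord]) >= 0))
  # damage_fraction definition: |lesion intersect region| / |region|
  region <- which(g$truth$critical_region_mask)
  d <- vapply(g$cohort$lesions,
              function(L) sum(L[region]) / length(region), numeric(1))
  expect_equal(d, g$truth$damage_fraction)
})

test_that("default volume distribution hits the target median within 20%", {
  g <- generate_cohort(simulation_config(n_subjects = 1000, seed = 31))
  med <- median(g$cohort$volumes_ml)
  expect_gt(med, 3.3 * 0.8)
  expect_lt(med, 3.3 * 1.2)
  # right skew: mean well above the median
  expect_gt(mean(g$cohort$volumes_ml), med)
})

test_that("volume effect induces a positive score-volume correlation", {
  cfg <- simulation_config(n_subjects = 400, seed = 17, volume_effect = 1.2)
  g <- generate_cohort(cfg)
  r <- cor(g$cohort$behavior, log(g$cohort$volumes_ml))
  expect_gt(r, 0)
  # large-n oracle: regenerate at 10x n, require agreement within 3 SE
  cfg10 <- simulation_config(n_subjects = 4000, seed = 18, volume_effect = 1.2)
  g10 <- generate_cohort(cfg10)
  r10 <- cor(g10$cohort$behavior, log(g10$cohort$volumes_ml))
  se <- sqrt(1 / (400 - 3))
  expect_lt(abs(atanh(r) - atanh(r10)), 3 * se)
})

test_that("null cohorts sever the lesion-score link but keep the marginal", {
  cfg <- simulation_config(n_subjects = 1000, seed = 23)
  g <- generate_cohort(cfg)
  nullco <- generate_null_cohort(cfg)
  # same score marginal (a permutation of the same vector)
  expect_identical(sort(nullco$behavior), sort(g$cohort$behavior))
  expect_false(identical(nullco$behavior, g$cohort$behavior))
  # correlation with damage fraction is 0 within 3 SE at n = 1000
  r <- cor(nullco$behavior, g$truth$damage_fraction)
  expect_lt(abs(r), 3 / sqrt(1000 - 3))
})

test_that("lesions are connected under face connectivity", {
  g <- generate_cohort(fast_config(n_subjects = 8, seed = 77))
  for (L in g$cohort$lesions) {
    lab <- label_components(L > 0, connectivity = 6)
    expect_equal(max(lab), 1L)
  }
})

test_that("effect_size_for_r2 calibrates the damage share of latent variance", {
  cfg <- simulation_config(n_subjects = 200, seed = 1)
  e <- effect_size_for_r2(cfg, 0.4, n_pilot = 800)
  cfg2 <- simulation_config(n_subjects = 3000, seed = 41, effect_size = e)
  g <- generate_cohort(cfg2)
  share <- var(e * g$truth$damage_fraction) / var(g$truth$latent_scores)
  expect_gt(share, 0.33)
  expect_lt(share, 0.47)
})

test_that("toy tract maps peak on the centerline and fall off with radius", {
  geom <- test_geom(c(12L, 12L, 12L))
  cl <- cbind(i = 2:11, j = 6, k = 6)
  atlas <- generate_toy_tract_atlas(geom, list(
    list(name = "tube", centerline = cl, radius_mm = 4, peak_prob = 1),
    list(name = "thin", centerline = cl, radius_mm = 0.05, peak_prob = 0.8)))
  expect_equal(atlas$tracts$tube[6, 6, 6], 1.0)
  # near-zero one voxel off a near-zero-radius tube
  expect_lt(atlas$tracts$thin[6, 7, 6], 1e-6)
  expect_equal(atlas$tracts$thin[6, 6, 6], 0.8)
  expect_error(generate_toy_tract_atlas(geom, list(
    list(name = "bad", centerline = cl, radius_mm = 1, peak_prob = 1.2))),
    "peak_prob")
  expect_error(generate_toy_tract_atlas(geom, list(
    list(name = "oob", centerline = cbind(1:20, 6, 6), radius_mm = 1,
         peak_prob = 1))),
    "leaves the grid")
})

test_that("disjoint tubes have disjoint supports above any threshold", {
  geom <- test_geom(c(16L, 16L, 16L))
  atlas <- generate_toy_tract_atlas(geom, list(
    list(name = "left", centerline = cbind(4, 2:15, 4), radius_mm = 1.5,
         peak_prob = 1),
    list(name = "right", centerline = cbind(13, 2:15, 13), radius_mm = 1.5,
         peak_prob = 1)))
  a <- atlas$tracts$left > 0.05
  b <- atlas$tracts$right > 0.05
  expect_equal(sum(a & b), 0)
  expect_gt(sum(a), 0)
})

test_that("cohorts written to disk round-trip through load_cohort", {
  dir <- withr::local_tempdir()
  g <- generate_cohort(fast_config(n_subjects = 6, seed = 55))
  write_cohort(g$cohort, dir, truth = g$truth)
  co <- load_cohort(Sys.glob(file.path(dir, "s*.nii.gz")),
                    file.path(dir, "behavior.csv"))
  expect_identical(co$subjects, g$cohort$subjects)
  expect_equal(co$behavior, g$cohort$behavior)
  expect_equal(co$lesions, g$cohort$lesions, ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "truth_critical_region.nii.gz")))
})
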