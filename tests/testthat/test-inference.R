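make_scheme <- function(...) suppressWarnings(permutation_scheme(...))

test_that("component labeling matches the flood-fill oracle on random grids", {
  for (seed in 1:3) {
    set.seed(seed)
    arr <- array(runif(20^3) < 0.12, dim = c(20, 20, 20))
    for (conn in c(6L, 18L, 26L)) {
      lab <- label_components(arr, conn)
      oracle <- flood_fill_oracle(arr, conn)
      expect_true(same_partition(lab, oracle))
    }
  }
})

test_that("labels are ordered by size with ties broken by smallest index", {
  arr <- array(FALSE, dim = c(10, 10, 10))
  arr[7:9, 7, 7] <- TRUE          # 3 voxels, later indices
  arr[1:5, 1, 1] <- TRUE          # 5 voxels
  arr[1:3, 5, 5] <- TRUE          # 3 voxels, earlier start
  lab <- label_components(arr, 26)
  expect_equal(max(lab), 3L)
  expect_true(all(lab[1:5, 1, 1] == 1L))
  expect_true(all(lab[1:3, 5, 5] == 2L))   # tie -> smaller linear index
  expect_true(all(lab[7:9, 7, 7] == 3L))
})

test_that("coarser connectivity never merges what finer connectivity separates", {
  for (seed in 4:6) {
    set.seed(seed)
    arr <- array(runif(15^3) < 0.15, dim = c(15, 15, 15))
    n6 <- max(label_components(arr, 6))
    n18 <- max(label_components(arr, 18))
    n26 <- max(label_components(arr, 26))
    expect_gte(n6, n18)
    expect_gte(n18, n26)
  }
})

test_that("cluster FWE p-values follow the add-one estimator", {
  clusters <- structure(list(
    labels = array(0L, c(4, 4, 4)),
    clusters = data.frame(id = 1L, voxel_count = 15L, peak_voxel = 1L),
    connectivity = 26L, geometry = test_geom(c(4L, 4L, 4L))),
    class = "cluster_set")
  out <- cluster_fwe(clusters, c(5, 10, 20))
  expect_equal(out$clusters$fwe_p, (1 + 1) / (3 + 1))  # only 20 >= 15
  big <- clusters
  big$clusters$voxel_count <- 500L
  expect_equal(cluster_fwe(big, rep(3L, 999))$clusters$fwe_p, 1 / 1000)
  expect_error(cluster_fwe(clusters, numeric(0)), "empty")
  # monotonicity: larger clusters never get larger fwe_p
  multi <- clusters
  multi$clusters <- data.frame(id = 1:3, voxel_count = c(40L, 12L, 3L),
                               peak_voxel = 1:3)
  fp <- cluster_fwe(multi, c(2, 5, 9, 14, 33))$clusters$fwe_p
  expect_true(all(diff(fp) >= 0))
})

test_that("thresholding separates blobs and tolerates empty results", {
  geom <- test_geom(c(12L, 12L, 12L))
  mask_arr <- array(TRUE, dim = c(12, 12, 12))
  mask <- structure(list(mask = mask_arr, min_overlap = 1L,
                         column_index = which(mask_arr), geometry = geom),
                    class = "analysis_mask")
  B <- 999L
  p <- rep(1, length(mask$column_index))
  arr <- array(FALSE, c(12, 12, 12))
  arr[2:4, 2:4, 2] <- TRUE
  arr[8:10, 8:10, 8] <- TRUE
  p[which(arr[mask$column_index])] <- 1 / (B + 1)
  pm <- structure(list(p = p, direction = "one-sided", n_permutations = B,
                       mask = mask), class = "voxel_pmap")
  scheme <- make_scheme(n_permutations = B, voxel_alpha = 0.005)
  cl <- threshold_and_cluster(pm, mask, scheme)
  expect_equal(nrow(cl$clusters), 2L)
  expect_equal(sort(cl$clusters$voxel_count), c(9L, 9L))
  # nothing significant -> empty but valid cluster set
  pm$p <- rep(0.5, length(p))
  cl0 <- threshold_and_cluster(pm, mask, scheme)
  expect_equal(nrow(cl0$clusters), 0L)
  expect_true(all(cl0$labels == 0L))
})

test_that("cluster report maps centers through the affine and filters by size", {
  geom <- test_geom(c(10L, 10L, 10L), vox = 2)
  labels <- array(0L, c(10, 10, 10))
  labels[3, 4, 5] <- 2L
  labels[3, 4, 6] <- 2L                      # vertical two-voxel cluster
  labels[6, 6, 6] <- 1L
  labels[7, 6, 6] <- 1L                      # symmetric two-voxel cluster
  clusters <- structure(list(
    labels = labels,
    clusters = data.frame(id = 1:2, voxel_count = c(2L, 2L),
                          peak_voxel = c(1L, 2L), fwe_p = c(0.02, 0.8)),
    connectivity = 26L, geometry = geom), class = "cluster_set")
  scheme <- make_scheme(n_permutations = 99, min_report_voxels = 1L)
  rep1 <- cluster_report(clusters, geom, scheme)
  expect_equal(nrow(rep1), 2L)
  # center of mass maps through the affine on fractional voxel indices
  single <- rep1[rep1$cluster == 2, ]
  expect_equal(c(single$center_x_mm, single$center_y_mm, single$center_z_mm),
               as.vector(voxel_to_world(c(3, 4, 5.5), geom)))
  # two-voxel cluster: midpoint of the two voxel centers
  pair <- rep1[rep1$cluster == 1, ]
  mid <- (voxel_to_world(c(6, 6, 6), geom) + voxel_to_world(c(7, 6, 6), geom)) / 2
  expect_equal(c(pair$center_x_mm, pair$center_y_mm, pair$center_z_mm),
               as.vector(mid))
  expect_true(pair$fwe_significant)
  expect_false(single$fwe_significant)
  expect_equal(rep1$cluster, c(1L, 2L))  # sorted by increasing fwe_p
  # size filter: 60 and 40 voxels at min_report_voxels = 50 -> one row
  clusters$clusters$voxel_count <- c(60L, 40L)
  scheme50 <- make_scheme(n_permutations = 99, min_report_voxels = 50L)
  expect_equal(nrow(cluster_report(clusters, geom, scheme50)), 1L)
})

test_that("permutation inference is deterministic with a bounded p floor", {
  cfg <- fast_config(n_subjects = 40, seed = 61, effect_size = 8,
                     noise_sd = 0.8)
  g <- generate_cohort(cfg)
  mask <- build_analysis_mask(g$cohort, 8L)
  ex <- exclude_nonoverlapping_subjects(g$cohort, mask)
  X <- flatten_cohort(ex$cohort, mask)
  nc <- nuisance_control(X, ex$cohort$behavior, ex$cohort$volumes_ml)
  scheme <- make_scheme(n_permutations = 49L, seed = 9)
  p1 <- permutation_test(nc$X_resid, nc$y_resid, svr_hyperparams(), scheme,
                         mask)
  p2 <- permutation_test(nc$X_resid, nc$y_resid, svr_hyperparams(), scheme,
                         mask)
  expect_identical(p1$pmap$p, p2$pmap$p)
  expect_identical(p1$null_max_sizes, p2$null_max_sizes)
  expect_identical(p1$beta_map$beta, p2$beta_map$beta)
  expect_gte(min(p1$pmap$p), 1 / 50)
  expect_lte(max(p1$pmap$p), 1)
  expect_equal(length(p1$null_max_sizes), 49L)
  # B below 19 is refused
  expect_error(permutation_test(nc$X_resid, nc$y_resid, svr_hyperparams(),
                                make_scheme(n_permutations = 10L), mask),
               "19")
})

test_that("voxel p-values use the one-sided add-one rank of observed beta", {
  cfg <- fast_config(n_subjects = 30, seed = 62)
  g <- generate_cohort(cfg)
  mask <- build_analysis_mask(g$cohort, 6L)
  ex <- exclude_nonoverlapping_subjects(g$cohort, mask)
  X <- flatten_cohort(ex$cohort, mask)
  nc <- nuisance_control(X, ex$cohort$behavior, ex$cohort$volumes_ml)
  scheme <- make_scheme(n_permutations = 39L, seed = 17)
  params <- svr_hyperparams(C = 3, gamma = 0.02, epsilon = 0.1)
  perm <- permutation_test(nc$X_resid, nc$y_resid, params, scheme, mask)
  # recompute the permuted betas independently from the same seed stream
  K <- rbf_kernel(nc$X_resid, gamma = 0.02)
  seeds <- lesionmap:::derive_seeds(17L, 39L)
  counts <- numeric(ncol(X))
  for (b in 1:39) {
    set.seed(seeds[b])
    yp <- nc$y_resid[sample.int(length(nc$y_resid))]
    fit <- lesionmap:::fit_svr_kernel(K, yp, 3, 0.1)
    bet <- drop(crossprod(nc$X_resid, fit$dual_coef))
    counts <- counts + (bet >= perm$beta_map$beta)
  }
  expect_equal(perm$pmap$p, (1 + counts) / 40)
})
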