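test_that("local maxima: singles, plateaus, and border handling", {
  v <- array(1, c(5, 5, 5)); v[3, 3, 3] <- 9
  mx <- find_local_maxima_3d(v)
  expect_length(mx, 1)
  expect_equal(mx[[1]]$centroid, c(3, 3, 3))
  expect_equal(mx[[1]]$value, 9)
  # a 3-voxel equal-intensity plateau is one maximum, not three; the
  # adjacent strictly lower 2-voxel is not a maximum
  v2 <- array(0, c(5, 7, 7)); v2[3, 3, 3:5] <- 5; v2[3, 4, 4] <- 2
  mx2 <- find_local_maxima_3d(v2)
  expect_length(mx2, 1)
  expect_length(mx2[[1]]$voxels, 3)
  expect_equal(mx2[[1]]$value, 5)
  expect_equal(mx2[[1]]$centroid, c(3, 3, 4))
  # maximum at a corner counts only in-bounds neighbours
  v3 <- array(0, c(4, 4, 4)); v3[1, 1, 1] <- 7
  expect_length(find_local_maxima_3d(v3), 1)
})

test_that("local maxima match the exhaustive oracle on random volumes", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- array(sample(0:6, 8 * 8 * 4, replace = TRUE), c(4, 8, 8))
    for (conn in c(6, 18, 26)) {
      got <- find_local_maxima_3d(v, conn)
      got_sets <- lapply(got, function(m) sort(m$voxels))
      want_sets <- bf_local_maxima(v, conn)
      key <- function(s) paste(s, collapse = ",")
      expect_setequal(vapply(got_sets, key, character(1)),
                      vapply(want_sets, key, character(1)))
    }
  }
})

test_that("background shell matches explicit enumeration, incl. borders and ball mode", {
  expect_equal(background_at_maximum(array(4, c(15, 15, 15)), c(8, 8, 8)), 4)
  set.seed(3)
  v <- array(sample(0:30, 20 * 20 * 10, replace = TRUE), c(10, 20, 20))
  for (cen in list(c(5, 10, 10), c(1, 1, 1), c(10, 20, 3), c(2, 7, 19))) {
    expect_equal(background_at_maximum(v, cen),
                 bf_shell_stat(v, cen, 6, 0.5, "shell", "mean"))
    expect_equal(background_at_maximum(v, cen,
                                       foci_params(background_stat = "median")),
                 bf_shell_stat(v, cen, 6, 0.5, "shell", "median"))
    expect_equal(background_at_maximum(v, cen, foci_params(shell_mode = "ball")),
                 bf_shell_stat(v, cen, 6, 0.5, "ball", "mean"))
  }
  # fractional centroid path
  cen <- c(5.5, 9.25, 10.75)
  expect_equal(background_at_maximum(v, cen),
               bf_shell_stat(v, cen, 6, 0.5, "shell", "mean"))
  # volume entirely smaller than the shell: degenerate
  expect_error(background_at_maximum(array(1:8, c(2, 2, 2)), c(1, 1, 1)),
               "degenerate shell")
})

test_that("region growth equals flood fill at the alpha level", {
  v <- array(0, c(9, 15, 15))
  v <- add_gauss_fixture(v, 5, 8, 8, 100, 1.6)
  v <- round(v)
  mx <- find_local_maxima_3d(v)
  expect_length(mx, 1)
  bg <- background_at_maximum(v, mx[[1]])
  reg <- grow_focus_region(v, mx[[1]], bg)
  thr <- bg + 0.5 * (mx[[1]]$value - bg)
  expect_identical(reg, bf_flood(v, mx[[1]]$voxels, thr))
  # alpha = 1 recovers the plateau itself
  reg1 <- grow_focus_region(v, mx[[1]], bg, foci_params(growth_fraction = 1))
  expect_setequal(reg1, mx[[1]]$voxels)
  # peak alone above threshold
  v2 <- array(0, c(13, 13, 13)); v2[7, 7, 7] <- 10
  mx2 <- find_local_maxima_3d(v2)
  bg2 <- background_at_maximum(v2, mx2[[1]])
  reg2 <- grow_focus_region(v2, mx2[[1]], bg2)
  expect_equal(length(reg2), 1)
  # decreasing alpha never shrinks the region
  sizes <- vapply(c(0.9, 0.6, 0.3, 0.1), function(a)
    length(grow_focus_region(v, mx[[1]], bg, foci_params(growth_fraction = a))),
    integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("detect_foci basics: constant volume, strict size filter", {
  expect_equal(nrow(detect_foci(array(5, c(8, 20, 20)))$foci), 0)
  # a k-voxel box plateau gives a region of exactly k voxels
  mk_box <- function(k_z, k_y, k_x) {
    v <- array(0, c(10, 24, 24))
    v[4:(3 + k_z), 10:(9 + k_y), 10:(9 + k_x)] <- 50
    v
  }
  v9 <- mk_box(1, 3, 3)   # 9-voxel plateau
  expect_equal(nrow(detect_foci(v9, foci_params(min_voxels = 8))$foci), 1)
  expect_equal(nrow(detect_foci(v9, foci_params(min_voxels = 9))$foci), 0)
  v21 <- mk_box(1, 3, 7)  # 21 voxels
  expect_equal(nrow(detect_foci(v21, foci_params(min_voxels = 20))$foci), 1)
  expect_equal(nrow(detect_foci(v21, foci_params(min_voxels = 21))$foci), 0)
})

test_that("rendered Gaussian focus passes or fails the size filter as counted", {
  v <- array(0, c(10, 24, 24))
  v <- round(add_gauss_fixture(v, 5, 12, 12, 80, 1.6))
  mx <- find_local_maxima_3d(v)
  bg <- background_at_maximum(v, mx[[1]])
  n_region <- length(bf_flood(v, mx[[1]]$voxels, bg + 0.5 * (mx[[1]]$value - bg)))
  expect_gt(n_region, 20)
  fs_small <- detect_foci(v, foci_params(min_voxels = 20L))
  expect_equal(nrow(fs_small$foci), 1)
  expect_equal(fs_small$foci$size_vox, n_region)
  fs_big <- detect_foci(v, foci_params(min_voxels = as.integer(n_region)))
  expect_equal(nrow(fs_big$foci), 0)
})

test_that("two nearby foci are split into disjoint regions; reject mode drops them", {
  v <- array(0, c(10, 30, 30))
  v <- add_gauss_fixture(v, 5, 15, 11, 90, 1.6)
  v <- round(add_gauss_fixture(v, 5, 15, 21, 80, 1.6))
  fs <- detect_foci(v, foci_params(min_voxels = 8))
  expect_equal(nrow(fs$foci), 2)
  expect_equal(length(intersect(fs$regions[[1]], fs$regions[[2]])), 0)
  # monotonicity of the size filter on the same volume
  n_by_min <- vapply(c(2L, 8L, 20L, 60L), function(mv)
    nrow(detect_foci(v, foci_params(min_voxels = mv))$foci), integer(1))
  expect_true(all(diff(n_by_min) <= 0))
  # reject mode never reports more foci than split mode
  n_rej <- nrow(detect_foci(v, foci_params(min_voxels = 8,
                                           multi_max_policy = "reject"))$foci)
  expect_lte(n_rej, 2)
})

test_that("mask restriction yields a subset of unmasked detections", {
  v <- array(0, c(10, 40, 40))
  v <- add_gauss_fixture(v, 5, 10, 10, 90, 1.5)
  v <- round(add_gauss_fixture(v, 5, 30, 30, 90, 1.5))
  mask <- array(0L, dim(v)); mask[, 1:20, 1:20] <- 1L
  fs_all <- detect_foci(v, foci_params(min_voxels = 8))
  fs_msk <- detect_foci(v, foci_params(min_voxels = 8), mask = mask)
  expect_equal(nrow(fs_all$foci), 2)
  expect_equal(nrow(fs_msk$foci), 1)
  key <- function(tb) paste(round(tb$z), round(tb$y), round(tb$x))
  expect_true(all(key(fs_msk$foci) %in% key(fs_all$foci)))
})

test_that("foci are assigned to nuclei with zero-count nuclei included", {
  v <- array(0, c(6, 30, 30))
  v <- add_gauss_fixture(v, 3, 10, 8, 90, 1.4)
  v <- round(add_gauss_fixture(v, 3, 10, 14, 80, 1.4))
  labels <- matrix(0L, 30, 30)
  labels[5:16, 4:18] <- 1L   # both foci inside nucleus 1
  labels[22:28, 22:28] <- 2L # empty nucleus
  lv <- extrude_labels_to_3d(labels, 6)
  fs <- detect_foci(v, foci_params(min_voxels = 8), mask = lv)
  res <- assign_foci_to_nuclei(fs, lv)
  expect_equal(res$counts$n_foci[res$counts$nucleus_id == 1], 2)
  expect_equal(res$counts$n_foci[res$counts$nucleus_id == 2], 0)
  # a focus outside all labels keeps nucleus_id 0 and is not counted
  fs2 <- detect_foci(v, foci_params(min_voxels = 8))
  labels0 <- matrix(0L, 30, 30); labels0[22:28, 22:28] <- 1L
  res2 <- assign_foci_to_nuclei(fs2, extrude_labels_to_3d(labels0, 6))
  expect_true(all(res2$fociset$foci$nucleus_id == 0))
  expect_equal(res2$counts$n_foci, 0L)
})

test_that("noiseless synthetic scene is recovered exactly per nucleus", {
  cfg <- generator_config(
    geometry = voxel_geometry(nx = 160, ny = 160, nz = 10),
    n_nuclei = c(hepatocyte = 3),
    foci_pi0 = 0, foci_mu = 4,
    noise = list(poisson = FALSE, gain = 1, read_sd = 0), seed = 31)
  sc <- build_scene(cfg)
  st <- render_stack(sc)
  res <- analyze_liver_stack(st)
  # map detected nuclei to truth by centroid
  f <- res$labelmap$features
  d2 <- outer(f$centroid_y, sc$nuclei$cy, "-")^2 +
    outer(f$centroid_x, sc$nuclei$cx, "-")^2
  truth_idx <- apply(d2, 1, which.min)
  expect_equal(nrow(f), nrow(sc$nuclei))
  got <- res$counts$n_foci[order(res$counts$nucleus_id)]
  expect_equal(got[f$label], sc$nuclei$n_foci[truth_idx])
})
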