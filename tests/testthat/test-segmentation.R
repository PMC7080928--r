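test_that("Otsu threshold separates classes and honours the user adjustment", {
  set.seed(1)
  img <- matrix(c(rep(10, 90), rep(200, 10))[sample(100)], 10, 10)
  lv <- auto_threshold(img)
  expect_gt(lv, 10); expect_lt(lv, 200)
  expect_equal(auto_threshold(img, segmentation_params(threshold_adjust = 2)),
               2 * lv)
  expect_error(auto_threshold(matrix(7, 5, 5)), "degenerate")
})

test_that("Otsu equals exhaustive between-class-variance search on random images", {
  for (seed in 1:4) {
    set.seed(seed)
    img <- matrix(sample(0:40, 64 * 64, replace = TRUE) +
                    sample(c(0, 120), 64 * 64, replace = TRUE, prob = c(.7, .3)),
                  64, 64)
    expect_equal(auto_threshold(img), bf_otsu(img))
  }
})

test_that("binary median filter matches the sliding-median oracle", {
  # constant input is unchanged
  expect_equal(binary_median_filter(matrix(TRUE, 9, 9)), matrix(TRUE, 9, 9))
  expect_equal(binary_median_filter(matrix(FALSE, 9, 9)), matrix(FALSE, 9, 9))
  # a single isolated foreground pixel is removed at radius 2
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_false(any(binary_median_filter(m)))
  # random fixtures at several densities, including edges
  for (p in c(0.2, 0.5, 0.8)) {
    set.seed(round(100 * p))
    m <- matrix(stats::runif(24 * 17) < p, 24, 17)
    expect_identical(binary_median_filter(m), bf_median_disk(m))
  }
})

test_that("fill holes equals the complement-flood-fill oracle and is idempotent", {
  # annulus becomes a solid disk
  a <- draw_disks(32, 32, cbind(16, 16), 10, value = 1) -
    draw_disks(32, 32, cbind(16, 16), 6, value = 1)
  filled <- fill_holes(a > 0)
  expect_equal(sum(filled), sum(draw_disks(32, 32, cbind(16, 16), 10, value = 1)))
  expect_identical(fill_holes(filled), filled)
  # random blob fixtures
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(stats::runif(40 * 40) < 0.55, 40, 40)
    f <- fill_holes(m)
    expect_identical(f, bf_fill_holes(m))
    expect_true(all(f[m]))          # never removes foreground
    expect_identical(fill_holes(f), f)
  }
})

test_that("two overlapping disks split under watershed and merge without it", {
  img <- draw_disks(64, 64, rbind(c(32, 25), c(32, 40)), 10)  # centres 1.5 r apart
  lm_ws <- build_nucleus_label_map(image2d(img), segmentation_params(min_area_px = 10))
  expect_equal(max(lm_ws$labels), 2)
  lm_no <- build_nucleus_label_map(image2d(img),
                                   segmentation_params(min_area_px = 10,
                                                       watershed_enabled = FALSE))
  expect_equal(max(lm_no$labels), 1)
})

test_that("two disjoint bright disks yield 2 labels with exact areas", {
  img <- draw_disks(80, 80, rbind(c(25, 25), c(55, 55)), 10)
  lm <- build_nucleus_label_map(image2d(img),
                                segmentation_params(min_area_px = 10,
                                                    median_radius_px = 0))
  expect_equal(max(lm$labels), 2)
  disk_area <- sum(draw_disks(80, 80, cbind(25, 25), 10) > 0)
  expect_equal(sort(lm$features$area_px), c(disk_area, disk_area))
})

test_that("pipeline filters respect min_area and border policy", {
  img <- draw_disks(60, 60, rbind(c(30, 30), c(3, 50)), 8)  # second disk clipped
  img[10, 10] <- 200  # speck
  lm <- build_nucleus_label_map(image2d(img),
                                segmentation_params(min_area_px = 20))
  expect_equal(max(lm$labels), 1)   # speck too small, border disk excluded
  lm_keep <- build_nucleus_label_map(image2d(img),
                                     segmentation_params(min_area_px = 20,
                                                         border_policy = "keep"))
  expect_equal(max(lm_keep$labels), 2)
})

test_that("label extrusion copies the footprint across z", {
  img <- draw_disks(40, 40, cbind(20, 20), 8)
  lm <- build_nucleus_label_map(image2d(img), segmentation_params(min_area_px = 10))
  v <- extrude_labels_to_3d(lm, 5)
  expect_equal(dim(v), c(5, 40, 40))
  for (z in 1:5) expect_identical(v[z, , ], lm$labels)
  area <- lm$features$area_px[1]
  expect_equal(sum(v == 1), area * 5)
})

test_that("classification: manual passthrough, errors, and shape rules", {
  img <- draw_disks(64, 64, rbind(c(20, 20), c(45, 45)), 9)
  lm <- build_nucleus_label_map(image2d(img), segmentation_params(min_area_px = 10))
  lm2 <- classify_nuclei(lm, rule = "manual",
                         manual_labels = list(`1` = "hepatocyte"))
  expect_equal(lm2$features$cell_class[1], "hepatocyte")
  expect_true(is.na(lm2$features$cell_class[2]))
  expect_error(classify_nuclei(lm, rule = "manual",
                               manual_labels = list(`9` = "hepatocyte")),
               "unknown label")
  # a perfect disk has elongation ~ 1, so it is never a non-hepatocyte
  lm3 <- classify_nuclei(lm, rule = "auto")
  expect_true(all(is.na(lm3$features$cell_class) |
                  lm3$features$cell_class != "non_hepatocyte"))
})

test_that("auto classification agrees with generator truth on a rendered scene", {
  cfg <- generator_config(seed = 21)
  sc <- build_scene(cfg)
  st <- render_stack(sc)
  lm <- build_nucleus_label_map(max_intensity_projection(st, "DAPI"))
  lm <- classify_nuclei(lm, rule = "auto")
  f <- lm$features
  d2 <- outer(f$centroid_y, sc$nuclei$cy, "-")^2 +
    outer(f$centroid_x, sc$nuclei$cx, "-")^2
  true_class <- sc$nuclei$cell_class[apply(d2, 1, which.min)]
  agreement <- mean(f$cell_class == true_class, na.rm = FALSE)
  expect_gte(agreement, 0.9)
})

test_that("polygon ROIs rasterize within bounds and carry nucleus counts", {
  poly <- cbind(c(5, 5, 20, 20), c(5, 20, 20, 5))  # (y, x) square
  rs <- roi_set(list(a = poly), dim_yx = c(32, 32),
                nucleus_counts = c(`1` = 4))
  expect_equal(sum(rs$labels == 1), 15 * 15)
  expect_error(roi_set(list(a = cbind(c(0, 5, 5), c(1, 1, 5))),
                       dim_yx = c(32, 32)), "bounds")
})
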