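test_that("Otsu threshold agrees with the reference implementation", {
  set.seed(101)
  for (i in 1:5) {
    v <- c(rnorm(500, 0.2, 0.05), rnorm(200, 0.8, 0.05))
    v <- pmin(1, pmax(0, v))
    thr <- otsu_threshold(v)
    ref <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)), range = range(v))
    # both must induce the same foreground/background split (the criterion
    # is flat across the empty gap between modes, so the exact threshold
    # value is convention-dependent)
    expect_equal(sum(v > thr), sum(v > ref))
    expect_lt(abs(thr - ref), 0.1)
  }
  expect_true(is.na(otsu_threshold(rep(0.5, 100))))
})

test_that("nucleus segmentation recovers ellipse area and counts", {
  img <- matrix(0.05, 128, 128)
  img[ellipse_mask(128, 128, 64, 64, 40, 25)] <- 0.9
  rois <- segment_nuclei(img)
  expect_length(rois, 1)
  expect_lt(abs(rois[[1]]$area - pi * 40 * 25) / (pi * 40 * 25), 0.02)
  expect_length(segment_nuclei(matrix(0, 64, 64)), 0)
  two <- matrix(0.05, 128, 128)
  two[ellipse_mask(128, 128, 32, 40, 18, 14)] <- 0.9
  two[ellipse_mask(128, 128, 96, 90, 18, 14)] <- 0.9
  expect_length(segment_nuclei(two), 2)
})

test_that("bright and dim masks partition the ROI exactly", {
  img <- matrix(0.05, 96, 96)
  nuc <- ellipse_mask(96, 96, 48, 48, 30, 24)
  img[nuc] <- 0.3
  disc <- ellipse_mask(96, 96, 48, 48, 8, 8)
  img[disc] <- 0.9
  roi <- segment_nuclei(matrix(0.05 + 0.9 * nuc, 96, 96))[[1]]
  bm <- bright_mask(img, roi)
  expect_false(bm$degenerate)
  expect_identical(bm$bright & bm$dim, matrix(FALSE, 96, 96))
  expect_identical(bm$bright | bm$dim, roi$mask)
  # recovered disc overlaps the planted one almost perfectly (IoU >= 0.9)
  iou <- sum(bm$bright & disc) / sum(bm$bright | disc)
  expect_gte(iou, 0.9)
  # uniform ROI intensity: degenerate, empty bright mask
  flat <- matrix(0, 96, 96); flat[roi$mask] <- 0.5
  bm2 <- bright_mask(flat, roi)
  expect_true(bm2$degenerate)
  expect_false(any(bm2$bright))
})

test_that("shape metrics match analytic discs and ellipses", {
  disc <- ellipse_mask(80, 80, 40, 40, 15, 15)
  sh <- object_shapes(disc)
  expect_identical(nrow(sh), 1L)
  expect_lt(abs(sh$circularity - 1), 0.05)
  expect_lt(abs(sh$aspect_ratio - 1), 0.05)
  expect_lt(abs(sh$area - pi * 15^2) / (pi * 15^2), 0.02)
  expect_lt(abs(sh$perimeter - 2 * pi * 15) / (2 * pi * 15), 0.05)
  ell <- ellipse_mask(100, 100, 50, 50, 20, 10)
  she <- object_shapes(ell)
  expect_lt(abs(she$aspect_ratio - 0.5), 0.05)
  expect_lt(she$circularity, 0.95)
  # rotated ellipse keeps its aspect ratio
  ell45 <- ellipse_mask(100, 100, 50, 50, 20, 10, theta = pi / 4)
  expect_lt(abs(object_shapes(ell45)$aspect_ratio - 0.5), 0.05)
  expect_identical(nrow(object_shapes(matrix(FALSE, 10, 10))), 0L)
})

test_that("shape metrics are invariant under translation and 90-degree rotation", {
  base <- matrix(FALSE, 90, 90)
  base[ellipse_mask(90, 90, 40, 45, 16, 9, theta = 0.4)] <- TRUE
  ref <- object_shapes(base)
  shifted <- matrix(FALSE, 90, 90)
  shifted[16:90, 11:90] <- base[1:75, 1:80]
  sh <- object_shapes(shifted)
  expect_equal(sh$area, ref$area)
  expect_equal(sh$perimeter, ref$perimeter, tolerance = 1e-12)
  expect_equal(sh$circularity, ref$circularity, tolerance = 1e-12)
  expect_equal(sh$aspect_ratio, ref$aspect_ratio, tolerance = 1e-12)
  rotated <- t(base)[nrow(base):1, ]
  rr <- object_shapes(rotated)
  expect_equal(rr$area, ref$area)
  expect_equal(rr$perimeter, ref$perimeter, tolerance = 1e-9)
  expect_equal(rr$aspect_ratio, ref$aspect_ratio, tolerance = 1e-9)
})

test_that("object count is monotone non-increasing in the area filter", {
  m <- matrix(FALSE, 100, 100)
  m[ellipse_mask(100, 100, 20, 20, 3, 3)] <- TRUE
  m[ellipse_mask(100, 100, 60, 60, 8, 8)] <- TRUE
  m[ellipse_mask(100, 100, 20, 80, 12, 12)] <- TRUE
  counts <- vapply(c(1, 25, 120, 300, 1000), function(a)
    nrow(object_shapes(m, min_area = a)), numeric(1))
  expect_equal(counts, c(3, 3, 2, 1, 0))
})

test_that("compartment Pearson behaves at the closed-form extremes", {
  set.seed(102)
  a <- matrix(runif(400), 20)
  bright <- matrix(rep(c(TRUE, FALSE), 200), 20)
  dim_m <- !bright
  same <- compartment_pearson(a, a, bright, dim_m)
  expect_equal(unname(same), c(1, 1))
  anti <- compartment_pearson(a, -a + 2, bright, dim_m)
  expect_equal(unname(anti), c(-1, -1))
  tiny <- compartment_pearson(a, a, matrix(FALSE, 20, 20), dim_m)
  expect_true(is.na(tiny[["r_bright"]]))
})

test_that("nucleus intensity stats have the stated closed forms", {
  roi <- structure(list(mask = matrix(TRUE, 10, 10), label = 1L, area = 100),
                   class = "nucleus_roi")
  flat <- matrix(4, 10, 10)
  st <- nucleus_intensity_stats(flat, roi)
  expect_equal(unname(st), c(4, 0))
  half <- matrix(rep(c(2, 6), each = 50), 10)
  st2 <- nucleus_intensity_stats(half, roi)
  expect_equal(st2[["mfi"]], 4)
  expect_equal(st2[["sd"]], 2)  # |a - b| / 2
  set.seed(103)
  v <- matrix(runif(100), 10)
  st3 <- nucleus_intensity_stats(v, roi)
  expect_equal(st3[["sd"]], sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
})

test_that("relative MFI normalization and QC overlays work", {
  expect_equal(relative_mfi(c(2, 4), control = c(1, 3)), c(1, 2))
  expect_error(relative_mfi(1, control = c(0, 0)), "positive")
  img <- matrix(0.1, 40, 40)
  nuc <- ellipse_mask(40, 40, 20, 20, 15, 12)
  img[nuc] <- 0.4
  disc <- ellipse_mask(40, 40, 20, 20, 4, 4)
  img[disc] <- 0.9
  path <- tempfile(fileext = ".png")
  write_overlay_png(img, disc, nuc, path)
  arr <- png::readPNG(path)
  expect_identical(dim(arr)[3], 3L)
  expect_gt(arr[20, 20, 1], 0.9)  # bright object rendered red
})

test_that("knockdown-like images yield more, rounder objects and dim-biased colocalization", {
  cfg <- sim_config(seed = 104, image = list(n_nuclei = 6L))
  qc <- lapply(gen_nucleus_images(cfg, "control")$images,
               quantify_nucleus_image)
  ql <- lapply(gen_nucleus_images(cfg, "low")$images, quantify_nucleus_image)
  nuc_c <- do.call(rbind, lapply(qc, `[[`, "nuclei"))
  nuc_l <- do.call(rbind, lapply(ql, `[[`, "nuclei"))
  obj_c <- do.call(rbind, lapply(qc, `[[`, "objects"))
  obj_l <- do.call(rbind, lapply(ql, `[[`, "objects"))
  expect_gt(mean(nuc_l$n_objects), mean(nuc_c$n_objects))
  expect_gt(median(obj_l$circularity), median(obj_c$circularity))
  expect_gt(median(obj_l$aspect_ratio), median(obj_c$aspect_ratio))
  # FBXO11 tracks NPM1 in the nucleoplasm, not in the bright bodies
  expect_true(all(nuc_c$r_dim > nuc_c$r_bright))
})
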