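test_that("z-score normalization is exact over the support and idempotent", {
  set.seed(5)
  vol <- array(0, c(20, 20, 4))
  mask <- array(runif(length(vol)) > 0.4, dim(vol))
  vol[mask] <- 3 + seq_len(sum(mask)) * 0.01   # constant-plus-ramp
  nv <- zscore_normalize(vol)
  expect_lt(abs(mean(nv[mask])), 1e-10)
  expect_lt(abs(sd(nv[mask]) - 1), 1e-10)
  expect_true(all(nv[!mask] == 0))
  nv2 <- zscore_normalize(nv)
  expect_lt(max(abs(nv2 - nv)), 1e-5)
  expect_error(zscore_normalize(array(0, c(4, 4))), "all-zero")
  cons <- array(0, c(4, 4)); cons[1:8] <- 2
  expect_error(zscore_normalize(cons), "constant")
})

test_that("center crop keeps all planes and centers the window", {
  vol <- array(rnorm(240 * 240 * 3), c(240, 240, 3))
  cr <- center_crop(vol)
  expect_equal(dim(cr), c(160, 160, 3))
  expect_equal(attr(cr, "crop_offset"), c(40, 40))
  expect_equal(cr[1, 1, 2], vol[41, 41, 2])
  # no-op crop
  same <- center_crop(vol[1:160, 1:160, , drop = FALSE])
  expect_equal(as.vector(same), as.vector(vol[1:160, 1:160, ]))
  # marked center voxel stays at the center
  vol2 <- array(0, c(200, 200, 1)); vol2[100, 100, 1] <- 7
  cr2 <- center_crop(vol2)
  expect_equal(cr2[80, 80, 1], 7)
  expect_error(center_crop(array(0, c(100, 100, 2))), "smaller")
})

test_that("slice_and_stack emits one 4-channel sample per plane, in order", {
  d <- c(12, 12, 7)
  vols <- list(t1 = array(1, d), t2 = array(2, d), t1ce = array(3, d),
               flair = array(4, d))
  lab <- array(0L, d); lab[6, 6, ] <- 4L
  samples <- slice_and_stack(vols, lab, case_id = "cc")
  expect_length(samples, 7)
  expect_equal(dim(samples[[1]]$image), c(12, 12, 4))
  for (s in samples) {
    expect_equal(apply(s$image, 3, mean), c(1, 2, 3, 4),
                 ignore_attr = TRUE)
  }
  expect_equal(samples[[3]]$id, "cc_003")
  # round trip: stacking the label slices restores the volume bit-exactly
  expect_identical(stack_labels(lapply(samples, `[[`, "label")), lab)
  # channel planes match the source volumes exactly
  set.seed(1)
  vols$t1ce <- array(rnorm(prod(d)), d)
  samples <- slice_and_stack(vols, NULL)
  for (k in seq_len(d[3])) {
    expect_identical(samples[[k]]$image[, , 3], vols$t1ce[, , k])
  }
  vols$flair <- array(0, c(12, 12, 6))
  expect_error(slice_and_stack(vols, NULL), "shapes differ")
})

test_that("labels_to_regions implements the nested WT/CT/ET mapping", {
  lab <- matrix(0L, 4, 4)
  expect_true(all(!unlist(labels_to_regions(lab))))
  lab[1, 1] <- 1L; lab[2, 2] <- 2L; lab[3, 3] <- 4L
  r <- labels_to_regions(lab)
  expect_equal(sum(r$wt), 3)
  expect_equal(sum(r$ct), 2)
  expect_equal(sum(r$et), 1)
  full <- matrix(4L, 3, 3)
  rf <- labels_to_regions(full)
  expect_true(all(rf$wt) && all(rf$ct) && all(rf$et))
  lab[4, 4] <- 3L
  expect_error(labels_to_regions(lab), "unexpected label value.*3")
})

test_that("region nesting holds for random label maps", {
  set.seed(99)
  for (i in 1:200) {
    lab <- matrix(sample(c(0L, 1L, 2L, 4L), 64, replace = TRUE), 8, 8)
    r <- labels_to_regions(lab)
    expect_true(all(r$wt[r$ct]))
    expect_true(all(r$ct[r$et]))
  }
})

test_that("regions round-trip through label images with nesting repair", {
  set.seed(4)
  lab <- matrix(sample(c(0L, 1L, 2L, 4L), 100, replace = TRUE), 10, 10)
  r <- labels_to_regions(lab)
  expect_identical(regions_to_label(r), lab)
  arr <- regions_to_array(r)
  expect_equal(dim(arr), c(10, 10, 3))
  expect_equal(arr[, , 3] == 1, r$et, ignore_attr = TRUE)
  # un-nested masks are repaired by intersection
  broken <- list(wt = matrix(FALSE, 2, 2), ct = matrix(TRUE, 2, 2),
                 et = matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_true(all(regions_to_label(broken, repair = TRUE) == 0L))
})

test_that("preprocessing a full-size case follows the shape contract", {
  dir <- withr::local_tempdir()
  write_phantom_case(dir, "pp", dims = c(180L, 180L, 6L),
                     spec = phantom_spec(image_size = 180L), seed = 2)
  out <- preprocess_case(file.path(dir, "pp"),
                         out_dir = file.path(dir, "prep"))
  expect_length(out$samples, 6)
  expect_equal(dim(out$samples[[1]]$image), c(160, 160, 4))
  expect_equal(nrow(out$manifest), 6)
  expect_true(all(file.exists(out$manifest$path)))
  # normalization before cropping: support statistics are from the full
  # volume, so the cropped support need not be exactly N(0,1), but close
  ch <- out$samples[[3]]$image[, , 1]
  expect_lt(abs(mean(ch[ch != 0])), 0.3)
  reloaded <- readRDS(out$manifest$path[3])
  expect_identical(reloaded$image, out$samples[[3]]$image)
})
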