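test_that("standardize_geometry is the identity on already-standard input", {
  arr <- withr::with_seed(1, array(stats::rnorm(240 * 240 * 150),
                                   dim = c(240, 240, 150)))
  v <- mri_volume(arr, c(1, 1, 1), "t1")
  out <- standardize_geometry(v)
  expect_identical(out$data, arr)
})

test_that("resampling a constant volume preserves the constant", {
  v <- mri_volume(array(7, dim = c(120, 120, 75)), c(2, 2, 2), "t2")
  out <- standardize_geometry(v)
  expect_equal(dim(out$data), c(240, 240, 150))
  expect_equal(unique(as.vector(out$data)), 7)
})

test_that("center crop maps input voxels to the contracted output voxels", {
  arr <- array(0, dim = c(300, 300, 200))
  arr[151, 151, 101] <- 42   # voxel (150,150,100) in 0-based coordinates
  out <- standardize_geometry(mri_volume(arr, c(1, 1, 1), "t1"))
  expect_equal(out$data[121, 121, 76], 42)  # lands at (120,120,75) 0-based
  expect_equal(sum(out$data), 42)
})

test_that("small volumes are zero-padded centrally and masks stay binary", {
  arr <- array(1, dim = c(200, 200, 100))
  out <- standardize_geometry(mri_volume(arr, c(1, 1, 1), "flair"))
  expect_equal(dim(out$data), c(240, 240, 150))
  # 20-voxel pad on each in-plane side, 25 slices on each end
  expect_equal(out$data[21, 21, 26], 1)
  expect_equal(out$data[20, 21, 26], 0)
  expect_equal(sum(out$data), 200 * 200 * 100)

  m <- array(0, dim = c(120, 120, 75))
  m[50:70, 40:60, 30:40] <- 1
  ms <- standardize_geometry(segmentation_mask(m, c(2, 2, 2)))
  expect_true(all(ms$data %in% c(0, 1)))
  expect_equal(dim(ms$data), c(240, 240, 150))
  expect_error(standardize_geometry(
    mri_volume(array(0, c(4, 4, 4))), target_spacing = c(0, 1, 1)),
    "spacing")
})

test_that("normalize_intensity maps the 1st-99th percentile window to 0-255", {
  arr <- withr::with_seed(3, array(stats::rexp(40 * 40 * 20, rate = 0.01),
                                   dim = c(40, 40, 20)))
  v <- normalize_intensity(mri_volume(arr))
  expect_gte(min(v$data), 0)
  expect_lte(max(v$data), 255)
  expect_true(all(v$data == round(v$data)))
  q <- stats::quantile(arr, c(0.01, 0.99), names = FALSE)
  expect_equal(v$data[arr <= q[1]],
               rep(0, sum(arr <= q[1])))
  expect_equal(v$data[arr >= q[2]],
               rep(255, sum(arr >= q[2])))
  expect_gte(mean(v$data == 255), 0.01 * 0.9)
  # worked mapping: p1=10, p99=210 puts 110 halfway -> 127.5 -> 128
  expect_equal((110 - 10) / (210 - 10) * 255, 127.5)
  expect_equal(mgmtfuse:::round_half_away(127.5), 128)
  expect_equal(mgmtfuse:::round_half_away(-127.5), -128)
})

test_that("a constant volume normalizes to zeros with a warning", {
  v <- mri_volume(array(5, dim = c(10, 10, 5)))
  expect_warning(out <- normalize_intensity(v), "degenerate")
  expect_equal(unique(as.vector(out$data)), 0)
})

test_that("normalization is idempotent to within one gray level", {
  arr <- withr::with_seed(4, array(stats::runif(30 * 30 * 10, 0, 1000),
                                   dim = c(30, 30, 10)))
  v1 <- normalize_intensity(mri_volume(arr))
  v2 <- normalize_intensity(v1)
  expect_lte(max(abs(v2$data - v1$data)), 1)
})

test_that("bounding box equals an exhaustive mask scan on random masks", {
  withr::with_seed(17, {
    for (trial in seq_len(100)) {
      m <- array(0, dim = c(150, 140, 5))
      n_blobs <- sample(1:3, 1)
      for (b in seq_len(n_blobs)) {
        r0 <- sample(1:120, 1); c0 <- sample(1:110, 1); z0 <- sample(1:5, 1)
        m[r0:min(150, r0 + sample(5:30, 1)),
          c0:min(140, c0 + sample(5:30, 1)), z0] <- 1
      }
      box <- compute_bounding_box(segmentation_mask(m), size = 64L)
      # oracle: exhaustive row/column scans
      rows <- which(apply(m, 1, sum) > 0)
      cols <- which(apply(m, 2, sum) > 0)
      expect_identical(box$row0, as.integer(min(pmin(min(rows) - 1, 150 - 64))))
      expect_identical(box$col0, as.integer(min(pmin(min(cols) - 1, 140 - 64))))
    }
  })
})

test_that("bounding box honours the worked corner cases", {
  m <- array(0, dim = c(240, 240, 3))
  m[41:91, 31:61, 2] <- 1
  box <- compute_bounding_box(segmentation_mask(m))
  expect_equal(box$row0, 40L)
  expect_equal(box$col0, 30L)
  expect_equal(c(box$height, box$width), c(128L, 128L))

  # tumor near the right edge: col0 clamps to 240 - 128 = 112
  m2 <- array(0, dim = c(240, 240, 3))
  m2[100:120, 201:231, 1] <- 1
  expect_equal(compute_bounding_box(segmentation_mask(m2))$col0, 112L)

  # single foreground voxel at 0-based (5, 7, 2)
  m3 <- array(0, dim = c(240, 240, 3))
  m3[6, 8, 3] <- 1
  b3 <- compute_bounding_box(segmentation_mask(m3))
  expect_equal(c(b3$row0, b3$col0), c(5L, 7L))

  expect_error(compute_bounding_box(
    segmentation_mask(array(0, dim = c(240, 240, 3)))), "empty mask")
})

test_that("volume_to_video crops losslessly into 150 frames", {
  arr <- withr::with_seed(5, array(sample(0:255, 240 * 240 * 150, TRUE),
                                   dim = c(240, 240, 150)))
  arr[50, 60, 42] <- 255
  v <- mri_volume(arr)
  box <- structure(list(row0 = 30L, col0 = 40L, height = 128L, width = 128L),
                   class = "bounding_box")
  clip <- volume_to_video(v, box)
  expect_equal(dim(clip$frames), c(150, 128, 128))
  # the max voxel lies inside the box: clip max equals volume max
  expect_equal(max(clip$frames), max(arr))
  expect_equal(clip$frames[42, 50 - 30, 60 - 40], arr[50, 60, 42])

  z <- volume_to_video(mri_volume(array(0, dim = c(240, 240, 150))), box)
  expect_true(all(z$frames == 0))

  bad <- structure(list(row0 = 200L, col0 = 0L, height = 128L, width = 128L),
                   class = "bounding_box")
  expect_error(volume_to_video(v, bad), "outside")
  short <- mri_volume(array(0, dim = c(240, 240, 100)))
  expect_error(volume_to_video(short, box), "150 slices")
})

test_that("delta volume is a pointwise subtraction computed pre-normalization", {
  arr <- withr::with_seed(6, array(stats::runif(20 * 20 * 8, 0, 100),
                                   dim = c(20, 20, 8)))
  a <- mri_volume(arr, modality = "t1wce")
  b <- mri_volume(arr, modality = "t1")
  expect_equal(unique(as.vector(compute_delta_volume(a, b)$data)), 0)

  c5 <- mri_volume(arr + 5, modality = "t1wce")
  d <- compute_delta_volume(c5, b)
  expect_equal(unique(round(as.vector(d$data), 10)), 5)
  expect_equal(d$modality, "delta")
  # constant difference then normalization hits the degenerate rule
  expect_warning(nd <- normalize_intensity(d), "degenerate")
  expect_equal(unique(as.vector(nd$data)), 0)

  wrong <- mri_volume(array(0, dim = c(10, 10, 8)), modality = "t1")
  expect_error(compute_delta_volume(a, wrong), "shape mismatch")
})

test_that("the subject pipeline yields five 150x128x128 clips in branch order", {
  subj <- generate_phantom_subject(small_phantom_config(seed = 8))
  prep <- preprocess_subject(subj$volumes, subj$mask)
  expect_named(prep$clips, mgmt_branches())
  for (clip in prep$clips) {
    expect_s3_class(clip, "video_clip")
    expect_equal(dim(clip$frames), c(150, 128, 128))
    expect_gte(min(clip$frames), 0)
    expect_lte(max(clip$frames), 255)
  }
  box <- prep$meta$bounding_box
  expect_gte(box$row0, 0)
  expect_lte(box$row0 + 128, 240)
})
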