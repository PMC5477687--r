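test_that("seed selection returns the in-window argmax with row-major tie-break", {
  f <- matrix(33, 5, 6)
  f[2, 3] <- 37
  expect_equal(select_seed(f), c(2, 3))                 # unique max
  # uniform window: smallest (row, col) wins
  expect_equal(select_seed(matrix(33, 4, 4)), c(1, 1))
  # global max outside the window must be ignored
  f2 <- matrix(33, 6, 6)
  f2[1, 1] <- 40                                        # outside window
  f2[4, 4] <- 36                                        # inside window
  w <- search_window(3, 6, 3, 6, "left")
  expect_equal(select_seed(f2, w), c(4, 4))
  # exhaustive-scan oracle on random frames
  set.seed(1)
  for (i in 1:25) {
    v <- random_small_frame()
    ok <- which(is.finite(v), arr.ind = TRUE)
    best <- ok[order(-v[ok], ok[, 1], ok[, 2])[1], ]
    expect_equal(select_seed(v), unname(best))
  }
  # all-invalid window errors
  expect_error(select_seed(matrix(NA_real_, 3, 3)), "no valid pixel")
})

test_that("region growth reproduces the hand-worked examples", {
  # uniform frame, zero tolerance: everything joins (delta = 0 throughout)
  r <- grow_region(matrix(33, 3, 3), c(2, 2),
                   seg_params(0, seed_region_radius = 0,
                              max_region_fraction = 1))
  expect_equal(r$size, 9L)
  expect_equal(r$mean_temp_c, 33)

  # 5x5 with a 3x3 37 C plateau in a 33 C ring: tolerance 1 admits exactly
  # the plateau (ring pixels deviate by 4)
  f <- matrix(33, 5, 5); f[2:4, 2:4] <- 37
  r <- grow_region(f, c(3, 3), seg_params(1, 0, 1))
  expect_equal(r$size, 9L)
  expect_true(all(r$pixels[, 1] %in% 2:4 & r$pixels[, 2] %in% 2:4))
  expect_equal(r$mean_temp_c, 37)
  expect_equal(r$stopped_by, "tolerance")

  # single step: sole neighbour 0.2 C away exceeds tolerance 0.1
  f <- matrix(c(37, 36.8), 1, 2)
  r <- grow_region(f, c(1, 1), seg_params(0.1, 0, 1))
  expect_equal(r$size, 1L)
  expect_equal(r$pixels, matrix(c(1L, 1L), 1, dimnames = list(NULL, c("row", "col"))))

  expect_error(grow_region(matrix(33, 3, 3), c(4, 1), seg_params(1)),
               "seed outside")
})

test_that("growth matches the naive from-scratch oracle on random small frames", {
  set.seed(101)
  for (i in 1:150) {
    v <- random_small_frame()
    seed <- random_seed_px(v)
    tt <- sample(c(0, 0.2, 0.5, 1, 2), 1)
    rad <- sample(0:1, 1)
    r <- grow_region(v, seed, seg_params(tt, rad, 1))
    expect_identical(unclass(r$mask), srg_oracle(v, seed, tt, rad, 1),
                     info = sprintf("case %d (tt=%g rad=%d)", i, tt, rad))
  }
})

test_that("region is monotone in the tolerance and always 8-connected around the seed", {
  set.seed(202)
  for (i in 1:40) {
    v <- random_small_frame(invalid_prob = 0)
    seed <- random_seed_px(v)
    tts <- sort(runif(3, 0, 2.5))
    masks <- lapply(tts, function(tt)
      grow_region(v, seed, seg_params(tt, 0, 1))$mask)
    expect_true(all(masks[[1]] <= masks[[2]]))
    expect_true(all(masks[[2]] <= masks[[3]]))
    for (m in masks) {
      expect_true(m[seed[1], seed[2]])
      expect_true(thermoroi:::is_connected8(m))
    }
  }
})

test_that("the size cap halts runaway growth", {
  r <- grow_region(matrix(33, 10, 10), c(5, 5),
                   seg_params(0, 0, max_region_fraction = 0.25))
  expect_equal(r$size, 25L)
  expect_equal(r$stopped_by, "cap")
})

test_that("invalid pixels never join a region and shrink the seed patch", {
  f <- matrix(33, 3, 3); f[1, 1] <- NA; f[3, 3] <- NaN
  r <- grow_region(f, c(2, 2), seg_params(5, 1, 1))
  expect_equal(r$size, 7L)
  expect_false(r$mask[1, 1] || r$mask[3, 3])
  expect_error(grow_region(f, c(1, 1), seg_params(1)), "invalid")
})

test_that("threshold baseline: median of the hottest quarter, no connectivity", {
  f <- matrix(1:16, 4, 4, byrow = TRUE)
  res <- threshold_segment(f)
  expect_equal(res$threshold_c, 14.5)                   # median of {13..16}
  expect_equal(sort(f[res$mask]), c(15, 16))
  # uniform window: every pixel ties the threshold and is kept
  resu <- threshold_segment(matrix(33, 3, 3))
  expect_equal(sum(resu$mask), 9L)
  expect_error(threshold_segment(matrix(33, 1, 3)), "at least 4")
})

test_that("threshold baseline scatters where region growing stays closed", {
  # plateau plus a distant equally hot speck: the baseline keeps both
  # (disconnected), region growing returns one closed component
  f <- matrix(33, 8, 8)
  f[2:4, 2:4] <- 37
  f[7, 7] <- 37
  thr <- threshold_segment(f)
  expect_false(thermoroi:::is_connected8(thr$mask))
  srg <- grow_region(f, select_seed(f), seg_params(1, 0, 1))
  expect_true(thermoroi:::is_connected8(srg$mask))
  expect_equal(srg$size, 9L)
})

test_that("sequence segmentation averages per-frame statistics arithmetically", {
  # constant sequence: the average equals any single frame
  f <- matrix(33, 12, 12); f[4:6, 4:6] <- 36
  s <- thermal_sequence(rep(list(f), 4))
  w <- search_window(1, 13, 1, 13, "left")
  res <- segment_sequence(s, w, seg_params(1, 0, 1), mask_band = NULL)
  expect_equal(res$mean_pixel_count, 9)
  expect_equal(res$mean_roi_temp_c, 36)
  expect_equal(res$n_frames_used, 4L)

  # two frames with 100- and 120-pixel plateaus: mean count 110
  f1 <- matrix(33, 20, 20); f1[3:12, 3:12] <- 36          # 100 px
  f2 <- matrix(33, 20, 20); f2[3:12, 3:14] <- 36          # 120 px
  s2 <- thermal_sequence(list(f1, f2))
  res2 <- segment_sequence(s2, search_window(1, 21, 1, 21, "left"),
                           seg_params(1, 0, 1), mask_band = NULL)
  expect_equal(res2$mean_pixel_count, 110)
})

test_that("unsegmentable frames are excluded from the average with a warning", {
  f <- matrix(33, 8, 8); f[3:4, 3:4] <- 36
  dead <- matrix(NA_real_, 8, 8)
  s <- thermal_sequence(list(f, dead, f))
  w <- search_window(1, 9, 1, 9, "left")
  expect_warning(res <- segment_sequence(s, w, seg_params(1, 0, 1),
                                         mask_band = NULL),
                 "unsegmentable")
  expect_equal(res$n_frames_used, 2L)
  expect_null(res$frames[[2]])
  expect_equal(res$mean_pixel_count, 4)
})

test_that("fiducial-band pixels are masked out of the window before growth", {
  # a 29 C disk adjacent to the plateau would be grown into at tolerance 8
  f <- matrix(33, 12, 12); f[4:6, 4:6] <- 36; f[4:6, 8:9] <- 29
  s <- thermal_sequence(list(f))
  w <- search_window(1, 13, 1, 13, "left")
  with_band <- segment_sequence(s, w, seg_params(8, 0, 1))
  without <- segment_sequence(s, w, seg_params(8, 0, 1), mask_band = NULL)
  expect_false(any(with_band$frames[[1]]$mask[f == 29]))
  expect_true(any(without$frames[[1]]$mask[f == 29]))
})

test_that("noise-free step plateau is recovered exactly for any tolerance below its height", {
  gen <- generate_sequence(test_scene(noise_sd_c = 0, n_frames = 1))
  f <- gen$sequence$frames[[1]]
  w <- test_window()
  truth <- gen$truth_masks[[1]][[1]]
  for (tt in c(0.05, 0.5, 1.0, 1.5, 1.95)) {
    r <- grow_region(f, select_seed(f, w), seg_params(tt, 0), window = w)
    expect_identical(unclass(r$mask), truth, info = sprintf("T_t = %g", tt))
  }
})

test_that("the automatic tolerance scan lands on the stable plateau", {
  gen <- generate_sequence(test_scene(noise_sd_c = 0.05, n_frames = 1))
  f <- gen$sequence$frames[[1]]
  auto <- auto_tolerance(f, test_window(), grid = seq(0.2, 3, by = 0.2))
  r <- grow_region(f, select_seed(f, test_window()), seg_params(auto$t_t, 1),
                   window = test_window())
  truth_n <- sum(gen$truth_masks[[1]][[1]])
  expect_lt(abs(r$size - truth_n) / truth_n, 0.05)
})
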