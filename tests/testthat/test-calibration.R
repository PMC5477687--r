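test_that("layout constructor rejects degenerate disk placements", {
  expect_error(fiducial_layout(rbind(c(0, 0), c(1, 1), c(2, 2), c(5, 0))),
               "collinear")
  expect_error(fiducial_layout(rbind(c(0, 0), c(0, 0), c(0, 8), c(18, 8))),
               "distinct")
  lay <- fiducial_layout()
  expect_equal(unname(lay$points_cm[, 1]), c(0, 18, 0, 18))  # 18 cm across
  expect_equal(unname(lay$points_cm[, 2]), c(0, 0, 8, 8))    # 8 cm down
})

test_that("fiducial disks are detected within half a pixel and ordered by corner", {
  gen <- generate_sequence(test_scene(noise_sd_c = 0))
  ctr <- detect_fiducials(gen$sequence$frames[[1]])
  # scene geometry: origin (24,24), 4 px/cm, 18x8 cm rectangle
  truth <- rbind(ul = c(24, 24), ur = c(24, 96),
                 ll = c(56, 24), lr = c(56, 96))
  expect_lt(max(abs(ctr - truth)), 0.5)
  expect_equal(rownames(ctr), c("ul", "ur", "ll", "lr"))
})

test_that("fiducial detection fails loudly on the wrong blob count and ignores warm blobs", {
  f <- matrix(33, 40, 40)
  centers <- list(c(10, 10), c(10, 30), c(30, 10))
  for (p in centers)
    f[(row(f) - p[1])^2 + (col(f) - p[2])^2 <= 4] <- 29.5
  expect_error(detect_fiducials(f), "expected 4 fiducial blobs, found 3")
  # a warm blob in the band-excluded range must not count as a disk
  f[(row(f) - 30)^2 + (col(f) - 30)^2 <= 4] <- 36
  expect_error(detect_fiducials(f), "found 3")
  # adding the fourth cool disk fixes it
  f[(row(f) - 30)^2 + (col(f) - 30)^2 <= 4] <- 29.5
  expect_equal(nrow(detect_fiducials(f)), 4L)
  # sub-minimum blobs are discarded as noise
  f[1, 1] <- 29.5
  expect_equal(nrow(detect_fiducials(f)), 4L)
})

test_that("four-point homography is exact: identity, pure scale, random recovery", {
  lay <- fiducial_layout()
  # identity correspondence: pixel coordinates already in cm
  px <- cbind(row = lay$points_cm[, "y_cm"], col = lay$points_cm[, "x_cm"])
  tr <- estimate_transform(px, lay)
  expect_lt(max(abs(tr$matrix / tr$matrix[3, 3] - diag(3))), 1e-9)
  expect_lt(tr$residual_cm, 1e-9)

  # 0.1 cm/px uniform scale
  px <- rbind(c(0, 0), c(0, 180), c(80, 0), c(80, 180))
  colnames(px) <- c("row", "col")
  tr <- estimate_transform(px, lay)
  H <- tr$matrix / tr$matrix[3, 3]
  expect_equal(H, diag(c(0.1, 0.1, 1)), tolerance = 1e-10)

  # recovery of 100 random known homographies, up to scale
  set.seed(33)
  src <- cbind(x = c(10, 210, 15, 205), y = c(12, 18, 170, 160))
  for (i in 1:100) {
    Ht <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
    Ht[3, 3] <- 1
    if (abs(det(Ht)) < 0.1) next
    hom <- Ht %*% rbind(t(src), 1)
    dst <- t(hom[1:2, ] / rep(hom[3, ], each = 2))
    est <- estimate_transform(cbind(row = src[, "y"], col = src[, "x"]),
                              fiducial_layout(dst))$matrix
    a <- Ht / Ht[which.max(abs(Ht))]
    b <- est / est[which.max(abs(est))]
    if (sign(a[which.max(abs(a))]) != sign(b[which.max(abs(b))])) b <- -b
    expect_lt(max(abs(a - b)), 1e-8)
  }
  expect_error(
    estimate_transform(rbind(c(0, 0), c(0, 1), c(0, 2), c(1, 1),
                             deparse.level = 0) |>
                         `colnames<-`(c("row", "col")), lay),
    "collinear|degenerate")
})

test_that("metric ROI area integrates the Jacobian: hand cases and affine exactness", {
  lay <- fiducial_layout()
  px <- rbind(c(0, 0), c(0, 180), c(80, 0), c(80, 180))
  colnames(px) <- c("row", "col")
  tr <- estimate_transform(px, lay)                      # 0.1 cm/px
  mask <- matrix(FALSE, 50, 50); mask[11:20, 11:20] <- TRUE   # 100 px
  expect_equal(roi_area_m2(mask, tr), 1e-4, tolerance = 1e-9) # 1 cm^2
  expect_equal(roi_area_m2(matrix(FALSE, 5, 5), tr), 0)
  # affine transform: area == pixel count x constant Jacobian, exactly
  A <- matrix(c(0.2, 0.03, -1, -0.05, 0.25, 2, 0, 0, 1), 3, 3, byrow = TRUE)
  tra <- structure(list(matrix = A, residual_cm = 0), class = "planar_transform")
  jac <- abs(det(A))
  expect_equal(roi_area_m2(mask, tra), 100 * jac * 1e-4, tolerance = 1e-12)
})

test_that("recovered metric area is invariant to pose translation and resolution", {
  base <- test_scene(noise_sd_c = 0, n_frames = 1)
  seg <- function(gen) {
    f <- gen$sequence$frames[[1]]
    w <- test_window()
    r <- grow_region(f, select_seed(f, w), seg_params(1, 0), window = w)
    tr <- estimate_transform(detect_fiducials(f), base$layout)
    roi_area_m2(r$mask, tr)
  }
  a0 <- seg(generate_sequence(base))

  # rigid translation of the whole scene (pose drift)
  shifted <- test_scene(noise_sd_c = 0, n_frames = 1, center = c(46, 88),
                        origin_px = c(30, 32))  # fiducials move with the body
  a1 <- seg(generate_sequence(shifted))
  expect_lt(abs(a1 - a0) / a0, 0.01)

  # same physical scene rendered at twice the pixel resolution
  hi <- test_scene(noise_sd_c = 0, n_frames = 1, px_per_cm = 8,
                   dims = c(192, 256), center = c(80, 160),
                   semi_axes = c(16, 22), origin_px = c(48, 48))
  genhi <- generate_sequence(hi)
  f <- genhi$sequence$frames[[1]]
  w <- search_window(50, 140, 110, 220, side = "left")
  r <- grow_region(f, select_seed(f, w), seg_params(1, 0), window = w)
  tr <- estimate_transform(detect_fiducials(f), hi$layout)
  a2 <- roi_area_m2(r$mask, tr)
  expect_lt(abs(a2 - a0) / a0, 0.01)
})

test_that("transforms serialize to JSON and back", {
  gen <- generate_sequence(test_scene(noise_sd_c = 0, n_frames = 1))
  tr <- calibrate_sequence(gen$sequence)
  p <- tempfile(fileext = ".json")
  write_transform(tr, p)
  tr2 <- read_transform(p)
  expect_equal(tr2$matrix, tr$matrix, tolerance = 1e-12)
  expect_equal(tr2$residual_cm, tr$residual_cm, tolerance = 1e-12)
})
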