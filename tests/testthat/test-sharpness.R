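test_that("default ROIs sit on the central band and fit inside the image", {
  r <- default_rois(1920, 1080)
  expect_equal(r$cx, c(480, 960, 1440))
  expect_equal(r$cy, rep(540, 3))
  expect_equal(r$diameter, rep(100, 3))
  r2 <- default_rois(200, 200)
  expect_equal(r2$cx, c(50, 100, 150))
  expect_equal(r2$cy, rep(100, 3))
  expect_true(all(r2$cx - 50 >= 0 & r2$cx + 50 <= 200))
  expect_error(default_rois(150, 150), "too small")
})

test_that("vectorised convolution matches the brute-force oracle", {
  img <- texture_image(24, 30, seed = 5)
  for (k in list(branchnav:::KERNEL_SOBEL_X, branchnav:::KERNEL_SOBEL_Y,
                 branchnav:::KERNEL_LAPLACIAN)) {
    expect_equal(branchnav:::conv3x3(img, k), conv3x3_oracle(img, k))
  }
})

test_that("uniform images score zero under every operator", {
  img <- matrix(120, 220, 220)
  roi <- default_rois(220, 220)[2, ]
  expect_equal(sobel_index(img, roi), 0)
  expect_equal(laplacian_index(img, roi), 0)
  expect_equal(canny_index(img, roi), 0)   # sd = 0: no error, empty edge map
})

test_that("a linear ramp has zero Laplacian away from borders", {
  img <- matrix(seq(0, 200, length.out = 220), 220, 220, byrow = TRUE)
  roi <- default_rois(220, 220)[2, ]
  expect_equal(laplacian_index(img, roi), 0)
})

test_that("a vertical step edge gives the closed-form Sobel response", {
  h <- 220; w <- 220
  delta <- 80
  img <- matrix(50, h, w)
  img[, 111:w] <- 50 + delta
  roi <- default_rois(w, h)[2, ]  # centred at (110, 110), d = 100
  # oracle: per-pixel gradient magnitude from the brute-force convolution
  sx <- conv3x3_oracle(img, branchnav:::KERNEL_SOBEL_X)
  sy <- conv3x3_oracle(img, branchnav:::KERNEL_SOBEL_Y)
  m <- branchnav:::roi_mask(h, w, roi)
  expect_equal(sobel_index(img, roi), sum(sqrt(sx[m]^2 + sy[m]^2)))
  # the two columns flanking the edge respond with 4 * delta per pixel
  n_edge_pixels <- sum(m[, 110]) + sum(m[, 111])
  expect_equal(sobel_index(img, roi), n_edge_pixels * 4 * delta)
})

test_that("ROIs outside the image are rejected", {
  img <- matrix(0, 220, 220)
  expect_error(sobel_index(img, list(cx = 10, cy = 10, diameter = 100)),
               "outside")
})

test_that("the Canny map is 0/255 and marks a clean step edge", {
  set.seed(6)
  img <- matrix(50, 220, 220) + rnorm(220 * 220, 0, 2)
  img[, 111:220] <- img[, 111:220] + 120
  edge <- canny_edge_map(img)
  expect_true(all(edge %in% c(0, 255)))
  # edge pixels concentrate on the two columns flanking the step
  expect_gt(sum(edge[, 109:112]), 0.9 * sum(edge))
  roi <- default_rois(220, 220)[2, ]
  idx <- canny_index(img, roi)
  expect_equal(idx %% 255, 0)
  expect_gt(idx, 0)
})

test_that("all three indexes decrease strictly under increasing blur", {
  base <- gen_branch_image(seed = 3, blur_sigma = 0, width = 480, height = 270)
  roi <- default_rois(480, 270)[2, ]
  sig <- c(0, 1, 2, 4, 8)
  idx <- t(vapply(sig, function(s) {
    img <- red_channel(gen_branch_image(seed = 3, blur_sigma = s,
                                        width = 480, height = 270)$image)
    c(sobel_index(img, roi), laplacian_index(img, roi), canny_index(img, roi))
  }, numeric(3)))
  expect_true(all(diff(idx[, 1]) < 0))
  expect_true(all(diff(idx[, 2]) < 0))
  expect_true(all(diff(idx[, 3]) <= 0))  # edge counts can saturate at 0
  expect_lt(idx[5, 3], idx[1, 3])
})

test_that("indexes are translation invariant for a texture containing the ROI", {
  set.seed(12)
  tex <- texture_image(140, 200, seed = 12)
  big <- matrix(100, 260, 400)
  big[61:200, 61:260] <- tex
  big2 <- matrix(100, 260, 400)
  big2[61:200, 121:320] <- tex  # shifted 60 px right
  roi1 <- list(cx = 160, cy = 130, diameter = 100)
  roi2 <- list(cx = 220, cy = 130, diameter = 100)
  expect_equal(sobel_index(big, roi1), sobel_index(big2, roi2))
  expect_equal(laplacian_index(big, roi1), laplacian_index(big2, roi2))
})

test_that("frame acceptance requires one ROI strictly above threshold", {
  thr <- sharpness_thresholds()
  expect_true(accept_frame(c(1.2e6, 0.3e6, 0.2e6), thr, "sobel"))
  expect_false(accept_frame(c(0, 0, 0), thr, "sobel"))
  expect_false(accept_frame(rep(thr$laplacian, 3), thr, "laplacian"))
  expect_true(accept_frame(rep(thr$laplacian + 1, 1), thr, "laplacian"))
  expect_error(accept_frame(1, thr, "prewitt"))
})

test_that("frame_sharpness computes the per-ROI operator table", {
  img <- gen_branch_image(seed = 4, width = 480, height = 270)$image
  sc <- frame_sharpness(img)
  expect_equal(sc$roi, c("left", "center", "right"))
  expect_true(all(c("idx_sobel", "idx_laplacian", "idx_canny") %in% names(sc)))
  expect_true(all(sc$idx_sobel >= 0))
  sc2 <- frame_sharpness(img, operators = "laplacian")
  expect_named(sc2, c("roi", "idx_laplacian"))
})

test_that("selection keeps the retention fraction of accepted frames", {
  sharp <- red_channel(gen_branch_image(seed = 5, width = 480, height = 270)$image)
  frames <- replicate(10, sharp, simplify = FALSE)
  # thresholds scaled to what this small fixture actually scores
  thr <- sharpness_thresholds(sobel = 1, laplacian = 1, canny = 1)
  sel <- select_frames(frames, thr, operator = "laplacian", retention = 0.2)
  expect_false(sel$reacquire)
  expect_length(sel$selected, 2)
  expect_equal(sum(tidy(sel)$selected), 2)
  # uniformly spaced over the accepted run
  expect_equal(diff(sel$selected), 9)
  expect_error(select_frames(list(), thr), "Empty")
})

test_that("an all-blurred video is flagged for re-acquisition", {
  blurred <- red_channel(gen_branch_image(seed = 5, blur_sigma = 8,
                                          width = 480, height = 270)$image)
  frames <- replicate(5, blurred, simplify = FALSE)
  sel <- select_frames(frames, sharpness_thresholds(), operator = "laplacian")
  expect_true(sel$reacquire)
  expect_length(sel$selected, 0)
})

test_that("operators separate sharp from motion-blurred fixtures with no overlap", {
  roi <- default_rois(480, 270)[2, ]
  idx_sharp <- vapply(1:10, function(i) {
    img <- red_channel(gen_branch_image(seed = 100 + i, width = 480,
                                        height = 270)$image)
    laplacian_index(img, roi)
  }, numeric(1))
  idx_blur <- vapply(1:10, function(i) {
    img <- red_channel(gen_branch_image(seed = 100 + i, motion_blur_len = 40,
                                        width = 480, height = 270)$image)
    laplacian_index(img, roi)
  }, numeric(1))
  expect_gt(min(idx_sharp), max(idx_blur))
})
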