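test_that("PNG round-trip preserves 8-bit channel values exactly", {
  px <- array(c(10L, 20L, 30L), c(2, 2, 3))
  px[, , 1] <- 10L; px[, , 2] <- 20L; px[, , 3] <- 30L
  img <- fundus_image(px, "rt")
  path <- withr::local_tempfile(fileext = ".png")
  save_image_png(img, path)
  back <- load_image(path)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$width, 2)
  expect_equal(back$height, 2)

  # arbitrary content round-trips bit-exactly too
  set.seed(4)
  px2 <- array(sample(0:255, 30 * 20 * 3, TRUE), c(20, 30, 3))
  p2 <- withr::local_tempfile(fileext = ".png")
  save_image_png(fundus_image(px2), p2)
  expect_identical(load_image(p2)$pixels, fundus_image(px2)$pixels)
})

test_that("RGBA input drops alpha, grayscale replicates, TIFF reads", {
  path <- withr::local_tempfile(fileext = ".png")
  rgba <- array(0, c(4, 5, 4))
  rgba[, , 1] <- 0.2; rgba[, , 2] <- 0.4; rgba[, , 3] <- 0.6; rgba[, , 4] <- 1
  png::writePNG(rgba, path)
  img <- load_image(path)
  expect_equal(dim(img$pixels), c(4, 5, 3))
  expect_true(all(img$pixels[, , 1] == round(0.2 * 255)))

  gray <- matrix(0.5, 6, 6)
  pg <- withr::local_tempfile(fileext = ".png")
  png::writePNG(gray, pg)
  gimg <- load_image(pg)
  expect_true(all(gimg$pixels == round(0.5 * 255)))
  expect_equal(dim(gimg$pixels)[3], 3)

  pt <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(rgba[, , 1:3], pt, bits.per.sample = 8L)
  expect_equal(dim(load_image(pt)$pixels), c(4, 5, 3))
})

test_that("unreadable files and unsupported depths are rejected", {
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(load_image(bad), "cannot read")
  expect_error(load_image("no/such/file.png"), "not found")

  deep <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 3, 3), deep, dpi = NULL, asp = NULL) # 8-bit fine
  p16 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(3, 3, 3)), p16, bits.per.sample = 16L)
  expect_error(load_image(p16), "bit depth")
})

test_that("default ROI sits at the rounded fovea-disc midpoint", {
  img <- uniform_image(c(100, 100, 100), w = 1000, h = 1000)
  roi <- default_roi(img, landmarks(c(400, 300), c(200, 300), img))
  expect_equal(roi$center, c(300, 300))
  expect_equal(roi$diameter, 250)
  # midpoint at .5 rounds half away from zero
  roi2 <- default_roi(img, landmarks(c(101, 100), c(100, 100), img), diameter = 50)
  expect_equal(roi2$center, c(101, 100))
  # disk exceeding the image is a geometry error
  small <- uniform_image(c(1, 2, 3), w = 200, h = 200)
  expect_error(default_roi(small, landmarks(c(50, 50), c(60, 50), small)),
               "exceeds")
})

test_that("landmarks must be distinct and inside the image", {
  img <- uniform_image(c(9, 9, 9), w = 50, h = 40)
  expect_error(landmarks(c(10, 10), c(10, 10)), "coincide")
  expect_error(landmarks(c(10, 10), c(60, 10), img), "outside")
})

test_that("disk membership matches brute-force enumeration", {
  img <- uniform_image(c(1, 1, 1), w = 60, h = 60)
  # degenerate and small disks
  expect_equal(nrow(roi_pixels(img, circular_roi(c(5, 5), 1, img))), 1)
  got3 <- roi_pixels(img, circular_roi(c(5, 5), 3, img))
  expect_equal(nrow(got3), 9)
  # random centers/diameters against the exhaustive distance check
  set.seed(31)
  for (i in 1:100) {
    d <- sample(1:20, 1)
    span <- ceiling(d / 2)
    cx <- sample(span:(60 - span - 1), 1); cy <- sample(span:(60 - span - 1), 1)
    roi <- circular_roi(c(cx, cy), d, img)
    got <- roi_pixels(img, roi)
    expect_equal(nrow(got), nrow(oracle_disk_pixels(c(cx, cy), d, 60, 60)),
                 info = sprintf("center (%d,%d) diameter %d", cx, cy, d))
  }
  # the protocol-sized 250-px disk agrees with the oracle count
  big <- uniform_image(c(1, 1, 1), w = 300, h = 300)
  roi <- circular_roi(c(150, 150), 250, big)
  expect_equal(nrow(roi_pixels(big, roi)),
               nrow(oracle_disk_pixels(c(150, 150), 250, 300, 300)))
})

test_that("channel stats match direct arithmetic and a two-pass oracle", {
  st <- channel_stats(rbind(c(10, 20, 30), c(30, 20, 10)))
  expect_equal(st["R", "mean"], 20)
  expect_equal(st["R", "min"], 10)
  expect_equal(st["R", "max"], 30)
  expect_equal(st["R", "median"], 20)
  expect_equal(st["R", "count"], 2)
  expect_equal(st["G", "sd"], 0)

  one <- channel_stats(matrix(c(255, 0, 0), 1))
  expect_equal(unname(unlist(one[, "mean"])), c(255, 0, 0))
  expect_true(all(one[, "sd"] == 0))

  set.seed(11)
  px <- cbind(sample(0:255, 10000, TRUE), sample(0:255, 10000, TRUE),
              sample(0:255, 10000, TRUE))
  st <- channel_stats(px)
  for (i in 1:3) {
    o <- oracle_two_pass(px[, i])
    expect_equal(st[i, "mean"], o$mean, tolerance = 1e-9)
    expect_equal(st[i, "sd"], o$sd, tolerance = 1e-9)
  }
  # permutation invariance and min <= median <= max
  st2 <- channel_stats(px[sample(nrow(px)), ])
  expect_equal(st2, st)
  expect_true(all(st[, "min"] <= st[, "median"] & st[, "median"] <= st[, "max"]))
  expect_error(channel_stats(px[0, ]), "empty ROI")
})

test_that("landmarks CSV round-trips with the exact header", {
  df <- data.frame(eye_id = c("a", "b"), fovea_x = c(400L, 410L),
                   fovea_y = 300L, disc_x = 200L, disc_y = 300L,
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(df, path)
  expect_identical(readLines(path)[1], "eye_id,fovea_x,fovea_y,disc_x,disc_y")
  expect_equal(read_landmarks_csv(path), df)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("eye,fx,fy,dx,dy", "a,1,2,3,4"), bad)
  expect_error(read_landmarks_csv(bad), "header")
})
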