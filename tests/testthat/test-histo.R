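test_that("ring labels follow hole-edge geometry and half-open bins", {
  # odd-sized image at 1 um/px so the hole centre is a pixel centre;
  # hole radius 100 um, outermost hole pixel on the axis at +100
  n <- 1501
  mpp <- 1
  hole <- disk_mask(n, 100)
  lab <- ring_labels(hole, mpp)
  c0 <- (n + 1) / 2
  # pixel 75 um from the hole edge (radial 175 um) sits in bin 1
  expect_equal(lab[c0 + 175, c0], 1L)
  # pixel inside the hole is unlabeled
  expect_true(is.na(lab[c0, c0]))
  # bins are half-open at 650 um
  expect_true(is.na(lab[c0 + 100 + 650, c0]))
  expect_equal(lab[c0 + 100 + 649, c0], 12L)
})

test_that("ring labels equal the brute-force distance loop", {
  n <- 64
  hole <- matrix(FALSE, n, n); hole[28:36, 30:38] <- TRUE
  lab <- ring_labels(hole, microns_per_pixel = 20)
  ref <- ring_labels_bruteforce(hole, 20)
  expect_identical(unclass(lab)[seq_len(n * n)], ref[seq_len(n * n)])
})

test_that("a border-touching hole is rejected", {
  hole <- matrix(FALSE, 50, 50); hole[1:10, 20:30] <- TRUE
  expect_error(ring_labels(hole, 10), "border")
})

test_that("ring pixel counts partition the image", {
  n <- 64
  hole <- matrix(FALSE, n, n); hole[30:34, 30:34] <- TRUE
  lab <- ring_labels(hole, microns_per_pixel = 25)
  art <- matrix(FALSE, n, n); art[1:10, 1:10] <- TRUE
  img <- matrix(1, n, n)
  prof <- bin_intensity(img, lab, art)
  n_beyond <- sum(is.na(lab)) - sum(hole)
  n_art_binned <- sum(art & !is.na(lab))
  expect_equal(sum(prof$n_pixels) + sum(hole) + n_beyond + n_art_binned,
               n * n)
})

test_that("bin intensity averages exclude artifact pixels", {
  n <- 64
  hole <- matrix(FALSE, n, n); hole[30:34, 30:34] <- TRUE
  lab <- ring_labels(hole, microns_per_pixel = 25)
  img <- matrix(7, n, n)
  prof <- bin_intensity(img, lab)
  expect_true(all(prof$mean_raw[prof$n_pixels > 0] == 7))
  # poison half the pixels of bin 0 through the artifact mask
  art <- matrix(FALSE, n, n)
  b0 <- which(lab == 0)
  art[b0[seq(1, length(b0), by = 2)]] <- TRUE
  img2 <- img; img2[art] <- 1e6
  prof2 <- bin_intensity(img2, lab, art)
  expect_equal(prof2$mean_raw[1], 7)
})

test_that("bin intensity equals a per-pixel loop oracle", {
  n <- 64
  hole <- matrix(FALSE, n, n); hole[20:26, 40:46] <- TRUE
  lab <- ring_labels(hole, microns_per_pixel = 15)
  withr::with_seed(2, img <- matrix(runif(n * n, 0, 1000), n, n))
  art <- matrix(FALSE, n, n); art[50:60, 5:15] <- TRUE
  prof <- bin_intensity(img, lab, art)
  for (b in prof$bin) {
    acc <- 0; cnt <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!is.na(lab[i, j]) && lab[i, j] == b && !art[i, j]) {
        acc <- acc + img[i, j]; cnt <- cnt + 1L
      }
    }
    expect_equal(prof$n_pixels[prof$bin == b], cnt)
    if (cnt > 0)
      expect_equal(prof$mean_raw[prof$bin == b], acc / cnt)
  }
})

test_that("profile normalization maps the background bin to its factor", {
  prof <- data.frame(bin = 0:12, mean_raw = rep(100, 13))
  expect_true(all(normalize_profile(prof, 1)$normalized == 1))
  expect_true(all(normalize_profile(prof, 0)$normalized == 0))
  prof$mean_raw[1] <- 200
  expect_equal(normalize_profile(prof, 0)$normalized[1], 1)
  # scale invariance
  prof2 <- prof; prof2$mean_raw <- prof2$mean_raw * 37.5
  expect_equal(normalize_profile(prof2, 1)$normalized,
               normalize_profile(prof, 1)$normalized)
  bad <- data.frame(bin = 0:12, mean_raw = c(rep(1, 12), 0))
  expect_error(normalize_profile(bad, 1), "background")
})

test_that("blob detection counts well-separated somata", {
  expect_equal(nrow(detect_centroids(matrix(0, 100, 100), 1)), 0L)

  n <- 600
  sig <- 3
  withr::with_seed(13, img <- matrix(rnorm(n * n, 500, 50), n, n))
  centers <- as.matrix(expand.grid(seq(60, 540, by = 68),
                                   seq(60, 540, by = 68)))[1:50, ]
  px <- -12:12
  patch <- 3000 * exp(-outer(px^2, px^2, "+") / (2 * sig^2))
  for (k in 1:50) {
    rr <- centers[k, 1] + px; cc <- centers[k, 2] + px
    img[rr, cc] <- img[rr, cc] + patch
  }
  found <- detect_centroids(img, microns_per_pixel = 1, soma_radius_um = 4)
  expect_gte(nrow(found), 48)
  expect_lte(nrow(found), 52)

  # a soma centred inside the artifact mask is not reported
  art <- matrix(FALSE, n, n)
  art[centers[1, 1] + (-15:15), centers[1, 2] + (-15:15)] <- TRUE
  found2 <- detect_centroids(img, 1, soma_radius_um = 4,
                             artifact_mask = art)
  expect_equal(nrow(found2), nrow(found) - 1L)
})

test_that("density profile is flat for a uniform point process", {
  n <- 1200
  hole <- disk_mask(n, 80)
  lab <- ring_labels(hole, microns_per_pixel = 2)
  withr::with_seed(4, {
    pts <- data.frame(x_px = sample.int(n, 6000, TRUE),
                      y_px = sample.int(n, 6000, TRUE))
  })
  prof <- density_profile(pts, lab)
  expect_true(all(abs(prof$normalized - 1) <
                    4 / sqrt(pmax(prof$count, 1))  + 0.2))
  expect_lt(abs(mean(prof$normalized) - 1), 0.15)
})

test_that("density is invariant to the pixel scale", {
  # the same physical scene sampled at 1 and 2 um/px
  mk <- function(n, mpp) {
    hole <- disk_mask(n, 100 / mpp)
    lab <- ring_labels(hole, mpp)
    step <- 20 / mpp
    g <- expand.grid(x = seq(1, n, by = step), y = seq(1, n, by = step))
    density_profile(data.frame(x_px = round(g$x), y_px = round(g$y)), lab)
  }
  p1 <- mk(1500, 1)
  p2 <- mk(750, 2)
  ok <- p1$count > 30
  expect_lt(max(abs(p1$density[ok] / p2$density[ok] - 1)), 0.2)
})

test_that("hole detection recovers a synthetic disk and honours overrides", {
  n <- 400
  mpp <- 2
  truth <- disk_mask(n, 40)
  withr::with_seed(7, img <- matrix(rnorm(n * n, 1000, 50), n, n))
  img[truth] <- img[truth] - 900
  found <- detect_hole(img, mpp)
  iou <- sum(found & truth) / sum(found | truth)
  expect_gte(iou, 0.95)

  user <- matrix(FALSE, n, n); user[1:5, 1:5] <- TRUE
  expect_equal(detect_hole(img, mpp, mask = user), user)

  expect_error(detect_hole(matrix(1, 50, 50), mpp), "contrast")
})
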