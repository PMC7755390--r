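test_that("IsoData threshold is the fixed point of the class-mean iteration", {
  expect_equal(threshold_isodata(matrix(c(rep(10, 50), rep(20, 50)), 10)), 15)
  expect_equal(threshold_isodata(matrix(c(0, 255), 1)), 127.5)
  ## hand-iterated fixed point on an asymmetric two-level image:
  ## 90 px at 10, 10 px at 110 -> T0 = 20, below-mean 10, above-mean 110 -> 60
  x <- matrix(c(rep(10, 90), rep(110, 10)), 10)
  expect_equal(threshold_isodata(x), 60)
  expect_error(threshold_isodata(matrix(5, 4, 4)), "constant")
})

test_that("connected components honor the requested connectivity", {
  m <- matrix(0, 5, 5); m[1, 1] <- 1; m[2, 2] <- 1; m[4, 4] <- 1
  expect_equal(max(label_components(m, 8)), 2)  # diagonal pair merges
  expect_equal(max(label_components(m, 4)), 3)
  expect_equal(max(label_components(matrix(0, 4, 4))), 0)
})

test_that("soma segmentation recovers disk geometry", {
  expect_equal(nrow(segment_somata(img8(matrix(0, 64, 64)), 10)$stats), 0)

  ## one filled disk, radius 20 px at 0.1 um/px: area ~ pi*(2 um)^2,
  ## perimeter ~ 2*pi*2 um
  d <- disk_mask(64, 32, 32, 20)
  s <- segment_somata(img8(d * 200), 100, min_soma_area_um2 = 5)
  expect_equal(nrow(s$stats), 1)
  expect_equal(s$stats$area_um2, pi * 4, tolerance = 0.03)
  expect_equal(s$stats$perimeter_um, 2 * pi * 2, tolerance = 0.05)
  expect_equal(s$stats$centroid_x, 31, tolerance = 0.01)  # 0-based centre

  two <- disk_mask(96, 25, 25, 12) | disk_mask(96, 70, 70, 12)
  s2 <- segment_somata(img8(two * 200), 100, min_soma_area_um2 = 1)
  expect_equal(sort(unique(s2$labels[s2$labels > 0])), c(1L, 2L))
  expect_equal(nrow(s2$stats), 2)

  ## the min-area gate separates somata from speckle
  sp <- two; sp[5, 5] <- TRUE
  s3 <- segment_somata(img8(sp * 200), 100, min_soma_area_um2 = 1)
  expect_equal(nrow(s3$stats), 2)
})

test_that("areas and perimeters scale with the pixel calibration", {
  d <- disk_mask(64, 32, 32, 15) * 200
  a <- segment_somata(img8(d, ps = 0.1), 100, min_soma_area_um2 = 1)$stats
  b <- segment_somata(img8(d, ps = 0.2), 100, min_soma_area_um2 = 1)$stats
  expect_equal(b$area_um2, a$area_um2 * 4)
  expect_equal(b$perimeter_um, a$perimeter_um * 2)
})

test_that("neuropil is the high-threshold foreground minus the somata", {
  sq <- matrix(0, 64, 64); sq[11:50, 11:50] <- 150
  im <- img8(sq)
  none <- segment_somata(im, 200)               # no somata
  np0 <- segment_neuropil(im, 100, none)
  expect_equal(sum(np0$labels > 0), 40 * 40)

  somas <- segment_somata(im, 100, min_soma_area_um2 = 1)
  np1 <- segment_neuropil(im, 100, somas)       # soma covers all foreground
  expect_equal(sum(np1$labels > 0), 0)

  ## disk soma inside a larger thresholded square -> annulus, by pixel count
  d <- disk_mask(64, 30, 30, 10)
  im2 <- img8(sq + d * 100)
  somas2 <- segment_somata(im2, 200, min_soma_area_um2 = 1)
  np2 <- segment_neuropil(im2, 100, somas2)
  expect_equal(sum(np2$labels > 0), 40 * 40 - sum(d))

  expect_error(segment_neuropil(img8(matrix(0, 32, 32)), 10, somas),
               "geometry")
})

test_that("AIS length equals the longest skeleton path", {
  expect_equal(nrow(segment_ais(img8(matrix(0, 64, 64)), 10)$stats), 0)

  bar <- matrix(0, 40, 130); bar[19:21, 16:115] <- 200  # 100 px x 3 px
  a <- segment_ais(img8(bar), 100, min_length_um = 1)
  expect_equal(nrow(a$stats), 1)
  expect_equal(a$stats$length_um, 10, tolerance = 0.05)

  ## L-shape with two 5 um arms -> geodesic ~ 10 um
  L <- matrix(0, 80, 80); L[15:65, 15:17] <- 200; L[63:65, 15:65] <- 200
  al <- segment_ais(img8(L), 100, min_length_um = 1)
  expect_equal(al$stats$length_um, 10, tolerance = 0.10)

  ## short segments are dropped by the length gate
  short <- matrix(0, 40, 40); short[20, 10:19] <- 200   # ~1 um
  expect_equal(nrow(segment_ais(img8(short), 100, min_length_um = 5)$stats), 0)
})

test_that("puncta detection applies class size minima with >= semantics", {
  qp <- quant_params()
  ## 5 px = 0.05 um^2 at 0.1 um/px: below the 0.06 GAD65 minimum
  m5 <- matrix(0, 32, 32); m5[16, 14:18] <- 200
  expect_equal(nrow(detect_puncta(img8(m5), 100, qp, "GAD65")$stats), 0)
  ## but retained for the 0.05 um^2 VGlut1 class (boundary, inclusive)
  expect_equal(nrow(detect_puncta(img8(m5), 100, qp, "VGlut1")$stats), 1)
  ## 6 px = 0.06 um^2: boundary case retained for GAD65
  m6 <- matrix(0, 32, 32); m6[16:17, 14:16] <- 200
  p6 <- detect_puncta(img8(m6), 100, qp, "GAD65")
  expect_equal(nrow(p6$stats), 1)
  expect_equal(p6$stats$area_um2, 0.06)
  expect_error(detect_puncta(img8(m6), 100, qp, "NotAMarker"), "unknown")
})

test_that("watershed splits touching blobs into separate puncta", {
  dumb <- (disk_mask(64, 26, 32, 8) | disk_mask(64, 40, 32, 8)) * 200
  p <- detect_puncta(img8(dumb), 100, quant_params(), "GAD65")
  expect_equal(nrow(p$stats), 2)
  ## two clearly separate blobs also give two puncta
  sep <- (disk_mask(64, 18, 32, 6) | disk_mask(64, 46, 32, 6)) * 200
  expect_equal(nrow(detect_puncta(img8(sep), 100, quant_params(), "GAD65")$stats), 2)
})

test_that("reported areas equal brute-force pixel counts exactly", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(0, 48, 48)
    for (k in 1:4) {
      cx <- sample(8:40, 1); cy <- sample(8:40, 1); r <- runif(1, 1.5, 3.5)
      m <- pmax(m, disk_mask(48, cx, cy, r) * 200)
    }
    p <- detect_puncta(img8(m), 100, quant_params(), "VGlut1")
    for (l in p$stats$label)
      expect_identical(p$stats$area_um2[p$stats$label == l],
                       sum(p$labels == l) * 0.1^2)
  }
})

test_that("detection is monotone in threshold and size minimum", {
  sc <- small_scene(noise = TRUE)
  im <- sc$images$presyn_marker
  areas <- vapply(c(60, 100, 140, 180),
                  function(t) sum(im$pixels >= t), numeric(1))
  expect_false(is.unsorted(rev(areas)))
  qp1 <- quant_params()
  counts <- vapply(c(0.03, 0.06, 0.12, 0.3), function(a) {
    qp <- qp1; qp$min_punctum_area_um2["GAD65"] <- a
    nrow(detect_puncta(im, 120, qp, "GAD65")$stats)
  }, numeric(1))
  expect_false(is.unsorted(rev(counts)))
})

test_that("border puncta are kept by default and dropped on request", {
  m <- matrix(0, 32, 32); m[1:3, 10:14] <- 200; m[16:17, 16:20] <- 200
  qp <- quant_params()
  expect_equal(nrow(detect_puncta(img8(m), 100, qp, "VGlut1")$stats), 2)
  expect_equal(nrow(detect_puncta(img8(m), 100, qp, "VGlut1",
                                  exclude_border = TRUE)$stats), 1)
})
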