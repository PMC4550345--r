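test_that("affine estimation recovers identity, translation and a general map", {
  pts <- cbind(c(0, 10, 3, 7), c(0, 2, 9, 5))
  t0 <- estimateAffine(pts, pts)
  expect_equal(unname(t0@coef), c(1, 0, 0, 0, 1, 0), tolerance = 1e-12)

  t1 <- estimateAffine(pts[1:3, ], pts[1:3, ] + rep(c(5, 2), each = 3))
  expect_equal(unname(t1@coef), c(1, 0, 5, 0, 1, 2), tolerance = 1e-10)

  truth <- c(1.02, 0.18, -14, -0.05, 0.97, 9)
  set.seed(2)
  src <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  dst <- cbind(truth[1] * src[, 1] + truth[2] * src[, 2] + truth[3],
               truth[4] * src[, 1] + truth[5] * src[, 2] + truth[6])
  fit <- estimateAffine(src, dst)
  expect_equal(unname(fit@coef), truth, tolerance = 1e-9)
  expect_lt(max(abs(applyTransform(fit, src) - dst)), 1e-9)
  expect_equal(unname(fit@coef), affineOracle(src, dst), tolerance = 1e-9)
})

test_that("affine estimation rejects underdetermined input", {
  expect_error(estimateAffine(cbind(1:2, 1:2), cbind(1:2, 1:2)),
               "underdetermined affine", class = "microspotGeometryError")
  col <- cbind(1:5, 2 * (1:5) + 3)  # collinear sources
  expect_error(estimateAffine(col, col), "collinear",
               class = "microspotGeometryError")
})

test_that("quadratic fit nests the affine model and interpolates at n = 6", {
  set.seed(4)
  src <- cbind(runif(12, 0, 80), runif(12, 0, 80))
  aff <- c(1.1, 0.2, -3, -0.1, 0.9, 5)
  dst <- cbind(aff[1] * src[, 1] + aff[2] * src[, 2] + aff[3],
               aff[4] * src[, 1] + aff[5] * src[, 2] + aff[6])
  q <- fitQuadratic(src, dst)
  expect_lt(max(abs(c(q@px[4:6], q@py[4:6]))), 1e-9)
  expect_equal(q@px[1:3], aff[c(3, 1, 2)], tolerance = 1e-9)

  # pure x-curvature recovered exactly
  dst2 <- cbind(src[, 1] + 0.001 * src[, 1]^2, src[, 2])
  q2 <- fitQuadratic(src, dst2)
  expect_equal(q2@px[[4]], 0.001, tolerance = 1e-9)
  o <- quadraticOracle(src, dst2)
  expect_equal(q2@px, unname(o$px), tolerance = 1e-9)
  expect_equal(q2@py, unname(o$py), tolerance = 1e-9)

  # 6 generic points (no conic through all of them): exact interpolation
  s6 <- cbind(c(0, 50, 8, 47, 22, 12), c(0, 5, 45, 52, 28, 9))
  d6 <- cbind(runif(6, 0, 60), runif(6, 0, 60))
  q6 <- fitQuadratic(s6, d6)
  expect_lt(max(abs(applyTransform(q6, s6) - d6)), 1e-8)

  expect_error(fitQuadratic(s6[1:5, ], d6[1:5, ]), "underdetermined quadratic",
               class = "microspotGeometryError")
  colin <- cbind(1:8, 2 * (1:8))   # all on a line: basis rank-deficient
  expect_error(fitQuadratic(colin, colin), "rank-deficient",
               class = "microspotGeometryError")
})

test_that("fits match the normal-equations oracle on random instances", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    src <- cbind(runif(n, -50, 150), runif(n, -50, 150))
    dst <- cbind(runif(n, -50, 150), runif(n, -50, 150))
    fa <- estimateAffine(src, dst)
    expect_equal(unname(fa@coef), affineOracle(src, dst), tolerance = 1e-8)
    fq <- fitQuadratic(src, dst)
    o <- quadraticOracle(src, dst)
    expect_equal(fq@px, unname(o$px), tolerance = 1e-8)
    expect_equal(fq@py, unname(o$py), tolerance = 1e-8)
  }
})

test_that("warping by the identity and by integer shifts is exact", {
  set.seed(8)
  img <- matrix(runif(30 * 40, 0, 255), 30, 40)
  ident <- new("AffineTransform2D", coef = c(1, 0, 0, 0, 1, 0))
  expect_equal(warpImage(img, ident), img)

  shift <- new("AffineTransform2D", coef = c(1, 0, 3, 0, 1, 5))
  out <- warpImage(img, shift, dim(img), "nearest")
  expect_equal(out[6:30, 4:40], img[1:25, 1:37])
  expect_true(all(out[1:5, ] == 0))
  expect_true(all(out[, 1:3] == 0))
})

test_that("affine round-trip reproduces the interior within bilinear bounds", {
  aff <- new("AffineTransform2D", coef = c(1.01, 0.05, 2, -0.03, 0.99, -1))
  # bilinear resampling is exact on (piecewise) linear images
  smooth <- outer(seq(0, 200, length.out = 50), seq(0, 55, length.out = 50), "+")
  back <- warpImage(warpImage(smooth, aff, dim(smooth)),
                    invertAffine(aff), dim(smooth))
  expect_lt(max(abs(back - smooth)[7:43, 7:43]), 1e-9)

  # on a band-limited random image the smoothing error stays within a few
  # intensity units away from the zero-filled border
  set.seed(9)
  img <- EBImage::gblur(matrix(runif(50 * 50, 0, 255), 50, 50), 2)
  back2 <- warpImage(warpImage(img, aff, dim(img)), invertAffine(aff), dim(img))
  expect_lt(max(abs(back2 - img)[7:43, 7:43]), 4)
})

test_that("quadratic warps invert by Newton iteration and compose correctly", {
  set.seed(10)
  img <- matrix(0, 60, 60)
  img[21:26, 31:36] <- 200
  q <- new("QuadraticTransform2D",
           px = c(1, 1.02, 0.03, 1e-4, 0, -5e-5),
           py = c(-2, -0.02, 0.99, 0, 5e-5, 1e-4))
  out <- warpImage(img, q, dim(img))
  # the bright patch moves where the forward map sends it
  ctr <- applyTransform(q, cbind(32.5, 22.5))
  bl <- findBlobs(out > 100, 1)
  expect_lt(abs(bl$x - ctr[1]), 1.0)
  expect_lt(abs(bl$y - ctr[2]), 1.0)

  # an extreme quadratic that folds the domain must be rejected
  fold <- new("QuadraticTransform2D",
              px = c(0, 1, 0, -0.02, 0, 0), py = c(0, 0, 1, 0, 0, 0))
  expect_error(warpImage(img, fold, dim(img)), "non-invertible",
               class = "microspotGeometryError")
})

test_that("cropToSpots windows follow the margin formula and clamp", {
  layout <- buildDefaultLayout()
  refs <- referenceCentroids(layout)
  pos <- refs[refs$role == "POS" &
              (refs$row %in% c(0, 5) | refs$col %in% c(0, 7)), ]
  blobs <- data.frame(x = pos$x, y = pos$y, area = 100L,
                      xmin = 0L, ymin = 0L, xmax = 1L, ymax = 1L)
  m <- matchAnchors(blobs, layout)
  img <- matrix(1, 400, 400)
  cr <- cropToSpots(img, m, layout, 0.75)
  expect_identical(unname(cr$window),
                   c(0L, 0L, 340L, 260L))
  cr0 <- cropToSpots(img, m, layout, 0)
  expect_identical(unname(cr0$window), c(30L, 30L, 310L, 230L))
  expect_identical(dim(cr0$image), c(201L, 281L))

  # grid partially outside a small image: clamped, no error
  small <- matrix(1, 100, 420)
  crs <- cropToSpots(small, m, layout, 0.75)
  expect_identical(unname(crs$window[c("ymin", "ymax")]), c(0L, 99L))
})

test_that("standardize places POS centroids on the reference grid", {
  layout <- miniLayout()
  spec <- cleanSpec(layout = layout, noise = list(sd = 1, scale = 0.01),
                    seed = 21L)
  scn <- renderScene(spec)
  std <- standardizeChip(scn$gray, layout, details = TRUE)
  refs <- referenceCentroids(layout)
  pos <- refs[refs$role == "POS", ]
  blobs <- findBlobs(thresholdMask(std$image, "otsu"), 30)
  m <- matchAnchors(blobs, layout)
  p <- anchorPairs(m)
  err <- sqrt((p$obsX - p$refX)^2 + (p$obsY - p$refY)^2)
  expect_lt(max(err), 0.5)   # identity-aberration scene: near no-op geometry

  spec2 <- cleanSpec(layout = layout,
                     aberration = list(rotation = 1, shear = 5,
                                       scale = c(1.03, 0.97),
                                       translation = c(4, -6), bow = c(4, 3)),
                     noise = list(sd = 2, scale = 0.02), seed = 22L)
  scn2 <- renderScene(spec2)
  std2 <- standardizeChip(scn2$gray, layout, details = TRUE)
  blobs2 <- findBlobs(thresholdMask(std2$image, "otsu"), 30)
  p2 <- anchorPairs(matchAnchors(blobs2, layout))
  err2 <- sqrt((p2$obsX - p2$refX)^2 + (p2$obsY - p2$refY)^2)
  expect_lt(max(err2), 1.0)
})

test_that("standardizing an already standardized image is a near no-op", {
  layout <- miniLayout()
  spec <- cleanSpec(layout = layout,
                    aberration = list(rotation = -2, shear = 3,
                                      scale = c(0.98, 1.02),
                                      translation = c(-5, 3), bow = c(-3, 2)),
                    noise = list(sd = 2, scale = 0.02), seed = 23L)
  scn <- renderScene(spec)
  std1 <- standardizeChip(scn$gray, layout)
  std2 <- standardizeChip(std1, layout)
  blobs <- findBlobs(thresholdMask(std2, "otsu"), 30)
  p <- anchorPairs(matchAnchors(blobs, layout))
  err <- sqrt((p$obsX - p$refX)^2 + (p$obsY - p$refY)^2)
  expect_lt(max(err), 0.5)
})
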