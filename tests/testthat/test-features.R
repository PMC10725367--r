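test_that("ROI extraction masks pixels elementwise", {
  img <- matrix(100L, 8, 8)
  expect_identical(extractROI(img, matrix(1L, 8, 8)), img)
  expect_error(extractROI(img, matrix(0L, 8, 8)), "empty-ROI")
  expect_error(extractROI(img, matrix(1L, 8, 9)), "dimension")
  checker <- matrix(rep(c(1L, 0L), length.out = 64), 8, 8)
  roi <- extractROI(img, checker)
  expect_true(all(roi[checker == 1L] == 100L))
  expect_true(all(roi[checker == 0L] == 0L))
})

test_that("circularity is 1 for disks, small for bars, shift-invariant", {
  expect_equal(circularity(diskMask(256, 40)), 1, tolerance = 0.05)
  bar <- matrix(0L, 60, 60); bar[30, 6:55] <- 1L
  expect_lt(circularity(bar), 0.2)
  d1 <- diskMask(256, 30, cx = 100, cy = 90)
  d2 <- diskMask(256, 30, cx = 160, cy = 170)
  expect_equal(circularity(d1), circularity(d2), tolerance = 1e-12)
  expect_error(circularity(matrix(0L, 5, 5)), "empty-ROI")
})

test_that("solidity matches convexity and an independent hull-area oracle", {
  expect_equal(solidity(ellipseMaskFx(160, 55, 30)), 1, tolerance = 0.02)
  # plus sign from two 10 x 50 bars; continuous-geometry hull area is
  # 50*50 - 4*(1/2*20*20) = 1700, region area 2*500 - 100 = 900
  plus <- matrix(0L, 60, 60)
  plus[26:35, 6:55] <- 1L
  plus[6:55, 26:35] <- 1L
  expect_equal(solidity(plus), 900 / 1700, tolerance = 0.05)
  # spiculation strictly lowers solidity at a fixed seed
  sol <- vapply(c(0L, 4L, 8L), function(k) {
    ph <- generatePhantom(phantomSpec(
      "malignant", imageSize = 96L, boundaryIrregularity = 0,
      nSpicules = k, textureHeterogeneity = 0, speckleSigma = 0,
      seed = 11L))
    solidity(ph$mask)
  }, numeric(1))
  expect_true(all(diff(sol) < 0))
  line <- matrix(0L, 20, 20); line[10, 5:15] <- 1L
  expect_error(solidity(line), "degenerate-region")
})

test_that("ellipse ratio is 1 for elliptical shapes and grows with spicules", {
  expect_equal(ellipseRatio(diskMask(160, 40)), 1, tolerance = 0.05)
  expect_equal(ellipseRatio(ellipseMaskFx(160, 60, 30)), 1,
               tolerance = 0.05)
  base <- generatePhantom(phantomSpec(
    "malignant", imageSize = 96L, boundaryIrregularity = 0,
    nSpicules = 0L, textureHeterogeneity = 0, speckleSigma = 0,
    seed = 11L))
  spic <- generatePhantom(phantomSpec(
    "malignant", imageSize = 96L, boundaryIrregularity = 0,
    nSpicules = 8L, textureHeterogeneity = 0, speckleSigma = 0,
    seed = 11L))
  expect_gt(ellipseRatio(spic$mask), ellipseRatio(base$mask))
})

test_that("brightness equals the band-mean difference", {
  m <- diskMask(60, 15)
  img <- matrix(100L, 60, 60); img[m == 1L] <- 50L
  expect_equal(brightness(img, m, bandK = 5L), 50)
  expect_equal(brightness(matrix(80L, 60, 60), m, bandK = 5L), 0)
  # ramp background: compare against brute-force distance bands
  ramp <- matrix(rep(seq_len(60), each = 60), 60, 60) + 0
  ramp[m == 1L] <- 10
  k <- 4
  fg <- which(m == 1L, arr.ind = TRUE)
  bg <- which(m == 0L, arr.ind = TRUE)
  dist2set <- function(pts, set) {
    apply(pts, 1, function(p)
      sqrt(min((set[, 1] - p[1])^2 + (set[, 2] - p[2])^2)))
  }
  outer_band <- bg[dist2set(bg, fg) <= k, , drop = FALSE]
  inner_band <- fg[dist2set(fg, bg) <= k, , drop = FALSE]
  expected <- abs(mean(ramp[outer_band]) - mean(ramp[inner_band]))
  expect_equal(brightness(ramp, m, bandK = k), expected, tolerance = 1e-9)
})

test_that("Shannon entropy and histogram energy follow the histogram", {
  m <- matrix(1L, 8, 8)
  expect_equal(shannonEntropy(matrix(7L, 8, 8), m), 0)
  two <- matrix(rep(c(10L, 200L), 32), 8, 8)
  expect_equal(shannonEntropy(two, m), 1)
  four <- matrix(rep(c(0L, 60L, 120L, 240L), 16), 8, 8)
  expect_equal(shannonEntropy(four, m), 2)
  expect_equal(histEnergy(matrix(7L, 8, 8), m), 1)
  expect_equal(histEnergy(two, m), 0.5)
  set.seed(4)
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  counts <- table(img)
  expect_equal(histEnergy(img, m), sum((counts / 64)^2))
})

test_that("GLCM respects direction, symmetry and normalization", {
  m <- matrix(1L, 8, 8)
  P <- glcm(matrix(100L, 8, 8), m, levels = 8L)
  expect_equal(sum(P), 1)
  expect_equal(sum(diag(P)), 1)  # constant image: one diagonal cell
  stripes <- matrix(rep(c(0L, 255L), length.out = 8), 8, 8)
  # rows alternate but are constant: horizontal pairs stay on-diagonal
  Ph <- glcm(stripes, m, levels = 2L, angles = 0)
  expect_equal(Ph[1, 1] + Ph[2, 2], 1)
  # vertical pairs alternate levels: all mass off-diagonal
  Pv <- glcm(stripes, m, levels = 2L, angles = pi / 2)
  expect_equal(Pv[1, 2] + Pv[2, 1], 1)
  expect_true(isSymmetric(Pv))
})

test_that("GLCM counts match a pair-enumeration oracle on small ROIs", {
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(8:32, 1)
    img <- matrix(sample(0:255, n * n, replace = TRUE), n, n)
    mask <- matrix(rbinom(n * n, 1, 0.7), n, n)
    mask[sample(n * n, 1)] <- 1L  # guarantee foreground
    q <- pmin(img %/% 32L + 1L, 8L)
    ref <- matrix(0, 8, 8)
    for (r in seq_len(n)) for (cl in seq_len(n)) {
      if (mask[r, cl] == 0) next
      for (off in offsets) {
        r2 <- r + off[1]; c2 <- cl + off[2]
        if (r2 < 1 || r2 > n || c2 < 1 || c2 > n) next
        if (mask[r2, c2] == 0) next
        ref[q[r, cl], q[r2, c2]] <- ref[q[r, cl], q[r2, c2]] + 1
      }
    }
    if (sum(ref) == 0) next
    ref <- ref + t(ref)
    ref <- ref / sum(ref)
    expect_equal(glcm(img, mask, levels = 8L), ref, tolerance = 1e-12)
  }
})

test_that("GLCM statistics match hand-evaluated formulas", {
  Pd <- diag(8) / 8
  fd <- glcmFeatures(Pd)
  expect_equal(unname(fd["contrast"]), 0)
  expect_equal(unname(fd["dissimilarity"]), 0)
  P2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f2 <- glcmFeatures(P2)
  expect_equal(unname(f2["dissimilarity"]), 1)
  expect_equal(unname(f2["contrast"]), 1)
  expect_equal(unname(f2["entropy"]), 1)
  expect_equal(unname(f2["correlation"]), -1)
  expect_error(glcmFeatures(matrix(0.3, 2, 2)), "normalization")
  # when all |i - j| <= 1 (any 2x2 GLCM), contrast equals dissimilarity
  for (s in 1:50) {
    set.seed(s)
    v <- runif(3)
    P <- matrix(c(v[1], v[2], v[2], v[3]), 2, 2)
    P <- P / sum(P)
    f <- glcmFeatures(P)
    expect_equal(unname(f["contrast"]), unname(f["dissimilarity"]),
                 tolerance = 1e-12)
  }
  # direct formula oracle on a random normalized matrix
  set.seed(9)
  P <- matrix(runif(64), 8, 8); P <- (P + t(P)); P <- P / sum(P)
  f <- glcmFeatures(P)
  I <- matrix(0:7, 8, 8); J <- t(I)
  expect_equal(unname(f["entropy"]), -sum(P * log2(P)), tolerance = 1e-12)
  expect_equal(unname(f["dissimilarity"]), sum(P * abs(I - J)),
               tolerance = 1e-12)
  expect_equal(unname(f["contrast"]), sum(P * (I - J)^2), tolerance = 1e-12)
  mg <- sum((0:7) * rowSums(P))
  s2 <- sum(rowSums(P) * ((0:7) - mg)^2)
  expect_equal(unname(f["correlation"]),
               sum(P * (I - mg) * (J - mg)) / s2, tolerance = 1e-12)
  expect_lte(abs(unname(f["correlation"])), 1)
})

test_that("all ten features are invariant to lesion translation", {
  ph <- generatePhantom(phantomSpec("malignant", imageSize = 96L,
                                    seed = 8L))
  pad <- 40L
  big <- function(x, dr, dc) {
    out <- matrix(0L, 96L + pad, 96L + pad)
    out[(1:96) + dr, (1:96) + dc] <- x
    out
  }
  # same background intensity outside the shifted frame
  bigImg <- function(x, dr, dc) {
    out <- matrix(x[1, 1], 96L + pad, 96L + pad)
    out[(1:96) + dr, (1:96) + dc] <- x
    out
  }
  f1 <- computeFeatures(bigImg(ph$image, 0L, 0L), big(ph$mask, 0L, 0L))
  f2 <- computeFeatures(bigImg(ph$image, pad, pad), big(ph$mask, pad, pad))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("histogram features ignore pixel arrangement inside the mask", {
  ph <- generatePhantom(phantomSpec("malignant", imageSize = 96L,
                                    seed = 12L))
  img <- ph$image
  set.seed(1)
  idx <- which(ph$mask == 1L)
  img2 <- img
  img2[idx] <- img[sample(idx)]
  expect_equal(shannonEntropy(img, ph$mask), shannonEntropy(img2, ph$mask))
  expect_equal(histEnergy(img, ph$mask), histEnergy(img2, ph$mask))
})

test_that("feature tables have the node-table layout", {
  co <- fixtureCohort()[c(1, 31)]  # one malignant, one benign
  ft <- buildFeatureTable(co)
  df <- as.data.frame(ft)
  expect_equal(dim(df), c(2L, 12L))
  expect_identical(names(df), c("id", featureNames(), "label"))
  expect_identical(nodeLabels(ft), c("malignant", "benign"))
  # permutation with class ordering disabled keeps the same row multiset
  ftA <- buildFeatureTable(co, orderByClass = FALSE)
  ftB <- buildFeatureTable(rev(co), orderByClass = FALSE)
  rowsA <- apply(nodeFeatures(ftA), 1, paste, collapse = ",")
  rowsB <- apply(nodeFeatures(ftB), 1, paste, collapse = ",")
  expect_setequal(rowsA, rowsB)
})

test_that("feature tables round-trip through CSV", {
  ft <- buildFeatureTable(fixtureCohort()[c(1, 2, 31, 32)])
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, path)
  back <- readFeatureTable(path)
  expect_equal(nodeFeatures(back), nodeFeatures(ft), tolerance = 1e-12)
  expect_identical(nodeLabels(back), nodeLabels(ft))
})
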