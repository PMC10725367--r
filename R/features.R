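#' Extract the lesion ROI by masking
#'
#' Bitwise-AND style masking: pixels keep their intensity where the mask
#' is foreground and are zeroed elsewhere. Downstream texture statistics
#' nevertheless use only mask-foreground pixels, so the zeroed background
#' never enters a histogram or co-occurrence count.
#'
#' @param image integer matrix of 8-bit intensities
#' @param mask binary matrix of the same shape (binarized at > 0)
#' @return integer matrix, image AND mask
#' @export
extractROI <- function(image, mask) {
  m <- checkImageMask(image, mask)
  out <- image
  out[m == 0L] <- 0L
  out
}

maskCoords <- function(mask) {
  which(mask == 1L, arr.ind = TRUE)
}

#' Circularity of a lesion mask
#'
#' 4 a_T / (pi d_max^2), where a_T is the foreground pixel count and
#' d_max the major-axis length of the moments-equivalent ellipse of the
#' region (4 sqrt(largest eigenvalue) of the coordinate covariance, with
#' a 1/12 pixel-extent correction). 1 for a disk, smaller for elongated
#' or irregular shapes.
#'
#' @param mask binary matrix
#' @return dimensionless circularity
#' @export
circularity <- function(mask) {
  m <- checkImageMask(mask, mask)
  xy <- maskCoords(m)
  aT <- nrow(xy)
  mu <- colMeans(xy)
  cc <- sweep(xy, 2, mu)
  S <- crossprod(cc) / aT + diag(1 / 12, 2)
  dmax <- 4 * sqrt(max(eigen(S, symmetric = TRUE,
                             only.values = TRUE)$values))
  4 * aT / (pi * dmax^2)
}

# number of pixel centers inside (or on) the convex hull of the
# foreground pixel centers
convexHullPixelArea <- function(xy) {
  h <- grDevices::chull(xy[, 2], xy[, 1])
  hx <- xy[h, 2]; hy <- xy[h, 1]
  rge <- apply(xy, 2, range)
  cand <- expand.grid(row = rge[1, 1]:rge[2, 1], col = rge[1, 2]:rge[2, 2])
  inside <- pracma::inpolygon(cand$col, cand$row, hx, hy, boundary = TRUE)
  sum(inside)
}

#' Solidity of a lesion mask
#'
#' Foreground area divided by the pixel area of its convex hull; 1 for
#' convex regions, lower for spiculated or branching shapes.
#'
#' @param mask binary matrix with at least 3 non-collinear foreground
#'   pixels
#' @return solidity in (0, 1]
#' @export
solidity <- function(mask) {
  m <- checkImageMask(mask, mask)
  xy <- maskCoords(m)
  if (nrow(unique(xy)) < 3L || qr(sweep(xy, 2, colMeans(xy)))$rank < 2L)
    stopf("degenerate-region error: foreground is collinear or too small")
  nrow(xy) / convexHullPixelArea(xy)
}

# minimum-area enclosing ellipse of 2-D points, solved as the dual
# D-optimal design problem with Frank-Wolfe updates plus away steps
# (Wolfe-Atwood), which converge linearly; returns list(center, shape
# matrix A with (x-c)' A (x-c) <= 1, area)
minAreaEllipse <- function(P, tol = 1e-6, maxIter = 100000L) {
  m <- nrow(P)
  d <- 2L
  nd <- d + 1L
  Q <- rbind(t(P), rep(1, m))
  u <- rep(1 / m, m)
  for (it in seq_len(maxIter)) {
    X <- Q %*% (u * t(Q))
    w <- colSums(Q * (solve(X) %*% Q))
    jUp <- which.max(w)
    epsUp <- w[jUp] / nd - 1
    active <- u > 0
    jDn <- which(active)[which.min(w[active])]
    epsDn <- 1 - w[jDn] / nd
    if (max(epsUp, epsDn) < tol) break
    if (epsUp >= epsDn) {
      lam <- (w[jUp] - nd) / (nd * (w[jUp] - 1))
      u <- (1 - lam) * u
      u[jUp] <- u[jUp] + lam
    } else {
      lam <- min((nd - w[jDn]) / (nd * (w[jDn] - 1)),
                 u[jDn] / (1 - u[jDn]))
      u <- (1 + lam) * u
      u[jDn] <- max(u[jDn] - lam, 0)
    }
  }
  c0 <- as.numeric(t(P) %*% u)
  A <- solve(t(P) %*% (u * P) - tcrossprod(c0)) / d
  list(center = c0, A = A, area = pi / sqrt(det(A)))
}

#' Enclosing-ellipse ratio of a lesion mask
#'
#' Area of the minimum-area ellipse enclosing the boundary pixels,
#' divided by the tumor area. Near 1 for round or elliptical lesions and
#' larger for spiculated, irregular boundaries.
#'
#' @param mask binary matrix, non-degenerate foreground
#' @param tol convergence tolerance of the iterative ellipse fit
#' @return dimensionless ratio (>= 1 up to discretization)
#' @export
ellipseRatio <- function(mask, tol = 1e-6) {
  m <- checkImageMask(mask, mask)
  xy <- maskCoords(m)
  if (nrow(unique(xy)) < 3L || qr(sweep(xy, 2, colMeans(xy)))$rank < 2L)
    stopf("degenerate-region error: foreground is collinear or too small")
  bnd <- boundaryPixels(m)
  # the enclosing ellipse depends only on the hull vertices of the boundary
  bnd <- bnd[grDevices::chull(bnd[, 2], bnd[, 1]), , drop = FALSE]
  ell <- minAreaEllipse(bnd, tol = tol)
  ell$area / nrow(xy)
}

# foreground pixels with a 4-neighbor outside the mask (or on the frame)
boundaryPixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] + pad[3:(nr + 2), 2:(nc + 1)] +
    pad[2:(nr + 1), 1:nc] + pad[2:(nr + 1), 3:(nc + 2)]
  which(core == 1L & nb < 4L, arr.ind = TRUE)
}

#' Boundary brightness of a lesion
#'
#' Distance-map band statistic of rim sharpness: the absolute difference
#' between the mean intensity of the surrounding tissue within `bandK`
#' pixels outside the lesion boundary and the mean intensity of the
#' outer part of the lesion within `bandK` pixels inside the boundary.
#'
#' @param image integer matrix of intensities
#' @param mask binary matrix, same shape
#' @param bandK band width in pixels (default 10)
#' @return absolute intensity difference
#' @export
brightness <- function(image, mask, bandK = 10L) {
  m <- checkImageMask(image, mask)
  if (bandK < 1L) stopf("parameter error: bandK must be >= 1")
  dIn <- EBImage::distmap(m)          # distance of foreground to background
  dOut <- EBImage::distmap(1L - m)    # distance of background to foreground
  inner <- m == 1L & dIn <= bandK
  outer <- m == 0L & dOut <= bandK
  if (!any(outer) || !any(inner))
    stopf("band-empty error: boundary band has no pixels within the image")
  abs(mean(image[outer]) - mean(image[inner]))
}

#' Shannon entropy of the ROI intensity histogram
#'
#' -sum p_i log2 p_i over the 8-bit intensity histogram of
#' mask-foreground pixels only; 0 for a constant region.
#'
#' @inheritParams brightness
#' @return entropy in bits
#' @export
shannonEntropy <- function(image, mask) {
  m <- checkImageMask(image, mask)
  v <- image[m == 1L]
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log2(p))
}

#' Histogram energy of the ROI
#'
#' E = sum of squared histogram proportions r(i) = q(i)/n over
#' mask-foreground pixels; 1 for a constant region, small for uniform
#' histograms.
#'
#' @inheritParams brightness
#' @return energy in (0, 1]
#' @export
histEnergy <- function(image, mask) {
  m <- checkImageMask(image, mask)
  v <- image[m == 1L]
  p <- as.numeric(table(v)) / length(v)
  sum(p^2)
}

#' Gray-level co-occurrence matrix of a masked region
#'
#' Intensities are quantized to `levels` uniform bins of [0, 255]; pairs
#' at the given pixel distance are counted along the four directions 0,
#' pi/4, pi/2 and 3pi/4, accumulated into one matrix, symmetrized and
#' normalized to sum 1. Both pixels of a counted pair must be inside the
#' mask, so the background never contributes.
#'
#' @inheritParams brightness
#' @param levels number of gray levels G (>= 2)
#' @param distance pair offset D in pixels (>= 1)
#' @param angles directions in radians (subset of the four standard ones)
#' @return levels x levels normalized symmetric matrix
#' @export
glcm <- function(image, mask, levels = 8L, distance = 1L,
                 angles = c(0, pi / 4, pi / 2, 3 * pi / 4)) {
  m <- checkImageMask(image, mask)
  if (levels < 2L) stopf("parameter error: levels must be >= 2")
  if (distance < 1L) stopf("parameter error: distance must be >= 1")
  q <- matrix(pmin(as.integer(image %/% (256 / levels)) + 1L, levels),
              nrow(image), ncol(image))
  G <- as.integer(levels)
  counts <- matrix(0, G, G)
  nr <- nrow(image); nc <- ncol(image)
  D <- as.integer(distance)
  for (ang in angles) {
    # row/col offset of the second pixel of the pair
    dr <- -as.integer(round(sin(ang))) * D
    dc <- as.integer(round(cos(ang))) * D
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(r1) == 0L || length(c1) == 0L) next
    m1 <- m[r1, c1, drop = FALSE]
    m2 <- m[r1 + dr, c1 + dc, drop = FALSE]
    ok <- m1 == 1L & m2 == 1L
    if (!any(ok)) next
    i <- q[r1, c1, drop = FALSE][ok]
    j <- q[r1 + dr, c1 + dc, drop = FALSE][ok]
    tab <- tabulate((j - 1L) * G + i, nbins = G * G)
    counts <- counts + matrix(tab, G, G)
  }
  if (sum(counts) == 0)
    stopf("no-pairs error: no valid in-mask pixel pairs at this offset")
  counts <- counts + t(counts)
  counts / sum(counts)
}

#' Texture statistics of a normalized GLCM
#'
#' entropy = -sum r_ij log2 r_ij; dissimilarity = sum r_ij |i-j|;
#' contrast = sum r_ij (i-j)^2, with 0-based gray-level indices.
#' Correlation defaults to the variance-normalized form
#' sum r_ij (i-m)(j-m) / sigma^2, which lies in [-1, 1]; set
#' `normalizedCorrelation = FALSE` for the unnormalized literal sum. A
#' degenerate matrix with zero gray-level variance reports correlation 1.
#'
#' @param P normalized (sum 1) non-negative co-occurrence matrix
#' @param normalizedCorrelation divide by the gray-level variance
#' @return named numeric: entropy, correlation, dissimilarity, contrast
#' @export
glcmFeatures <- function(P, normalizedCorrelation = TRUE) {
  if (abs(sum(P) - 1) > 1e-9)
    stopf("normalization error: GLCM must sum to 1 (got %.6g)", sum(P))
  if (any(P < 0)) stopf("normalization error: GLCM must be non-negative")
  G <- nrow(P)
  idx <- 0:(G - 1)
  I <- matrix(idx, G, G)
  J <- t(I)
  pos <- P > 0
  entropy <- -sum(P[pos] * log2(P[pos]))
  dissimilarity <- sum(P * abs(I - J))
  contrast <- sum(P * (I - J)^2)
  mg <- sum(idx * rowSums(P))
  covIJ <- sum(P * (I - mg) * (J - mg))
  if (normalizedCorrelation) {
    s2 <- sum(rowSums(P) * (idx - mg)^2)
    correlation <- if (s2 < 1e-15) 1 else covIJ / s2
  } else {
    correlation <- covIJ
  }
  c(entropy = entropy, correlation = correlation,
    dissimilarity = dissimilarity, contrast = contrast)
}

#' Default feature-extraction settings
#'
#' GLCM quantization G = 8 levels, pair distance D = 1, the four
#' standard directions, normalized GLCM correlation, and a 10-pixel
#' brightness band.
#'
#' @return named list of settings
#' @export
featureConfig <- function() {
  list(glcmLevels = 8L, glcmDistance = 1L,
       glcmAngles = c(0, pi / 4, pi / 2, 3 * pi / 4),
       normalizedCorrelation = TRUE, brightnessBand = 10L)
}

#' Compute the ten-feature vector of one image
#'
#' @param image integer matrix of 8-bit intensities
#' @param mask binary matrix, same shape, non-empty
#' @param config settings list, see \code{\link{featureConfig}}
#' @return named numeric vector in \code{\link{featureNames}} order
#' @export
computeFeatures <- function(image, mask, config = featureConfig()) {
  m <- checkImageMask(image, mask)
  P <- glcm(image, m, levels = config$glcmLevels,
            distance = config$glcmDistance, angles = config$glcmAngles)
  gf <- glcmFeatures(P, normalizedCorrelation = config$normalizedCorrelation)
  out <- c(
    circularity = circularity(m),
    solidity = solidity(m),
    shannon_entropy = shannonEntropy(image, m),
    glcm_entropy = unname(gf["entropy"]),
    glcm_correlation = unname(gf["correlation"]),
    glcm_dissimilarity = unname(gf["dissimilarity"]),
    glcm_contrast = unname(gf["contrast"]),
    hist_energy = histEnergy(image, m),
    ellipse_ratio = ellipseRatio(m),
    brightness = brightness(image, m, bandK = config$brightnessBand)
  )
  out[featureNames()]
}

#' Build the node feature table of a cohort
#'
#' One row per image with sequential ids. With `orderByClass = TRUE`
#' (default) malignant images come first, mirroring the node ordering of
#' the real node table; otherwise cohort order is kept.
#'
#' @param cohort list of image/mask/label triplets
#' @param config feature settings, see \code{\link{featureConfig}}
#' @param orderByClass put malignant nodes first
#' @return a \linkS4class{FeatureTable}
#' @export
buildFeatureTable <- function(cohort, config = featureConfig(),
                              orderByClass = TRUE) {
  if (length(cohort) == 0L) stopf("empty-cohort error: no images")
  labels <- vapply(cohort, function(x) x$label, character(1))
  ord <- if (orderByClass) order(labels != "malignant") else
    seq_along(cohort)
  rows <- lapply(seq_along(ord), function(i) {
    k <- ord[i]
    tryCatch(computeFeatures(cohort[[k]]$image, cohort[[k]]$mask, config),
             error = function(e)
               stopf("feature error at image %d: %s", k, conditionMessage(e)))
  })
  feats <- do.call(rbind, rows)
  colnames(feats) <- featureNames()
  new("FeatureTable", features = feats,
      ids = seq_along(ord), labels = labels[ord])
}

#' Write a feature table as CSV
#'
#' Header: id, the ten feature names, label (0 = benign, 1 = malignant).
#'
#' @param table a \linkS4class{FeatureTable}
#' @param path output CSV path
#' @export
writeFeatureTable <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by \code{\link{writeFeatureTable}}
#'
#' @param path CSV path
#' @return a \linkS4class{FeatureTable}
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path)
  feats <- as.matrix(df[featureNames()])
  new("FeatureTable", features = feats, ids = as.integer(df$id),
      labels = ifelse(df$label == 1, "malignant", "benign"))
}
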