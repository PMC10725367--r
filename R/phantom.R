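#' Construct a PhantomSpec
#'
#' Convenience constructor with per-class defaults from
#' \code{\link{phantomPresets}}. Any argument given explicitly overrides
#' the preset.
#'
#' @param classLabel "benign" or "malignant"
#' @param imageSize square image side in pixels (>= 64)
#' @param boundaryIrregularity radial harmonic amplitude (>= 0)
#' @param nSpicules number of sharp radial spikes (>= 0)
#' @param textureHeterogeneity intra-lesion intensity field scale (>= 0)
#' @param speckleSigma relative std of multiplicative Rayleigh speckle (>= 0)
#' @param rimContrast background-minus-lesion mean intensity (8-bit units)
#' @param seed RNG seed
#' @return a validated \linkS4class{PhantomSpec}
#' @examples
#' spec <- phantomSpec("malignant", seed = 7)
#' ph <- generatePhantom(spec)
#' dim(ph$image)
#' @export
phantomSpec <- function(classLabel = c("benign", "malignant"),
                        imageSize = 256L,
                        boundaryIrregularity = NULL,
                        nSpicules = NULL,
                        textureHeterogeneity = NULL,
                        speckleSigma = NULL,
                        rimContrast = NULL,
                        seed = 1L) {
  classLabel <- match.arg(classLabel)
  p <- phantomPresets()[[classLabel]]
  pick <- function(x, d) if (is.null(x)) d else x
  new("PhantomSpec",
      imageSize = as.integer(imageSize),
      classLabel = classLabel,
      boundaryIrregularity = as.numeric(pick(boundaryIrregularity,
                                             p$boundaryIrregularity)),
      nSpicules = as.integer(pick(nSpicules, p$nSpicules)),
      textureHeterogeneity = as.numeric(pick(textureHeterogeneity,
                                             p$textureHeterogeneity)),
      speckleSigma = as.numeric(pick(speckleSigma, p$speckleSigma)),
      rimContrast = as.numeric(pick(rimContrast, p$rimContrast)),
      seed = as.integer(seed))
}

#' Per-class phantom presets
#'
#' The default study conditions of the synthetic cohorts. Benign-like
#' lesions: near-elliptical smooth contour, homogeneous interior, sharp
#' bright rim, light speckle. Malignant-like lesions: irregular
#' spiculated contour, heterogeneous interior, weaker rim, heavier
#' speckle. The presets are data, not constants: override any entry via
#' `generateCohort(presetOverrides = ...)`.
#'
#' @return named list with `benign` and `malignant` parameter lists
#' @export
phantomPresets <- function() {
  list(
    benign = list(boundaryIrregularity = 0.03, nSpicules = 0L,
                  textureHeterogeneity = 0.08, speckleSigma = 0.06,
                  rimContrast = 60),
    malignant = list(boundaryIrregularity = 0.25, nSpicules = 7L,
                     textureHeterogeneity = 0.45, speckleSigma = 0.18,
                     rimContrast = 25)
  )
}

# largest 4-connected foreground component of a binary matrix
largest4Component <- function(mask) {
  fg <- which(mask == 1L)
  if (length(fg) == 0L) return(mask)
  nr <- nrow(mask)
  pos <- integer(length(mask)); pos[fg] <- seq_along(fg)
  edges <- NULL
  rr <- ((fg - 1L) %% nr) + 1L
  # right neighbors (same row, next column) and down neighbors
  right <- fg + nr
  ok <- right <= length(mask) & pos[pmin(right, length(mask))] > 0L
  e1 <- cbind(pos[fg[ok]], pos[right[ok]])
  down <- fg + 1L
  ok2 <- rr < nr & down <= length(mask) & pos[pmin(down, length(mask))] > 0L
  e2 <- cbind(pos[fg[ok2]], pos[down[ok2]])
  g <- igraph::graph_from_edgelist(rbind(e1, e2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- fg[comp$membership == which.max(comp$csize)]
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[keep] <- 1L
  out
}

#' Generate one phantom image/mask/label triplet
#'
#' Draws a star-convex lesion contour r(theta) = r0 (1 +
#' irregularity * sum of sine harmonics + spicule spikes) into a uniform
#' background, fills the interior with a band-limited heterogeneity
#' field, applies multiplicative Rayleigh-like speckle over the whole
#' image, and clips to 8-bit. All randomness flows through the spec's
#' seed: identical specs give bit-identical output.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return list with `image` (integer matrix, 0-255), `mask` (integer
#'   matrix, 0/1, one 4-connected component strictly inside the border)
#'   and `label`
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  s <- spec@imageSize
  withSeed(spec@seed, {
    cx <- s / 2 + runif(1, -0.04, 0.04) * s
    cy <- s / 2 + runif(1, -0.04, 0.04) * s
    a <- s * 0.26 * runif(1, 0.9, 1.1)
    b <- a * runif(1, 0.62, 0.78)
    phi <- runif(1, 0, pi)
    harm <- 2:7
    hAmp <- runif(length(harm), 0.4, 1) / harm
    hPh <- runif(length(harm), 0, 2 * pi)
    ns <- spec@nSpicules
    spTh <- if (ns > 0) sort(runif(ns, 0, 2 * pi)) else numeric(0)
    spAmp <- if (ns > 0) runif(ns, 0.25, 0.4) else numeric(0)
    spW <- if (ns > 0) runif(ns, 0.07, 0.11) else numeric(0)

    # keep the lesion strictly inside the border
    maxFac <- 1 + spec@boundaryIrregularity * sum(hAmp) +
      (if (ns > 0) max(spAmp) else 0)
    lim <- s / 2 - 6
    if (a * maxFac > lim) {
      sc <- lim / (a * maxFac)
      a <- a * sc; b <- b * sc
    }

    col <- matrix(rep(seq_len(s), each = s), s, s)
    row <- matrix(rep(seq_len(s), s), s, s)
    dx <- col - cx
    dy <- row - cy
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    th <- atan2(v, u)
    rBase <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    fac <- 1
    if (spec@boundaryIrregularity > 0) {
      pert <- 0
      for (k in seq_along(harm))
        pert <- pert + hAmp[k] * sin(harm[k] * th + hPh[k])
      fac <- fac + spec@boundaryIrregularity * pert
    }
    if (ns > 0) {
      for (j in seq_len(ns)) {
        d <- abs(th - spTh[j])
        d <- pmin(d, 2 * pi - d)
        fac <- fac + spAmp[j] * exp(-0.5 * (d / spW[j])^2)
      }
    }
    fac <- pmax(fac, 0.2)
    rr <- sqrt(u^2 + v^2)
    mask <- (rr <= rBase * fac) * 1L
    mask[1, ] <- 0L; mask[s, ] <- 0L; mask[, 1] <- 0L; mask[, s] <- 0L
    mask <- largest4Component(mask)

    muIn <- 90
    muBg <- muIn + spec@rimContrast
    img <- matrix(muBg, s, s)
    if (spec@textureHeterogeneity > 0) {
      field <- 0
      nf <- 5L
      fx <- runif(nf, 0.01, 0.06); fy <- runif(nf, 0.01, 0.06)
      fph <- runif(nf, 0, 2 * pi)
      sgx <- sample(c(-1, 1), nf, replace = TRUE)
      for (j in seq_len(nf))
        field <- field + sin(2 * pi * (sgx[j] * fx[j] * col + fy[j] * row) +
                               fph[j])
      field <- field / sqrt(nf / 2)  # approximately unit variance
      lesion <- muIn * (1 + spec@textureHeterogeneity * field)
    } else {
      lesion <- matrix(muIn, s, s)
    }
    img[mask == 1L] <- lesion[mask == 1L]

    if (spec@speckleSigma > 0) {
      ray <- sqrt(-2 * log(runif(length(img))))
      z <- (ray - sqrt(pi / 2)) / sqrt((4 - pi) / 2)
      img <- img * pmax(0, 1 + spec@speckleSigma * z)
    }
    img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), s, s)
    list(image = img, mask = mask, label = spec@classLabel)
  })
}

#' Generate a seeded cohort of phantoms
#'
#' Per-phantom seeds are derived reproducibly from the master seed;
#' malignant phantoms come first in the returned list, mirroring the
#' node ordering of the real node table.
#'
#' @param nBenign,nMalignant class counts (sum >= 2)
#' @param presetOverrides named list like
#'   `list(malignant = list(nSpicules = 4))` merged over
#'   \code{\link{phantomPresets}}
#' @param seed master seed
#' @param imageSize square image side in pixels
#' @return list of `generatePhantom` triplets
#' @export
generateCohort <- function(nBenign, nMalignant, presetOverrides = list(),
                           seed = 1L, imageSize = 256L) {
  nBenign <- as.integer(nBenign); nMalignant <- as.integer(nMalignant)
  if (nBenign + nMalignant == 0L)
    stopf("empty-cohort error: both class counts are zero")
  if (nBenign + nMalignant < 2L)
    stopf("cohort must contain at least 2 phantoms")
  presets <- phantomPresets()
  for (cl in names(presetOverrides))
    presets[[cl]][names(presetOverrides[[cl]])] <- presetOverrides[[cl]]
  labels <- c(rep("malignant", nMalignant), rep("benign", nBenign))
  seeds <- childSeeds(seed, length(labels))
  lapply(seq_along(labels), function(i) {
    p <- presets[[labels[i]]]
    generatePhantom(new(
      "PhantomSpec", imageSize = as.integer(imageSize),
      classLabel = labels[i],
      boundaryIrregularity = as.numeric(p$boundaryIrregularity),
      nSpicules = as.integer(p$nSpicules),
      textureHeterogeneity = as.numeric(p$textureHeterogeneity),
      speckleSigma = as.numeric(p$speckleSigma),
      rimContrast = as.numeric(p$rimContrast),
      seed = seeds[i]))
  })
}

#' Write a cohort to PNG files plus a manifest CSV
#'
#' Mask files use the image stem plus "_mask"; the manifest lists
#' filename and class label.
#'
#' @param cohort list of phantom triplets from \code{\link{generateCohort}}
#' @param dir output directory (created if missing)
#' @return path of the manifest CSV, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cohort), function(i) {
    ph <- cohort[[i]]
    stem <- sprintf("%s_%03d", ph$label, i)
    png::writePNG(ph$image / 255, file.path(dir, paste0(stem, ".png")))
    png::writePNG(ph$mask + 0, file.path(dir, paste0(stem, "_mask.png")))
    data.frame(filename = paste0(stem, ".png"), label = ph$label)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir directory containing the PNGs and manifest.csv
#' @return list of image/mask/label triplets (8-bit integer matrices);
#'   color PNGs are converted to gray by luminance
#' @export
readCohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- readGrayPNG(file.path(dir, manifest$filename[i]))
    stem <- sub("\\.png$", "", manifest$filename[i])
    msk <- readGrayPNG(file.path(dir, paste0(stem, "_mask.png")))
    list(image = img, mask = (msk > 0) * 1L, label = manifest$label[i])
  })
}

# read a PNG as an 8-bit integer gray matrix (luminance for color input)
readGrayPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L)
    x <- 0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}
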