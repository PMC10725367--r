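# internal helpers shared across modules

# evaluate expr under a temporary RNG state; never touches global stream
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# derive n reproducible child seeds (< 2^31) from one master seed
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# binarize a mask at > 0 and validate it against its image
checkImageMask <- function(image, mask, requireForeground = TRUE) {
  if (!all(dim(image) == dim(mask)))
    stopf("dimension error: image is %dx%d but mask is %dx%d",
          nrow(image), ncol(image), nrow(mask), ncol(mask))
  m <- (mask > 0) * 1L
  if (requireForeground && sum(m) == 0L)
    stopf("empty-ROI error: mask has no foreground pixels")
  m
}

# stratified index split by label into given proportions (sums to 1)
stratifiedSplit <- function(labels, props = c(train = 0.8, val = 0.1,
                                              test = 0.1), seed = 1L) {
  stopifnot(abs(sum(props) - 1) < 1e-9)
  out <- lapply(props, function(p) integer(0))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      sizes <- floor(props * n)
      # largest-remainder rounding
      rem <- n - sum(sizes)
      if (rem > 0) {
        ord <- order(props * n - sizes, decreasing = TRUE)
        sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
      }
      at <- 0L
      for (k in seq_along(props)) {
        out[[k]] <- c(out[[k]], idx[at + seq_len(sizes[k])])
        at <- at + sizes[k]
      }
    }
  })
  lapply(out, sort)
}

# stratified k folds; returns list of test-index vectors
stratifiedFolds <- function(labels, k, seed = 1L) {
  folds <- vector("list", k)
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      if (length(idx) < k)
        stopf("fold error: class '%s' has %d nodes, fewer than k = %d",
              cl, length(idx), k)
      grp <- rep(seq_len(k), length.out = length(idx))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[grp == f])
    }
  })
  lapply(folds, sort)
}

# atomic JSON write: temp file in the same directory, then rename
writeJsonAtomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
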