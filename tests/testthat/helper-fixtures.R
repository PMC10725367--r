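# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# filled disk mask
diskMask <- function(size, r, cx = size / 2, cy = size / 2) {
  col <- matrix(rep(seq_len(size), each = size), size, size)
  row <- matrix(rep(seq_len(size), size), size, size)
  ((row - cy)^2 + (col - cx)^2 <= r^2) * 1L
}

# filled axis-aligned ellipse mask (semi-axes a along columns, b rows)
ellipseMaskFx <- function(size, a, b, cx = size / 2, cy = size / 2) {
  col <- matrix(rep(seq_len(size), each = size), size, size)
  row <- matrix(rep(seq_len(size), size), size, size)
  (((col - cx) / a)^2 + ((row - cy) / b)^2 <= 1) * 1L
}

# independent 4-connected component count (BFS by matrix dilation)
count4Components <- function(mask) {
  left <- mask
  n <- 0L
  while (any(left == 1L)) {
    n <- n + 1L
    seedIdx <- which(left == 1L)[1]
    comp <- matrix(0L, nrow(mask), ncol(mask))
    comp[seedIdx] <- 1L
    repeat {
      grown <- comp
      grown[-1, ] <- pmax(grown[-1, ], comp[-nrow(comp), ])
      grown[-nrow(comp), ] <- pmax(grown[-nrow(comp), ], comp[-1, ])
      grown[, -1] <- pmax(grown[, -1], comp[, -ncol(comp)])
      grown[, -ncol(comp)] <- pmax(grown[, -ncol(comp)], comp[, -1])
      grown <- grown * left
      if (identical(grown, comp)) break
      comp <- grown
    }
    left <- left * (1L - comp)
  }
  n
}

# small benign/malignant cohort reused across files (built once)
fixtureCohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generateCohort(30, 30, seed = 20260929L,
                                       imageSize = 128L)
  .fixtures$cohort
}

fixtureFeatureTable <- function() {
  if (is.null(.fixtures$ft))
    .fixtures$ft <- buildFeatureTable(fixtureCohort())
  .fixtures$ft
}

# a random small labeled edge table for filter/threshold tests
randomEdgeTable <- function(n = 20L, seed = 1L) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    new("EdgeTable",
        edges = data.frame(source = pairs[, 1], target = pairs[, 2],
                           weight = stats::runif(nrow(pairs), -1, 1)),
        nNodes = n)
  })
}
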