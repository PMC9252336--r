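#' Fit a min-max normalizer on training features
#'
#' Learns per-feature minima and ranges on the training rows only (plus any
#' SMOTE rows derived from them), so no test-set information leaks into the
#' scaling. [applyNormalizer()] maps values to `[0, 1]`; constant features
#' map to 0 and out-of-range values are clipped to `[0, 1]`.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @return a [MinMaxNormalizer-class].
#' @examples
#' nz <- fitNormalizer(matrix(c(2, 4, 6), ncol = 1))
#' applyNormalizer(nz, matrix(7, ncol = 1))  # clipped to 1
#' @export
fitNormalizer <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("fitNormalizer requires a finite numeric matrix")
  mins <- apply(x, 2, min)
  ranges <- apply(x, 2, max) - mins
  new("MinMaxNormalizer", mins = mins, ranges = ranges,
      featureNames = colnames(x) %||% character())
}

#' @rdname fitNormalizer
#' @param normalizer a fitted [MinMaxNormalizer-class].
#' @export
applyNormalizer <- function(normalizer, x) {
  if (!is(normalizer, "MinMaxNormalizer") || !length(normalizer@mins))
    stop("applyNormalizer requires a fitted MinMaxNormalizer")
  x <- as.matrix(x)
  if (ncol(x) != length(normalizer@mins))
    stop("normalizer was fit on ", length(normalizer@mins),
         " features, input has ", ncol(x))
  r <- normalizer@ranges
  scaled <- sweep(x, 2, normalizer@mins)
  scaled <- sweep(scaled, 2, ifelse(r > 0, r, 1), "/")
  scaled[, r == 0] <- 0
  pmin(pmax(scaled, 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic degree-2 term ordering: originals, squares, cross products
# (i, j), i < j, lexicographic. Returns index pairs for the first m terms.
elevationTermIndex <- function(d, m, includeSquares = TRUE,
                               includeBias = FALSE) {
  i <- integer(0); j <- integer(0)
  if (includeBias) { i <- 0L; j <- 0L }                  # constant 1
  i <- c(i, seq_len(d));         j <- c(j, rep(0L, d))   # originals
  if (includeSquares) { i <- c(i, seq_len(d)); j <- c(j, seq_len(d)) }
  if (length(i) < m && d >= 2) {
    pairs <- combn(d, 2)                                 # lexicographic
    need <- min(m - length(i), ncol(pairs))
    i <- c(i, pairs[1, seq_len(need)])
    j <- c(j, pairs[2, seq_len(need)])
  }
  keep <- seq_len(min(m, length(i)))
  list(i = i[keep], j = j[keep])
}

#' Polynomial elevated dimensions
#'
#' Degree-2 feature elevation by interactive multiplication: emits the
#' original features, their squares, then all pairwise products
#' `x_i * x_j` (i < j) in lexicographic order, truncated to the first
#' `targetSide^2` terms (or zero-padded up to that length). With the default
#' 194 features and `targetSide = 117` the output has exactly
#' 13 689 entries, ready to reshape into a 117 x 117 image.
#'
#' @param x numeric vector of features, or a matrix (samples in rows).
#' @param targetSide side length of the target square image (default 117).
#' @param includeSquares include the squared terms (default TRUE).
#' @param includeBias prepend a constant-1 term (default FALSE).
#' @return a vector of length `targetSide^2`, or a matrix with that many
#'   columns for matrix input.
#' @examples
#' length(polynomialElevate(rnorm(194)))  # 13689
#' @export
polynomialElevate <- function(x, targetSide = 117, includeSquares = TRUE,
                              includeBias = FALSE) {
  vec <- is.null(dim(x))
  x <- rbind(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("polynomialElevate requires finite numeric input")
  if (targetSide < 1) stop("targetSide must be positive")
  m <- targetSide^2
  idx <- elevationTermIndex(ncol(x), m, includeSquares, includeBias)
  out <- matrix(0.0, nrow(x), m)
  lhs <- idx$i > 0
  terms <- matrix(1.0, nrow(x), length(idx$i))
  terms[, lhs] <- x[, idx$i[lhs], drop = FALSE]
  rhs <- idx$j > 0
  terms[, rhs] <- terms[, rhs, drop = FALSE] * x[, idx$j[rhs], drop = FALSE]
  out[, seq_len(ncol(terms))] <- terms
  if (vec) out[1, ] else out
}

#' Reshape an elevated feature vector into a square image
#'
#' Row-major reshape: the first `side` entries become row 1, and
#' `flattenImage(toImage(v)) == v`.
#'
#' @param v numeric vector of length `side^2`.
#' @param side image side length; inferred as `sqrt(length(v))` if omitted.
#' @return a `side x side` numeric matrix.
#' @export
toImage <- function(v, side = NULL) {
  if (is.null(side)) side <- as.integer(round(sqrt(length(v))))
  if (length(v) != side^2)
    stop("vector of length ", length(v), " cannot form a ", side, "x", side,
         " image")
  matrix(v, side, side, byrow = TRUE)
}

#' @rdname toImage
#' @param img a square image matrix.
#' @export
flattenImage <- function(img) as.vector(t(img))

# corner-aligned linear interpolation matrix (newN x oldN)
interpMatrix <- function(oldN, newN) {
  A <- matrix(0.0, newN, oldN)
  if (oldN == 1) { A[, 1] <- 1; return(A) }
  pos <- seq(1, oldN, length.out = newN)
  lo <- pmin(floor(pos), oldN - 1)
  fr <- pos - lo
  A[cbind(seq_len(newN), lo)] <- 1 - fr
  A[cbind(seq_len(newN), lo + 1)] <- A[cbind(seq_len(newN), lo + 1)] + fr
  A
}

#' Bilinear image resize
#'
#' Corner-aligned separable bilinear interpolation: sample positions span
#' the full source grid including both corners, so constant images stay
#' constant and corner pixels are preserved. Used to shrink the 117 x 117
#' elevated-feature image to the network's 112 x 112 input.
#'
#' @param img square numeric matrix.
#' @param newSide output side length (default 112).
#' @return a `newSide x newSide` matrix.
#' @export
resizeImage <- function(img, newSide = 112) {
  if (newSide < 1) stop("newSide must be >= 1")
  if (nrow(img) != ncol(img)) stop("resizeImage expects a square image")
  if (nrow(img) < 2) stop("image side must be >= 2")
  A <- interpMatrix(nrow(img), newSide)
  A %*% img %*% t(A)
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Splits sample indices into train and test partitions. The test size is
#' the nearest integer to `n * testFraction` (per class when stratified, so
#' a balanced 296 + 296 cohort at 0.3 yields 89 + 89 = 178 test samples).
#' Deterministic under `seed`.
#'
#' @param labels class label per sample (any vector); only its length is
#'   used when `stratified = FALSE`.
#' @param testFraction fraction of samples held out, in (0, 1); default 0.3.
#' @param stratified preserve class proportions (default TRUE).
#' @param seed optional RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
splitTrainTest <- function(labels, testFraction = 0.3, stratified = TRUE,
                           seed = NULL) {
  n <- length(labels)
  if (n < 2) stop("need at least two samples to split")
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  if (stratified) {
    if (length(unique(labels)) < 2)
      stop("stratified split requires at least two classes")
    test <- unlist(lapply(split(seq_len(n), labels), function(idx) {
      sample(idx, roundHalfUp(length(idx) * testFraction))
    }), use.names = FALSE)
  } else {
    test <- sample.int(n, roundHalfUp(n * testFraction))
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Random-erasing augmentation
#'
#' With probability `probability`, overwrites one axis-aligned rectangle of
#' the image whose area fraction and aspect ratio are drawn uniformly from
#' the given ranges (rejection-sampled, at most 100 attempts, to fit inside
#' the image). Defaults follow the original random-erasing recipe:
#' probability 0.5, area in (0.02, 0.33), aspect in (0.3, 3.3),
#' uniform-random fill. Applied online, per mini-batch, during training
#' only.
#'
#' @param img square image matrix (values in `[0, 1]` for uniform fill).
#' @param probability erase probability.
#' @param areaRange (low, high) fractions of the image area.
#' @param aspectRange (low, high) height/width aspect ratio bounds.
#' @param fill one of `"uniform"` (iid U(0,1) pixels), `"mean"`, `"zero"`.
#' @return the (possibly) erased image.
#' @export
randomErase <- function(img, probability = 0.5, areaRange = c(0.02, 0.33),
                        aspectRange = c(0.3, 3.3),
                        fill = c("uniform", "mean", "zero")) {
  fill <- match.arg(fill)
  stopifnot(probability >= 0, probability <= 1,
            areaRange[1] >= 0, areaRange[1] <= areaRange[2],
            areaRange[2] <= 1, all(aspectRange > 0))
  if (nrow(img) < 2) stop("image side must be >= 2")
  if (probability == 0 || runif(1) > probability) return(img)
  S <- nrow(img)
  for (attempt in seq_len(100)) {
    area <- runif(1, areaRange[1], areaRange[2]) * S * S
    aspect <- runif(1, aspectRange[1], aspectRange[2])
    h <- as.integer(round(sqrt(area * aspect)))
    w <- as.integer(round(sqrt(area / aspect)))
    if (h < 1 || w < 1 || h > S || w > S) next
    r0 <- sample.int(S - h + 1, 1)
    c0 <- sample.int(S - w + 1, 1)
    rows <- r0:(r0 + h - 1); cols <- c0:(c0 + w - 1)
    img[rows, cols] <- switch(fill,
      uniform = runif(h * w),
      mean = mean(img),
      zero = 0)
    return(img)
  }
  img  # geometry impossible within 100 attempts: leave unchanged
}

#' Partition indices into mini-batches
#'
#' @param indices integer sample indices.
#' @param batchSize batch size (default 23, the training batch size).
#' @param shuffle shuffle before batching (default TRUE).
#' @param seed optional RNG seed.
#' @return list of index vectors; all of size `batchSize` except possibly
#'   the last, together covering `indices` exactly once.
#' @export
makeBatches <- function(indices, batchSize = 23, shuffle = TRUE,
                        seed = NULL) {
  if (length(indices) == 0) stop("cannot batch an empty index set")
  if (batchSize < 1) stop("batchSize must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (shuffle) indices <- sample(indices)
  unname(split(indices, ceiling(seq_along(indices) / batchSize)))
}
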