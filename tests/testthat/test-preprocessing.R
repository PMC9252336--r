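# --- SMOTE ---

test_that("SMOTE balances the study cohort to 296 per class", {
  co <- generateCohort(cohortConfig(seed = 1))
  b <- smoteBalance(co, k = 5, seed = 2)
  expect_equal(unname(table(diagnosis(b))), c(296, 296), ignore_attr = TRUE)
  expect_equal(sum(isSynthetic(b)), 135)
  # original samples are untouched, in order
  expect_identical(featureMatrix(b)[1:457, ], featureMatrix(co))
  # synthetic rows carry the minority label
  expect_true(all(diagnosis(b)[isSynthetic(b)] == "HC"))
  expect_true(all(severity(b)[isSynthetic(b)] == "none"))
})

test_that("already balanced input is returned unchanged", {
  co <- generateCohort(smallCohortConfig(nPD = 20, nHC = 20, nEarly = 15,
                                         nModAdv = 5, seed = 2))
  expect_identical(smoteBalance(co, seed = 1), co)
})

test_that("synthetic samples lie on segments between minority neighbors", {
  # 2-point minority with k = 1: every synthetic point must be collinear
  # with and between the two originals
  set.seed(8)
  f <- matrix(rnorm(6 * 194), 6, 194)
  colnames(f) <- gaitPD:::gaitFeatureNames()
  rownames(f) <- sprintf("S%02d", 1:6)
  cd <- S4Vectors::DataFrame(
    subject_id = rownames(f),
    diagnosis = c(rep("PD", 4), "HC", "HC"),
    severity = c(rep("early", 4), "none", "none"),
    synthetic = FALSE, row.names = rownames(f))
  co <- gaitPD:::newGaitCohort(t(f), cd)
  b <- smoteBalance(co, k = 1, seed = 3)
  a <- f[5, ]; bb <- f[6, ]
  ab <- bb - a
  for (i in which(isSynthetic(b))) {
    s <- featureMatrix(b)[i, ]
    tproj <- sum((s - a) * ab) / sum(ab^2)
    expect_gte(tproj, 0); expect_lte(tproj, 1)
    # collinear: residual after projecting onto the segment is zero
    expect_lt(sqrt(sum((s - (a + tproj * ab))^2)), 1e-9)
  }
})

test_that("SMOTE geometry holds against a nearest-neighbor oracle", {
  # every synthetic sample must sit on a segment from some minority point
  # to one of its k nearest minority neighbors
  co <- generateCohort(smallCohortConfig(seed = 9))
  k <- 3
  b <- smoteBalance(co, k = k, seed = 10)
  M <- featureMatrix(co)[diagnosis(co) == "HC", ]
  D <- as.matrix(dist(M)); diag(D) <- Inf
  synth <- featureMatrix(b)[isSynthetic(b), , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    ok <- FALSE
    for (base in seq_len(nrow(M))) {
      for (nn in order(D[base, ])[seq_len(k)]) {
        a <- M[base, ]; bb <- M[nn, ]
        ab <- bb - a
        tproj <- sum((s - a) * ab) / sum(ab^2)
        if (tproj >= -1e-9 && tproj <= 1 + 1e-9 &&
            sqrt(sum((s - (a + tproj * ab))^2)) < 1e-8) { ok <- TRUE; break }
      }
      if (ok) break
    }
    expect_true(ok, label = paste("synthetic sample", i, "on a k-NN segment"))
  }
})

test_that("SMOTE rejects degenerate inputs", {
  co <- generateCohort(smallCohortConfig(seed = 2))
  expect_error(smoteBalance(co, labels = rep("PD", ncol(co))), "two classes")
  expect_error(smoteBalance(co, k = 18), "smaller k|k <")
})

# --- normalizer ---

test_that("min-max normalizer follows the fit/clip/degenerate rules", {
  nz <- fitNormalizer(cbind(a = c(2, 4, 6), b = c(5, 5, 5)))
  out <- applyNormalizer(nz, cbind(a = c(2, 4, 6), b = c(5, 5, 5)))
  expect_equal(out[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(out[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  # out-of-range test values are clipped
  expect_equal(applyNormalizer(nz, cbind(a = 7, b = 5))[1, 1], 1,
               ignore_attr = TRUE)
  expect_equal(applyNormalizer(nz, cbind(a = 0, b = 5))[1, 1], 0,
               ignore_attr = TRUE)
  expect_error(applyNormalizer(new("MinMaxNormalizer"), cbind(1)), "fitted")
})

# --- polynomial elevation ---

test_that("elevation emits originals, squares and cross terms in order", {
  # toy 3-vector against a double-loop enumeration oracle
  x <- c(1, 2, 3)
  oracle <- c(x, x^2, x[1] * x[2], x[1] * x[3], x[2] * x[3])
  got <- polynomialElevate(x, targetSide = 2)   # truncated to 4 terms
  expect_equal(got, oracle[1:4])
  got9 <- polynomialElevate(x, targetSide = 3)  # all 9 terms exactly
  expect_equal(got9, oracle)
  # zero-padding beyond the available terms
  got16 <- polynomialElevate(x, targetSide = 4)
  expect_equal(got16, c(oracle, rep(0, 7)))
})

test_that("194 features elevate to a 13689-vector and the zero vector maps to zero", {
  v <- polynomialElevate(rnorm(194), targetSide = 117)
  expect_length(v, 13689)
  expect_equal(polynomialElevate(rep(0, 194), targetSide = 117),
               rep(0, 13689))
  expect_error(polynomialElevate(c(1, NA, 3)), "finite")
})

test_that("matrix elevation equals row-wise elevation", {
  set.seed(3)
  X <- matrix(rnorm(4 * 10), 4, 10)
  M <- polynomialElevate(X, targetSide = 8)
  for (i in 1:4)
    expect_equal(M[i, ], polynomialElevate(X[i, ], targetSide = 8))
})

# --- image reshape and resize ---

test_that("toImage is a row-major reshape and flatten inverts it", {
  img <- toImage(c(1, 2, 3, 4), 2)
  expect_equal(img, matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  set.seed(5)
  v <- rnorm(117^2)
  expect_equal(flattenImage(toImage(v, 117)), v)
  expect_error(toImage(1:5, 2), "cannot form")
})

test_that("bilinear resize matches a separable 1-D interpolation oracle", {
  # two-pass oracle built from stats::approx, independent of interpMatrix
  oracleResize <- function(img, newSide) {
    old <- nrow(img)
    pos <- seq(1, old, length.out = newSide)
    tmp <- t(apply(img, 1, function(row) approx(seq_len(old), row, pos)$y))
    apply(tmp, 2, function(col) approx(seq_len(old), col, pos)$y)
  }
  ramp <- outer(1:3, 1:3, function(i, j) i + 10 * j)
  expect_equal(resizeImage(ramp, 5), oracleResize(ramp, 5), tolerance = 1e-9)
  set.seed(6)
  img <- randomImage(17)
  expect_equal(resizeImage(img, 12), oracleResize(img, 12), tolerance = 1e-9)
  expect_equal(resizeImage(img, 23), oracleResize(img, 23), tolerance = 1e-9)
})

test_that("resize preserves constants and produces the 112-square", {
  const <- matrix(3.7, 117, 117)
  out <- resizeImage(const, 112)
  expect_equal(dim(out), c(112, 112))
  expect_equal(max(abs(out - 3.7)), 0, tolerance = 1e-12)
  expect_error(resizeImage(matrix(1, 4, 4), 0), ">= 1")
})

# --- split ---

test_that("70/30 split sizes use nearest-integer rounding per class", {
  s <- splitTrainTest(rep(0:1, each = 296), 0.3, TRUE, seed = 1)
  expect_length(s$test, 178)
  expect_length(s$train, 592 - 178)
  y <- rep(0:1, each = 296)
  expect_equal(unname(table(y[s$test])), c(89, 89), ignore_attr = TRUE)
  expect_length(splitTrainTest(rep(0:1, 5), 0.3, FALSE, seed = 2)$test, 3)
})

test_that("splits are disjoint, covering and seed-deterministic", {
  y <- rep(c("a", "b"), c(31, 17))
  s1 <- splitTrainTest(y, 0.25, TRUE, seed = 7)
  s2 <- splitTrainTest(y, 0.25, TRUE, seed = 7)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), seq_along(y))
  expect_error(splitTrainTest(y, 1.2), "between 0 and 1")
  expect_error(splitTrainTest(rep("a", 10), 0.3, TRUE), "two classes")
})

# --- random erasing ---

test_that("random erasing is a no-op at probability zero and seed-stable", {
  img <- randomImage(20, seed = 1)
  expect_identical(randomErase(img, probability = 0), img)
  set.seed(42); e1 <- randomErase(img, probability = 1)
  set.seed(42); e2 <- randomErase(img, probability = 1)
  expect_identical(e1, e2)
})

test_that("erased pixels form exactly one axis-aligned rectangle", {
  img <- matrix(0.5, 30, 30)
  for (s in 1:10) {
    set.seed(s)
    out <- randomErase(img, probability = 1, fill = "zero")
    changed <- which(out != img, arr.ind = TRUE)
    n <- nrow(changed)
    if (n == 0) succeed() else {
      h <- diff(range(changed[, 1])) + 1
      w <- diff(range(changed[, 2])) + 1
      expect_equal(n, h * w)  # a filled rectangle, nothing outside it
    }
  }
})

# --- batching ---

test_that("batching covers every index once with a 23-sized layout", {
  b <- makeBatches(1:592, 23, shuffle = TRUE, seed = 1)
  expect_length(b, 26)
  expect_equal(lengths(b), c(rep(23, 25), 17))
  expect_setequal(unlist(b), 1:592)
  expect_equal(makeBatches(1:23, 23, shuffle = FALSE), list(1:23))
  expect_error(makeBatches(integer(0)), "empty")
  # multiset equality for arbitrary n
  set.seed(2)
  idx <- sample(1000, 77)
  expect_setequal(unlist(makeBatches(idx, 10, seed = 3)), idx)
})

test_that("pipeline shape chain runs 194 -> 13689 -> 117x117 -> 112x112", {
  set.seed(12)
  x <- runif(194)
  v <- polynomialElevate(x, targetSide = 117)
  expect_length(v, 13689)
  img <- toImage(v, 117)
  expect_equal(dim(img), c(117, 117))
  small <- resizeImage(img, 112)
  expect_equal(dim(small), c(112, 112))
})
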