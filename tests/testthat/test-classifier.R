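# PCA features and the one-vs-one Gaussian-kernel SVM.

test_that("PCA features are centered, ordered and nested", {
  set.seed(1)
  H <- matrix(rnorm(40 * 16), 40, 16)
  fs <- buildFeatures(H, nComponents = 3)
  expect_lt(max(abs(colMeans(fs@scores))), 1e-10)
  expect_true(all(diff(fs@explainedVariance) <= 1e-12))
  # reconstruction error shrinks as components are added
  recon <- function(k) {
    pc <- prcomp(H, center = TRUE)
    approxH <- pc$x[, 1:k] %*% t(pc$rotation[, 1:k])
    sum((sweep(H, 2, pc$center) - approxH)^2)
  }
  expect_lte(recon(3), recon(2))
  expect_error(buildFeatures(H, nComponents = 17), "exceeds")
})

test_that("the SVM separates separated clouds and not permuted labels", {
  set.seed(2)
  X <- rbind(matrix(rnorm(60, mean = 0), 30, 2),
             matrix(rnorm(60, mean = 6), 30, 2))
  labs <- rep(c("a", "b"), each = 30)
  fs <- new("FeatureSet", scores = X, labels = factor(labs),
            basis = matrix(0, 2, 2), center = c(0, 0),
            explainedVariance = c(0.5, 0.5))
  m <- trainClassifier(fs)
  expect_equal(attr(m, "resubstitution"), 1)
  expect_error(trainClassifier(new("FeatureSet", scores = X,
                                   labels = factor(rep("a", 60)),
                                   basis = matrix(0, 2, 2), center = c(0, 0),
                                   explainedVariance = c(0.5, 0.5))),
               "two classes")
  # permuted labels on structureless 5-class data: near-chance accuracy
  set.seed(3)
  acc <- vapply(1:20, function(i) {
    Xn <- matrix(rnorm(50 * 3), 50, 3)
    ln <- factor(sample(rep(letters[1:5], 10)))
    fsn <- new("FeatureSet", scores = Xn, labels = ln,
               basis = matrix(0, 3, 3), center = rep(0, 3),
               explainedVariance = rep(0.2, 3))
    attr(trainClassifier(fsn), "resubstitution")
  }, numeric(1))
  expect_lte(mean(acc), 0.35)
})

test_that("training and prediction are deterministic", {
  ens <- smallEnsemble()
  fs <- buildFeatures(ens$hrfs, ens$labels)
  m1 <- trainClassifier(fs)
  m2 <- trainClassifier(fs)
  p1 <- predictScores(m1, fs@scores)
  p2 <- predictScores(m2, fs@scores)
  expect_identical(p1$label, p2$label)
})

test_that("mechanism prediction follows the class geometry", {
  ens <- smallEnsemble()
  fs <- buildFeatures(ens$hrfs, ens$labels)
  model <- trainClassifier(fs)
  # a training PBR HRF is predicted PBR
  i <- which(ens$labels == "PBR")[1]
  expect_equal(predictMechanism(model, ens$hrfs[i, ])$label, "PBR")
  # a clean NDA-preset HRF is predicted NDA
  tr <- poissonTrain(2.6, 600, seed = 99)
  y <- boldAtTR(simulateMechanism(makePreset("NDA"), tr, tEnd = 600), 2)
  hN <- normalizeHrf(estimateHrf(y, tr))
  expect_equal(predictMechanism(model, hN)$label, "NDA")
  # a sign-flipped canonical positive response is never called PBR
  flipped <- -canonicalBasis(2)$h[1:16]
  expect_false(predictMechanism(model, flipped)$label == "PBR")
  expect_error(predictMechanism(model, rep(0, 16)), "all-zero")
  expect_error(predictMechanism(model, rep(1, 5)), "length")
})

test_that("stratified cross-validation is well formed and deterministic", {
  ens <- smallEnsemble()
  cv1 <- crossValidate(ens$hrfs, ens$labels, k = 4, seed = 1)
  cv1b <- crossValidate(ens$hrfs, ens$labels, k = 4, seed = 1)
  expect_identical(cv1$predicted, cv1b$predicted)
  # folds are stratified: every class appears in every fold
  for (f in 1:4)
    expect_setequal(unique(as.character(ens$labels[cv1$folds == f])),
                    levels(ens$labels))
  expect_equal(rowSums(cv1$confusion), table(ens$labels),
               ignore_attr = TRUE)
  expect_equal(cv1$misclassification + cv1$accuracy, 1)
  expect_error(crossValidate(ens$hrfs, ens$labels, k = 20), "at least k")
  # paper-mode (global PCA) runs and reports the same structure
  cvp <- crossValidate(ens$hrfs, ens$labels, k = 4, seed = 1,
                       paperMode = TRUE)
  expect_s3_class(cvp$perClass, "data.frame")
  expect_equal(sum(cvp$confusion), nrow(ens$hrfs))
})

test_that("the ensemble generator is reproducible and labeled", {
  e1 <- generateTrainingEnsemble(M = 3, mechanisms = c("PBR", "NDA"),
                                 seed = 5)
  e2 <- generateTrainingEnsemble(M = 3, mechanisms = c("PBR", "NDA"),
                                 seed = 5)
  expect_identical(e1$hrfs, e2$hrfs)
  expect_equal(dim(e1$hrfs), c(6, 16))
  expect_equal(as.character(e1$labels), rep(c("PBR", "NDA"), each = 3))
  expect_equal(max(abs(e1$hrfs)), 1)  # normalized
})
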