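test_that("a k-element protein contributes 3 rows per element incl. the NTR", {
  p <- TALEProtein(c("NI", "HD", "NN", "NG", "NI"))  # 4.5 nominal repeats
  fr <- featureRowsForProtein(p)
  expect_equal(nrow(fr$meta), 3L * 6L)  # NTR + 5 elements
  expect_equal(sum(fr$meta$element_index == 0L), 3L)
  ## NTR rows carry no position/length/N-neighbour features
  ntr <- fr$X[fr$meta$element_index == 0L, , drop = FALSE]
  expect_true(all(ntr[, grepl("^(pos|lpos|len|llen|nN)\\|", colnames(ntr))] == 0))
  ## last element's C neighbour is the CTR
  last <- fr$X[fr$meta$element_index == 5L, , drop = FALSE]
  expect_true(all(rowSums(last[, grepl("^nC\\|NI\\|.\\|CTR$",
                                       colnames(last))]) == 1))
})

test_that("panel weights are 1 / (number of proteins of the same length)", {
  p1 <- TALEProtein(rep("NI", 5L), id = "a")
  p2 <- TALEProtein(rep("HD", 5L), id = "b")
  p3 <- TALEProtein(rep("NG", 7L), id = "c")
  tr <- truthContextModel(noise_sd = 0)
  ems <- lapply(list(p1, p2, p3), truthEM, truth = tr)
  fm <- buildFeatureMatrix(list(p1, p2, p3), ems)
  w <- tapply(fm$weights, fm$meta$protein_id, unique)
  expect_equal(as.numeric(w[c("a", "b", "c")]), c(0.5, 0.5, 1))
})

test_that("standardized columns have mean 0 and unit variance", {
  set.seed(3)
  X <- cbind(rnorm(50L), runif(50L), rep(2, 50L))
  colnames(X) <- c("f1", "f2", "const")
  expect_message(std <- sifted:::standardizeColumns(X), "constant")
  expect_false("const" %in% colnames(std$X))
  expect_true(all(abs(colMeans(std$X)) < 1e-9))
  expect_true(all(abs(apply(std$X, 2L, sd) - 1) < 1e-9))
})

test_that("the elastic-net path starts at all-zero coefficients", {
  set.seed(7)
  X <- scale(matrix(rnorm(200L * 10L), 200L))
  y <- X[, 1L] * 2 + rnorm(200L, 0, 0.5)
  ep <- elasticNetPath(X, y)
  b_at_max <- as.matrix(coef(ep$fit, s = ep$lambda[1L]))[-1L, ]
  expect_true(all(abs(b_at_max) < 1e-12))
  b_at_min <- as.matrix(coef(ep$fit, s = min(ep$lambda)))[-1L, ]
  expect_gt(abs(b_at_min[1L]), 1)
  expect_error(elasticNetPath(X, rep(1, 200L)), "zero variance")
})

test_that("ridge at vanishing penalty matches closed-form OLS on orthonormal X", {
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(400L * 6L), 400L))) * sqrt(400L)  # orthonormal cols
  beta <- c(1.5, -2, 0.5, 0, 1, -0.7)
  y <- as.numeric(Q %*% beta) + rnorm(400L, 0, 0.1)
  fit <- glmnet::glmnet(Q, y, alpha = 0, lambda = c(1e-6, 1e-7),
                        standardize = FALSE, intercept = TRUE)
  ols <- coef(lm(y ~ Q))
  expect_equal(unname(as.matrix(coef(fit, s = 1e-7))[-1L, ]),
               unname(ols[-1L]), tolerance = 1e-4)
})

test_that("a planted sparse model is recovered at the one-SE penalty", {
  set.seed(9)
  n <- 500L; pfeat <- 60L
  X <- scale(matrix(rnorm(n * pfeat), n))
  truth_idx <- 1:5
  beta <- numeric(pfeat); beta[truth_idx] <- c(2, -1.5, 1, -1, 0.8)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, 0.2)
  cvfit <- glmnet::cv.glmnet(X, y, alpha = 0.95, standardize = FALSE)
  b <- as.matrix(coef(cvfit, s = "lambda.1se"))[-1L, ]
  expect_setequal(which(b != 0), truth_idx)
  expect_true(all(sign(b[truth_idx]) == sign(beta[truth_idx])))
})

test_that("nestedCV returns one shared penalty and protein-grouped predictions", {
  panel <- simulatePanel(8L, c(5.5, 9.5), pair_coverage = TRUE, seed = 15L)
  truth <- truthContextModel()
  ems <- lapply(seq_along(panel), function(i)
    truthEM(panel[[i]], truth, seed = 500L + i))
  cv <- suppressMessages(nestedCV(panel, ems, seed = 5L))
  expect_length(cv$report$lambda_1se, 1L)
  expect_true(cv$report$lambda_1se %in% cv$report$lambda)
  expect_gte(cv$report$lambda_1se, cv$report$lambda_min)
  expect_length(cv$report$lambda, 100L)
  expect_true(all(diff(cv$report$lambda) < 0))
  ho <- cv$report$heldout
  expect_false(any(is.na(ho$predicted)))
  expect_gt(cor(ho$observed, ho$predicted), 0.8)
  expect_error(nestedCV(panel[1:4], ems[1:4]), "more proteins")
})

test_that("held-out predictions are invariant to panel order", {
  panel <- simulatePanel(7L, c(5.5, 8.5), pair_coverage = TRUE, seed = 19L)
  truth <- truthContextModel()
  ems <- lapply(seq_along(panel), function(i)
    truthEM(panel[[i]], truth, seed = 700L + i))
  cv1 <- suppressMessages(nestedCV(panel, ems, seed = 3L))
  perm <- c(4L, 1L, 7L, 2L, 6L, 3L, 5L)
  cv2 <- suppressMessages(nestedCV(panel[perm], ems[perm], seed = 3L))
  p <- predictEM(panel[[1L]], cv1$model)$em
  q <- predictEM(panel[[1L]], cv2$model)$em
  expect_equal(as.matrix(p), as.matrix(q), tolerance = 0.15)
  expect_equal(cv1$report$lambda_1se, cv2$report$lambda_1se,
               tolerance = 0.5)
})

test_that("the RVD-only reduced model is a per-type lookup table", {
  panel <- simulatePanel(8L, c(5.5, 9.5), pair_coverage = TRUE, seed = 23L)
  truth <- truthContextModel(position_scale = 0, length_scale = 0,
                             neighbour_scale = 0, noise_sd = 0)
  ems <- lapply(panel, truthEM, truth = truth)
  cv <- suppressMessages(nestedCV(panel, ems, seed = 7L, rvd_only = TRUE))
  ## every NI column of every predicted matrix is identical
  em1 <- predictEM(panel[[1L]], cv$model)$em
  em2 <- predictEM(panel[[2L]], cv$model)$em
  rv1 <- rvds(panel[[1L]]); rv2 <- rvds(panel[[2L]])
  i1 <- which(rv1 == "NI")[1L]; i2 <- which(rv2 == "NI")[1L]
  expect_equal(as.matrix(em1)[, i1 + 1L], as.matrix(em2)[, i2 + 1L],
               tolerance = 1e-9, ignore_attr = TRUE)
  ## and matches a hand-built lookup from the training responses
  fm <- buildFeatureMatrix(panel, ems, rvd_only = TRUE)
  look <- tapply(fm$y, paste(fm$meta$type, fm$meta$base), mean)
  expect_equal(as.matrix(em1)["C", i1 + 1L], unname(look[["NI C"]]),
               tolerance = 0.05)
})

test_that("predicted matrices respond to length only through length features", {
  cm0 <- rawContextModel(c("ind|NI|C" = 3, "ind|NI|G" = 3.5,
                           "ind|NI|T" = 3))
  pA <- TALEProtein(rep("NI", 6L)); pB <- TALEProtein(rep("NI", 12L))
  eA <- predictEM(pA, cm0)$em; eB <- predictEM(pB, cm0)$em
  expect_equal(unname(as.matrix(eA)[, 3L]), unname(as.matrix(eB)[, 3L]))
  cmL <- rawContextModel(c("ind|NI|C" = 3, "llen|NI|C" = -0.5))
  eA2 <- predictEM(pA, cmL)$em; eB2 <- predictEM(pB, cmL)$em
  expect_lt(as.matrix(eB2)["C", 3L], as.matrix(eA2)["C", 3L])
})

test_that("neighbour log2 ratios have the planted sign and antisymmetry", {
  cm0 <- rawContextModel(numeric(0))
  expect_equal(neighborEffectLog2Ratio(cm0, "NI", "C", "NN", "N"), 0)
  ## planted positive NN|G-context coefficient: NN next to NI is more
  ## specific, so non-anchored frequencies drop
  cm <- rawContextModel(c("ind|NN|A" = 1, "ind|NN|C" = 3, "ind|NN|T" = 3,
                          "nC|NN|A|NI" = 0.7, "nC|NN|C|NI" = 0.7,
                          "nC|NN|T|NI" = 0.7))
  r <- neighborEffectLog2Ratio(cm, "NN", "A", "NI", "C")
  expect_lt(r, 0)
  rG <- neighborEffectLog2Ratio(cm, "NN", "G", "NI", "C")
  expect_gt(rG, 0)  # anchor base gains frequency
  expect_error(neighborEffectLog2Ratio(cm, "NN", "A", "CTR", "N"),
               "invalid")
  expect_error(neighborEffectLog2Ratio(cm, "NTR", "A", "NI", "N"),
               "no N-terminal")
})

test_that("context models serialize to TSV and back without changing predictions", {
  panel <- simulatePanel(7L, c(5.5, 8.5), pair_coverage = TRUE, seed = 27L)
  truth <- truthContextModel()
  ems <- lapply(seq_along(panel), function(i)
    truthEM(panel[[i]], truth, seed = 900L + i))
  cv <- suppressMessages(nestedCV(panel, ems, seed = 11L))
  f <- tempfile(fileext = ".tsv")
  writeContextModel(cv$model, f)
  m2 <- readContextModel(f)
  p <- TALEProtein(c("NI", "HD", "NN", "NG", "NN", "HD"))
  expect_equal(as.matrix(predictEM(p, cv$model)$em),
               as.matrix(predictEM(p, m2)$em), tolerance = 1e-8)
})
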