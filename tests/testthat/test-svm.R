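post <- MONTAGE$posterior

test_that("separable toy problem trains to perfect accuracy", {
  set.seed(1)
  X <- matrix(rnorm(24 * 13, sd = 0.01), 24, 13)
  colnames(X) <- post
  is_cc <- rep(c(TRUE, FALSE), each = 12)
  X[is_cc, 3] <- X[is_cc, 3] - 2      # CC low on one electrode
  X[!is_cc, 3] <- X[!is_cc, 3] + 2
  m <- train_linear_svm(X, is_cc, seed = 1)
  sc <- svmp1_score(m, X)
  expect_true(all(sc[is_cc] < sc[!is_cc][which.min(sc[!is_cc])] + 1e-9))
  pred <- classify_scores(sc, threshold_rule("SVMP1", mean(range(sc))))
  expect_identical(pred, ifelse(is_cc, "CC", "non-CC"))
  # the separating electrode dominates the weights
  expect_identical(unname(which.max(abs(m$w))), 3L)
  # orientation: lower score = CC
  expect_lt(mean(sc[is_cc]), mean(sc[!is_cc]))
})

test_that("duplicating the dataset leaves the solution unchanged", {
  set.seed(2)
  X <- matrix(rnorm(30 * 13), 30, 13); colnames(X) <- post
  is_cc <- rep(c(TRUE, FALSE), c(10, 20))
  X[is_cc, ] <- X[is_cc, ] - 0.8
  m1 <- verpmark:::svm_dcd(X, ifelse(is_cc, 1, -1), cost = 1)
  m2 <- verpmark:::svm_dcd(rbind(X, X), rep(ifelse(is_cc, 1, -1), 2),
                           cost = 0.5)
  # duplicated data at half cost: identical effective problem
  expect_equal(m1$w, m2$w, tolerance = 1e-5)
  expect_equal(m1$b, m2$b, tolerance = 1e-5)
})

test_that("weights match the independent QP oracle", {
  # 2-D toy and a realistic 13-D instance, several costs
  for (p in c(2L, 13L)) {
    set.seed(p)
    n <- 20
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(1, -1), length.out = n)
    X[y == 1, 1] <- X[y == 1, 1] + 1.5
    for (cost in c(0.25, 1, 4)) {
      fit <- verpmark:::svm_dcd(X, y, cost)
      orc <- svm_qp_oracle(X, y, cost)
      expect_lt(max(abs(fit$w - orc$w)), 1e-4)
      expect_lt(abs(fit$b - orc$b), 1e-4)
    }
  }
})

test_that("svmp1_score is the stated affine function of z", {
  m <- structure(list(w = setNames(rep(1 / 13, 13), post), b = 0,
                      cost = 1, orientation = "lower", training_n = 52),
                 class = "linear_biomarker_model")
  set.seed(3)
  z <- rnorm(13); names(z) <- post
  expect_equal(svmp1_score(m, z), mean(z))        # reduces to MPP1
  expect_equal(svmp1_score(m, setNames(rep(0, 13), post)), 0)
  m$b <- 2.5
  expect_equal(svmp1_score(m, setNames(rep(0, 13), post)), 2.5)
  set.seed(4)
  w <- rnorm(13); names(w) <- post
  m$w <- w; m$b <- -0.3
  expect_equal(svmp1_score(m, z), sum(w * z) - 0.3, tolerance = 1e-12)

  # uniform weights rank identically to MPP1 (Spearman rho = 1)
  Z <- matrix(rnorm(20 * 13), 20, 13); colnames(Z) <- post
  mu <- structure(list(w = setNames(rep(1 / 13, 13), post), b = 0),
                  class = "linear_biomarker_model")
  expect_equal(cor(svmp1_score(mu, Z), rowMeans(Z), method = "spearman"), 1)
})

test_that("classify_scores places the boundary on the CC side", {
  rule <- threshold_rule("MPP1", 0.408, "le")
  expect_identical(classify_scores(-0.5, rule), "CC")
  expect_identical(classify_scores(1.2, rule), "non-CC")
  expect_identical(classify_scores(0.408, rule), "CC")   # boundary -> CC
})

test_that("training rejects degenerate inputs", {
  X <- matrix(rnorm(10 * 13), 10, 13); colnames(X) <- post
  expect_error(train_linear_svm(X, rep(TRUE, 10)), "classes")
  expect_error(train_linear_svm(X, rep(c(TRUE, FALSE), 5),
                                cost_grid = numeric(0)), "grid")
})

test_that("model JSON round-trip scores bit-identically", {
  set.seed(6)
  X <- matrix(rnorm(30 * 13), 30, 13); colnames(X) <- post
  is_cc <- rep(c(TRUE, FALSE), c(10, 20))
  X[is_cc, ] <- X[is_cc, ] - 1
  m <- train_linear_svm(X, is_cc, seed = 2)
  dev <- verpmark:::frozen_artifacts(
    m, list(mpp1 = threshold_rule("MPP1", 0.408, source = "t"),
            svmp1 = threshold_rule("SVMP1", -0.830, source = "t")),
    MONTAGE)
  path <- tempfile(fileext = ".json")
  write_model_json(dev, path)
  back <- read_model_json(path)
  expect_identical(back$model$w, m$w)
  expect_identical(back$model$b, m$b)
  expect_identical(svmp1_score(back$model, X), svmp1_score(m, X))
  expect_identical(back$rules$mpp1$threshold, 0.408)
})
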