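test_that("regression metrics agree with a direct-formula oracle", {
  # perfect prediction
  x <- c(5.1, 6.2, 7.3, 8.1)
  m <- regression_metrics(x, x)
  expect_equal(m$R, 1); expect_equal(m$R2, 1); expect_equal(m$RMSE, 0)

  # constant offset: RMSE 1, R 1, R2 = 1 - n/Tss
  m2 <- regression_metrics(x, x + 1)
  expect_equal(m2$RMSE, 1)
  expect_equal(m2$R, 1)
  tss <- sum((x - mean(x))^2)
  expect_equal(m2$R2, 1 - length(x) / tss)

  # random vectors against an independent direct-summation implementation
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    m3 <- regression_metrics(a, b)
    n <- 6
    r_direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(m3$R, r_direct, tolerance = 1e-10)
    expect_equal(m3$R, cor(a, b), tolerance = 1e-10)
    expect_equal(m3$R2, 1 - sum((a - b)^2) / sum((a - mean(a))^2),
                 tolerance = 1e-10)
    expect_equal(m3$RMSE, sqrt(sum((a - b)^2) / n), tolerance = 1e-10)
  }

  # zero-variance vector: R undefined and flagged
  m4 <- regression_metrics(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.nan(m4$R))
  expect_true(m4$degenerate)
})

test_that("external validation refuses overlapping partitions", {
  fm <- small_features()
  y <- seq(5, 8, length.out = nrow(fm))
  m <- fit_model(fm[1:40, ], y[1:40], "GB", list(trees = 20), seed = 1)
  expect_error(external_validate(m, fm, y, 1:40, 35:50), "overlap")
  ev <- external_validate(m, fm, y, 1:40, 41:60)
  expect_true(is.finite(ev$RMSE))
})

test_that("cross-validation folds partition the data; bootstrap holds out 10%", {
  folds <- liabprof:::make_folds(100, 5, seed = 2)
  expect_equal(sort(unique(folds)), 1:5)
  expect_true(all(table(folds) == 20))

  fm <- small_features()[1:50, ]
  y <- seq(5, 8, length.out = 50)
  r <- internal_validate(fm, y, "MLR", protocol = "bootstrap",
                         iterations = 3, seed = 4)
  expect_equal(nrow(r$values), 3)
  expect_true(all(is.finite(r$values[, "RMSE"])))
  expect_error(internal_validate(fm, y, "MLR", protocol = "cv",
                                 iterations = 0), "iterations")
})

test_that("internal validation is invariant to compound order given the seed", {
  fm <- small_features()[1:40, ]
  y <- seq(5, 8, length.out = 40)
  r1 <- internal_validate(fm, y, "MLR", protocol = "cv", iterations = 2,
                          seed = 9)
  perm <- sample(40)   # test RNG state independent of the protocol's
  r2 <- internal_validate(fm[perm, ], y[perm], "MLR", protocol = "cv",
                          iterations = 2, seed = 9)
  expect_equal(r1$mean, r2$mean, tolerance = 1e-9)
})

test_that("enrichment factors match brute-force ranking counts", {
  # perfect ranking, M = 100, A = 2, chi = 5% -> EF = (2/5)/(2/100) = 20
  y <- seq(0, 9.9, length.out = 100)
  ef <- enrichment_factor(y, y, chi = 0.05)
  expect_equal(ef$A, 2); expect_equal(ef$M_chi, 5); expect_equal(ef$A_chi, 2)
  expect_equal(ef$EF, 20)

  # both actives in the top 1%: M_chi = 1 at 1%, EF = (1/1)/(2/100) = 50
  ef1 <- enrichment_factor(y, y, chi = 0.01)
  expect_equal(ef1$M_chi, 1); expect_equal(ef1$A_chi, 1)
  expect_equal(ef1$EF, 50)

  # reversed perfect ranking scores zero enrichment
  ef0 <- enrichment_factor(y, -y, chi = 0.05)
  expect_equal(ef0$EF, 0)

  # EF bound and random-ranking expectation
  set.seed(5)
  efs <- replicate(200, {
    sc <- rnorm(100)
    e <- enrichment_factor(y, sc, chi = 0.10)
    expect_lte(e$EF, min(1 / 0.10, 100 / e$A))
    e$EF
  })
  expect_lt(abs(mean(efs) - 1), 0.35)

  # AUC: perfect ranking 1, reversed 0, cross-checked against pROC
  expect_equal(attr(enrichment_factor(y, y, 0.05), "auc"), 1)
  expect_equal(attr(enrichment_factor(y, -y, 0.05), "auc"), 0)
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- rnorm(100)
  e <- enrichment_factor(y, sc, 0.05)
  lab <- as.integer(rank(-y) <= 2)
  proc_auc <- as.numeric(suppressMessages(pROC::auc(lab, sc,
                                                    direction = "<")))
  expect_equal(attr(e, "auc"), proc_auc, tolerance = 1e-10)

  expect_error(enrichment_factor(y[1:10], y[1:10]), "too small")
})
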