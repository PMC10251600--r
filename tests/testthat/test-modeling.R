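test_that("Latin hypercube designs stratify every parameter marginally", {
  for (algo in c("GB", "RF")) {
    space <- default_space(algo)
    for (n in c(1, 4, 9)) {
      cfgs <- sample_lhs(space, n, seed = 3)
      expect_length(cfgs, n)
      u <- attr(cfgs, "design")
      # brute-force stratum membership: each of n equal strata holds exactly
      # one sample, per parameter
      for (j in seq_len(ncol(u))) {
        strata <- floor(u[, j] * n)
        expect_setequal(strata, 0:(n - 1))
      }
      # decoded configurations respect bounds and integrality
      for (cfg in cfgs) {
        for (k in seq_len(nrow(space))) {
          v <- cfg[[space$name[k]]]
          expect_gte(v, space$lower[k])
          expect_lte(v, space$upper[k])
          if (space$integer[k]) expect_equal(v, round(v))
        }
      }
    }
    expect_identical(sample_lhs(space, 5, seed = 11),
                     sample_lhs(space, 5, seed = 11))
  }
})

test_that("MLR recovers an exactly linear low-dimensional signal", {
  set.seed(7)
  x <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
  beta <- c(2, -1, 0.5, 3, 0)
  y <- as.numeric(x %*% beta) + 1.5
  m <- fit_model(x, y, "MLR", seed = 1)
  expect_false(m$ridge_stabilized)
  p <- predict(m, x)
  mm <- regression_metrics(y, p)
  expect_equal(mm$R, 1, tolerance = 1e-10)
  expect_lt(mm$RMSE, 1e-8)
})

test_that("singular designs fall back to ridge stabilization, flagged", {
  set.seed(8)
  x <- matrix(rnorm(10 * 30), 10, 30)   # p > n
  y <- rnorm(10)
  m <- fit_model(x, y, "MLR", seed = 1)
  expect_true(m$ridge_stabilized)
  expect_true(all(is.finite(predict(m, x))))
})

test_that("ensemble fits are reproducible under a fixed seed", {
  fm <- small_features()
  y <- seq(5, 8, length.out = nrow(fm))
  for (algo in c("RF", "GB")) {
    m1 <- fit_model(fm, y, algo, seed = 21)
    m2 <- fit_model(fm, y, algo, seed = 21)
    expect_identical(predict(m1, fm), predict(m2, fm))
  }
})

test_that("tuning returns an in-bounds configuration no worse than any LHS seed", {
  fm <- small_features()
  set.seed(31)
  # depth-dependent synthetic signal over a few fingerprint bits
  bits <- fm[, 12:2059]
  active <- which(colMeans(bits) > 0.2 & colMeans(bits) < 0.8)[1:6]
  y <- 6 + 1.5 * bits[, active[1]] * bits[, active[2]] -
    bits[, active[3]] + 0.5 * bits[, active[4]] + rnorm(nrow(fm), sd = 0.1)
  tn <- tune(fm, y, "GB", n_init = 4, max_generations = 4,
             time_budget = 120, seed = 5)
  space <- default_space("GB")
  for (k in seq_len(nrow(space))) {
    v <- tn$best_config[[space$name[k]]]
    expect_gte(v, space$lower[k]); expect_lte(v, space$upper[k])
  }
  lhs_scores <- tn$trace$cv_rmse[tn$trace$generation == 0]
  expect_lte(tn$best_score, min(lhs_scores))         # GA never loses to LHS
  expect_lte(tn$best_score, max(lhs_scores))         # ... or to its worst seed
  expect_equal(tn$best_score, min(tn$trace$cv_rmse)) # trace is exhaustive
  expect_true(tn$stopped_on %in% c("stagnation", "max_generations",
                                   "time_budget"))
})

test_that("champion selection maximizes Pearson R with ties to gradient boosting", {
  gb <- list(model = structure(list(algorithm = "GB"), class = "tuned_model"),
             R = 0.84)
  rf <- list(model = structure(list(algorithm = "RF"), class = "tuned_model"),
             R = 0.81)
  expect_equal(select_champion(list(rf, gb))$model$algorithm, "GB")
  expect_equal(select_champion(list(gb))$R, 0.84)
  rf_tied <- list(model = structure(list(algorithm = "RF"),
                                    class = "tuned_model"), R = 0.84)
  expect_equal(select_champion(list(rf_tied, gb))$model$algorithm, "GB")
  expect_error(select_champion(list()), "no candidate")
})
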