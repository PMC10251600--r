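#' @title Regression models and hyperparameter tuning
#' @description Three regressors for pACTIVITY: a multi-linear baseline
#'   (ordinary least squares, ridge-stabilized when the design is singular),
#'   random forest (ranger) and gradient boosting (xgboost, histogram tree
#'   method). Hyperparameters of the ensembles are tuned by a hybrid scheme:
#'   a Latin-hypercube design seeds an evolutionary (genetic-algorithm)
#'   search whose objective is the 5-fold cross-validated RMSE on the
#'   training partition only, with stagnation and wall-clock early stopping.
#' @name modeling
NULL

#' Default hyperparameter spaces
#'
#' Bounds (and scales) for the tunable parameters: for gradient boosting the
#' number of trees, tree depth, histogram bin count, minimum leaf size,
#' learning rate (log scale) and L1/L2 regularization; for random forest the
#' number of trees, depth, leaf size and per-split feature fraction.
#'
#' @param algo `"GB"` or `"RF"`.
#' @return data.frame with columns `name`, `lower`, `upper`, `log`,
#'   `integer`.
#' @export
default_space <- function(algo = c("GB", "RF")) {
  algo <- match.arg(algo)
  if (algo == "GB") {
    data.frame(
      name = c("trees", "depth", "learning_rate", "leaf_size", "l1", "l2",
               "bins"),
      lower = c(50, 2, 0.01, 1, 0, 0, 20),
      upper = c(1000, 12, 0.3, 30, 10, 10, 100),
      log = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
      integer = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      name = c("trees", "depth", "leaf_size", "feature_fraction"),
      lower = c(100, 4, 1, 0.2),
      upper = c(1000, 20, 10, 1.0),
      log = c(FALSE, FALSE, FALSE, FALSE),
      integer = c(TRUE, TRUE, TRUE, FALSE),
      stringsAsFactors = FALSE)
  }
}

# Map a unit-cube row to a named configuration respecting scale and type.
decode_config <- function(u, space) {
  lo <- space$lower; hi <- space$upper
  v <- ifelse(space$log,
              exp(log(lo) + u * (log(hi) - log(lo))),
              lo + u * (hi - lo))
  v <- ifelse(space$integer, round(v), v)
  v <- pmin(pmax(v, lo), hi)
  stats::setNames(as.list(v), space$name)
}

#' Latin hypercube sample of hyperparameter configurations
#'
#' Each of the `n` samples occupies a distinct stratum of each parameter's
#' range (one sample per equal-probability stratum per dimension), giving a
#' space-filling, seeded-deterministic design.
#'
#' @param space hyperparameter space (see [default_space()]).
#' @param n number of configurations.
#' @param seed integer seed.
#' @return list of named configurations; the raw unit-cube design is
#'   attached as attribute `design`.
#' @export
sample_lhs <- function(space, n, seed = 1) {
  stopifnot(n >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(space))
  cfgs <- lapply(seq_len(n), function(i) decode_config(u[i, ], space))
  attr(cfgs, "design") <- u
  cfgs
}

#' Fit a single regression model
#'
#' @param x numeric feature matrix (train rows).
#' @param y pACTIVITY vector.
#' @param algo `"MLR"`, `"RF"` or `"GB"`.
#' @param config named list of hyperparameters (ensembles only; defaults
#'   used for missing entries).
#' @param seed integer seed controlling all stochastic elements.
#' @param similarity optional train similarity-bit matrix stored for later
#'   applicability-domain assessment.
#' @return object of class `tuned_model`.
#' @export
fit_model <- function(x, y, algo = c("MLR", "RF", "GB"), config = list(),
                      seed = 1, similarity = NULL) {
  algo <- match.arg(algo)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2, all(is.finite(y)))
  ridge_flag <- FALSE
  fit <- switch(algo,
    MLR = {
      xs <- cbind(`(Intercept)` = 1, x)
      qr_ <- qr(xs)
      if (qr_$rank < ncol(xs)) {
        # singular design (p >= n is the norm at 2059 features):
        # closed-form ridge with a small penalty, intercept unpenalized
        ridge_flag <- TRUE
        mu <- colMeans(x); yc <- y - mean(y)
        xc <- sweep(x, 2, mu)
        lambda <- 1e-2 * nrow(x)
        beta <- solve(crossprod(xc) + diag(lambda, ncol(x)),
                      crossprod(xc, yc))
        list(coef = as.numeric(beta), mu = mu, intercept = mean(y))
      } else {
        cf <- qr.coef(qr_, y)
        list(coef = cf[-1], mu = rep(0, ncol(x)), intercept = cf[1])
      }
    },
    RF = {
      cfg <- utils::modifyList(list(trees = 500, depth = 0, leaf_size = 5,
                                    feature_fraction = 1 / 3), config)
      ranger::ranger(x = as.data.frame(x), y = y,
                     num.trees = cfg$trees,
                     max.depth = if (cfg$depth >= 20) 0 else cfg$depth,
                     min.node.size = cfg$leaf_size,
                     mtry = max(1, floor(cfg$feature_fraction * ncol(x))),
                     seed = seed, num.threads = 1)
    },
    GB = {
      cfg <- utils::modifyList(list(trees = 300, depth = 6,
                                    learning_rate = 0.1, leaf_size = 1,
                                    l1 = 0, l2 = 1, bins = 64), config)
      dtr <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror",
                      eta = cfg$learning_rate,
                      max_depth = cfg$depth,
                      min_child_weight = cfg$leaf_size,
                      alpha = cfg$l1, lambda = cfg$l2,
                      tree_method = "hist", max_bin = cfg$bins,
                      nthread = 1, seed = seed),
        data = dtr, nrounds = cfg$trees, verbose = 0)
    })
  structure(list(algorithm = algo, config = config, fit = fit,
                 ridge_stabilized = ridge_flag, seed = seed,
                 feature_names = colnames(x),
                 train_similarity = similarity),
            class = "tuned_model")
}

#' Predict pACTIVITY with a fitted model
#' @param object a `tuned_model`.
#' @param newdata feature matrix with the training column layout.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.tuned_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  switch(object$algorithm,
    MLR = {
      f <- object$fit
      as.numeric(sweep(x, 2, f$mu) %*% f$coef) + f$intercept
    },
    RF = ranger::predictions(stats::predict(object$fit, as.data.frame(x),
                                            num.threads = 1)),
    GB = stats::predict(object$fit, xgboost::xgb.DMatrix(x)))
}

#' @export
print.tuned_model <- function(x, ...) {
  cat("Tuned", x$algorithm, "model",
      if (x$ridge_stabilized) "(ridge-stabilized)" else "", "\n")
  if (length(x$config) > 0)
    cat("  config:", paste(names(x$config),
                           signif(unlist(x$config), 3),
                           sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Fixed 5-fold assignment used for every candidate of one tuning run,
# so candidate scores are directly comparable.
make_folds <- function(n, k = 5, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# k-fold CV RMSE of one configuration. When a deadline (POSIXct) is given,
# evaluation stops after the current fold once it passes; the RMSE over the
# completed folds is returned (at least one fold always completes).
cv_rmse <- function(x, y, algo, config, folds, seed = 1, deadline = NULL) {
  k <- max(folds)
  err <- numeric(0)
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- fit_model(x[tr, , drop = FALSE], y[tr], algo, config, seed = seed)
    p <- predict(m, x[!tr, , drop = FALSE])
    err <- c(err, (y[!tr] - p)^2)
    if (!is.null(deadline) && Sys.time() > deadline && f < k) break
  }
  sqrt(mean(err))
}

#' Tune ensemble hyperparameters (Latin hypercube + genetic algorithm)
#'
#' Stage 1 evaluates a Latin-hypercube design; stage 2 evolves the
#' population by tournament selection, uniform crossover and per-gene
#' mutation, with elitism. The objective is 5-fold CV-RMSE on the training
#' partition. Stops when the best score has not improved for
#' `stagnation` consecutive generations, when `max_generations` is reached,
#' or when the wall-clock budget expires.
#'
#' @param x,y training feature matrix and response.
#' @param algo `"GB"` or `"RF"`.
#' @param space hyperparameter space (default [default_space()]).
#' @param n_init Latin-hypercube size (also the GA population size).
#' @param max_generations GA generation cap.
#' @param stagnation consecutive non-improving generations tolerated.
#' @param time_budget wall-clock budget in seconds (default 300; the
#'   long-run preset used for full-scale tuning is 6000).
#' @param k CV fold count.
#' @param seed integer seed.
#' @return list with `best_config`, `best_score` (CV-RMSE) and `trace`
#'   (data.frame of every evaluated configuration and score).
#' @export
tune <- function(x, y, algo = c("GB", "RF"), space = default_space(algo),
                 n_init = 10, max_generations = 30, stagnation = 5,
                 time_budget = 300, k = 5, seed = 1) {
  algo <- match.arg(algo)
  t0 <- Sys.time()
  elapsed <- function() as.numeric(difftime(Sys.time(), t0, units = "secs"))
  folds <- make_folds(length(y), k, seed)
  npar <- nrow(space)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)
  pop <- lhs::randomLHS(n_init, npar)

  trace <- list()
  deadline <- t0 + time_budget
  evaluate <- function(u, gen) {
    cfg <- decode_config(u, space)
    sc <- cv_rmse(x, y, algo, cfg, folds, seed, deadline = deadline)
    trace[[length(trace) + 1]] <<- c(generation = gen,
                                     unlist(cfg), cv_rmse = sc)
    sc
  }
  scores <- numeric(n_init)
  for (i in seq_len(n_init)) {
    scores[i] <- evaluate(pop[i, ], 0L)
    if (elapsed() > time_budget && i < n_init) {
      if (all(!is.finite(scores[seq_len(i)])))
        stop("tuning budget exhausted before any evaluation completed")
      pop <- pop[seq_len(i), , drop = FALSE]
      scores <- scores[seq_len(i)]
      break
    }
  }

  best_u <- pop[which.min(scores), ]
  best_score <- min(scores)
  stag <- 0L
  gen <- 0L
  pmut <- 0.1; pcross <- 0.8; tourn <- 3L
  while (gen < max_generations && stag < stagnation &&
         elapsed() < time_budget && nrow(pop) >= 2) {
    gen <- gen + 1L
    npop <- nrow(pop)
    sel <- function() {   # tournament selection
      cand <- sample.int(npop, min(tourn, npop))
      cand[which.min(scores[cand])]
    }
    children <- matrix(0, npop, npar)
    children[1, ] <- pop[which.min(scores), ]   # elitism
    for (i in 2:npop) {
      p1 <- pop[sel(), ]; p2 <- pop[sel(), ]
      child <- ifelse(stats::runif(npar) < 0.5, p1, p2)
      if (stats::runif(1) > pcross) child <- p1
      mut <- stats::runif(npar) < pmut
      child[mut] <- stats::runif(sum(mut))
      children[i, ] <- child
    }
    newscores <- scores
    newscores[1] <- scores[which.min(scores)]
    for (i in 2:npop) {
      newscores[i] <- evaluate(children[i, ], gen)
      if (elapsed() > time_budget) {
        children <- children[seq_len(i), , drop = FALSE]
        newscores <- newscores[seq_len(i)]
        break
      }
    }
    pop <- children; scores <- newscores
    if (min(scores) < best_score - 1e-12) {
      best_score <- min(scores)
      best_u <- pop[which.min(scores), ]
      stag <- 0L
    } else stag <- stag + 1L
  }

  trace <- as.data.frame(do.call(rbind, trace))
  list(best_config = decode_config(best_u, space),
       best_score = best_score, trace = trace,
       generations = gen, stopped_on = if (stag >= stagnation) "stagnation"
       else if (gen >= max_generations) "max_generations" else "time_budget")
}

#' Select the champion model
#'
#' The candidate with the highest external-validation Pearson R; exact ties
#' are broken in favour of gradient boosting.
#'
#' @param candidates list of elements each having `model` (a `tuned_model`)
#'   and `R` (external Pearson correlation).
#' @return the winning element of `candidates`.
#' @export
select_champion <- function(candidates) {
  if (length(candidates) == 0) stop("no candidate models")
  rs <- vapply(candidates, function(c) c$R, numeric(1))
  if (all(!is.finite(rs))) stop("no candidate with finite R")
  best <- max(rs, na.rm = TRUE)
  idx <- which(rs == best)
  if (length(idx) > 1) {
    gb <- idx[vapply(candidates[idx],
                     function(c) c$model$algorithm == "GB", logical(1))]
    if (length(gb) > 0) idx <- gb
  }
  candidates[[idx[1]]]
}
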