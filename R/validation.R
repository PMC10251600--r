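#' @title Model validation and screening-power metrics
#' @description Pearson R, determination coefficient and RMSE; internal
#'   validation by iterated 5-fold cross-validation, 90/10 bootstrap and
#'   y-randomization; external validation on the held-out test partition;
#'   and virtual-screening power via enrichment factors and ranking AUC.
#' @name validation
NULL

#' Regression metrics for paired actual/predicted values
#'
#' R is the Pearson correlation cov(X,Y)/(s_X s_Y), R2 the determination
#' coefficient 1 - Rss/Tss, and RMSE the root mean squared error
#' sqrt(mean((X - Y)^2)), with X the actual and Y the predicted values.
#'
#' @param actual numeric vector of observed pACTIVITY values.
#' @param predicted numeric vector of predictions, same length.
#' @return named list with `R`, `R2`, `RMSE` and logical `degenerate`
#'   (TRUE when a zero-variance vector makes R undefined; R is then NaN).
#' @export
regression_metrics <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2)
  n <- length(actual)
  mx <- mean(actual); my <- mean(predicted)
  covxy <- sum((actual - mx) * (predicted - my)) / (n - 1)
  sx <- sqrt(sum((actual - mx)^2) / (n - 1))
  sy <- sqrt(sum((predicted - my)^2) / (n - 1))
  degenerate <- sx == 0 || sy == 0
  r <- if (degenerate) NaN else covxy / (sx * sy)
  rss <- sum((actual - predicted)^2)
  tss <- sum((actual - mx)^2)
  r2 <- if (tss == 0) NaN else 1 - rss / tss
  rmse <- sqrt(mean((actual - predicted)^2))
  list(R = r, R2 = r2, RMSE = rmse, degenerate = degenerate)
}

#' External validation on the held-out test partition
#'
#' Asserts that the test indices never overlap the training indices, then
#' scores the model's test-set predictions.
#'
#' @param model a `tuned_model`.
#' @param x full feature matrix.
#' @param y full response vector.
#' @param train,test index vectors from [split_dataset()].
#' @return list of metrics (see [regression_metrics()]).
#' @export
external_validate <- function(model, x, y, train, test) {
  if (length(intersect(train, test)) > 0)
    stop("train/test overlap detected: external validation is invalid")
  p <- predict(model, x[test, , drop = FALSE])
  regression_metrics(y[test], p)
}

#' Internal validation protocols
#'
#' Three complementary protocols, each refitting the model from scratch:
#' `"cv"` (k-fold cross-validation; every compound is held out exactly once
#' per iteration), `"bootstrap"` (a 90% resample trains, the held-out 10%
#' scores) and `"y_scrambling"` (the response is permuted before refitting;
#' metrics near zero indicate absence of chance correlation). Metrics are
#' averaged over `iterations` repeats.
#'
#' @param x,y training-partition features and response.
#' @param algo `"MLR"`, `"RF"` or `"GB"`.
#' @param config hyperparameter list for the ensembles.
#' @param protocol `"cv"`, `"bootstrap"` or `"y_scrambling"`.
#' @param iterations repeat count (desk-scale default 20; the full-scale
#'   preset is 100).
#' @param k fold count for `"cv"` and for scoring `"y_scrambling"`.
#' @param seed integer seed.
#' @return list with per-metric `mean` and `sd` plus the per-iteration
#'   values.
#' @export
internal_validate <- function(x, y, algo, config = list(),
                              protocol = c("cv", "bootstrap", "y_scrambling"),
                              iterations = 20, k = 5, seed = 1) {
  protocol <- match.arg(protocol)
  if (iterations < 1) stop("iterations must be >= 1")
  # canonical compound order (response, then feature sum) makes resampling
  # assignments - and hence the report - invariant to input row order
  ord <- order(y, rowSums(as.matrix(x)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  vals <- matrix(NA_real_, iterations, 3,
                 dimnames = list(NULL, c("R", "R2", "RMSE")))
  n <- length(y)
  for (it in seq_len(iterations)) {
    itseed <- seed + it
    set.seed(itseed)
    if (protocol == "bootstrap") {
      ntr <- round(0.9 * n)
      tr <- sample.int(n, ntr)
      te <- setdiff(seq_len(n), tr)
      m <- fit_model(x[tr, , drop = FALSE], y[tr], algo, config,
                     seed = itseed)
      mm <- regression_metrics(y[te], predict(m, x[te, , drop = FALSE]))
    } else {
      yy <- if (protocol == "y_scrambling") sample(y) else y
      folds <- make_folds(n, k, itseed)
      pred <- numeric(n)
      for (f in seq_len(k)) {
        tr <- folds != f
        m <- fit_model(x[tr, , drop = FALSE], yy[tr], algo, config,
                       seed = itseed)
        pred[!tr] <- predict(m, x[!tr, , drop = FALSE])
      }
      mm <- regression_metrics(yy, pred)
    }
    vals[it, ] <- c(mm$R, mm$R2, mm$RMSE)
  }
  list(protocol = protocol, iterations = iterations,
       mean = colMeans(vals), sd = apply(vals, 2, stats::sd),
       values = vals)
}

#' Full validation report for one dataset
#'
#' Runs external validation plus the three internal protocols for one
#' algorithm/configuration, mirroring the per-target layout of a
#' protocol-by-metric summary table.
#'
#' @inheritParams internal_validate
#' @param train,test split indices.
#' @param model optional pre-fitted `tuned_model` for the external row
#'   (refitted from `config` if missing).
#' @param protocols which protocols to run (default all four).
#' @return nested list keyed by protocol.
#' @export
validation_report <- function(x, y, algo, config = list(), train, test,
                              iterations = 20, seed = 1, model = NULL,
                              protocols = c("external", "cv", "bootstrap",
                                            "y_scrambling")) {
  if (is.null(model))
    model <- fit_model(x[train, , drop = FALSE], y[train], algo, config,
                       seed = seed)
  xt <- x[train, , drop = FALSE]; yt <- y[train]
  rep <- list()
  if ("external" %in% protocols) {
    ext <- external_validate(model, x, y, train, test)
    rep$external <- list(mean = c(R = ext$R, R2 = ext$R2, RMSE = ext$RMSE),
                         sd = c(R = NA, R2 = NA, RMSE = NA))
  }
  for (p in intersect(c("cv", "bootstrap", "y_scrambling"), protocols))
    rep[[p]] <- internal_validate(xt, yt, algo, config, p, iterations,
                                  seed = seed)
  structure(rep, class = "validation_report", algorithm = algo)
}

#' Enrichment factor and ranking AUC
#'
#' Actives are defined as the top `active_fraction` (default 2%) of the
#' dataset by actual pACTIVITY; the selection set is the top `chi` fraction
#' of the score ranking. EF = (A_chi/M_chi)/(A/M). Selection sizes use the
#' ceiling so the 1% selection is never empty. Ties in the activity ranking
#' are broken deterministically (descending activity, then ascending
#' compound identifier); the AUC is the Mann-Whitney rank statistic with
#' midrank tie correction.
#'
#' @param y_true actual pACTIVITY values.
#' @param y_score predicted values (the ranking variable).
#' @param chi top fraction(s) of the ranking to evaluate (default 1%, 5%,
#'   10%).
#' @param active_fraction fraction labelled active (default 0.02).
#' @param ids optional compound identifiers for deterministic tie-breaking.
#' @return data.frame with one row per `chi`: `chi`, `A_chi`, `M_chi`, `A`,
#'   `M`, `EF`; the ranking AUC is attached as attribute `auc`.
#' @export
enrichment_factor <- function(y_true, y_score, chi = c(0.01, 0.05, 0.10),
                              active_fraction = 0.02, ids = NULL) {
  M <- length(y_true)
  stopifnot(length(y_score) == M)
  if (M < 1 / active_fraction)
    stop("dataset too small: no compound would be labelled active")
  if (is.null(ids)) ids <- as.character(seq_len(M))
  A <- ceiling(active_fraction * M)
  ord_true <- order(-y_true, ids)
  active <- logical(M)
  active[ord_true[seq_len(A)]] <- TRUE
  if (A == 0) stop("no actives after labelling")

  ord_score <- order(-y_score, ids)
  res <- do.call(rbind, lapply(chi, function(ch) {
    Mchi <- ceiling(ch * M)
    sel <- ord_score[seq_len(Mchi)]
    Achi <- sum(active[sel])
    data.frame(chi = ch, A_chi = Achi, M_chi = Mchi, A = A, M = M,
               EF = (Achi / Mchi) / (A / M))
  }))
  # Mann-Whitney AUC with midranks
  r <- rank(y_score, ties.method = "average")
  n1 <- sum(active); n0 <- M - n1
  auc <- if (n0 == 0) 1 else (sum(r[active]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  attr(res, "auc") <- auc
  res
}
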