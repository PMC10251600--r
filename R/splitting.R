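#' @title Train/test partitioning
#' @description Stratified sampling on the dependent variable (pACTIVITY) is
#'   the default 80/20 partition; random, diversity (max-min Tanimoto) and
#'   Murcko-scaffold splits are available as alternatives.
#' @name splitting
NULL

# Equal-width 1-log-unit bins over the observed pACTIVITY range; bins with
# fewer than 2 members are merged into their nearest neighbouring bin.
stratification_bins <- function(y, width = 1.0) {
  rng <- range(y)
  breaks <- seq(floor(rng[1] / width) * width, rng[2] + width, by = width)
  b <- as.integer(cut(y, breaks, include.lowest = TRUE, right = FALSE))
  repeat {
    tab <- table(b)
    small <- as.integer(names(tab)[tab < 2])
    if (length(small) == 0 || length(tab) == 1) break
    s <- small[1]
    others <- setdiff(as.integer(names(tab)), s)
    nearest <- others[which.min(abs(others - s))]
    b[b == s] <- nearest
  }
  b
}

#' Partition a dataset into train and test indices
#'
#' @param dataset a `curated_dataset`, or a data.frame with `pACTIVITY` (and
#'   `standardized_smiles` for the scaffold/diversity strategies).
#' @param strategy one of `"stratified"` (default), `"random"`,
#'   `"diversity"`, `"scaffold"`.
#' @param train_fraction proportion of compounds assigned to training
#'   (default 0.8).
#' @param seed integer seed; identical seeds give identical partitions.
#' @param similarity optional precomputed n x 2048 similarity-bit matrix
#'   (used by the diversity strategy; computed on the fly if missing).
#' @return list with integer vectors `train` and `test` forming a disjoint,
#'   exhaustive partition of `seq_len(n)`.
#' @export
split_dataset <- function(dataset, strategy = c("stratified", "random",
                                                "diversity", "scaffold"),
                          train_fraction = 0.8, seed = 1,
                          similarity = NULL) {
  strategy <- match.arg(strategy)
  cmp <- if (inherits(dataset, "curated_dataset")) dataset$compounds else dataset
  n <- nrow(cmp)
  if (n < 5) stop("dataset too small to split (need >= 5 compounds)")
  n_train <- round(n * train_fraction)
  if (n_train < 1 || n_train >= n)
    stop("train_fraction leaves an empty partition")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  train <- switch(strategy,
    random = sort(sample.int(n, n_train)),
    stratified = {
      b <- stratification_bins(cmp$pACTIVITY)
      tr <- integer(0)
      for (lev in sort(unique(b))) {
        idx <- which(b == lev)
        k <- round(length(idx) * train_fraction)
        k <- max(1L, min(k, length(idx) - 1L))
        if (length(idx) == 1) k <- 1L
        tr <- c(tr, sample(idx, k))
      }
      sort(tr)
    },
    scaffold = {
      scaf <- vapply(cmp$standardized_smiles, function(s) {
        ms <- murcko_scaffold(s)
        if (is.na(ms) || !nzchar(ms)) paste0("acyclic:", s) else ms
      }, character(1), USE.NAMES = FALSE)
      groups <- split(seq_len(n), scaf)
      groups <- groups[sample.int(length(groups))]   # seeded group order
      sizes <- lengths(groups)
      groups <- groups[order(-sizes)]                # big groups to train first
      tr <- integer(0)
      for (gidx in groups) {
        if (length(tr) + length(gidx) <= n_train || length(tr) == 0)
          tr <- c(tr, gidx)
        if (length(tr) >= n_train) break
      }
      sort(tr)
    },
    diversity = {
      if (is.null(similarity)) {
        fp <- compute_fingerprints(cmp$standardized_smiles)
        similarity <- fp$similarity
      }
      n_test <- n - n_train
      # max-min picking: seed with the compound farthest from the centroid,
      # then repeatedly add the compound most dissimilar to the picked set
      picked <- integer(0)
      first <- sample.int(n, 1)
      picked <- first
      maxsim <- rep(-Inf, n)
      repeat {
        last <- picked[length(picked)]
        s <- as.numeric(similarity %*% similarity[last, ]) /
          (rowSums(similarity) + sum(similarity[last, ]) -
             as.numeric(similarity %*% similarity[last, ]))
        s[is.na(s)] <- 1
        maxsim <- pmax(maxsim, s)
        maxsim[picked] <- Inf
        if (length(picked) >= n_test) break
        picked <- c(picked, which.min(maxsim))
      }
      sort(setdiff(seq_len(n), picked))
    })

  test <- setdiff(seq_len(n), train)
  stopifnot(length(train) + length(test) == n,
            length(intersect(train, test)) == 0)
  list(train = train, test = test)
}

# save/restore the RNG state so split_dataset does not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
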