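test_that("the packaged liability mapping has 7 groups with the printed memberships", {
  mp <- load_liability_mapping()
  expect_named(mp, c("CV", "CNS", "GI", "ED", "PU", "RE", "IM"))
  expect_equal(lengths(mp),
               c(CV = 24L, CNS = 19L, GI = 13L, ED = 7L, PU = 5L, RE = 2L,
                 IM = 6L))
  # several targets belong to more than one group
  expect_gt(sum(lengths(mp)), length(unique(unlist(mp))))
  expect_true("KCNH2" %in% mp$CV)
  expect_true(all(c("AVPR1A", "PTGS1") == sort(mp$RE)))
  expect_error(load_liability_mapping(known_targets = "KCNH2"), "unknown")
})

test_that("concern classification applies the 6.5 cutoff inclusively", {
  expect_equal(classify_concern(7.2), "C")
  expect_equal(classify_concern(5.0), "nC")
  expect_equal(classify_concern(6.5), "C")   # boundary convention
  expect_equal(classify_concern(c(6.49, 6.51)), c("nC", "C"))
  expect_equal(classify_concern(7, cutoff = 8), "nC")
})

test_that("liability scores equal the concern fraction per group", {
  mp <- load_liability_mapping()
  all_targets <- unique(unlist(mp))

  allC <- setNames(rep("C", length(all_targets)), all_targets)
  s1 <- liability_scores(allC, mp)
  expect_true(all(s1$Ls == 1))

  noC <- setNames(rep("nC", length(all_targets)), all_targets)
  s0 <- liability_scores(noC, mp)
  expect_true(all(s0$Ls == 0))

  # arbitrary mixes against a counting oracle
  set.seed(14)
  for (i in 1:10) {
    flags <- setNames(sample(c("C", "nC"), length(all_targets), TRUE),
                      all_targets)
    s <- liability_scores(flags, mp)
    for (g in names(mp)) {
      oracle <- sum(flags[mp[[g]]] == "C") / length(mp[[g]])
      expect_equal(s$Ls[s$group == g], oracle)
      expect_equal(s$C[s$group == g] + s$nC[s$group == g],
                   length(mp[[g]]))
    }
    # monotone: flipping one nC to C never lowers any score
    nc <- names(flags)[flags == "nC"]
    if (length(nc) > 0) {
      flags2 <- flags; flags2[nc[1]] <- "C"
      s2 <- liability_scores(flags2, mp)
      expect_true(all(s2$Ls >= s$Ls))
    }
  }
  expect_error(liability_scores(allC[-1], mp), "missing concern flag")
  # direct ratio example: 2 concerns among 5 targets
  mini <- list(CV = paste0("t", 1:5), CNS = "t1", GI = "t1", ED = "t1",
               PU = "t1", RE = "t1", IM = "t1")
  f <- setNames(c("C", "C", "nC", "nC", "nC"), paste0("t", 1:5))
  expect_equal(liability_scores(f, mini)$Ls[1], 0.4)
})

test_that("applicability domain uses max Tanimoto with a strict threshold", {
  fm <- small_features()
  sim <- attr(fm, "similarity")
  m <- constant_model(7, sim[1:10, , drop = FALSE])

  a <- assess_ad(sim[1, ], m)
  expect_equal(a$max_tc, 1)
  expect_true(a$fulfilled)

  # 3-compound toy store against an exhaustive pairwise oracle
  store <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 0, 1, 1))
  q <- c(1, 1, 1, 0)
  toy <- constant_model(7, store)
  oracle <- max(apply(store, 1, function(r) {
    inter <- sum(q & r); uni <- sum(q | r); inter / uni
  }))
  a2 <- assess_ad(q, toy)
  expect_equal(a2$max_tc, oracle)

  # strict inequality at the threshold
  a3 <- assess_ad(q, toy, threshold = oracle)
  expect_false(a3$fulfilled)

  expect_error(assess_ad(q, constant_model(7, store[0, , drop = FALSE])),
               "fingerprint store")
})

test_that("profiling composes predictions, flags, scores and AD", {
  lib <- small_library()
  fm <- small_features()
  sim <- attr(fm, "similarity")
  mp <- load_liability_mapping()
  targets <- unique(unlist(mp))
  # constant-prediction registry: half concern, half not
  preds <- setNames(rep(c(9, 2), length.out = length(targets)), targets)
  registry <- lapply(preds, function(v)
    constant_model(v, sim[1:20, , drop = FALSE]))

  prof <- profile_compounds(c(lib[1], "((bad", lib[21]), registry)
  expect_length(prof, 3)
  expect_false(is.null(prof[[2]]$error))

  p <- prof[[1]]
  expect_length(p$predictions, length(targets))
  expect_equal(nrow(p$scores), 7)
  # score oracle from the constant predictions
  flags <- classify_concern(preds)
  names(flags) <- targets
  expect_equal(p$scores$Ls,
               liability_scores(flags, load_liability_mapping())$Ls)
  # AD: query 1 and 21 are in / out of the 20-compound stores
  expect_equal(p$ad_score, 1)
  expect_equal(prof[[3]]$ad_score,
               mean(vapply(registry, function(m)
                 max_tanimoto_to_set(sim[21, ], m$train_similarity) > 0.7,
                 logical(1))))

  # profile invariant to registry ordering
  prof_r <- profile_compounds(lib[1], rev(registry))
  expect_equal(sort(prof_r[[1]]$scores$Ls), sort(p$scores$Ls))
  expect_equal(prof_r[[1]]$ad_score, p$ad_score)

  # all-below-cutoff registry: every group scores 0
  low <- lapply(targets, function(t) constant_model(2, sim[1:5, ,
                                                           drop = FALSE]))
  names(low) <- targets
  s <- profile_compounds(lib[2], low)[[1]]$scores
  expect_true(all(s$Ls == 0))

  expect_error(profile_compounds(lib[1], list()), "empty")

  summ <- profile_summary(prof)
  expect_equal(nrow(summ), 3)
  expect_true(all(c("CV", "CNS", "GI", "ED", "PU", "RE", "IM", "AD")
                  %in% names(summ)))
})

test_that("the two-sigma variable cutoff reflects the training distribution", {
  y <- c(5, 6, 7, 6, 6.5)
  expect_equal(two_sigma_cutoff(y), mean(y) + 2 * sd(y))
})
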