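test_that("Murcko scaffolds and basic frameworks behave as defined", {
  benz <- as.character(murcko_scaffold("c1ccccc1"))
  expect_equal(as.character(murcko_scaffold("Cc1ccccc1")), benz)
  expect_equal(murcko_scaffold("CCCCO"), "")          # acyclic: no scaffold
  expect_true(is.na(murcko_scaffold("((((")))

  # heteroatom abstraction: pyridine's framework is benzene
  expect_equal(as.character(basic_framework("c1ccncc1")), benz)
  expect_equal(as.character(basic_framework("Cc1ccccc1")), benz)
  # saturated heterocycle: morpholine -> cyclohexane
  expect_equal(as.character(basic_framework("O1CCNCC1")),
               as.character(basic_framework("C1CCCCC1")))

  # idempotence and atom-ordering invariance (canonicalization property)
  for (smi in c("c1ccncc1", "C1CCNCC1c1ccccc1", "O=C1CCCN1C")) {
    fw <- as.character(basic_framework(smi))
    expect_equal(as.character(basic_framework(fw)), fw)
  }
  expect_equal(as.character(basic_framework("c1ccc(cc1)N1CCOCC1")),
               as.character(basic_framework("C1COCCN1c1ccccc1")))
})

test_that("scaffold table averages, autoscales and conserves membership", {
  # two compounds sharing the benzene framework with descriptor values 2 / 4,
  # plus a second framework and an acyclic compound
  ds <- structure(list(
    target_id = "toy",
    compounds = data.frame(
      standardized_smiles = c("Cc1ccccc1", "CCc1ccccc1", "C1CCNCC1",
                              "CCCC"),
      pACTIVITY = c(6, 7, 8, 5),
      n_source_records = 1L)), class = "curated_dataset")
  feat <- matrix(c(2, 4, 10, 99), ncol = 1,
                 dimnames = list(NULL, "desc"))
  st <- scaffold_table(list(ds), list(feat))

  expect_equal(nrow(st$table), 2)          # benzene + piperidine frameworks
  expect_equal(st$n_acyclic, 1)
  expect_equal(sum(st$info$member_count) + st$n_acyclic, 4)
  # hand computation: averaged value 3 pre-scaling for the shared framework
  expect_equal(unname(st$raw_means[1, "desc"]), 3)
  expect_equal(st$info$member_count[1], 2L)
  expect_equal(st$info$mean_pACTIVITY[1], 6.5)
  # autoscaling: mean 0, SD 1 per feature column
  expect_lt(abs(mean(st$table[, 1])), 1e-9)
  expect_equal(sd(st$table[, 1]), 1, tolerance = 1e-9)
})

test_that("PCA returns ordered variance fractions and centered scores", {
  # 2-column toy with known covariance: closed-form larger eigenvalue
  set.seed(20)
  n <- 400
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- cbind(a = z1, b = 0.8 * z1 + 0.6 * z2)
  S <- stats::cov(x)
  tr <- S[1, 1] + S[2, 2]; det_ <- S[1, 1] * S[2, 2] - S[1, 2]^2
  lam1 <- (tr + sqrt(tr^2 - 4 * det_)) / 2
  p <- pca_project(x, 2)
  expect_equal(stats::var(p$scores[, 1]), lam1, tolerance = 1e-9)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-12)
  # projecting the mean row gives the origin
  centered_mean <- colMeans(x) - colMeans(x)
  expect_equal(as.numeric(centered_mean %*% p$loadings), c(0, 0))
  expect_error(pca_project(x, 5), "components")
})

test_that("dataset distance matrices match exhaustive oracles", {
  mk <- function(id, smiles, pact) structure(
    list(target_id = id,
         compounds = data.frame(standardized_smiles = smiles,
                                pACTIVITY = pact, n_source_records = 1L)),
    class = "curated_dataset")
  lib <- small_library()
  d1 <- mk("A", lib[1:5], c(5.1, 5.4, 5.2, 5.8, 5.5))
  d2 <- mk("B", lib[6:10], c(7.1, 7.9, 7.4, 7.2, 7.6))
  d3 <- mk("C", lib[1:5], c(5.1, 5.4, 5.2, 5.8, 5.5))

  out <- dataset_distance_matrices(list(d1, d2, d3))
  expect_equal(unname(diag(out$ks_statistic)), rep(0, 3))
  expect_equal(out$ks_statistic, t(out$ks_statistic))
  expect_equal(out$mean_tanimoto, t(out$mean_tanimoto))
  expect_true(all(out$mean_tanimoto >= 0 & out$mean_tanimoto <= 1))
  # disjoint pACTIVITY ranges -> KS statistic 1
  expect_equal(out$ks_statistic["A", "B"], 1)
  # identical distributions -> KS statistic 0
  expect_equal(out$ks_statistic["A", "C"], 0)

  # brute-force ECDF sup oracle on two 5-point samples
  a <- c(5.1, 5.4, 5.2, 5.8, 5.5); b <- c(5.3, 5.45, 5.0, 5.9, 5.6)
  d4 <- mk("D", lib[6:10], b)
  out2 <- dataset_distance_matrices(list(d1, d4))
  grid <- sort(unique(c(a, b)))
  sup <- max(vapply(grid, function(t)
    abs(mean(a <= t) - mean(b <= t)), numeric(1)))
  expect_equal(out2$ks_statistic["A", "D"], sup)
})
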