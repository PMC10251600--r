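test_that("structure standardization strips salts, neutralizes and canonicalizes", {
  expect_equal(as.character(standardize_structure("CCO.[Na+].[Cl-]")), "CCO")
  expect_equal(as.character(standardize_structure("CC(=O)[O-]")), "CC(=O)O")

  benz <- standardize_structure("c1ccccc1")
  expect_equal(as.character(standardize_structure(benz)), as.character(benz))

  # hypervalent nitro is rewritten charge-separated, and the result is stable
  nitro <- as.character(standardize_structure("Cc1ccccc1N(=O)=O"))
  expect_match(nitro, "\\[N\\+\\]")
  expect_match(nitro, "\\[O-\\]")
  expect_equal(as.character(standardize_structure(nitro)), nitro)

  # quaternary ammonium cannot be neutralized and keeps its charge
  expect_match(as.character(standardize_structure("CC[N+](C)(C)C")),
               "\\[N\\+\\]")
  # protonated amine is neutralized
  expect_equal(as.character(standardize_structure("CC[NH3+]")), "CCN")

  bad <- standardize_structure("this is not smiles")
  expect_true(is.na(bad))
  expect_equal(attr(bad, "reason"), "unparsable")

  # largest organic fragment wins over a larger inorganic one
  expect_equal(as.character(standardize_structure("CC.OS(=O)(=O)O")), "CC")
})

test_that("activity normalization converts to negative log molar", {
  expect_equal(normalize_activity(1, "uM"), 6)
  expect_equal(normalize_activity(10, "uM"), 5)
  expect_equal(normalize_activity(1, "M"), 0)
  expect_equal(normalize_activity(c(100, 1), c("nM", "mM")), c(7, 3))
  expect_error(normalize_activity(-1, "uM"), "positive")
  expect_error(normalize_activity(1, "parsec"), "unsupported")
})

test_that("record filters drop non-human, censored and foreign activity types", {
  rec <- data.frame(
    structure = c("CCO", "CCN", "CCC", "CCCl", "CCF"),
    value = c(1, 2, 3, 4, 5), unit = "uM",
    activity_type = c("Ki", "IC50", "AC50", "Kd", "EC50"),
    species = c("human", "rat", "human", "Homo Sapiens", "human"),
    censor = c("none", "none", "none", ">", "none"),
    stringsAsFactors = FALSE)
  out <- apply_filters(rec)
  expect_equal(out$records$structure, c("CCO", "CCF"))  # order preserved
  expect_equal(unname(out$removed),
               c(1L, 1L, 1L))  # rat; AC50; censored Kd
  expect_equal(nrow(rec), nrow(out$records) + sum(out$removed))
})

test_that("de-duplication takes the per-structure median, invariant to order", {
  d <- deduplicate(c("a", "a", "a"), c(5, 6, 9))
  expect_equal(d$pACTIVITY, 6)
  expect_equal(d$n_source_records, 3L)

  d1 <- deduplicate("b", 7.3)
  expect_equal(d1$pACTIVITY, 7.3)
  expect_equal(d1$n_source_records, 1L)

  # oracle: sorted-median over every permutation of the input order
  vals <- c(5, 6, 7, 8)
  perms <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2))
  sorted <- sort(vals)
  oracle <- mean(sorted[c(2, 3)])   # even-length median by hand
  for (p in perms) {
    d <- deduplicate(rep("x", 4), vals[p])
    expect_equal(d$pACTIVITY, oracle)
  }
})

test_that("curation round-trips the synthetic artifact table exactly", {
  art <- raw_table()
  ds <- curate_dataset(art$raw, "T1")
  book <- art$bookkeeping

  # injected censored/non-human/salt records are gone; compound set matches
  expect_setequal(ds$compounds$standardized_smiles, unique(book$smiles))

  # per-compound value equals the brute-force median of the emitted records
  for (s in ds$compounds$standardized_smiles) {
    v <- sort(book$pACTIVITY[book$smiles == s])
    n <- length(v)
    med <- if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + c(0, 1)])
    expect_equal(ds$compounds$pACTIVITY[
      ds$compounds$standardized_smiles == s], med, tolerance = 1e-9)
  }

  # provenance reconciles
  expect_equal(nrow(art$raw), nrow(ds$compounds) + sum(ds$provenance))
})

test_that("curation is idempotent", {
  art <- raw_table()
  ds <- curate_dataset(art$raw, "T1")
  # feed the curated output back through the full pipeline stage
  rec2 <- data.frame(structure = ds$compounds$standardized_smiles,
                     value = 10^(-ds$compounds$pACTIVITY), unit = "M",
                     activity_type = "Ki", species = "human",
                     censor = "none", stringsAsFactors = FALSE)
  ds2 <- curate_dataset(rec2, "T1")
  expect_equal(ds2$compounds$standardized_smiles,
               ds$compounds$standardized_smiles)
  expect_equal(ds2$compounds$pACTIVITY, ds$compounds$pACTIVITY,
               tolerance = 1e-9)
  expect_true(all(ds2$compounds$n_source_records == 1L))
})
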