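#' @title Synthetic structure-activity panels
#' @description Generates raw-format structure-activity tables with known
#'   ground truth so every pipeline stage is testable offline: a packaged
#'   fragment grammar assembles valid, diverse SMILES; a seeded
#'   structure-activity function with Gaussian noise produces pACTIVITY
#'   values whose sample mean/SD match the statistics typical of curated
#'   liability panels (mean ~6.6 log units, SD ~0.6); and an artifact
#'   injector decorates the clean records with the raw-data pathologies the
#'   curation stage must remove (salts, censored values, non-human species,
#'   duplicates, mixed units and activity types).
#' @name synthetic_data
NULL

# Fragment grammar: ring cores with open attachment slots ("%s") and
# substituent fragments. Assembled combinatorially; all pieces are valid
# SMILES by construction.
.CORES <- c(
  "c1ccc(%s)cc1", "c1ccc(%s)c(%s)c1", "c1ccnc(%s)c1", "c1ccc2ccc(%s)cc2c1",
  "c1cnc(%s)nc1", "c1csc(%s)c1", "c1[nH]c2ccccc2c1%s", "C1CCN(%s)CC1",
  "C1CCC(%s)CC1", "C1CCN(%s)C(=O)C1", "c1oc(%s)cc1", "C1CN(%s)CCN1%s",
  "c1cc2nccnc2cc1%s", "C1COC(%s)CN1", "c1nnc(%s)o1", "C1CC1%s",
  "c1ccc2[nH]ncc2c1%s", "C1CCOC(%s)C1")
.LINKERS <- c("C", "CC", "CCC", "OC", "COC", "NC", "C(=O)", "C(=O)N",
              "NC(=O)", "S(=O)(=O)", "OCC", "C=C", "CNC", "CCO")
.SUBS <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "N", "NC", "N(C)C", "F",
           "Cl", "Br", "C(F)(F)F", "C#N", "C(=O)O", "C(=O)OC", "C(=O)N",
           "S(=O)(=O)N", "OCC", "CO", "C(C)O", "CC=C", "[N+](=O)[O-]")

# Build one random SMILES from the grammar.
assemble_smiles <- function() {
  core <- sample(.CORES, 1)
  nslots <- lengths(regmatches(core, gregexpr("%s", core, fixed = TRUE)))
  fills <- character(nslots)
  for (i in seq_len(nslots)) {
    kind <- sample(c("sub", "linked_core", "linker_sub", "none"), 1,
                   prob = c(0.45, 0.25, 0.2, 0.1))
    fills[i] <- switch(kind,
      none = "",
      sub = sample(.SUBS, 1),
      linker_sub = paste0(sample(.LINKERS, 1), sample(.SUBS, 1)),
      linked_core = {
        c2 <- sample(.CORES, 1)
        n2 <- lengths(regmatches(c2, gregexpr("%s", c2, fixed = TRUE)))
        inner <- do.call(sprintf,
                         c(list(c2), as.list(rep("", n2))))
        # renumber ring-closure digits of the inner core to avoid clashes
        inner <- chartr("12", "89", inner)
        paste0(sample(.LINKERS, 1), gsub("\\(\\)", "", inner))
      })
  }
  smi <- do.call(sprintf, c(list(core), as.list(fills)))
  gsub("()", "", smi, fixed = TRUE)
}

#' Generate a library of valid, unique SMILES
#'
#' Random assembly from the packaged fragment grammar (aromatic and
#' saturated ring cores, linkers, substituents). Every emitted SMILES
#' parses, standardizes to itself (modulo canonicalization) and is unique
#' after standardization.
#'
#' @param n library size.
#' @param seed integer seed; the output is a pure function of `(n, seed)`.
#' @return character vector of `n` canonical SMILES.
#' @export
generate_library <- function(n, seed = 1) {
  stopifnot(n >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  seen <- character(0)
  max_tries <- 60 * n + 1000
  tries <- 0
  while (length(seen) < n && tries < max_tries) {
    tries <- tries + 1
    batch <- min(200, max(50, n - length(seen)))
    raw <- vapply(seq_len(batch), function(i) assemble_smiles(),
                  character(1))
    std <- vapply(raw, function(s) {
      r <- tryCatch(standardize_structure(s),
                    error = function(e) NA_character_)
      as.character(r)
    }, character(1), USE.NAMES = FALSE)
    std <- std[!is.na(std) & nzchar(std)]
    seen <- unique(c(seen, std))
  }
  if (length(seen) < n)
    stop("fragment grammar failed to produce ", n, " unique structures")
  seen[seq_len(n)]
}

#' Simulate per-target activities with a known structure-activity function
#'
#' The generating function is linear in a seeded subset of feature columns:
#' a physicochemical part (autoscaled descriptors) and/or a
#' fingerprint-bit-weighted part over `n_signal_bits` seeded EC/FC bits.
#' Gaussian noise of SD `noise_sd` is added; the clean signal is scaled to
#' SD `sqrt(sd_target^2 - noise_sd^2)` and the sum shifted so the realized
#' sample mean/SD match the requested targets. The generating coefficients
#' and the clean signal are stored for parameter-recovery tests.
#'
#' @param library character vector of canonical SMILES (or a precomputed
#'   feature matrix via `features`).
#' @param targets character vector of target labels (panel).
#' @param form `"mixed"` (default), `"linear"` (descriptors only) or
#'   `"bits"` (fingerprint-bit weights only).
#' @param noise_sd Gaussian noise SD in log units (default 0.3).
#' @param mean_target,sd_target sample statistics to emulate (defaults 6.6
#'   and 0.6).
#' @param n_signal_bits number of fingerprint bits carrying signal (64).
#' @param seed integer seed; per-target coefficients are seeded
#'   perturbations of a shared base.
#' @param features optional feature matrix from [build_feature_matrix()].
#' @return list with `records` (data.frame: target, smiles, pACTIVITY),
#'   `truth` (per-target list: coefficients, clean signal, noise) and
#'   `features`.
#' @export
simulate_activities <- function(library, targets = "T1",
                                form = c("mixed", "linear", "bits"),
                                noise_sd = 0.3, mean_target = 6.6,
                                sd_target = 0.6, n_signal_bits = 64,
                                seed = 1, features = NULL) {
  form <- match.arg(form)
  stopifnot(noise_sd >= 0, length(targets) >= 1)
  if (is.null(features))
    features <- build_feature_matrix(
      data.frame(standardized_smiles = library))
  n <- nrow(features)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  pc <- scale(features[, .PHYSCHEM_NAMES, drop = FALSE])
  pc[is.nan(pc)] <- 0
  bits <- features[, setdiff(colnames(features), .PHYSCHEM_NAMES),
                   drop = FALSE]
  # signal bits are drawn from informative-prevalence substructures (present
  # in 5-95% of the library): rare bits carry no learnable signal
  prev <- colMeans(bits)
  eligible <- which(prev >= 0.05 & prev <= 0.95)
  if (length(eligible) < n_signal_bits) eligible <- order(-pmin(prev, 1 - prev))[
    seq_len(min(ncol(bits), n_signal_bits * 2))]
  sig_bits <- sample(eligible, n_signal_bits)
  # heavy-tailed weights: a dozen dominant pharmacophore-like effects over a
  # background of minor contributions, as in real SAR series
  n_dom <- min(12L, n_signal_bits)
  dom <- sample(n_signal_bits, n_dom)
  base_bw <- stats::rnorm(n_signal_bits, sd = 0.3)
  base_bw[dom] <- stats::rnorm(n_dom, sd = 3)
  # pairwise substructure interactions among the dominant fragments emulate
  # activity cliffs: the effect of one fragment depends on another
  n_inter <- max(1L, n_dom %/% 3L)
  inter_pairs <- matrix(sample(sig_bits[dom], 2 * n_inter, replace = TRUE),
                        ncol = 2)
  base_pc <- stats::rnorm(ncol(pc))
  base_iw <- stats::rnorm(n_inter, sd = 2)
  sig_sd <- sqrt(max(sd_target^2 - noise_sd^2, 0.01))

  records <- list(); truth <- list()
  for (tg in targets) {
    cf_pc <- base_pc + stats::rnorm(ncol(pc), sd = 0.3)
    cf_bw <- base_bw * (1 + stats::rnorm(n_signal_bits, sd = 0.2))
    cf_iw <- base_iw * (1 + stats::rnorm(n_inter, sd = 0.2))
    bit_part <- as.numeric(bits[, sig_bits, drop = FALSE] %*% cf_bw) +
      as.numeric((bits[, inter_pairs[, 1], drop = FALSE] *
                    bits[, inter_pairs[, 2], drop = FALSE]) %*% cf_iw)
    raw <- switch(form,
      linear = as.numeric(pc %*% cf_pc),
      bits = bit_part,
      mixed = 0.5 * as.numeric(pc %*% cf_pc) + bit_part)
    s <- stats::sd(raw)
    clean <- if (s > 0) (raw - mean(raw)) / s * sig_sd else raw * 0
    noise <- stats::rnorm(n, sd = noise_sd)
    y <- clean + noise
    y <- y - mean(y) + mean_target
    records[[tg]] <- data.frame(target = tg, smiles = library,
                                pACTIVITY = y, stringsAsFactors = FALSE)
    truth[[tg]] <- list(coef_physchem = cf_pc, coef_bits = cf_bw,
                        coef_interactions = cf_iw,
                        interaction_pairs = inter_pairs,
                        signal_bits = sig_bits, clean = clean,
                        noise = noise, form = form, noise_sd = noise_sd)
  }
  list(records = do.call(rbind, records), truth = truth,
       features = features)
}

#' Inject raw-data artifacts into clean records
#'
#' Produces a raw activity table of the kind the curation stage consumes.
#' Artifacts never destroy clean information: censored and non-human records
#' are *additional* corrupted copies of existing rows, duplicates are extra
#' copies with Gaussian jitter on the activity, and salt decoration appends
#' a counter-ion to the structure in place. Units are rewritten (with exact
#' value conversion) according to `unit_mix`, and activity-type labels drawn
#' from `type_mix`. Curation therefore recovers exactly the clean compound
#' set, with per-compound pACTIVITY equal to the median over each
#' compound's emitted records.
#'
#' @param records clean data.frame with `target`, `smiles`, `pACTIVITY`.
#' @param censored_fraction,nonhuman_fraction,duplicate_fraction fractions
#'   of the clean rows receiving each artifact (counts are
#'   `round(fraction * n)`).
#' @param salt_fraction fraction of rows whose SMILES gains a counter-ion.
#' @param duplicate_jitter_sd SD (log units) of the jitter on duplicate
#'   copies.
#' @param unit_mix named probabilities over units (default mostly nM/uM).
#' @param type_mix named probabilities over activity types.
#' @param seed integer seed.
#' @return list with `raw` (the artifacted ActivityRecord table) and
#'   `bookkeeping` (the emitted usable records per compound, for round-trip
#'   checks).
#' @export
inject_artifacts <- function(records, censored_fraction = 0.05,
                             nonhuman_fraction = 0.05,
                             duplicate_fraction = 0.15,
                             salt_fraction = 0.1,
                             duplicate_jitter_sd = 0.2,
                             unit_mix = c(nM = 0.6, uM = 0.35, mM = 0.05),
                             type_mix = c(IC50 = 0.4, EC50 = 0.2, Ki = 0.3,
                                          Kd = 0.1),
                             seed = 1) {
  stopifnot(all(c("target", "smiles", "pACTIVITY") %in% names(records)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(records)
  # carbon-free counter-ions so the largest-organic-fragment rule always
  # recovers the parent compound
  salts <- c(".[Na+].[Cl-]", ".Cl", ".[K+].[Br-]", ".OS(=O)(=O)O")

  mk_row <- function(smiles, pact, type, species, censor) {
    unit <- sample(names(unit_mix), length(pact), replace = TRUE,
                   prob = unit_mix)
    molar <- 10^(-pact)
    value <- molar / c(nM = 1e-9, uM = 1e-6, mM = 1e-3, M = 1)[unit]
    data.frame(structure = smiles, value = value, unit = unit,
               activity_type = type, species = species, censor = censor,
               stringsAsFactors = FALSE)
  }

  types <- sample(names(type_mix), n, replace = TRUE, prob = type_mix)
  raw <- mk_row(records$smiles, records$pACTIVITY, types, "human", "none")
  raw$target <- records$target
  book <- data.frame(target = records$target, smiles = records$smiles,
                     pACTIVITY = records$pACTIVITY,
                     stringsAsFactors = FALSE)

  # duplicates: extra jittered copies of clean rows (kept by curation)
  ndup <- round(duplicate_fraction * n)
  if (ndup > 0) {
    idx <- sample.int(n, ndup)
    pj <- records$pACTIVITY[idx] + stats::rnorm(ndup,
                                                sd = duplicate_jitter_sd)
    dup <- mk_row(records$smiles[idx], pj,
                  sample(names(type_mix), ndup, TRUE, type_mix),
                  "human", "none")
    dup$target <- records$target[idx]
    raw <- rbind(raw, dup)
    book <- rbind(book, data.frame(target = records$target[idx],
                                   smiles = records$smiles[idx],
                                   pACTIVITY = pj))
  }

  # censored copies (dropped by curation)
  ncen <- round(censored_fraction * n)
  if (ncen > 0) {
    idx <- sample.int(n, ncen)
    cen <- mk_row(records$smiles[idx], records$pACTIVITY[idx] - 1,
                  sample(names(type_mix), ncen, TRUE, type_mix),
                  "human", sample(c(">", "<"), ncen, TRUE))
    cen$target <- records$target[idx]
    raw <- rbind(raw, cen)
  }

  # non-human copies (dropped by curation)
  nnh <- round(nonhuman_fraction * n)
  if (nnh > 0) {
    idx <- sample.int(n, nnh)
    nh <- mk_row(records$smiles[idx],
                 records$pACTIVITY[idx] + stats::rnorm(nnh, sd = 0.5),
                 sample(names(type_mix), nnh, TRUE, type_mix),
                 sample(c("rat", "mouse", "canis familiaris"), nnh, TRUE),
                 "none")
    nh$target <- records$target[idx]
    raw <- rbind(raw, nh)
  }

  # salt decoration in place (stripped by curation)
  nsalt <- round(salt_fraction * nrow(raw))
  if (nsalt > 0) {
    idx <- sample.int(nrow(raw), nsalt)
    raw$structure[idx] <- paste0(raw$structure[idx],
                                 sample(salts, nsalt, replace = TRUE))
  }

  raw <- raw[sample.int(nrow(raw)), , drop = FALSE]   # shuffle row order
  rownames(raw) <- NULL
  list(raw = raw, bookkeeping = book)
}

#' Generate a complete raw synthetic panel
#'
#' Convenience wrapper: library + activities + artifacts.
#'
#' @inheritParams simulate_activities
#' @inheritParams inject_artifacts
#' @param n compounds per target.
#' @return list with `raw`, `bookkeeping`, `clean`, `truth`, `library`,
#'   `features`.
#' @export
generate_panel <- function(n = 500, targets = paste0("T", 1:3),
                           form = "mixed", noise_sd = 0.3, seed = 1, ...) {
  lib <- generate_library(n, seed = seed)
  sim <- simulate_activities(lib, targets = targets, form = form,
                             noise_sd = noise_sd, seed = seed + 1)
  art <- inject_artifacts(sim$records, seed = seed + 2, ...)
  list(raw = art$raw, bookkeeping = art$bookkeeping, clean = sim$records,
       truth = sim$truth, library = lib, features = sim$features)
}
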