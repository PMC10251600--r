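#' @title Curation of raw structure-activity records
#' @description Converts heterogeneous raw activity records (salts, mixed
#'   units, censored values, non-human measurements, duplicates) into
#'   QSAR-ready datasets: one canonical structure per compound with a single
#'   representative pACTIVITY value.
#' @name curation
NULL

# Supported concentration units -> mol/L conversion factors.
.UNIT_TABLE <- c(nM = 1e-9, uM = 1e-6, `µM` = 1e-6, mM = 1e-3, M = 1)

.ALLOWED_SPECIES <- c("homo sapiens", "human")
.ALLOWED_TYPES <- c("IC50", "EC50", "Ki", "Kd")

#' Convert an activity value to pACTIVITY
#'
#' pACTIVITY is the negative decadic logarithm of the molar activity:
#' 1 uM maps to 6.0, 10 uM to 5.0.
#'
#' @param value positive activity value(s).
#' @param unit concentration unit, one of `"nM"`, `"uM"` (or `"µM"`), `"mM"`,
#'   `"M"`; recycled against `value`.
#' @return numeric vector of pACTIVITY values (log units).
#' @export
#' @examples
#' normalize_activity(1, "uM")   # 6
#' normalize_activity(10, "uM")  # 5
normalize_activity <- function(value, unit) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("activity values must be positive and finite")
  fac <- .UNIT_TABLE[as.character(unit)]
  if (any(is.na(fac)))
    stop("unsupported unit(s): ",
         paste(unique(unit[is.na(fac)]), collapse = ", "))
  -log10(value * unname(fac))
}

# Split a SMILES into dot-separated components (dots never occur inside
# brackets in SMILES, so a plain split is exact).
split_components <- function(smiles) strsplit(smiles, ".", fixed = TRUE)[[1]]

# Standardize common charge-separated functional groups on the graph:
# hypervalent neutral nitro N(=O)=O -> [N+](=O)[O-]; hypervalent azide
# N=N=N -> N=[N+]=[N-]; hypervalent tertiary N-oxide -> [N+][O-].
standardize_groups <- function(g) {
  bondsum <- vapply(seq_along(g$elem), function(i)
    sum(g$border[[i]]), numeric(1))
  for (i in seq_along(g$elem)) {
    if (g$elem[i] != "N" || g$charge[i] != 0) next
    if (bondsum[i] < 4) next
    ks <- which((g$bonds$a1 == i | g$bonds$a2 == i) & g$bonds$order == 2)
    if (length(ks) == 0) next
    other <- ifelse(g$bonds$a1[ks] == i, g$bonds$a2[ks], g$bonds$a1[ks])
    oxy <- ks[g$elem[other] == "O"]
    if (length(oxy) > 0) {
      # nitro / N-oxide: demote one N=O to N(+)-O(-)
      k <- oxy[1]; o <- ifelse(g$bonds$a1[k] == i, g$bonds$a2[k], g$bonds$a1[k])
      g$bonds$order[k] <- 1L
      g$charge[i] <- 1L; g$charge[o] <- -1L
    } else {
      nn <- ks[g$elem[other] == "N"]
      if (length(nn) > 0) {
        # azide-like: central N becomes +, a terminal double-bonded N becomes -
        term <- nn[g$degree[other[g$elem[other] == "N"]][1] == 1]
        k <- if (length(term) > 0 && !is.na(term[1])) term[1] else nn[1]
        o <- ifelse(g$bonds$a1[k] == i, g$bonds$a2[k], g$bonds$a1[k])
        g$charge[i] <- 1L; g$charge[o] <- -1L
      }
    }
    bondsum <- vapply(seq_along(g$elem), function(ii)
      sum(g$border[[ii]]), numeric(1))
  }
  g
}

# Neutralize isolated charges: -1 on O/S/N gains a proton, +1 on N with an
# implicit H loses one. Charges whose graph neighbor carries the opposite
# charge (nitro, N-oxide, azide, betaines) are left untouched.
neutralize <- function(g) {
  opp <- vapply(seq_along(g$elem), function(i) {
    nb <- g$nbr[[i]]
    length(nb) > 0 && any(sign(g$charge[nb]) == -sign(g$charge[i]) &
                            g$charge[nb] != 0)
  }, logical(1))
  for (i in seq_along(g$elem)) {
    if (g$charge[i] == 0 || opp[i]) next
    if (g$charge[i] < 0 && g$elem[i] %in% c("O", "S", "N")) {
      g$charge[i] <- g$charge[i] + 1L
    } else if (g$charge[i] > 0 && g$elem[i] == "N" && g$nH[i] >= 1) {
      g$charge[i] <- g$charge[i] - 1L
    }
  }
  g
}

#' Standardize a raw SMILES string
#'
#' Applies the cleaning rules used throughout the pipeline: the largest
#' organic fragment is kept (salt/counter-ion removal), charge-separated
#' groups (nitro, N-oxide, azide) are rewritten in their canonical
#' charge-separated form, isolated charges are neutralized, and the result is
#' emitted as an OpenBabel canonical SMILES. Purely 2D: no geometry is ever
#' generated. Deterministic and idempotent up to canonicalization.
#'
#' @param smiles a single raw SMILES string.
#' @return canonical standardized SMILES, or `NA_character_` with attribute
#'   `reason` when the input cannot be processed.
#' @export
#' @examples
#' standardize_structure("CCO.[Na+].[Cl-]")  # "CCO"
#' standardize_structure("CC(=O)[O-]")       # "CC(=O)O"
standardize_structure <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles))
    return(structure(NA_character_, reason = "empty_input"))
  comp <- split_components(smiles)
  if (length(comp) > 1) {
    gs <- mol_graphs(comp)
    nheavy <- vapply(gs, function(g) if (is.null(g)) -1L else length(g$elem),
                     integer(1))
    hasC <- vapply(gs, function(g) !is.null(g) && any(g$elem == "C"),
                   logical(1))
    cand <- which(hasC)
    if (length(cand) == 0) cand <- which(nheavy > 0)
    if (length(cand) == 0)
      return(structure(NA_character_, reason = "unparsable"))
    best <- cand[nheavy[cand] == max(nheavy[cand])]
    if (length(best) > 1) {   # tie-break: lexicographic canonical SMILES
      cans <- vapply(comp[best], canonicalize_smiles, character(1))
      best <- best[order(cans)][1]
    }
    smiles <- comp[best[1]]
  }
  g <- mol_graphs(smiles)[[1]]
  if (is.null(g)) return(structure(NA_character_, reason = "unparsable"))
  g <- standardize_groups(g)
  g <- neutralize(g)
  out <- molblock_to_cansmi(graph_to_molblock(g))
  if (is.na(out)) return(structure(NA_character_, reason = "sanitization"))
  out
}

#' Filter raw activity records by the sequential cleaning rules
#'
#' Retains only records measured in human (species label `"homo sapiens"` or
#' `"human"`, case-insensitive), with an allowed activity type and, by
#' default, no censor qualifier. Record order is preserved and the number of
#' records removed by each rule (applied sequentially) is returned.
#'
#' @param records data.frame with columns `structure`, `value`, `unit`,
#'   `activity_type`, `species`, `censor`.
#' @param rules list with elements `species` (allowed labels),
#'   `activity_types` (allowed labels) and `drop_censored` (logical).
#' @return list with `records` (the retained rows) and `removed` (named
#'   integer vector of per-rule removal counts).
#' @export
apply_filters <- function(records,
                          rules = list(species = .ALLOWED_SPECIES,
                                       activity_types = .ALLOWED_TYPES,
                                       drop_censored = TRUE)) {
  stopifnot(is.data.frame(records))
  req <- c("structure", "value", "unit", "activity_type", "species", "censor")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  removed <- c(species = 0L, activity_type = 0L, censored = 0L)

  keep <- tolower(trimws(records$species)) %in% tolower(rules$species)
  removed["species"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$activity_type %in% rules$activity_types
  removed["activity_type"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  if (isTRUE(rules$drop_censored)) {
    cens <- !is.na(records$censor) & records$censor %in% c(">", "<")
    removed["censored"] <- sum(cens)
    records <- records[!cens, , drop = FALSE]
  }
  if (nrow(records) == 0) warning("no records retained after filtering")
  list(records = records, removed = removed)
}

#' Collapse standardized records to one compound per structure
#'
#' De-duplication is keyed on exact standardized-SMILES match; the median
#' pACTIVITY over all records of a compound is taken as its representative
#' value, so the result is invariant to record order.
#'
#' @param smiles character vector of standardized SMILES.
#' @param pactivity numeric vector of pACTIVITY values, same length.
#' @return data.frame with columns `standardized_smiles`, `pACTIVITY`,
#'   `n_source_records`, ordered by first appearance.
#' @export
deduplicate <- function(smiles, pactivity) {
  stopifnot(length(smiles) == length(pactivity), length(smiles) >= 1)
  key <- factor(smiles, levels = unique(smiles))
  med <- tapply(pactivity, key, stats::median)
  cnt <- tapply(pactivity, key, length)
  data.frame(standardized_smiles = levels(key),
             pACTIVITY = as.numeric(med),
             n_source_records = as.integer(cnt),
             stringsAsFactors = FALSE)
}

#' Curate a raw activity table into a QSAR-ready dataset
#'
#' Runs the full sequential curation: rule-based filtering
#' ([apply_filters()]), structure standardization
#' ([standardize_structure()]), unit normalization to pACTIVITY
#' ([normalize_activity()]) and median de-duplication ([deduplicate()]).
#'
#' @param records raw record data.frame (see [apply_filters()]).
#' @param target_id label for the dataset (protein symbol).
#' @param rules filter rule list; see [apply_filters()]. Restricting
#'   `activity_types` to `c("Ki","Kd")` or `c("IC50","EC50")` reproduces
#'   binding-only / functional-only model variants.
#' @return object of class `curated_dataset`: list with `target_id`,
#'   `compounds` (data.frame), and `provenance` (named removal counts
#'   reconciling to `raw = retained_records + sum(removed)`).
#' @export
curate_dataset <- function(records, target_id = "target",
                           rules = list(species = .ALLOWED_SPECIES,
                                        activity_types = .ALLOWED_TYPES,
                                        drop_censored = TRUE)) {
  n_raw <- nrow(records)
  flt <- apply_filters(records, rules)
  rec <- flt$records
  removed <- flt$removed

  std <- vapply(rec$structure, function(s) {
    r <- standardize_structure(s)
    as.character(r)
  }, character(1), USE.NAMES = FALSE)
  bad <- is.na(std)
  removed <- c(removed, unparsable = sum(bad))
  rec <- rec[!bad, , drop = FALSE]
  std <- std[!bad]

  badval <- !is.finite(rec$value) | rec$value <= 0 |
    !(as.character(rec$unit) %in% names(.UNIT_TABLE))
  removed <- c(removed, bad_value = sum(badval))
  rec <- rec[!badval, , drop = FALSE]
  std <- std[!badval]

  if (nrow(rec) == 0) {
    warning("curation produced an empty dataset")
    compounds <- data.frame(standardized_smiles = character(0),
                            pACTIVITY = numeric(0),
                            n_source_records = integer(0))
  } else {
    pact <- normalize_activity(rec$value, rec$unit)
    compounds <- deduplicate(std, pact)
  }
  removed <- c(removed, duplicate = nrow(rec) - nrow(compounds))
  stopifnot(n_raw == nrow(compounds) + sum(removed))
  structure(list(target_id = target_id, compounds = compounds,
                 provenance = removed),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("Curated dataset:", x$target_id, "-", nrow(x$compounds),
      "compounds\n")
  cat("  pACTIVITY mean", round(mean(x$compounds$pACTIVITY), 2),
      "SD", round(stats::sd(x$compounds$pACTIVITY), 2), "\n")
  cat("  removed:", paste(names(x$provenance), x$provenance,
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read raw activity records from a delimited text file
#'
#' @param path file path (CSV).
#' @param col_map optional named character vector mapping the six canonical
#'   column names to the file's column names.
#' @return raw record data.frame suitable for [curate_dataset()].
#' @export
read_activity_records <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) names(df)[names(df) == col_map[[nm]]] <- nm
  }
  df
}

#' Write a curated dataset as delimited text
#' @param dataset a `curated_dataset`.
#' @param path output CSV path.
#' @export
write_curated <- function(dataset, path) {
  utils::write.csv(dataset$compounds, path, row.names = FALSE)
  invisible(path)
}
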