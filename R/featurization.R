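#' @title 2059-feature compound encoding
#' @description Each curated compound is encoded by 11 physicochemical
#'   descriptors plus two radius-6 circular fingerprints folded to 1024 bits
#'   each: an extended-connectivity (EC) fingerprint built on atomic
#'   invariants and a feature-invariant (FC) fingerprint built on
#'   pharmacophoric atom features. The 2048-bit EC||FC concatenation is the
#'   similarity vector used for applicability-domain assessment.
#' @name featurization
NULL

.PHYSCHEM_NAMES <- c("MW", "LogP", "TPSA", "HBD", "HBA", "RotatableBonds",
                     "AromaticRings", "AliphaticRings", "StereoCenters",
                     "FractionCsp3", "HeavyAtoms")

.FP_RADIUS <- 6L
.FP_BITS <- 1024L

# 31-bit deterministic integer hash of a numeric vector (values < 2^31).
hash_vec <- function(x) {
  h <- 17
  for (v in x) h <- (h * 31 + (v %% 2147483647)) %% 2147483647
  h
}

# Count rotatable bonds: non-ring single bonds between two non-terminal
# heavy atoms (classic strict definition without amide exclusion).
count_rotatable <- function(g) {
  if (nrow(g$bonds) == 0) return(0L)
  rot <- g$bonds$order == 1 & !g$ring_bond &
    g$degree[g$bonds$a1] >= 2 & g$degree[g$bonds$a2] >= 2
  sum(rot)
}

# Fraction of carbons that are sp3: carbon, not aromatic, all single bonds.
fraction_csp3 <- function(g) {
  isC <- g$elem == "C"
  if (!any(isC)) return(0)
  sp3 <- vapply(seq_along(g$elem), function(i)
    isC[i] && !g$aromatic[i] && (g$degree[i] == 0 ||
                                   all(g$border[[i]] == 1)), logical(1))
  sum(sp3) / sum(isC)
}

# Count stereocentres annotated in a canonical SMILES ('@' or '@@' atoms).
count_stereocenters <- function(smiles) {
  n2 <- lengths(regmatches(smiles, gregexpr("@@", smiles)))
  n1 <- lengths(regmatches(smiles, gregexpr("@", smiles)))
  as.integer(n1 - n2)  # '@@' contributes 2 to n1 and 1 to n2 -> one centre
}

#' Compute the 11 physicochemical descriptors
#'
#' Descriptors: molecular weight, calculated logP, topological polar surface
#' area, H-bond donor and acceptor counts (OpenBabel), rotatable bonds,
#' aromatic and aliphatic ring counts, annotated stereocentre count, fraction
#' of sp3 carbons and heavy-atom count.
#'
#' @param smiles character vector of standardized SMILES.
#' @return numeric matrix `length(smiles)` x 11 with fixed column order.
#' @export
compute_physchem <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  pr <- tryCatch(
    do.call(rbind, ChemmineOB::forEachMol(
      "SMILES", paste(smiles, collapse = "\n"),
      function(m) ChemmineOB::prop_OB(m))),
    error = function(e) NULL)
  if (is.null(pr) || nrow(pr) != length(smiles))
    stop("physchem descriptor computation failed: unparsable input present")
  gs <- mol_graphs(smiles)
  bad <- vapply(gs, is.null, logical(1))
  if (any(bad))
    stop("unparsable compound(s): ",
         paste(smiles[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  m <- matrix(0, nrow = length(smiles), ncol = length(.PHYSCHEM_NAMES),
              dimnames = list(NULL, .PHYSCHEM_NAMES))
  m[, "MW"] <- pr$MW
  m[, "LogP"] <- pr$logP
  m[, "TPSA"] <- pr$TPSA
  m[, "HBD"] <- pr$HBD
  m[, "HBA"] <- pr$HBA1
  m[, "RotatableBonds"] <- vapply(gs, count_rotatable, integer(1))
  m[, "AromaticRings"] <- vapply(gs, function(g) g$n_arom_rings, integer(1))
  m[, "AliphaticRings"] <- vapply(gs, function(g) g$n_aliph_rings, integer(1))
  m[, "StereoCenters"] <- count_stereocenters(smiles)
  m[, "FractionCsp3"] <- vapply(gs, fraction_csp3, numeric(1))
  m[, "HeavyAtoms"] <- vapply(gs, function(g) length(g$elem), numeric(1))
  m
}

# Pharmacophoric atom features for the FC (feature-invariant) fingerprint:
# donor, acceptor, basic, acidic, halogen, aromatic.
atom_features <- function(g) {
  n <- length(g$elem)
  donor <- g$elem %in% c("N", "O") & g$nH >= 1
  acceptor <- g$elem %in% c("N", "O") & g$charge <= 0
  halogen <- g$elem %in% c("F", "Cl", "Br", "I")
  carbonylC <- vapply(seq_len(n), function(i) {
    g$elem[i] == "C" && any(g$border[[i]] == 2 &
                              g$elem[g$nbr[[i]]] %in% c("O", "S"))
  }, logical(1))
  basic <- vapply(seq_len(n), function(i) {
    g$elem[i] == "N" && !g$aromatic[i] && g$charge[i] >= 0 &&
      (g$degree[i] == 0 || all(g$border[[i]] == 1)) &&
      !any(carbonylC[g$nbr[[i]]])
  }, logical(1))
  acidic <- vapply(seq_len(n), function(i) {
    if (!(g$elem[i] == "O" && g$nH[i] >= 1)) return(FALSE)
    any(vapply(g$nbr[[i]], function(j) {
      g$elem[j] %in% c("C", "S", "P") &&
        any(g$border[[j]] == 2 & g$elem[g$nbr[[j]]] == "O")
    }, logical(1)))
  }, logical(1))
  cbind(donor, acceptor, basic, acidic, halogen, aromatic = g$aromatic)
}

# Initial atom invariants.
init_invariants <- function(g, type = c("ec", "fc")) {
  type <- match.arg(type)
  n <- length(g$elem)
  if (type == "ec") {
    z <- .ATOMIC_NUMBER[g$elem]; z[is.na(z)] <- 0L
    vapply(seq_len(n), function(i)
      hash_vec(c(z[i], g$degree[i], g$nH[i], g$charge[i] + 8,
                 as.numeric(g$aromatic[i]), as.numeric(g$in_ring[i]))),
      numeric(1))
  } else {
    f <- atom_features(g)
    vapply(seq_len(n), function(i) hash_vec(c(1, f[i, ])), numeric(1))
  }
}

# Circular (Morgan-style) fingerprint of one molecular graph.
morgan_bits <- function(g, type = c("ec", "fc"), radius = .FP_RADIUS,
                        nbits = .FP_BITS) {
  type <- match.arg(type)
  inv <- init_invariants(g, type)
  ids <- inv
  for (r in seq_len(radius)) {
    newinv <- inv
    for (i in seq_along(inv)) {
      nb <- g$nbr[[i]]
      if (length(nb) == 0) next
      pairs <- cbind(g$border[[i]], inv[nb])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      newinv[i] <- hash_vec(c(r, inv[i], t(pairs)))
    }
    inv <- newinv
    ids <- c(ids, inv)
  }
  bits <- integer(nbits)
  bits[unique(as.integer(ids %% nbits)) + 1L] <- 1L
  bits
}

#' Compute EC, FC and similarity fingerprints for SMILES
#'
#' @param smiles character vector of standardized SMILES.
#' @return list with binary matrices `ec` (n x 1024), `fc` (n x 1024) and
#'   `similarity` (n x 2048, the EC||FC concatenation).
#' @export
compute_fingerprints <- function(smiles) {
  gs <- mol_graphs(smiles)
  bad <- vapply(gs, is.null, logical(1))
  if (any(bad))
    stop("unparsable compound(s): ",
         paste(smiles[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  ec <- t(vapply(gs, morgan_bits, integer(.FP_BITS), type = "ec"))
  fc <- t(vapply(gs, morgan_bits, integer(.FP_BITS), type = "fc"))
  colnames(ec) <- paste0("EC", seq_len(.FP_BITS))
  colnames(fc) <- paste0("FC", seq_len(.FP_BITS))
  list(ec = ec, fc = fc, similarity = cbind(ec, fc))
}

#' Build the full 2059-column feature matrix for a curated dataset
#'
#' Column order is physicochemical descriptors first, then the 1024 EC bits,
#' then the 1024 FC bits. Row order follows the dataset.
#'
#' @param dataset a `curated_dataset` (or data.frame with a
#'   `standardized_smiles` column).
#' @return numeric matrix n x 2059 with named columns and attribute
#'   `similarity` holding the n x 2048 similarity-bit matrix.
#' @export
build_feature_matrix <- function(dataset) {
  cmp <- if (inherits(dataset, "curated_dataset")) dataset$compounds else dataset
  if (nrow(cmp) == 0) stop("empty dataset")
  smiles <- cmp$standardized_smiles
  pc <- compute_physchem(smiles)
  fp <- compute_fingerprints(smiles)
  m <- cbind(pc, fp$ec, fp$fc)
  stopifnot(ncol(m) == 2059)
  attr(m, "similarity") <- fp$similarity
  m
}

#' Drop low-variance and highly correlated columns
#'
#' Used ahead of PCA in the chemical-space analysis: columns with standard
#' deviation below `sd_min` are removed, then column pairs with absolute
#' Pearson correlation above `r_max` are scanned in fixed column order and
#' the later member of each offending pair is removed, which makes the result
#' deterministic and the operation idempotent.
#'
#' @param m numeric matrix.
#' @param sd_min minimum column standard deviation (default 0.01).
#' @param r_max maximum allowed absolute pairwise correlation (default 0.95).
#' @return the reduced matrix, with attribute `dropped` naming removed
#'   columns.
#' @export
filter_descriptors <- function(m, sd_min = 0.01, r_max = 0.95) {
  stopifnot(is.matrix(m), sd_min > 0, sd_min <= 1 || TRUE, r_max > 0)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  sds <- apply(m, 2, stats::sd)
  low <- sds < sd_min
  dropped <- colnames(m)[low]
  m2 <- m[, !low, drop = FALSE]
  if (ncol(m2) == 0) stop("all columns dropped by variance filter")
  if (ncol(m2) >= 2) {
    cc <- abs(suppressWarnings(stats::cor(m2)))
    cc[is.na(cc)] <- 0
    keep <- rep(TRUE, ncol(m2))
    for (j in seq_len(ncol(m2))) {
      if (!keep[j]) next
      for (k in seq_len(ncol(m2))) {
        if (k <= j || !keep[k]) next
        if (cc[j, k] > r_max) keep[k] <- FALSE
      }
    }
    dropped <- c(dropped, colnames(m2)[!keep])
    m2 <- m2[, keep, drop = FALSE]
  }
  attr(m2, "dropped") <- dropped
  m2
}
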