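# Internal molecular-graph layer on top of ChemmineR / OpenBabel.
# Everything downstream (descriptors, circular fingerprints, scaffolds) works on
# the light-weight graph produced by mol_graph() rather than on SDF objects.

# SDF charge codes (V2000 column 5) -> formal charge
.SDF_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
                 `6` = -2L, `7` = -3L)

.DEFAULT_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L, Cl = 1L,
                      Br = 1L, I = 1L, B = 3L, Si = 4L, Se = 2L, As = 3L)

.ATOMIC_NUMBER <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L,
                    P = 15L, S = 16L, Cl = 17L, As = 33L, Se = 34L, Br = 35L,
                    I = 53L)

#' Parse SMILES strings into an SDFset
#'
#' Thin wrapper around [ChemmineR::smiles2sdf()] that assigns unique compound
#' ids and validates the parse. Invalid SMILES yield atom-free records, which
#' are reported as failures.
#'
#' @param smiles character vector of SMILES strings.
#' @return an `SDFset` with one entry per input (possibly empty molecules for
#'   unparsable inputs).
#' @keywords internal
#' @noRd
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  nm <- paste0("cmp", seq_along(smiles))
  x <- stats::setNames(smiles, nm)
  suppressWarnings(ChemmineR::smiles2sdf(x))
}

# Decode one SDF entry into the internal graph representation.
# Returns NULL when the molecule has no atoms (parse failure sentinel).
sdf_to_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  if (nrow(ab) == 0) return(NULL)
  elem <- sub("_.*$", "", rownames(ab))
  chcode <- as.character(ab[, "C6"])  # V2000 charge field (C4 = element is the rowname)
  charge <- unname(.SDF_CHARGE[chcode])
  charge[is.na(charge)] <- 0L
  n <- length(elem)

  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) %/% 7, ncol = 7,
                                     byrow = FALSE)
  if (nrow(bb) > 0) {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }

  nbr <- vector("list", n)
  border <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]; o <- bonds$order[k]
    nbr[[i]] <- c(nbr[[i]], j); border[[i]] <- c(border[[i]], o)
    nbr[[j]] <- c(nbr[[j]], i); border[[j]] <- c(border[[j]], o)
  }
  degree <- vapply(nbr, length, integer(1))
  bondsum <- vapply(border, function(o) sum(as.integer(o)), integer(1))

  # ring perception (smallest rings) + aromaticity from ChemmineR
  in_ring <- rep(FALSE, n)
  aromatic <- rep(FALSE, n)
  n_arom_rings <- 0L; n_aliph_rings <- 0L
  rg <- NULL
  if (nrow(bonds) >= n) {  # cyclomatic number > 0 for a connected graph
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE,
                                        inner = TRUE)),
      error = function(e) NULL)
    if (!is.null(rg) && length(rg$RINGS) > 0) {
      for (ri in seq_along(rg$RINGS)) {
        idx <- as.integer(sub("^.*_", "", rg$RINGS[[ri]]))
        in_ring[idx] <- TRUE
        if (isTRUE(rg$AROMATIC[[ri]])) {
          aromatic[idx] <- TRUE
          n_arom_rings <- n_arom_rings + 1L
        } else n_aliph_rings <- n_aliph_rings + 1L
      }
    }
  }
  # a bond is a ring bond when both ends lie in one perceived ring
  ring_bond <- rep(FALSE, nrow(bonds))
  if (any(in_ring) && !is.null(rg) && length(rg$RINGS) > 0) {
    rsets <- lapply(rg$RINGS, function(r) as.integer(sub("^.*_", "", r)))
    for (k in seq_len(nrow(bonds))) {
      for (rs in rsets) {
        if (bonds$a1[k] %in% rs && bonds$a2[k] %in% rs) {
          ring_bond[k] <- TRUE; break
        }
      }
    }
  }

  defv <- .DEFAULT_VALENCE[elem]
  defv[is.na(defv)] <- bondsum[is.na(defv)]  # metals etc.: no implicit H
  cap <- ifelse(elem == "C", defv - abs(charge), defv + charge)
  nH <- pmax(0L, as.integer(cap) - bondsum)

  list(elem = elem, charge = charge, degree = degree, nH = nH,
       aromatic = aromatic, in_ring = in_ring, bonds = bonds,
       ring_bond = ring_bond, nbr = nbr, border = border,
       n_arom_rings = n_arom_rings, n_aliph_rings = n_aliph_rings)
}

#' Parse a batch of SMILES into molecular graphs
#' @return list of graphs (NULL entries for unparsable SMILES)
#' @keywords internal
#' @noRd
mol_graphs <- function(smiles) {
  sdf <- tryCatch(parse_smiles(smiles), error = function(e) NULL)
  if (!is.null(sdf) && length(sdf) == length(smiles)) {
    return(lapply(seq_along(smiles), function(i) {
      g <- tryCatch(sdf_to_graph(sdf[[i]]), error = function(e) NULL)
      if (is.null(g)) g <- single_atom_graph(smiles[i])
      g
    }))
  }
  # batch parse failed (some SMILES invalid): fall back to per-molecule parsing
  lapply(smiles, function(s) {
    one <- tryCatch(parse_smiles(s), error = function(e) NULL)
    g <- if (is.null(one)) NULL else
      tryCatch(sdf_to_graph(one[[1]]), error = function(e) NULL)
    if (is.null(g)) g <- single_atom_graph(s)
    g
  })
}

# ChemmineR rejects bond-free molecules (e.g. methane) as invalid SDF; build
# the trivial one-heavy-atom graph directly from OpenBabel's molblock.
single_atom_graph <- function(smiles) {
  mb <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
                 error = function(e) NULL)
  if (is.null(mb)) return(NULL)
  lines <- strsplit(mb, "\n")[[1]]
  if (length(lines) < 5) return(NULL)
  natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(natoms) || natoms != 1 || nbonds != 0) return(NULL)
  elem <- trimws(substr(lines[5], 32, 34))
  charge <- unname(.SDF_CHARGE[trimws(substr(lines[5], 37, 39))])
  if (is.na(charge)) charge <- 0L
  defv <- .DEFAULT_VALENCE[elem]; if (is.na(defv)) defv <- 0L
  cap <- if (identical(elem, "C")) defv - abs(charge) else defv + charge
  list(elem = elem, charge = charge, degree = 0L,
       nH = max(0L, as.integer(cap)),
       aromatic = FALSE, in_ring = FALSE,
       bonds = data.frame(a1 = integer(0), a2 = integer(0),
                          order = integer(0)),
       ring_bond = logical(0), nbr = list(integer(0)),
       border = list(integer(0)),
       n_arom_rings = 0L, n_aliph_rings = 0L)
}

# Serialize a (possibly edited) graph back to a V2000 molblock string.
graph_to_molblock <- function(g) {
  n <- length(g$elem); nb <- nrow(g$bonds)
  chcode <- rep(0L, n)
  chcode[g$charge == 1L] <- 3L; chcode[g$charge == 2L] <- 2L
  chcode[g$charge == 3L] <- 1L; chcode[g$charge == -1L] <- 5L
  chcode[g$charge == -2L] <- 6L; chcode[g$charge == -3L] <- 7L
  atoms <- vapply(seq_len(n), function(i)
    sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, g$elem[i], chcode[i]), character(1))
  bondl <- if (nb > 0) vapply(seq_len(nb), function(k)
    sprintf("%3d%3d%3d  0", g$bonds$a1[k], g$bonds$a2[k], g$bonds$order[k]),
    character(1)) else character(0)
  paste0("mol\n liabprof\n\n",
         sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000\n", n, nb),
         paste(c(atoms, bondl), collapse = "\n"),
         if (n > 0) "\n", "M  END\n$$$$\n")
}

#' Canonicalize a SMILES string (OpenBabel canonical form)
#' @keywords internal
#' @noRd
canonicalize_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) "")
  smi <- sub("[\t\n ].*$", "", out)
  if (!nzchar(smi)) NA_character_ else smi
}

# molblock text -> canonical SMILES (NA on failure)
molblock_to_cansmi <- function(mb) {
  out <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", mb),
                  error = function(e) "")
  smi <- sub("[\t\n ].*$", "", out)
  if (!nzchar(smi)) NA_character_ else smi
}

#' Tanimoto similarity between binary fingerprint vectors
#'
#' @param a,b binary (0/1) vectors of equal length.
#' @return similarity in \[0, 1\]; defined as 1 when both vectors are all-zero.
#' @export
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

#' Maximum Tanimoto similarity of a query against a fingerprint store
#'
#' Vectorized maximum of [tanimoto()] between `query` and each row of a
#' binary matrix; the workhorse of applicability-domain assessment.
#'
#' @param query binary vector.
#' @param mat binary matrix with `length(query)` columns.
#' @return the maximum similarity in \[0, 1\].
#' @export
max_tanimoto_to_set <- function(query, mat) {
  stopifnot(ncol(mat) == length(query))
  inter <- as.numeric(mat %*% query)
  uni <- rowSums(mat) + sum(query) - inter
  s <- ifelse(uni == 0, 1, inter / uni)
  max(s)
}
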