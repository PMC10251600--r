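#' @title Chemical-space analysis
#' @description Basic-framework scaffolds (Murcko scaffold with every atom
#'   converted to carbon, preserving ramifications, double bonds and
#'   aromaticity), scaffold-grouped descriptor tables for PCA maps, and
#'   pairwise dataset comparison matrices (Kolmogorov-Smirnov distances of
#'   pACTIVITY distributions and mean inter-dataset Tanimoto similarity).
#' @name chemspace
NULL

# Reduce a graph to its Murcko scaffold: iteratively delete terminal
# (degree-1) heavy atoms so only ring systems and their linkers remain.
scaffold_graph <- function(g) {
  keep <- rep(TRUE, length(g$elem))
  repeat {
    deg <- rep(0L, length(g$elem))
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
      if (keep[i] && keep[j]) { deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L }
    }
    drop <- keep & deg <= 1
    if (!any(drop) || all(drop)) { if (all(drop)) keep[] <- FALSE; break }
    keep[drop] <- FALSE
  }
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  remap <- match(seq_along(g$elem), idx)
  bonds <- g$bonds[keep[g$bonds$a1] & keep[g$bonds$a2], , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  list(elem = g$elem[idx], charge = g$charge[idx], bonds = bonds)
}

#' Murcko scaffold of a compound
#'
#' Ring systems plus the linkers connecting them, with all side chains and
#' terminal atoms removed, as a canonical SMILES. Acyclic molecules have no
#' scaffold and return `""`.
#'
#' @param smiles a single SMILES string.
#' @return canonical scaffold SMILES, `""` for acyclic molecules, or `NA` if
#'   the input cannot be processed.
#' @export
#' @examples
#' murcko_scaffold("Cc1ccccc1")  # toluene -> benzene
murcko_scaffold <- function(smiles) {
  g <- mol_graphs(smiles)[[1]]
  if (is.null(g)) return(NA_character_)
  sg <- scaffold_graph(g)
  if (is.null(sg)) return("")
  molblock_to_cansmi(graph_to_molblock(sg))
}

#' Basic framework of a compound
#'
#' The Murcko scaffold with every atom converted to carbon while bond orders
#' (including aromaticity) are retained; charges, isotopes and stereo
#' annotations are dropped. This is a higher level of abstraction than the
#' scaffold itself and is used as the grouping term of the chemical-space
#' maps. Idempotent; acyclic molecules return `""`.
#'
#' @param smiles a single SMILES string.
#' @return canonical framework SMILES, `""` for acyclic molecules, or `NA`
#'   with attribute `reason` on sanitization failure.
#' @export
#' @examples
#' basic_framework("c1ccncc1")  # pyridine -> benzene
basic_framework <- function(smiles) {
  g <- mol_graphs(smiles)[[1]]
  if (is.null(g)) return(structure(NA_character_, reason = "unparsable"))
  sg <- scaffold_graph(g)
  if (is.null(sg)) return("")
  sg$elem[] <- "C"
  sg$charge[] <- 0L
  out <- molblock_to_cansmi(graph_to_molblock(sg))
  if (is.na(out)) {
    # rings that cannot kekulize after abstraction: single-bond skeleton
    sg$bonds$order[] <- 1L
    out <- molblock_to_cansmi(graph_to_molblock(sg))
    if (is.na(out)) return(structure(NA_character_, reason = "sanitization"))
    warning("framework fell back to single-bond skeleton for: ", smiles)
  }
  out
}

#' Scaffold-grouped feature table
#'
#' Groups the compounds of one or more curated datasets by basic framework,
#' averages the feature columns within each group and autoscales them
#' column-wise (mean 0, SD 1). Acyclic compounds (no framework) are excluded
#' from the table and counted separately.
#'
#' @param datasets list of `curated_dataset` objects.
#' @param features list of feature matrices matching `datasets` row-for-row
#'   (e.g. from [build_feature_matrix()]); physicochemical columns are the
#'   natural choice for interpretable maps.
#' @return list with `table` (framework x feature matrix, autoscaled),
#'   `info` (data.frame: framework, member_count, mean/SD pACTIVITY,
#'   target_occurrence), `n_acyclic` and `raw_means` (pre-scaling averages).
#' @export
scaffold_table <- function(datasets, features) {
  stopifnot(length(datasets) == length(features))
  smiles <- unlist(lapply(datasets, function(d) d$compounds$standardized_smiles))
  pact <- unlist(lapply(datasets, function(d) d$compounds$pACTIVITY))
  dsid <- rep(seq_along(datasets),
              vapply(datasets, function(d) nrow(d$compounds), integer(1)))
  feat <- do.call(rbind, lapply(features, function(f) f[, , drop = FALSE]))

  fw <- vapply(smiles, function(s) {
    r <- basic_framework(s)
    as.character(r)
  }, character(1), USE.NAMES = FALSE)
  acyclic <- !is.na(fw) & fw == ""
  valid <- !is.na(fw) & fw != ""

  key <- factor(fw[valid], levels = unique(fw[valid]))
  raw_means <- apply(feat[valid, , drop = FALSE], 2,
                     function(col) tapply(col, key, mean))
  raw_means <- matrix(raw_means, nrow = nlevels(key),
                      dimnames = list(levels(key), colnames(feat)))
  scaled <- scale(raw_means)
  # constant columns scale to NaN; keep them at 0
  scaled[is.nan(scaled)] <- 0

  info <- data.frame(
    framework = levels(key),
    member_count = as.integer(tapply(rep(1, sum(valid)), key, sum)),
    mean_pACTIVITY = as.numeric(tapply(pact[valid], key, mean)),
    sd_pACTIVITY = as.numeric(tapply(pact[valid], key, stats::sd)),
    target_occurrence = as.integer(tapply(dsid[valid], key,
                                          function(x) length(unique(x)))),
    stringsAsFactors = FALSE)
  list(table = scaled, info = info, n_acyclic = sum(acyclic),
       raw_means = raw_means)
}

#' Principal component analysis of a feature table
#'
#' Centered (unscaled beyond the caller's autoscaling) PCA via the singular
#' value decomposition. Inputs are normally pre-reduced with
#' [filter_descriptors()].
#'
#' @param m numeric matrix (rows = scaffolds/compounds, columns = features).
#' @param n_components number of components to return.
#' @return list with `scores`, `loadings` and `explained_variance`
#'   (fractions, non-increasing).
#' @export
pca_project <- function(m, n_components = 2) {
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  if (n_components > min(nrow(m) - 1, ncol(m)))
    stop("more components requested than available")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       loadings = p$rotation[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)])
}

#' Pairwise dataset comparison matrices
#'
#' For every pair of datasets, the Kolmogorov-Smirnov statistic and p-value
#' comparing their pACTIVITY distributions, and the mean Tanimoto similarity
#' over cross-set compound pairs (within-set mean similarity on the
#' diagonal). Above `max_per_set` compounds a seeded subsample keeps the
#' pairwise cost bounded.
#'
#' @param datasets list of `curated_dataset` objects (each >= 2 compounds).
#' @param similarities optional list of similarity-bit matrices matching
#'   `datasets`; computed on the fly if missing.
#' @param max_per_set subsample cap per dataset for the Tanimoto matrix.
#' @param seed subsampling seed.
#' @return list of symmetric matrices `ks_statistic`, `ks_pvalue`,
#'   `mean_tanimoto`.
#' @export
dataset_distance_matrices <- function(datasets, similarities = NULL,
                                      max_per_set = 200, seed = 1) {
  k <- length(datasets)
  stopifnot(k >= 1)
  if (is.null(similarities))
    similarities <- lapply(datasets, function(d)
      compute_fingerprints(d$compounds$standardized_smiles)$similarity)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sub <- lapply(similarities, function(s) {
    if (nrow(s) > max_per_set) s[sample.int(nrow(s), max_per_set), ,
                                 drop = FALSE] else s
  })
  ksD <- matrix(0, k, k); ksP <- matrix(1, k, k); mt <- matrix(0, k, k)
  nm <- vapply(datasets, function(d) d$target_id, character(1))
  dimnames(ksD) <- dimnames(ksP) <- dimnames(mt) <- list(nm, nm)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (j > i) {
        kt <- suppressWarnings(
          stats::ks.test(datasets[[i]]$compounds$pACTIVITY,
                         datasets[[j]]$compounds$pACTIVITY))
        ksD[i, j] <- ksD[j, i] <- unname(kt$statistic)
        ksP[i, j] <- ksP[j, i] <- kt$p.value
      }
      a <- sub[[i]]; b <- sub[[j]]
      inter <- a %*% t(b)
      uni <- outer(rowSums(a), rowSums(b), "+") - inter
      s <- ifelse(uni == 0, 1, inter / uni)
      if (i == j) {
        n <- nrow(a)
        val <- if (n > 1) (sum(s) - n) / (n * (n - 1)) else 1
      } else val <- mean(s)
      mt[i, j] <- mt[j, i] <- val
    }
  }
  list(ks_statistic = ksD, ks_pvalue = ksP, mean_tanimoto = mt)
}
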