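#' Permutation test for allele-versus-species clustering on a tree
#'
#' Operationalises the trans-species polymorphism signature — clones
#' clustering by allele rather than by species — as the Fitch parsimony
#' score of species labels on the tree. A score at the minimum
#' (n_species - 1) means species are monophyletic; a high score means
#' species are intermingled across the tree, as expected when allelic
#' lineages predate speciation. The null distribution shuffles species
#' labels across leaves; when a cluster (paralog) assignment is supplied,
#' shuffling is stratified within clusters and scores are summed over the
#' clusters' induced subtrees, so paralogy itself does not masquerade as
#' allelic trans-speciation.
#'
#' Two summaries are emitted: `p_species_clustering` = P(null <= observed)
#' (small when species cluster *more* than random, i.e. no trans-species
#' signal), and the intermixing index
#' (observed - min) / (mean(null) - min), which is 0 for
#' species-monophyletic trees and near 1 when species are as intermixed
#' as random labelling.
#'
#' @param tree a `phylo`; tips must be named in `species`.
#' @param species named character vector: tip label -> species code.
#' @param clusters optional `cluster_assignment` (or named vector) mapping
#'   tip labels to paralog clusters; enables the stratified test.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @return a `transpecies_test` list: observed_score, min_possible,
#'   null_scores, p_species_clustering, intermixing_index, index_ci
#'   (bootstrap 95% CI), per_clade (species sharing per cluster, when
#'   clusters given).
#' @export
transpecies_test <- function(tree, species, clusters = NULL,
                             n_perm = 999L, seed = 1L) {
  stopifnot(n_perm >= 99L)
  species <- species[tree$tip.label]
  if (length(unique(species)) < 2L) stop("need >= 2 species")
  if (!is.null(clusters) && inherits(clusters, "data.frame")) {
    clusters <- stats::setNames(clusters$cluster, clusters$id)
  }
  set.seed(seed)
  if (is.null(clusters)) {
    parts <- list(list(tree = tree, tips = tree$tip.label))
  } else {
    cl <- clusters[tree$tip.label]
    parts <- lapply(split(tree$tip.label, cl), function(tips) {
      if (length(tips) < 3L) return(list(tree = NULL, tips = tips))
      list(tree = ape::keep.tip(tree, tips), tips = tips)
    })
  }
  score_parts <- function(labels) {
    tot <- 0L
    min_tot <- 0L
    for (p in parts) {
      sp <- labels[p$tips]
      k <- length(unique(sp))
      min_tot <- min_tot + (k - 1L)
      if (is.null(p$tree)) {
        tot <- tot + (k - 1L)  # <3 tips: any labelling costs k-1 changes
      } else {
        tot <- tot + as.integer(fitch_score(p$tree, sp))
      }
    }
    c(score = tot, min = min_tot)
  }
  obs <- score_parts(species)
  null_scores <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- species
    for (p in parts) {
      perm[p$tips] <- sample(species[p$tips])
    }
    null_scores[b] <- score_parts(perm)[["score"]]
  }
  observed <- obs[["score"]]
  min_possible <- obs[["min"]]
  p_clust <- (1 + sum(null_scores <= observed)) / (n_perm + 1)
  denom <- mean(null_scores) - min_possible
  index <- if (denom > 0) (observed - min_possible) / denom else
    ifelse(observed == min_possible, 0, NA_real_)
  boot_idx <- replicate(200L, {
    d <- mean(sample(null_scores, replace = TRUE)) - min_possible
    if (d > 0) (observed - min_possible) / d else NA_real_
  })
  ci <- stats::quantile(boot_idx, c(0.025, 0.975), na.rm = TRUE,
                        names = FALSE)
  per_clade <- if (!is.null(clusters)) {
    clade_species_sharing(tree, clusters, species)
  } else NULL
  structure(list(
    observed_score = observed, min_possible = min_possible,
    null_scores = null_scores, p_species_clustering = p_clust,
    intermixing_index = index, index_ci = ci, per_clade = per_clade,
    n_perm = n_perm, stratified = !is.null(clusters)
  ), class = "transpecies_test")
}

#' @export
print.transpecies_test <- function(x, ...) {
  cat("Trans-species clustering test",
      if (x$stratified) "(stratified within clusters)" else "(global)", "\n")
  cat(sprintf("  species-label parsimony: %d (minimum %d, null mean %.1f)\n",
              x$observed_score, x$min_possible, mean(x$null_scores)))
  cat(sprintf("  intermixing index: %.3f [%.3f, %.3f]\n",
              x$intermixing_index, x$index_ci[1], x$index_ci[2]))
  cat(sprintf("  P(null <= observed) = %.4f  (small => species-monophyletic)\n",
              x$p_species_clustering))
  invisible(x)
}

#' Species sharing per cluster
#'
#' For each cluster of tree leaves, counts the distinct species present;
#' clusters containing two or more species are flagged trans-species.
#'
#' @param tree a `phylo` (used for its tip set).
#' @param clusters a `cluster_assignment` or named vector tip -> cluster.
#' @param species named vector tip -> species code.
#' @return data.frame: cluster, n_leaves, n_species, species (comma
#'   separated), trans_species flag.
#' @export
clade_species_sharing <- function(tree, clusters, species) {
  if (inherits(clusters, "data.frame")) {
    clusters <- stats::setNames(clusters$cluster, clusters$id)
  }
  tips <- tree$tip.label
  cl <- clusters[tips]
  rows <- lapply(sort(unique(cl)), function(k) {
    sp <- sort(unique(species[tips[cl == k]]))
    data.frame(cluster = k, n_leaves = sum(cl == k),
               n_species = length(sp),
               species = paste(sp, collapse = ","),
               trans_species = length(sp) >= 2L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-hot genotype matrix from polymorphic alignment columns
#'
#' Builds the records x (site, allele) indicator matrix used for PCA/DAPC:
#' one column per allele of every polymorphic site passing the
#' minor-allele-count filter, mean-centred. Gaps are treated as an allele
#' state when `indels_as_alleles = TRUE` (default), since indel
#' presence/absence is informative for allele classes; `N` never
#' contributes an indicator.
#'
#' @param aln a `clone_alignment`.
#' @param maf_min minimum count of the second-most-frequent state for a
#'   site to be retained (default 1 = all polymorphic sites).
#' @param indels_as_alleles treat `-` as an allele state.
#' @return numeric matrix, rownames = record ids, with attribute `sites`.
#' @export
genotype_matrix <- function(aln, maf_min = 1L, indels_as_alleles = TRUE) {
  mat <- aln$seq
  blocks <- list()
  sites <- integer(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    keepmask <- col != "N"
    if (!indels_as_alleles) keepmask <- keepmask & col != "-"
    states <- table(col[keepmask])
    if (length(states) < 2L) next
    if (sort(states, decreasing = TRUE)[2L] < maf_min) next
    for (s in names(states)) {
      ind <- as.numeric(col == s & keepmask)
      blocks[[paste0("c", j, "_", s)]] <- ind
    }
    sites <- c(sites, j)
  }
  if (length(blocks) == 0L) stop("no polymorphic sites")
  X <- do.call(cbind, blocks)
  rownames(X) <- rownames(mat)
  X <- scale(X, center = TRUE, scale = FALSE)
  attr(X, "sites") <- sites
  X
}

#' Discriminant analysis of principal components (DAPC)
#'
#' PCA by eigendecomposition of the centred genotype matrix, followed by
#' linear discriminant analysis on the retained principal-component
#' scores. The published reproduction profile retains 10 PCs and 3
#' discriminant functions; by default `n_pca` is chosen to explain at
#' least 80% of variance when not given.
#'
#' @param X genotype matrix from [genotype_matrix()].
#' @param groups named character/factor vector: record id -> group.
#' @param n_pca number of PCs to retain (clamped to the matrix rank, with
#'   a warning); `NULL` = smallest number explaining >= 80% variance.
#' @param n_da number of discriminant functions (clamped to groups - 1).
#' @return a `dapc_model` list: scores (PC scores), coords (discriminant
#'   coordinates), posterior (per-record group membership probabilities),
#'   assign (predicted group), accuracy (reassignment proportion),
#'   eig (LD eigenvalues), var_explained, n_pca, n_da, groups.
#' @export
dapc_fit <- function(X, groups, n_pca = 10L, n_da = 3L) {
  groups <- factor(groups[rownames(X)])
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  pos <- pc$sdev^2 > 1e-9 * pc$sdev[1L]^2
  rank <- sum(pos)
  varex <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  if (is.null(n_pca)) n_pca <- which(varex >= 0.8)[1L]
  if (n_pca > rank) {
    warning("n_pca reduced to matrix rank (", rank, ")")
    n_pca <- rank
  }
  max_da <- nlevels(groups) - 1L
  if (n_da > max_da) {
    warning("n_da clamped to groups - 1 (", max_da, ")")
    n_da <- max_da
  }
  scores <- pc$x[, seq_len(n_pca), drop = FALSE]
  fit <- MASS::lda(scores, grouping = groups)
  pred <- stats::predict(fit, scores)
  n_da <- min(n_da, ncol(pred$x))
  structure(list(
    scores = scores,
    coords = pred$x[, seq_len(n_da), drop = FALSE],
    posterior = pred$posterior,
    assign = pred$class,
    accuracy = mean(pred$class == groups),
    eig = fit$svd^2,
    var_explained = varex[n_pca],
    n_pca = n_pca, n_da = n_da, groups = groups
  ), class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat("DAPC:", x$n_pca, "PCs (", sprintf("%.1f%%", 100 * x$var_explained),
      "variance ),", x$n_da, "discriminant function(s),",
      nlevels(x$groups), "groups\n")
  cat(sprintf("reassignment accuracy: %.3f\n", x$accuracy))
  invisible(x)
}
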