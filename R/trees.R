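#' Pairwise p-distance matrix
#'
#' Proportion of differing sites per pair, over columns where neither
#' sequence has a gap or N (`pairwise` deletion) or over globally gap-free
#' columns (`complete` deletion).
#'
#' @param aln a `clone_alignment`.
#' @param mode `"pairwise"` or `"complete"` deletion.
#' @return symmetric numeric matrix with zero diagonal, dimnames = record ids.
#' @export
pdistance_matrix <- function(aln, mode = c("pairwise", "complete")) {
  mode <- match.arg(mode)
  mat <- aln$seq
  if (mode == "complete") {
    keep <- colSums(mat == "-" | mat == "N") == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  ids <- rownames(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ok <- mat != "-" & mat != "N"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        stop("no comparable columns between '", ids[i], "' and '", ids[j], "'")
      }
      d[i, j] <- d[j, i] <- sum(mat[i, comp] != mat[j, comp]) / nc
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei neighbor joining (via \pkg{ape}); recovers additive
#' trees exactly. Negative branch lengths are clamped to zero with a
#' message, the usual practice for NJ on noisy distances.
#'
#' @param dist symmetric numeric matrix with zero diagonal.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (!isTRUE(all.equal(dist, t(dist)))) stop("distance matrix not symmetric")
  if (any(abs(diag(dist)) > 1e-12)) stop("distance matrix diagonal not zero")
  tr <- ape::nj(as.dist(dist))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' @importFrom stats as.dist
NULL

#' Fitch/Hartigan small-parsimony score of leaf states on a tree
#'
#' Minimum number of state changes needed to explain the leaf labelling,
#' computed by the count-based generalisation of Fitch's algorithm that is
#' exact on multifurcating trees. Ties in the ancestral assignment are
#' broken deterministically towards the alphabetically first state.
#'
#' @param tree a `phylo` tree (rooted or unrooted; unrooted trees are
#'   scored from their internal root node, which does not change the score).
#' @param leaf_states named character vector, names = tip labels.
#' @return integer score with attribute `assignment`: one optimal state per
#'   node (tips first, then internal nodes, in `phylo` node order).
#' @export
fitch_score <- function(tree, leaf_states) {
  tips <- tree$tip.label
  if (!all(tips %in% names(leaf_states))) {
    stop("unlabeled leaves: ",
         paste(setdiff(tips, names(leaf_states)), collapse = ", "))
  }
  states <- sort(unique(as.character(leaf_states[tips])))
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  children <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    children[[p]] <- c(children[[p]], tree$edge[e, 2L])
  }
  # postorder over internal nodes
  po <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 2L])
  internal_po <- c(po[po > n_tip], root)
  sets <- matrix(FALSE, n_node, length(states),
                 dimnames = list(NULL, states))
  sets[cbind(seq_len(n_tip),
             match(as.character(leaf_states[tips]), states))] <- TRUE
  score <- 0L
  for (v in internal_po) {
    kids <- children[[v]]
    votes <- colSums(sets[kids, , drop = FALSE])
    m <- max(votes)
    sets[v, ] <- votes == m
    score <- score + length(kids) - as.integer(m)
  }
  # top-down deterministic assignment: keep parent's state when possible,
  # otherwise first (alphabetical) state in the node's set
  assignment <- character(n_node)
  pre <- c(root, ape::reorder.phylo(tree, "cladewise")$edge[, 2L])
  parent <- integer(n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  for (v in pre) {
    if (v == root || !sets[v, assignment[parent[v]]]) {
      assignment[v] <- states[which(sets[v, ])[1L]]
    } else {
      assignment[v] <- assignment[parent[v]]
    }
  }
  structure(score, assignment = assignment)
}

#' Bootstrap support for an NJ tree by column resampling
#'
#' @param aln a `clone_alignment` (>= 3 records).
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param mode deletion mode passed to [pdistance_matrix()].
#' @return the point-estimate NJ tree with `node.label` = support fraction
#'   of each internal node over `n_reps` replicates.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L,
                              mode = "pairwise") {
  stopifnot(n_reps >= 1L)
  point <- nj_tree(pdistance_matrix(aln, mode))
  set.seed(seed)
  counts <- integer(point$Nnode)
  boot_trees <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(n_columns(aln), replace = TRUE)
    baln <- subset_alignment(aln, columns = cols)
    boot_trees[[b]] <- suppressMessages(nj_tree(pdistance_matrix(baln, mode)))
  }
  cl <- ape::prop.clades(point, boot_trees, rooted = FALSE)
  cl[is.na(cl)] <- 0L
  point$node.label <- cl / n_reps
  point
}

#' Read / write Newick trees
#'
#' Thin wrappers over \pkg{ape}'s Newick parser so externally built trees
#' (e.g. maximum-likelihood trees) can be supplied to downstream analyses.
#'
#' @param path Newick file.
#' @return `read_newick`: a `phylo`; `write_newick`: `path` invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree a `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
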