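# Independent oracles, coded from first principles and kept separate from
# the package's implementation paths.

# brute-force segregating sites and mean pairwise differences:
# explicit double loop over pairs and columns
oracle_site_stats <- function(mat) {
  drop <- apply(mat, 2, function(col) any(col %in% c("-", "N")))
  m <- mat[, !drop, drop = FALSE]
  S <- 0L
  for (j in seq_len(ncol(m))) {
    if (length(unique(m[, j])) > 1L) S <- S + 1L
  }
  total <- 0
  npair <- 0L
  n <- nrow(m)
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      d <- 0L
      for (j in seq_len(ncol(m))) if (m[i, j] != m[k, j]) d <- d + 1L
      total <- total + d
      npair <- npair + 1L
    }
  }
  list(S = S, pi_total = total / npair, n_sites = ncol(m))
}

# textbook Tajima (1989) formula, written independently
oracle_tajima <- function(S, pi_total, n) {
  if (S == 0) return(NA_real_)
  i <- 1:(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  V <- e1 * S + e2 * S * (S - 1)
  (pi_total - S / a1) / sqrt(V)
}

# D' from the 2x2 haplotype contingency table, parameterised by explicit
# gamete counts rather than per-site major alleles
oracle_dprime <- function(x, y) {
  ax <- names(sort(table(x), decreasing = TRUE))
  ay <- names(sort(table(y), decreasing = TRUE))
  pA <- mean(x == ax[1])
  pB <- mean(y == ay[1])
  pAB <- mean(x == ax[1] & y == ay[1])
  D <- pAB - pA * pB
  if (D == 0) return(0)
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  D / dmax
}

# genetic code from Biostrings, for codon oracles independent of the
# package's seqinr-derived table
oracle_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

# expected syn/nonsyn sites by direct neighbor enumeration
oracle_ng_sites <- function(codon) {
  gc <- oracle_code()
  nts <- c("A", "C", "G", "T")
  s <- 0L; n <- 0L
  ch <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (nt in nts[nts != ch[pos]]) {
    nb <- ch; nb[pos] <- nt
    aa <- gc[[paste(nb, collapse = "")]]
    if (aa == "*") next
    if (aa == gc[[codon]]) s <- s + 1L else n <- n + 1L
  }
  c(ES = s / 3, EN = n / 3)
}

# pathway counts by explicit recursion over substitution orderings
oracle_pathway <- function(a, b) {
  gc <- oracle_code()
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  walk <- function(cur, remaining) {
    if (length(remaining) == 0) return(list(c(0, 0)))
    out <- list()
    for (pos in remaining) {
      nxt <- cur; nxt[pos] <- cb[pos]
      if (gc[[paste(nxt, collapse = "")]] == "*") next
      step <- if (gc[[paste(nxt, collapse = "")]] ==
                  gc[[paste(cur, collapse = "")]]) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, setdiff(remaining, pos))) {
        out[[length(out) + 1]] <- step + tail
      }
    }
    out
  }
  paths <- walk(ca, which(ca != cb))
  if (length(paths) == 0) return(c(s = NA_real_, n = NA_real_))
  m <- do.call(rbind, paths)
  c(s = mean(m[, 1]), n = mean(m[, 2]))
}

# exhaustive small-parsimony score: enumerate all internal-state
# combinations of a phylo tree
oracle_fitch <- function(tree, leaf_states) {
  states <- unique(as.character(leaf_states))
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  combos <- expand.grid(rep(list(states), n_int), stringsAsFactors = FALSE)
  best <- Inf
  node_state <- character(n_tip + n_int)
  node_state[1:n_tip] <- as.character(leaf_states[tree$tip.label])
  for (r in seq_len(nrow(combos))) {
    node_state[(n_tip + 1):(n_tip + n_int)] <- unlist(combos[r, ])
    changes <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# random additive distance matrix from a random topology with known
# branch lengths; returns both
oracle_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  d <- ape::cophenetic.phylo(tr)
  list(tree = tr, dist = d[sort(rownames(d)), sort(rownames(d))])
}

random_alignment <- function(n, L, states = c("A", "C", "G", "T")) {
  mat <- matrix(sample(states, n * L, replace = TRUE), n, L)
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  alignment(mat, parse_labels = FALSE)
}
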