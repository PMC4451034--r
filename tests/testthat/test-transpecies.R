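test_that("species-monophyletic trees score the minimum with index 0", {
  tr <- ape::read.tree(text = "((A1,A2),(B1,B2));")
  sp <- c(A1 = "spA", A2 = "spA", B1 = "spB", B2 = "spB")
  res <- transpecies_test(tr, sp, n_perm = 99, seed = 1)
  expect_equal(res$observed_score, res$min_possible)
  expect_equal(res$intermixing_index, 0)

  # with enough leaves, monophyly is detected as significant clustering
  tr10 <- ape::read.tree(
    text = "(((A1,A2),(A3,(A4,A5))),((B1,B2),(B3,(B4,B5))));")
  sp10 <- setNames(rep(c("spA", "spB"), each = 5), tr10$tip.label)
  res10 <- transpecies_test(tr10, sp10, n_perm = 199, seed = 1)
  expect_equal(res10$intermixing_index, 0)
  expect_lte(res10$p_species_clustering, 0.05)

  expect_error(transpecies_test(tr, c(A1 = "x", A2 = "x", B1 = "x",
                                      B2 = "x"), n_perm = 99),
               ">= 2 species")
})

test_that("permutation p matches exhaustive enumeration on 8 leaves", {
  # two allele clades, each containing both species: the trans-species
  # configuration
  tr <- ape::read.tree(text = "(((A1,B1),(A2,B2)),((A3,B3),(A4,B4)));")
  sp <- setNames(rep(c("spA", "spB"), 4),
                 c("A1", "B1", "A2", "B2", "A3", "B3", "A4", "B4"))
  obs <- as.integer(fitch_score(tr, sp))

  # exhaustive null: all ways to place the 4 spA labels on 8 leaves
  tips <- tr$tip.label
  combos <- combn(8, 4)
  null_all <- apply(combos, 2, function(ix) {
    lab <- setNames(rep("spB", 8), tips)
    lab[tips[ix]] <- "spA"
    as.integer(fitch_score(tr, lab))
  })
  p_exact <- mean(null_all <= obs)

  res <- transpecies_test(tr, sp, n_perm = 999, seed = 42)
  expect_equal(res$observed_score, obs)
  expect_equal(res$p_species_clustering, p_exact, tolerance = 0.05)
  expect_gt(res$intermixing_index, 0)
})

test_that("permutation p-values are valid under the null", {
  set.seed(64)
  tr <- ape::rtree(10)
  tr$tip.label <- sprintf("t%d", 1:10)
  alpha <- 0.2
  n_perm <- 99
  hits <- 0
  n_rep <- 150
  for (r in seq_len(n_rep)) {
    sp <- setNames(sample(rep(c("x", "y"), 5)), tr$tip.label)
    res <- transpecies_test(tr, sp, n_perm = n_perm, seed = r)
    if (res$p_species_clustering <= alpha) hits <- hits + 1
  }
  bound <- alpha + 1 / (n_perm + 1)
  mc_slack <- 2.6 * sqrt(bound * (1 - bound) / n_rep)
  expect_lte(hits / n_rep, bound + mc_slack)
})

test_that("clade species sharing flags multi-species clusters", {
  tr <- ape::read.tree(text = "((A1,A2),(B1,B2));")
  clusters <- c(A1 = "Cath1", A2 = "Cath1", B1 = "Cath2", B2 = "Cath2")
  sp <- c(A1 = "Gmo", A2 = "Gch", B1 = "Gmo", B2 = "Gmo")
  tab <- clade_species_sharing(tr, clusters, sp)
  expect_equal(tab$n_species, c(2L, 1L))
  expect_equal(tab$trans_species, c(TRUE, FALSE))
})

test_that("simulated trans-species flags match generator truth", {
  d <- simulate_dataset(sim_config(seed = 8))
  cl <- assign_clusters(d$aln)
  tm <- d$truth$clone_map
  tr <- suppressMessages(nj_tree(pdistance_matrix(d$aln)))
  sp <- setNames(tm$species[match(rownames(d$aln$seq), tm$id)],
                 rownames(d$aln$seq))
  tab <- clade_species_sharing(tr, cl, sp)
  truth_flags <- vapply(sort(unique(cl$cluster)), function(k) {
    ids <- cl$id[cl$cluster == k]
    length(unique(tm$species[match(ids, tm$id)])) >= 2
  }, TRUE)
  expect_equal(tab$trans_species, unname(truth_flags))
})

test_that("genotype matrix one-hot encodes polymorphic sites", {
  mat <- rbind(s1 = c("A", "A", "C"), s2 = c("A", "C", "C"),
               s3 = c("A", "C", "C"), s4 = c("A", "A", "C"))
  aln <- alignment(mat, parse_labels = FALSE)
  X <- genotype_matrix(aln)
  # only site 2 is polymorphic: two indicator columns, centred
  expect_equal(ncol(X), 2L)
  expect_equal(attr(X, "sites"), 2L)
  expect_equal(unname(colSums(X)), c(0, 0))
  raw <- X[, "c2_A"] + 0.5  # uncentre: 2/2 split
  expect_equal(unname(raw), c(1, 0, 0, 1))

  expect_error(genotype_matrix(alignment(
    rbind(s1 = c("A", "A"), s2 = c("A", "A")), parse_labels = FALSE)),
    "no polymorphic sites")
})

test_that("PCA scores match an independent eigendecomposition", {
  set.seed(12)
  aln <- random_alignment(6, 8)
  X <- genotype_matrix(aln)
  pc_scores <- stats::prcomp(X, center = FALSE)$x
  eig <- eigen(tcrossprod(X))
  k <- 3
  for (j in seq_len(k)) {
    ours <- pc_scores[, j]
    theirs <- eig$vectors[, j] * sqrt(max(eig$values[j], 0))
    expect_true(isTRUE(all.equal(ours, theirs, tolerance = 1e-6,
                                 check.attributes = FALSE)) ||
                isTRUE(all.equal(ours, -theirs, tolerance = 1e-6,
                                 check.attributes = FALSE)))
  }
})

test_that("DAPC separates clearly distinct groups completely", {
  base <- rep("A", 60)
  other <- base
  other[1:18] <- "C"   # 30% divergent
  mat <- rbind(matrix(rep(base, 5), 5, byrow = TRUE),
               matrix(rep(other, 5), 5, byrow = TRUE))
  set.seed(4)
  mat[cbind(sample(10, 12, TRUE), sample(60, 12, TRUE))] <- "G"
  rownames(mat) <- sprintf("s%d", 1:10)
  aln <- alignment(mat, parse_labels = FALSE)
  X <- genotype_matrix(aln)
  groups <- setNames(rep(c("g1", "g2"), each = 5), rownames(mat))
  fit <- suppressWarnings(dapc_fit(X, groups, n_pca = 5, n_da = 3))
  expect_equal(fit$accuracy, 1)
  expect_equal(fit$n_da, 1L)  # clamped to groups - 1
  # between-group separation dwarfs within-group spread
  coord <- fit$coords[, 1]
  between <- abs(mean(coord[1:5]) - mean(coord[6:10]))
  within <- max(stats::sd(coord[1:5]), stats::sd(coord[6:10]))
  expect_gt(between, 5 * within)
})

test_that("allele-defined groups beat species-defined groups on
           simulated trans-species data", {
  accs <- t(vapply(1:3, function(s) {
    d <- simulate_dataset(sim_config(seed = s))
    cl <- assign_clusters(d$aln)
    scr <- screen_singletons(d$aln, cl)
    reps <- select_representatives(scr$corrected, cl)
    X <- genotype_matrix(reps)
    tm <- d$truth$clone_map
    rep_class <- vapply(seq_len(nrow(reps$meta)), function(i) {
      m <- reps$meta[i, ]
      cand <- tm[tm$barcode == m$barcode, ]
      rows <- match(cand$id, rownames(scr$corrected$seq))
      same <- apply(scr$corrected$seq[rows, , drop = FALSE], 1, paste,
                    collapse = "") ==
        paste(reps$seq[i, ], collapse = "")
      cand$class[which(same)[1]]
    }, "")
    da <- dapc_fit(X, setNames(rep_class, reps$meta$id))
    ds <- dapc_fit(X, setNames(reps$meta$species, reps$meta$id))
    c(allele = da$accuracy, species = ds$accuracy)
  }, c(allele = 0, species = 0)))
  expect_gt(mean(accs[, "allele"]), mean(accs[, "species"]))
})

test_that("DAPC coordinates are invariant to record order", {
  set.seed(21)
  aln <- random_alignment(12, 40)
  X <- genotype_matrix(aln)
  groups <- setNames(rep(c("a", "b", "c"), each = 4), rownames(aln$seq))
  f1 <- suppressWarnings(dapc_fit(X, groups, n_pca = 6, n_da = 2))
  perm <- sample(12)
  f2 <- suppressWarnings(dapc_fit(X[perm, ], groups, n_pca = 6, n_da = 2))
  # posteriors per record must agree regardless of input order
  expect_equal(f2$posterior[rownames(f1$posterior), ],
               f1$posterior, tolerance = 1e-6)
})
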