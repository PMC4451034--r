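mk_aln <- function(...) {
  seqs <- c(...)
  alignment(seqs)
}

test_that("auto clustering separates divergent groups at the threshold", {
  a <- paste(rep("A", 50), collapse = "")
  b <- paste(c(rep("A", 40), rep("C", 10)), collapse = "")  # 20% divergent
  aln <- mk_aln("100001-1.Gmo.Ice" = a, "100001-2.Gmo.Ice" = a,
                "100002-1.Gmo.Ice" = b, "100002-2.Gmo.Ice" = b)
  cl <- assign_clusters(aln, threshold = 0.10)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_false(cl$cluster[1] == cl$cluster[3])

  same <- mk_aln("100001-1.Gmo.Ice" = a, "100002-1.Gmo.Ice" = a)
  expect_equal(length(unique(assign_clusters(same)$cluster)), 1L)

  expect_error(assign_clusters(aln, threshold = 0), "threshold")
  expect_error(assign_clusters(aln, threshold = 1.2), "threshold")
})

test_that("auto clustering recovers simulated paralogs exactly", {
  d <- simulate_dataset(sim_config(seed = 7))
  cl <- assign_clusters(d$aln)
  truth <- d$truth$clone_map$paralog[match(cl$id, d$truth$clone_map$id)]
  expect_equal(length(unique(cl$cluster)), length(unique(truth)))
  # one-to-one mapping between clusters and true paralogs
  tab <- table(cl$cluster, truth)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("user-mode clustering reads labels from file", {
  a <- paste(rep("A", 30), collapse = "")
  aln <- mk_aln("100001-1.Gmo.Ice" = a, "100002-1.Gmo.Ice" = a)
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("id\tcluster", "100001-1.Gmo.Ice\tCath1",
               "100002-1.Gmo.Ice\tCath2"), tf)
  cl <- assign_clusters(aln, "user", labels_file = tf)
  expect_equal(cl$cluster, c("Cath1", "Cath2"))
})

# fixture for the singleton rule: individual I1 has 3 clones in one
# cluster; clone 2 carries a unique base at column 5
screen_fixture <- function(other_variable = FALSE) {
  base <- "AAAAAAAAAA"
  v5 <- function(s, ch) {
    substr(s, 5, 5) <- ch
    s
  }
  seqs <- c("100001-1.Gmo.Ice" = base,
            "100001-2.Gmo.Ice" = v5(base, "G"),
            "100001-3.Gmo.Ice" = base,
            "100002-1.Gmo.Ice" = if (other_variable) v5(base, "G") else base,
            "100002-2.Gmo.Ice" = base,
            "100002-3.Gmo.Ice" = base)
  alignment(seqs)
}

test_that("non-recurrent singletons are masked to the group majority", {
  aln <- screen_fixture(other_variable = FALSE)
  cl <- assign_clusters(aln)
  out <- screen_singletons(aln, cl)
  dec <- out$report[out$report$column == 5, ]
  expect_equal(dec$decision, "error_masked")
  expect_equal(dec$clone, "100001-2.Gmo.Ice")
  expect_equal(unname(out$corrected$seq["100001-2.Gmo.Ice", 5]), "A")
})

test_that("singletons recurring in another individual are kept as SNPs", {
  aln <- screen_fixture(other_variable = TRUE)
  cl <- assign_clusters(aln)
  out <- screen_singletons(aln, cl)
  dec <- out$report[out$report$column == 5, ]
  expect_true(all(dec$decision == "snp_retained"))
  expect_equal(unname(out$corrected$seq["100001-2.Gmo.Ice", 5]), "G")
  expect_true("100002" %in% unlist(strsplit(dec$evidence_individuals, ",")))
})

test_that("identical clones yield no masking decisions", {
  base <- "ACGTACGTAC"
  aln <- alignment(c("100001-1.Gmo.Ice" = base, "100001-2.Gmo.Ice" = base,
                     "100001-3.Gmo.Ice" = base))
  cl <- assign_clusters(aln)
  out <- screen_singletons(aln, cl)
  expect_equal(nrow(out$report), 0L)
  expect_identical(out$corrected$seq, aln$seq)
})

test_that("screening requires parseable barcodes", {
  aln <- suppressWarnings(alignment(c("weird" = "ACGT", "odd" = "ACGT")))
  cl <- assign_clusters(aln)
  expect_error(screen_singletons(aln, cl), "barcode")
})

test_that("screening is idempotent and leaves non-singleton columns alone", {
  d <- simulate_dataset(sim_config(seed = 5))
  cl <- assign_clusters(d$aln)
  once <- screen_singletons(d$aln, cl)
  twice <- screen_singletons(once$corrected, cl)
  expect_identical(twice$corrected$seq, once$corrected$seq)
  expect_equal(sum(twice$report$decision == "error_masked"), 0L)

  # masking never touches a column that is non-singleton within its group
  changed <- which(once$corrected$seq != d$aln$seq, arr.ind = TRUE)
  meta <- d$aln$meta
  clv <- cl$cluster[match(meta$id, cl$id)]
  for (r in seq_len(nrow(changed))) {
    i <- changed[r, 1]; j <- changed[r, 2]
    grp <- which(meta$barcode == meta$barcode[i] & clv == clv[i])
    col <- d$aln$seq[grp, j]
    expect_equal(sum(col == d$aln$seq[i, j]), 1L)  # was a true singleton
  }
})

test_that("representatives collapse identical forms and keep lone clones", {
  base <- "ACGTACGTAC"
  aln <- alignment(c("100001-1.Gmo.Ice" = base, "100001-2.Gmo.Ice" = base,
                     "100001-3.Gmo.Ice" = base))
  cl <- assign_clusters(aln)
  reps <- select_representatives(aln, cl)
  expect_equal(n_records(reps), 1L)
  expect_equal(reps$meta$id, "100001-cons.Gmo.Ice")
  expect_equal(reps$meta$n_clones, 3L)

  # one individual with clones in three clusters keeps all three
  a <- paste(rep("A", 40), collapse = "")
  b <- paste(c(rep("C", 20), rep("A", 20)), collapse = "")
  c3 <- paste(rep("G", 40), collapse = "")
  aln3 <- alignment(c("152027-1.Gch.Pac" = a, "152027-2.Gch.Pac" = b,
                      "152027-3.Gch.Pac" = c3))
  cl3 <- assign_clusters(aln3)
  expect_equal(length(unique(cl3$cluster)), 3L)
  reps3 <- select_representatives(aln3, cl3)
  expect_equal(n_records(reps3), 3L)
  expect_setequal(reps3$meta$id,
                  c("152027-1.Gch.Pac", "152027-2.Gch.Pac",
                    "152027-3.Gch.Pac"))
})

test_that("representative count matches generator truth without errors", {
  cfg <- sim_config(seed = 9, error_rate = 0)
  d <- simulate_dataset(cfg)
  cl <- assign_clusters(d$aln)
  scr <- screen_singletons(d$aln, cl)
  reps <- select_representatives(scr$corrected, cl)
  truth_forms <- nrow(unique(d$truth$clone_map[c("barcode", "class")]))
  expect_equal(n_records(reps), truth_forms)
})

test_that("form table reproduces the study bookkeeping shape", {
  d <- simulate_dataset(sim_config(seed = 4))
  cl <- assign_clusters(d$aln)
  scr <- screen_singletons(d$aln, cl)
  tab <- tabulate_forms(scr$corrected, cl)
  tot <- attr(tab, "totals")
  expect_equal(unname(tot["individuals"]), 27L)
  expect_equal(unname(tot["clones"]), 97L)
  expect_equal(unname(tot["origins"]), 12L)
  expect_equal(nrow(tab), 27L)
  expect_true(all(tab$n_forms >= 1))

  # per-individual forms match truth when no errors are injected
  cfg0 <- sim_config(seed = 4, error_rate = 0)
  d0 <- simulate_dataset(cfg0)
  cl0 <- assign_clusters(d0$aln)
  tab0 <- tabulate_forms(screen_singletons(d0$aln, cl0)$corrected, cl0)
  truth0 <- aggregate(class ~ barcode,
                      data = unique(d0$truth$clone_map[c("barcode", "class")]),
                      FUN = length)
  expect_equal(tab0$n_forms[match(truth0$barcode, tab0$barcode)],
               truth0$class)

  empty <- tabulate_forms(subset_alignment(d$aln, integer(0)), cl)
  expect_equal(nrow(empty), 0L)
})
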