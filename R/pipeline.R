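#' Run the full clone-library analysis pipeline
#'
#' Orchestrates the analysis graph: cluster assignment, singleton PCR-error
#' screening, representative selection, NJ trees, sliding-window diversity
#' statistics, linkage disequilibrium, per-codon selection scans (when an
#' annotation is available), and the trans-species permutation test with
#' DAPC. All stages are pure functions of (input, config, seed); re-running
#' with the same inputs gives identical outputs.
#'
#' @param aln a `clone_alignment` (e.g. from [read_alignment()] or a
#'   generator dataset's `$aln`).
#' @param annotation optional `gene_annotation`; when the alignment is in
#'   reference coordinates the identity projection is used, otherwise pass
#'   `ref_row` to project through a reference record.
#' @param ref_row optional record id carrying the annotation coordinates.
#' @param cluster_threshold divergence cut for paralog clustering (0.10).
#' @param window,step sliding-window parameters (defaults 100/25).
#' @param maf_count minor-allele count threshold for LD (default 3).
#' @param n_perm permutations for the trans-species test (default 999).
#' @param n_pca,n_da DAPC dimensions (defaults 10/3, the reproduction
#'   profile).
#' @param seed RNG seed for permutation and bootstrap stages.
#' @param out_dir optional directory; when given, writes representatives
#'   FASTA, Newick trees, window/LD/codon TSVs, a trans-species JSON-like
#'   summary TSV and a run log.
#' @return list with elements `clusters`, `screen` (report), `corrected`,
#'   `representatives`, `form_table`, `tree` (NJ on representatives),
#'   `windows` (per-cluster window stats), `ld` (per-cluster), `codon`
#'   (per region, when annotated), `transpecies`, `dapc_alleles`,
#'   `dapc_species`.
#' @export
run_all <- function(aln, annotation = NULL, ref_row = NULL,
                    cluster_threshold = 0.10, window = 100L, step = 25L,
                    maf_count = 3L, n_perm = 999L, n_pca = 10L, n_da = 3L,
                    seed = 1L, out_dir = NULL) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("clustering ", n_records(aln), " clones at threshold ",
      cluster_threshold)
  clusters <- assign_clusters(aln, "auto", threshold = cluster_threshold)
  k <- length(unique(clusters$cluster))
  say("  ", k, " cluster(s)")

  say("screening singleton PCR errors")
  scr <- screen_singletons(aln, clusters)
  say("  ", attr(scr$report, "n_masked"), " site(s) masked, ",
      sum(scr$report$decision == "snp_retained"), " singleton SNP(s) retained")

  reps <- select_representatives(scr$corrected, clusters)
  say("  ", n_records(reps), " representative(s) from ",
      n_records(aln), " clones")
  form_table <- tabulate_forms(scr$corrected, clusters)

  rep_clusters <- structure(
    data.frame(id = reps$meta$id, cluster = reps$meta$cluster,
               stringsAsFactors = FALSE),
    class = c("cluster_assignment", "data.frame"))
  tree <- nj_tree(pdistance_matrix(reps))

  proj <- NULL
  if (!is.null(annotation)) {
    proj <- if (is.null(ref_row)) annotation_columns(annotation) else
      project_annotation(annotation, reps, ref_row)
  }

  windows <- list()
  ld <- list()
  codon <- list()
  for (cl in sort(unique(reps$meta$cluster))) {
    sub <- subset_alignment(reps, reps$meta$cluster == cl)
    if (n_records(sub) < 4L) next
    windows[[cl]] <- sliding_windows(sub, window, step)
    ld[[cl]] <- ld_matrix(sub, maf_count)
    if (!is.null(proj)) {
      sub_tree <- ape::keep.tip(tree, rownames(sub$seq))
      exon123 <- unlist(proj[c("exon1", "exon2", "exon3")], use.names = FALSE)
      codon[[cl]] <- list(
        exon4 = region_scan(sub, sub_tree, proj[["exon4"]]),
        exons123 = region_scan(sub, sub_tree, exon123))
    }
  }

  species <- stats::setNames(reps$meta$species, reps$meta$id)
  say("trans-species permutation test (", n_perm, " permutations)")
  ts <- transpecies_test(tree, species, clusters = rep_clusters,
                         n_perm = n_perm, seed = seed)
  say(sprintf("  intermixing index %.3f, P(null <= obs) = %.4f",
              ts$intermixing_index, ts$p_species_clustering))

  X <- genotype_matrix(reps, maf_min = 1L)
  allele_groups <- stats::setNames(reps$meta$cluster, reps$meta$id)
  dapc_a <- dapc_fit(X, allele_groups, n_pca = n_pca,
                     n_da = min(n_da, length(unique(allele_groups)) - 1L))
  dapc_s <- dapc_fit(X, species, n_pca = n_pca,
                     n_da = min(n_da, length(unique(species)) - 1L))
  say(sprintf("DAPC reassignment accuracy: alleles %.3f, species %.3f",
              dapc_a$accuracy, dapc_s$accuracy))

  res <- list(clusters = clusters, screen = scr$report,
              corrected = scr$corrected, representatives = reps,
              form_table = form_table, tree = tree, windows = windows,
              ld = ld, codon = codon, transpecies = ts,
              dapc_alleles = dapc_a, dapc_species = dapc_s)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_alignment(scr$corrected, file.path(out_dir, "corrected.fasta"))
    write_alignment(reps, file.path(out_dir, "representatives.fasta"))
    write_newick(tree, file.path(out_dir, "representatives.nwk"))
    utils::write.table(scr$report, file.path(out_dir, "screen_decisions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(form_table, file.path(out_dir, "form_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (cl in names(windows)) {
      utils::write.table(windows[[cl]],
                         file.path(out_dir, paste0("windows_", cl, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (nrow(ld[[cl]]$table) > 0L) {
        utils::write.table(ld[[cl]]$table,
                           file.path(out_dir, paste0("ld_", cl, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    for (cl in names(codon)) {
      for (reg in names(codon[[cl]])) {
        utils::write.table(
          codon[[cl]][[reg]],
          file.path(out_dir, paste0("codon_", cl, "_", reg, ".tsv")),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    ts_df <- data.frame(observed_score = ts$observed_score,
                        min_possible = ts$min_possible,
                        intermixing_index = ts$intermixing_index,
                        p_species_clustering = ts$p_species_clustering)
    utils::write.table(ts_df, file.path(out_dir, "transpecies.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  res
}
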