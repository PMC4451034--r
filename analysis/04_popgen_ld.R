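#!/usr/bin/env Rscript
# Sliding-window diversity (pi, Watterson's theta, Tajima's D; 100 bp
# windows, 25 bp step) per paralog cluster, linkage disequilibrium D'
# among high-frequency sites, and the four-gamete check.
suppressMessages(library(transpoly))

reps <- read_alignment("results/representatives.fasta")
meta <- read.delim("results/representatives_meta.tsv",
                   colClasses = c(barcode = "character"))
e4 <- annotation_columns(default_annotation())$exon4

for (k in sort(unique(meta$cluster))) {
  sub <- subset_alignment(reps, meta$cluster == k)
  if (n_records(sub) < 6) next
  w <- sliding_windows(sub, window = 100, step = 25)
  write.table(w, sprintf("results/windows_%s.tsv", k), sep = "\t",
              row.names = FALSE, quote = FALSE)
  we4 <- w[w$start >= min(e4) & w$end <= max(e4), ]
  cat(sprintf("%s (n=%d): max D %.2f, max exon-4 D %.2f, windows |D|>2: %d\n",
              k, n_records(sub), max(w$tajima_D, na.rm = TRUE),
              suppressWarnings(max(we4$tajima_D, na.rm = TRUE)),
              sum(abs(w$tajima_D) > 2, na.rm = TRUE)))

  ld <- ld_matrix(sub, maf_min = 3L)
  if (nrow(ld$table) > 0) {
    write.table(ld$table, sprintf("results/ld_%s.tsv", k), sep = "\t",
                row.names = FALSE, quote = FALSE)
    cat(sprintf("  LD: %d site pairs, mean |D'| = %.2f\n",
                nrow(ld$table), mean(abs(ld$table$D_prime))))
  }
  fg <- four_gamete_pairs(sub, maf_min = 2L)
  cat(sprintf("  four-gamete pairs: %d\n", nrow(fg)))
}
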