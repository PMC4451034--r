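#!/usr/bin/env Rscript
# Cluster the clones into paralogs, screen singleton PCR errors with the
# within-individual / cross-individual recurrence rule, and collapse the
# library to one representative per distinct form per individual.
suppressMessages(library(transpoly))

aln <- read_alignment("results/clones_balancing.fasta")
cl <- assign_clusters(aln, threshold = 0.10)
cat("clusters found:", paste(sort(unique(cl$cluster)), collapse = " "), "\n")

scr <- screen_singletons(aln, cl)
cat(sum(scr$report$decision == "error_masked"), "sites masked as PCR error;",
    sum(scr$report$decision == "snp_retained"),
    "recurrent singletons retained as SNPs\n")

reps <- select_representatives(scr$corrected, cl)
tab <- tabulate_forms(scr$corrected, cl)
tot <- attr(tab, "totals")
cat(tot["clones"], "clones from", tot["individuals"],
    "individuals reduced to", n_records(reps), "representatives\n")

write_alignment(reps, "results/representatives.fasta")
write.table(cl, "results/clusters.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(scr$report, "results/screen_decisions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cbind(reps$meta), "results/representatives_meta.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(tab, "results/form_table.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
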