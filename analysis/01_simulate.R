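#!/usr/bin/env Rscript
# Generate the two study datasets: a clone library under the balancing
# regime (allele classes older than every species split) and a neutral
# control in which allele variation postdates speciation. Both use the
# bookkeeping table's design: 27 individuals, 97 clones, 3 paralogs.
suppressMessages(library(transpoly))

dir.create("results", showWarnings = FALSE)
seed <- 1L

bal <- simulate_dataset(sim_config(seed = seed))
neu <- neutral_control(sim_config(seed = seed))

write_alignment(bal$aln, "results/clones_balancing.fasta")
write_alignment(neu$aln, "results/clones_neutral.fasta")
write.table(bal$truth$clone_map, "results/truth_balancing.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(neu$truth$clone_map, "results/truth_neutral.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(bal$truth$errors, "results/injected_errors.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("balancing:", n_records(bal$aln), "clones;",
    nrow(bal$truth$errors), "injected PCR errors\n")
cat("neutral:  ", n_records(neu$aln), "clones;",
    nrow(neu$truth$errors), "injected PCR errors\n")
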