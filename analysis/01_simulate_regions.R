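#!/usr/bin/env Rscript
# Simulate the ancestral region and the two derived lineages, and write
# the sequences, annotations and truth logs that the downstream
# comparisons use.

source("analysis/00_config.R")

out <- ensure_dir(file.path(RESULTS_DIR, "sim"))
sim <- study_pair()

cat(sprintf("ancestor: %d bp, %d genes, %d ancestral TEs\n",
            region_length(sim$ancestor),
            nrow(gene_annotations(sim$ancestor)),
            nrow(te_annotations(sim$ancestor))))
for (side in c("a", "b")) {
  lin <- sim[[side]]
  cat(sprintf("%s: %d bp (%+d vs ancestor), %d events logged\n",
              lin$region$name, region_length(lin$region),
              region_length(lin$region) - region_length(sim$ancestor),
              length(lin$log$events)))
  stopifnot(identical(replay_truth_log(sim$ancestor, lin$log)$seq,
                      lin$region$seq))
  write_region_fasta(lin$region,
                     file.path(out, paste0(lin$region$name, ".fa")))
  write_region_gff3(lin$region,
                    file.path(out, paste0(lin$region$name, ".gff3")))
  write_truth_log(lin$log,
                  file.path(out, paste0(lin$region$name, "_truth.json")))
}
write_region_fasta(sim$ancestor, file.path(out, "ancestor.fa"))
write_region_gff3(sim$ancestor, file.path(out, "ancestor.gff3"))
cat("truth logs replay to the derived sequences exactly\n")
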