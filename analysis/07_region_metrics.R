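#!/usr/bin/env Rscript
# Region-size variation across the study species (from the published
# segment sizes) and sequence composition of the simulated regions.

source("analysis/00_config.R")

out <- ensure_dir(file.path(RESULTS_DIR, "metrics"))

entries <- rbind(size_delta("O. nivara", 214, 202),
                 size_delta("O. glaberrima", 190, 309),
                 size_delta("O. punctata", 192, 339),
                 size_delta("O. australiensis", 190, 401),
                 size_delta("O. brachyantha", 150, 342),
                 size_delta("Sorghum", 138, 313))
tbl <- table1_report(entries)
cat("size variation relative to the reference region (kb):\n")
print(tbl, row.names = FALSE)
write_size_report(tbl, file.path(out, "size_variation.tsv"))
cat("  wrote", file.path(out, "size_variation.tsv"), "\n")

sim <- study_pair()
for (side in c("a", "b")) {
  reg <- sim[[side]]$region
  cf <- composition_fractions(reg)
  cat(sprintf("\ncomposition of %s (%d bp):\n", reg$name,
              region_length(reg)))
  print(cf, row.names = FALSE, digits = 3)
  write_tsv(cf, file.path(out, paste0("composition_", reg$name, ".tsv")))
}
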