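#!/usr/bin/env Rscript
# Anchor simulated clone end-sequence pairs from lineage B onto the
# lineage A reference using the three orthologous-clone criteria, then
# select a minimum tiling set.

source("analysis/00_config.R")

sim <- study_pair()
ref <- sim$a$region
bseq <- sim$b$region$seq
nb <- nchar(bseq)
rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

set.seed(SIM_SEED + 1L)
# simulated BAC-like clones on lineage B: end pairs read inward
clone_starts <- seq(1000, nb - 165000, by = 45000)
pairs <- lapply(seq_along(clone_starts), function(i) {
  s <- clone_starts[i]
  len <- sample(120000:160000, 1)
  e <- min(s + len, nb - 600)
  list(clone_id = sprintf("BB%03d", i),
       end1 = substr(bseq, s, s + 499),
       end2 = rc(substr(bseq, e - 499, e)))
})

anchors <- do.call(rbind, lapply(pairs, map_end_pair, reference = ref,
                                 min_span = 100000, max_span = 500000))
cat(sprintf("%d clones mapped, %d accepted by the three criteria\n",
            nrow(anchors), sum(anchors$accepted)))
sel <- select_tiling_clones(anchors, c(1, region_length(ref)))
cat(sprintf("minimum tiling set: %s (%.1f%% of the reference covered)\n",
            paste(sel, collapse = ", "), 100 * attr(sel, "coverage")))

out <- ensure_dir(file.path(RESULTS_DIR, "anchoring"))
write_tsv(anchors, file.path(out, "anchors.tsv"))
write_tsv(data.frame(clone_id = as.character(sel),
                     coverage = attr(sel, "coverage")),
          file.path(out, "tiling_selection.tsv"))
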