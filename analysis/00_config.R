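# Shared configuration for the analysis drivers. Every driver sources
# this file and re-derives the same deterministic simulation, so each
# script can be run on its own from the repository root.

library(retroscape)

RESULTS_DIR <- "results"
SIM_SEED <- 2011L

# The study pair: lineage A emulates an expanded Asian-rice-like region
# (many young lineage-specific LTR-retrotransposon insertions); lineage B
# emulates a contracted African-rice-like region with fewer insertions, a
# solo-LTR reduction, one large (> 3 kb) deletion and a segmental
# inversion with one breakpoint inside an ancestral element.
study_pair_config <- function() {
  base <- sim_config(
    seed = SIM_SEED,
    region_length = 300000,
    n_genes_per_cluster = 6,
    n_ancestral_tes = 8,
    tsd_length = 5,
    r = 1.3e-8)
  # pick the ancestral element carrying the inversion breakpoint from the
  # deterministic ancestor: one well clear of the 37-kb deletion window
  anc <- simulate_ancestral_region(base)
  tes <- te_annotations(anc)
  bp_el <- tes$id[tes$start > 150000 & tes$end < 240000][1]
  stopifnot(!is.na(bp_el))
  base$lineage_a <- list(lineage = "lineageA", age = 5e5, n_te = 9)
  base$lineage_b <- list(lineage = "lineageB", age = 5e5, n_te = 3,
                         solo_ltr = 1,
                         indels = list(list(type = "del", size = 37000,
                                            start = 60000)),
                         inversion = list(size = 20000,
                                          breakpoint_in_element = bp_el))
  base
}

study_pair <- function() simulate_region_pair(study_pair_config())

ensure_dir <- function(path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  path
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat("  wrote", path, "\n")
}
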