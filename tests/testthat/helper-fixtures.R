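# Shared fixtures for the test suite; everything is generated in code.

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Concordance of TSD polarization calls against the simulator truth.
polarization_concordance <- function(sim, max_mismatch = 0) {
  bl <- build_colinearity_blocks(sim$a$region, sim$b$region)
  calls <- classify_te_insertions(sim$a$region, sim$b$region, bl,
                                  max_mismatch = max_mismatch)
  tr <- truth_insertions(sim)
  m <- merge(calls, tr, by.x = "element_id", by.y = "id")
  want <- ifelse(m$lineage == "ancestral", "shared",
                 paste0("unique_to_", m$lineage))
  list(accuracy = mean(m$status == want), n = nrow(m))
}

# A noiseless pair with the requested planted/ancestral element counts.
noiseless_pair <- function(seed, n_a = 7L, n_b = 5L, n_ancestral = 6L,
                           region_length = 250000L) {
  simulate_region_pair(sim_config(
    seed = seed, region_length = region_length,
    n_ancestral_tes = n_ancestral,
    lineage_a = list(age = 0, n_te = n_a, substitutions = FALSE),
    lineage_b = list(age = 0, n_te = n_b, substitutions = FALSE)))
}

# Brute-force minimum-cardinality maximum-coverage interval subset.
brute_force_tiling <- function(spans, target) {
  n <- nrow(spans)
  cover_len <- function(idx) {
    if (length(idx) == 0L) return(0L)
    ir <- IRanges::IRanges(start = pmax(spans$span_start[idx], target[1L]),
                           end = pmin(spans$span_end[idx], target[2L]))
    ir <- ir[IRanges::start(ir) <= IRanges::end(ir)]
    if (length(ir) == 0L) return(0L)
    sum(IRanges::width(IRanges::reduce(ir)))
  }
  best_cov <- 0L; best_k <- n + 1L
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    cv <- cover_len(idx)
    if (cv > best_cov || (cv == best_cov && length(idx) < best_k)) {
      best_cov <- cv; best_k <- length(idx)
    }
  }
  list(coverage = best_cov, k = best_k)
}

# Fig-4-style gene presence instance: five genes present in the three AA
# taxa, absent in the BB taxon and the outgroup.
gene_presence_instance <- function() {
  st <- ape::read.tree(
    text = "(((sativa,nivara),glaberrima),punctata,sorghum);")
  st <- ape::root(st, outgroup = "sorghum", resolve.root = TRUE)
  genes <- c("a.1", "b.1", "12.3", "b.2", "a.2")
  tab <- matrix(0L, length(genes), length(st$tip.label),
                dimnames = list(genes, st$tip.label))
  tab[, c("sativa", "nivara", "glaberrima")] <- 1L
  aa <- c("sativa", "nivara", "glaberrima")
  scenarios <- list(
    aa_lineage_gains = list(
      list(type = "gain", branch = aa, genes = "a.1"),
      list(type = "gain", branch = aa, genes = "b.1"),
      list(type = "gain", branch = aa, genes = c("12.3", "b.2", "a.2"))),
    presplit_gains_bb_losses = list(
      list(type = "gain", branch = c(aa, "punctata"), genes = "a.1"),
      list(type = "gain", branch = c(aa, "punctata"), genes = "b.1"),
      list(type = "gain", branch = c(aa, "punctata"),
           genes = c("12.3", "b.2", "a.2")),
      list(type = "loss", branch = "punctata", genes = c("a.1", "b.1")),
      list(type = "loss", branch = "punctata",
           genes = c("12.3", "b.2", "a.2"))))
  list(tree = st, table = tab, scenarios = scenarios)
}

# Two-subpopulation marker frequencies: 6 diagnostic (fixed in g1, absent
# in g2) plus 6 shared polymorphic markers segregating at 0.5 in both.
two_group_freqs <- function() {
  mk <- sprintf("R%02d", 1:12)
  list(markers = mk,
       g1 = stats::setNames(c(rep(1, 6), rep(0.5, 6)), mk),
       g2 = stats::setNames(c(rep(0, 6), rep(0.5, 6)), mk))
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
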