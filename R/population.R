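#' Sample a population marker matrix from per-group insertion frequencies
#'
#' Draws a varieties x markers matrix of presence (1) / absence (0) /
#' missing (NA) calls. Each subpopulation has its own per-marker presence
#' frequency; marker frequencies are specified, not evolved (no
#' coalescent). Missing-data injection is off by default.
#'
#' @param markers Character vector of marker ids.
#' @param pop_config List with `groups`: a list of
#'   `list(name, n, freq = <named per-marker frequencies>)`; optional
#'   `missing_rate` (default 0).
#' @param seed RNG seed.
#' @return Integer matrix (rownames variety ids, colnames marker ids) with
#'   attribute `groups`: named character vector of subpopulation labels.
#' @export
generate_population <- function(markers, pop_config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- pop_config$groups
  missing_rate <- pop_config$missing_rate %||% 0
  stopifnot(length(groups) >= 1L, missing_rate >= 0, missing_rate <= 1)
  rows <- list(); labels <- character()
  for (g in groups) {
    freq <- g$freq[markers]
    if (anyNA(freq) || any(freq < 0) || any(freq > 1))
      stop("marker frequencies must be in [0, 1] and cover all markers")
    for (i in seq_len(g$n)) {
      calls <- as.integer(stats::runif(length(markers)) < freq)
      if (missing_rate > 0) {
        miss <- stats::runif(length(markers)) < missing_rate
        calls[miss] <- NA_integer_
      }
      vid <- sprintf("%s_%02d", g$name, i)
      rows[[vid]] <- calls
      labels[vid] <- g$name
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- markers
  attr(m, "groups") <- labels
  m
}

#' Simulate a structured population segregating insertion markers
#'
#' Builds a base haplotype (the regional sequence without any of the
#' polymorphic elements), plants one LTR element specification per marker
#' at well-separated sites, designs junction and empty-site primer pairs
#' for each marker, and samples a presence/absence matrix from the
#' group frequencies. Variety sequences can then be materialized for
#' in-silico genotyping with [call_junction_presence()].
#'
#' @param groups As in [generate_population()] (`freq` may be a single
#'   number applied to all markers, or a named vector).
#' @param n_markers Number of insertion markers.
#' @param region_length Base haplotype length in bp.
#' @param element_length Total element length in bp (default 6000; larger
#'   than the default PCR `max_amplicon`, so an occupied site never
#'   yields an empty-site product).
#' @param ltr_length LTR length in bp.
#' @param tsd_length Target-site duplication length in bp.
#' @param primer_length Primer length in bp.
#' @param missing_rate Probability of a missing call (default 0).
#' @param seed RNG seed.
#' @return List of class `population_sim`: `base_seq`, `markers` (list of
#'   marker definitions, see [marker_def()]), `sites`, `element_seqs`,
#'   `calls` (the truth matrix with `groups` attribute),
#'   `tsd_length`.
#' @export
simulate_population <- function(groups, n_markers = 12L,
                                region_length = 30000L,
                                element_length = 6000L, ltr_length = 1000L,
                                tsd_length = 5L, primer_length = 20L,
                                missing_rate = 0, seed = 1L) {
  set.seed(seed)
  base_seq <- random_dna(region_length)
  spacing <- (region_length - 2000L) %/% (n_markers + 1L)
  if (spacing < 1000L) stop("region too short for the requested markers")
  sites <- 1000L + spacing * seq_len(n_markers)
  marker_ids <- sprintf("R%02d", seq_len(n_markers))
  element_seqs <- lapply(seq_len(n_markers), function(i)
    te_element(element_length - 2L * ltr_length, ltr_length,
               id = marker_ids[i])$seq)
  names(element_seqs) <- marker_ids
  pl <- primer_length
  markers <- lapply(seq_len(n_markers), function(i) {
    s <- sites[i]
    up <- substr(base_seq, s - 140L, s - 141L + pl)
    elem <- element_seqs[[i]]
    junction_rev <- revcomp(substr(elem, 181L, 180L + pl))
    empty_rev <- revcomp(substr(base_seq, s + tsd_length + 120L,
                                s + tsd_length + 119L + pl))
    marker_def(marker_ids[i], junction = c(up, junction_rev),
               empty_site = c(up, empty_rev))
  })
  names(markers) <- marker_ids
  groups <- lapply(groups, function(g) {
    if (length(g$freq) == 1L && is.null(names(g$freq)))
      g$freq <- stats::setNames(rep(g$freq, n_markers), marker_ids)
    g
  })
  calls <- generate_population(marker_ids,
                               list(groups = groups,
                                    missing_rate = missing_rate))
  structure(list(base_seq = base_seq, markers = markers, sites = sites,
                 element_seqs = element_seqs, calls = calls,
                 tsd_length = tsd_length),
            class = "population_sim")
}

#' Materialize one variety's regional sequence
#'
#' Inserts, right to left, every element the variety carries (missing
#' calls are materialized as absent).
#'
#' @param sim A `population_sim`.
#' @param variety Variety id (rowname of `sim$calls`).
#' @return Character sequence.
#' @export
materialize_variety <- function(sim, variety) {
  calls <- sim$calls[variety, ]
  seq <- sim$base_seq
  t <- sim$tsd_length
  for (i in rev(seq_along(calls))) {
    if (isTRUE(calls[i] == 1L)) {
      s <- sim$sites[i]
      site_seq <- substr(seq, s, s + t - 1L)
      seq <- paste0(substr(seq, 1L, s + t - 1L),
                    sim$element_seqs[[i]], site_seq,
                    substr(seq, s + t, nchar(seq)))
    }
  }
  seq
}

#' Insertion-marker definition
#'
#' @param marker_id Marker id (stored verbatim).
#' @param junction Length-2 character vector: forward and reverse primer
#'   of the insertion-junction (or inversion-boundary) assay.
#' @param empty_site Optional length-2 vector: primers of the empty-site
#'   assay.
#' @param junction_type `"insertion_junction"` (default) or
#'   `"inversion_boundary"` (same machinery, different interpretation).
#' @return A `marker_def` list.
#' @export
marker_def <- function(marker_id, junction, empty_site = NULL,
                       junction_type = "insertion_junction") {
  stopifnot(length(junction) == 2L, all(nchar(junction) > 0))
  if (!is.null(empty_site))
    stopifnot(length(empty_site) == 2L, all(nchar(empty_site) > 0))
  structure(list(marker_id = marker_id, junction = toupper(junction),
                 empty_site = if (is.null(empty_site)) NULL
                 else toupper(empty_site),
                 junction_type = junction_type),
            class = "marker_def")
}

# Sizes of the in-silico PCR products of a convergent primer pair (exact
# matching, both orientations).
pcr_product_sizes <- function(seq, fwd, rev, max_amplicon) {
  find_all <- function(p) {
    m <- gregexpr(p, seq, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer() else as.integer(m)
  }
  sizes <- integer()
  for (orient in 1:2) {
    f <- if (orient == 1L) fwd else rev
    r <- if (orient == 1L) rev else fwd
    fs <- find_all(f)
    rs <- find_all(revcomp(r))
    for (i in fs) {
      for (j in rs) {
        size <- j + nchar(r) - i
        if (j >= i && size <= max_amplicon)
          sizes <- c(sizes, size)
      }
    }
  }
  sizes
}

#' In-silico genotyping of an insertion marker
#'
#' Emulates junction PCR: exact primer matches in convergent orientation
#' within `max_amplicon` constitute a productive amplicon. A productive
#' insertion-junction assay calls `present`; a productive empty-site
#' assay calls `absent`; neither calls `missing`; conflicting productive
#' assays call `missing` with a `conflict` attribute.
#'
#' @param variety_seq The variety's regional sequence.
#' @param marker A [marker_def()].
#' @param max_amplicon Maximum productive amplicon size in bp
#'   (default 5000).
#' @return `"present"`, `"absent"` or `"missing"`.
#' @export
call_junction_presence <- function(variety_seq, marker,
                                   max_amplicon = 5000L) {
  variety_seq <- toupper(variety_seq)
  junction_ok <- length(pcr_product_sizes(variety_seq, marker$junction[1L],
                                          marker$junction[2L],
                                          max_amplicon)) > 0L
  empty_ok <- !is.null(marker$empty_site) &&
    length(pcr_product_sizes(variety_seq, marker$empty_site[1L],
                             marker$empty_site[2L], max_amplicon)) > 0L
  if (junction_ok && empty_ok) {
    out <- "missing"
    attr(out, "conflict") <- TRUE
    return(out)
  }
  if (junction_ok) return("present")
  if (empty_ok) return("absent")
  "missing"
}

#' Genotype every variety of a simulated population
#'
#' @param sim A `population_sim`.
#' @param max_amplicon Passed to [call_junction_presence()].
#' @return Integer matrix parallel to `sim$calls` (1/0/NA).
#' @export
genotype_population <- function(sim, max_amplicon = 5000L) {
  vids <- rownames(sim$calls)
  out <- matrix(NA_integer_, length(vids), length(sim$markers),
                dimnames = list(vids, names(sim$markers)))
  for (v in vids) {
    seq <- materialize_variety(sim, v)
    for (m in names(sim$markers)) {
      call <- call_junction_presence(seq, sim$markers[[m]], max_amplicon)
      out[v, m] <- switch(call, present = 1L, absent = 0L, NA_integer_)
    }
  }
  attr(out, "groups") <- attr(sim$calls, "groups")
  out
}

#' Per-group marker frequencies with fixation and diagnostic flags
#'
#' Frequency is present / (present + absent) per group, excluding missing
#' calls. A marker is `fixed` in a group at frequency 1 with at least one
#' informative call, and `diagnostic` for a group when fixed there and at
#' frequency 0 in every other group. Groups with no informative calls get
#' `NA`.
#'
#' @param m Marker matrix (1/0/NA; rownames varieties).
#' @param groups Named character vector of group labels per variety
#'   (default: the matrix's `groups` attribute).
#' @return Data frame: `marker`, `group`, `n_informative`, `frequency`,
#'   `fixed`, `diagnostic`.
#' @export
marker_frequencies <- function(m, groups = attr(m, "groups")) {
  if (is.null(groups)) stop("group labels required")
  groups <- groups[rownames(m)]
  if (anyNA(groups)) stop("group labels must cover all varieties")
  gl <- unique(groups)
  rows <- list()
  for (mk in colnames(m)) {
    freqs <- stats::setNames(rep(NA_real_, length(gl)), gl)
    ninf <- stats::setNames(integer(length(gl)), gl)
    for (g in gl) {
      x <- m[groups == g, mk]
      ninf[g] <- sum(!is.na(x))
      if (ninf[g] > 0L) freqs[g] <- mean(x, na.rm = TRUE)
    }
    for (g in gl) {
      fixed <- !is.na(freqs[g]) && freqs[g] == 1
      others <- freqs[setdiff(gl, g)]
      diagnostic <- fixed && length(others) > 0L &&
        all(!is.na(others)) && all(others == 0)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, group = g, n_informative = ninf[g],
        frequency = freqs[g], fixed = fixed, diagnostic = diagnostic,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binary distance matrix from presence/absence calls
#'
#' `d(i, j)` is the proportion of mismatching markers among markers
#' informative in both varieties (pairwise deletion of missing calls);
#' the Jaccard complement is available as an option. A pair with zero
#' shared informative markers is an error.
#'
#' @param m Marker matrix (1/0/NA).
#' @param method `"mismatch"` (default) or `"jaccard"`.
#' @return Symmetric labeled distance matrix.
#' @export
binary_distance_matrix <- function(m, method = c("mismatch", "jaccard")) {
  method <- match.arg(method)
  n <- nrow(m)
  stopifnot(n >= 3L)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(ok))
        stop(sprintf("no shared informative markers: %s vs %s",
                     rownames(m)[i], rownames(m)[j]))
      xi <- m[i, ok]; xj <- m[j, ok]
      d[i, j] <- d[j, i] <- if (method == "mismatch") {
        mean(xi != xj)
      } else {
        both <- sum(xi == 1L & xj == 1L)
        either <- sum(xi == 1L | xj == 1L)
        if (either == 0L) 0 else 1 - both / either
      }
    }
  }
  d
}

#' Cluster varieties by their insertion-marker haplotypes
#'
#' Neighbor-joining tree on the binary marker distance matrix, with
#' subpopulation labels carried as the `groups` attribute of the tree.
#'
#' @param m Marker matrix (1/0/NA) with a `groups` attribute (or pass
#'   `groups`).
#' @param groups Named group labels per variety.
#' @param method Distance method, see [binary_distance_matrix()].
#' @return An `ape::phylo` tree.
#' @export
cluster_varieties <- function(m, groups = attr(m, "groups"),
                              method = "mismatch") {
  d <- binary_distance_matrix(m, method = method)
  tree <- neighbor_joining(d)
  if (!is.null(groups)) attr(tree, "groups") <- groups[tree$tip.label]
  tree
}

#' Is a set of tips monophyletic on an unrooted tree?
#'
#' True when an edge of the tree separates exactly the given tips from
#' the rest (trivial for a single tip).
#'
#' @param tree An `ape::phylo`.
#' @param tips Character vector of tip labels.
#' @export
tips_monophyletic <- function(tree, tips) {
  if (length(tips) <= 1L || length(tips) >= length(tree$tip.label) - 1L)
    return(TRUE)
  is_split(tree, tips, min_support = -Inf)
}
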