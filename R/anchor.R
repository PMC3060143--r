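#' Map one clone end sequence onto a reference region
#'
#' Exact k-mer seeding plus ungapped extension: seeds taken every
#' `seed_stride` bp along the end (and its reverse complement) are located
#' exactly in the reference; each seed hit proposes a diagonal, and the
#' full end is scored ungapped against the reference at that diagonal
#' (`match = +1`, `mismatch = -1`). Hits overlapping the best hit's span
#' are treated as the same locus; the end is "unique" when the best score
#' is at least `unique_margin` times the best score at any other locus.
#'
#' @param end_seq Nucleotide sequence of the clone end.
#' @param ref_seq Reference sequence (character).
#' @param k Seed length (default 31).
#' @param seed_stride Distance between seed starts (default `k`).
#' @param unique_margin Best/second-best score ratio declaring uniqueness
#'   (default 1.2).
#' @param min_score_frac Minimum best score as a fraction of the end
#'   length for a hit to count (default 0.5).
#' @return List: `start`, `end`, `strand`, `score`, `unique`, `no_hit`.
#' @export
map_end <- function(end_seq, ref_seq, k = 31L, seed_stride = k,
                    unique_margin = 1.2, min_score_frac = 0.5) {
  end_seq <- toupper(end_seq); ref_seq <- toupper(ref_seq)
  len <- nchar(end_seq)
  stopifnot(len >= k)
  cand <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") end_seq else revcomp(end_seq)
    offs <- unique(c(seq(1L, len - k + 1L, by = seed_stride), len - k + 1L))
    diags <- integer()
    for (o in offs) {
      seed <- substr(q, o, o + k - 1L)
      m <- gregexpr(seed, ref_seq, fixed = TRUE)[[1L]]
      if (m[1L] == -1L) next
      diags <- c(diags, as.integer(m) - o + 1L)
    }
    for (d in unique(diags))
      cand[[length(cand) + 1L]] <- list(strand = strand, diag = d, q = q)
  }
  if (length(cand) == 0L)
    return(list(start = NA_integer_, end = NA_integer_,
                strand = NA_character_, score = -Inf, unique = FALSE,
                no_hit = TRUE))
  nref <- nchar(ref_seq)
  scored <- lapply(cand, function(cc) {
    rs <- max(1L, cc$diag)
    re <- min(nref, cc$diag + len - 1L)
    qs <- rs - cc$diag + 1L
    qe <- re - cc$diag + 1L
    eq <- seq_chars(substr(ref_seq, rs, re)) ==
      seq_chars(substr(cc$q, qs, qe))
    list(start = rs, end = re, strand = cc$strand,
         score = sum(eq) - sum(!eq))
  })
  scores <- vapply(scored, function(h) h$score, numeric(1))
  best <- scored[[which.max(scores)]]
  if (best$score < min_score_frac * len)
    return(list(start = NA_integer_, end = NA_integer_,
                strand = NA_character_, score = best$score,
                unique = FALSE, no_hit = TRUE))
  other <- vapply(scored, function(h)
    h$start > best$end || h$end < best$start, logical(1))
  second <- if (any(other)) max(scores[other]) else -Inf
  uniq <- !is.finite(second) || second <= 0 ||
    best$score >= unique_margin * second
  list(start = best$start, end = best$end, strand = best$strand,
       score = best$score, unique = uniq, no_hit = FALSE)
}

#' Anchor a clone end-sequence pair to a reference region
#'
#' Applies the three orthologous-clone selection criteria to a pair of
#' clone end sequences: (1) at least one end maps uniquely; (2) the two
#' ends align in forward/reverse (opposite-strand) orientation; (3) the
#' implied clone span (outermost hit coordinate to outermost hit
#' coordinate) lies within `[min_span, max_span]`. A clone is accepted
#' only if all three hold; an end with no hit yields `accepted = FALSE`
#' with the `no_hit` flag set, never an error.
#'
#' @param pair List with `clone_id`, `end1`, `end2` (sequences).
#' @param reference A [region()] or plain sequence.
#' @param min_span,max_span Span bounds in bp (defaults 100,000 and
#'   500,000).
#' @param ... Passed to [map_end()].
#' @return One-row data frame: per-end hit coordinates/strand/uniqueness,
#'   `span_start`, `span_end`, `implied_span`, the three criteria flags,
#'   `accepted`, `no_hit`.
#' @export
map_end_pair <- function(pair, reference, min_span = 100000L,
                         max_span = 500000L, ...) {
  stopifnot(min_span < max_span, nchar(pair$end1) > 0, nchar(pair$end2) > 0)
  ref_seq <- if (inherits(reference, "region")) reference$seq else reference
  h1 <- map_end(pair$end1, ref_seq, ...)
  h2 <- map_end(pair$end2, ref_seq, ...)
  no_hit <- h1$no_hit || h2$no_hit
  has_unique_end <- (!h1$no_hit && h1$unique) || (!h2$no_hit && h2$unique)
  opposite <- !no_hit && !identical(h1$strand, h2$strand)
  span_start <- if (no_hit) NA_integer_ else min(h1$start, h2$start)
  span_end <- if (no_hit) NA_integer_ else max(h1$end, h2$end)
  implied <- if (no_hit) NA_integer_ else span_end - span_start + 1L
  span_ok <- !no_hit && implied >= min_span && implied <= max_span
  data.frame(clone_id = pair$clone_id,
             end1_start = h1$start, end1_end = h1$end,
             end1_strand = h1$strand, end1_unique = h1$unique,
             end2_start = h2$start, end2_end = h2$end,
             end2_strand = h2$strand, end2_unique = h2$unique,
             span_start = span_start, span_end = span_end,
             implied_span = implied,
             has_unique_end = has_unique_end,
             opposite_orientation = opposite,
             span_in_bounds = span_ok,
             accepted = !no_hit && has_unique_end && opposite && span_ok,
             no_hit = no_hit, stringsAsFactors = FALSE)
}

#' Select a minimum tiling set of accepted clones
#'
#' Left-to-right sweep over the accepted clones' implied spans: among
#' clones overlapping the current uncovered position, the one extending
#' furthest right is chosen (ties broken by longest span, then
#' lexicographic clone id); uncoverable gaps are skipped. For interval
#' spans this yields a minimum-cardinality subset achieving the maximum
#' possible coverage of the target interval.
#'
#' @param anchors Data frame of anchor results ([map_end_pair()] rows).
#' @param target_interval Numeric length-2 vector `c(start, end)`.
#' @return Character vector of selected clone ids (left-to-right), with
#'   attributes `coverage` (fraction of the target covered) and `warning`
#'   (set when no anchors were accepted).
#' @export
select_tiling_clones <- function(anchors, target_interval) {
  acc <- anchors[anchors$accepted %in% TRUE, , drop = FALSE]
  t0 <- target_interval[1L]; t1 <- target_interval[2L]
  if (nrow(acc) == 0L) {
    out <- character()
    attr(out, "coverage") <- 0
    attr(out, "warning") <- "no accepted anchors"
    return(out)
  }
  s <- pmax(acc$span_start, t0)
  e <- pmin(acc$span_end, t1)
  ok <- e >= s
  acc <- acc[ok, , drop = FALSE]; s <- s[ok]; e <- e[ok]
  sel <- character(); covered <- 0
  pos <- t0
  repeat {
    reach <- which(s <= pos & e >= pos)
    if (length(reach) == 0L) {
      nxt <- s[s > pos]
      if (length(nxt) == 0L) break
      pos <- min(nxt)
      next
    }
    ord <- order(-e[reach], -(e[reach] - s[reach]),
                 acc$clone_id[reach], method = "radix")
    pick <- reach[ord[1L]]
    sel <- c(sel, acc$clone_id[pick])
    covered <- covered + (e[pick] - max(pos, s[pick]) + 1L)
    pos <- e[pick] + 1L
    if (pos > t1) break
  }
  attr(sel, "coverage") <- covered / (t1 - t0 + 1L)
  sel
}
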