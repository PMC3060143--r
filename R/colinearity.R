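#' Build colinearity blocks between two orthologous regions
#'
#' Finds k-mers that occur exactly once in region `a` and exactly once in
#' region `b` (counting both strands of `b`), and chains co-diagonal
#' anchors into maximal colinear runs. Forward runs share a constant
#' diagonal (`b_pos - a_pos`), inverted runs a constant anti-diagonal
#' (`b_pos + a_pos`); runs break at anchor gaps larger than `max_gap`.
#' Runs spanning less than `min_block` bp of `a` are discarded, and
#' overlapping runs are resolved longest-first so blocks are
#' non-overlapping in both regions.
#'
#' @param a,b [region()] objects (or plain sequences).
#' @param k K-mer size (default 21).
#' @param min_block Minimum block span in bp (default 1000).
#' @param max_gap Maximum anchor gap within a run in bp (default 1000).
#' @return Data frame of blocks sorted by `a_start`: `a_start`, `a_end`,
#'   `b_start`, `b_end`, `orientation` (`forward`/`inverted`),
#'   `identity` (per-base identity over the ungapped block alignment),
#'   `n_anchors`.
#' @export
build_colinearity_blocks <- function(a, b, k = 21L, min_block = 1000L,
                                     max_gap = 1000L) {
  seq_a <- if (inherits(a, "region")) a$seq else toupper(a)
  seq_b <- if (inherits(b, "region")) b$seq else toupper(b)
  stopifnot(nchar(seq_a) >= k, nchar(seq_b) >= k)
  na <- nchar(seq_a); nb <- nchar(seq_b)
  kmers_at <- function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }
  singles <- function(x) !(duplicated(x) | duplicated(x, fromLast = TRUE))
  ka <- kmers_at(seq_a)
  kb_f <- kmers_at(seq_b)
  kb_r <- kmers_at(revcomp(seq_b))
  kb_all <- c(kb_f, kb_r)
  sa <- singles(ka)
  sb <- singles(kb_all)
  idx_b <- which(sb)
  pos_a <- which(sa)
  hit <- match(ka[pos_a], kb_all[idx_b])
  keep <- !is.na(hit)
  pos_a <- pos_a[keep]
  j <- idx_b[hit[keep]]
  nf <- length(kb_f)
  fwd <- j <= nf
  b_start <- ifelse(fwd, j, nb - (j - nf) - k + 2L)
  anchors <- data.frame(pa = pos_a, pb = as.integer(b_start),
                        fwd = fwd)
  if (nrow(anchors) == 0L) return(empty_blocks())
  anchors$key <- ifelse(anchors$fwd, anchors$pb - anchors$pa,
                        anchors$pb + anchors$pa)
  anchors <- anchors[order(anchors$fwd, anchors$key, anchors$pa), ]
  grp_break <- c(TRUE, diff(anchors$pa) > max_gap |
                   diff(anchors$key) != 0L |
                   diff(as.integer(anchors$fwd)) != 0L)
  run_id <- cumsum(grp_break)
  blocks <- do.call(rbind, lapply(split(anchors, run_id), function(g) {
    a_start <- min(g$pa); a_end <- max(g$pa) + k - 1L
    if (g$fwd[1L]) {
      b_start <- min(g$pb); b_end <- max(g$pb) + k - 1L
    } else {
      b_start <- min(g$pb); b_end <- max(g$pb) + k - 1L
    }
    data.frame(a_start = a_start, a_end = a_end,
               b_start = b_start, b_end = b_end,
               orientation = if (g$fwd[1L]) "forward" else "inverted",
               n_anchors = nrow(g), stringsAsFactors = FALSE)
  }))
  blocks <- blocks[blocks$a_end - blocks$a_start + 1L >= min_block, ,
                   drop = FALSE]
  if (nrow(blocks) == 0L) return(empty_blocks())
  # resolve overlaps longest-first; boundary-kmer overlaps are trimmed,
  # real conflicts dropped
  blocks <- blocks[order(-(blocks$a_end - blocks$a_start)), , drop = FALSE]
  kept <- blocks[0L, , drop = FALSE]
  trim_left <- function(bl, da) {
    bl$a_start <- bl$a_start + da
    if (bl$orientation == "forward") bl$b_start <- bl$b_start + da
    else bl$b_end <- bl$b_end - da
    bl
  }
  trim_right <- function(bl, da) {
    bl$a_end <- bl$a_end - da
    if (bl$orientation == "forward") bl$b_end <- bl$b_end - da
    else bl$b_start <- bl$b_start + da
    bl
  }
  for (i in seq_len(nrow(blocks))) {
    bl <- blocks[i, , drop = FALSE]
    ok <- TRUE
    for (j in seq_len(nrow(kept))) {
      kp <- kept[j, , drop = FALSE]
      ov_a <- min(bl$a_end, kp$a_end) - max(bl$a_start, kp$a_start) + 1L
      ov_b <- min(bl$b_end, kp$b_end) - max(bl$b_start, kp$b_start) + 1L
      ov <- max(ov_a, ov_b, 0L)
      if (ov == 0L) next
      if (ov > 2L * k) { ok <- FALSE; break }
      # small boundary overlap: trim this block away from the kept one
      if (ov_a > 0L) {
        if (kp$a_start <= bl$a_start) bl <- trim_left(bl, ov_a)
        else bl <- trim_right(bl, ov_a)
      }
      ov_b <- min(bl$b_end, kp$b_end) - max(bl$b_start, kp$b_start) + 1L
      if (ov_b > 0L) {
        # overlap only on the b side: trim the corresponding a flank
        if (kp$b_start <= bl$b_start) {
          if (bl$orientation == "forward") bl <- trim_left(bl, ov_b)
          else bl <- trim_right(bl, ov_b)
        } else {
          if (bl$orientation == "forward") bl <- trim_right(bl, ov_b)
          else bl <- trim_left(bl, ov_b)
        }
      }
      if (bl$a_end - bl$a_start + 1L < min_block) { ok <- FALSE; break }
    }
    if (ok) kept <- rbind(kept, bl)
  }
  blocks <- kept
  blocks <- blocks[order(blocks$a_start), , drop = FALSE]
  blocks$identity <- vapply(seq_len(nrow(blocks)), function(i) {
    sa_ <- substr(seq_a, blocks$a_start[i], blocks$a_end[i])
    sb_ <- substr(seq_b, blocks$b_start[i], blocks$b_end[i])
    if (blocks$orientation[i] == "inverted") sb_ <- revcomp(sb_)
    if (nchar(sa_) != nchar(sb_)) return(NA_real_)
    mean(seq_chars(sa_) == seq_chars(sb_))
  }, numeric(1))
  rownames(blocks) <- NULL
  blocks[, c("a_start", "a_end", "b_start", "b_end", "orientation",
             "identity", "n_anchors")]
}

empty_blocks <- function() {
  data.frame(a_start = integer(), a_end = integer(), b_start = integer(),
             b_end = integer(), orientation = character(),
             identity = numeric(), n_anchors = integer(),
             stringsAsFactors = FALSE)
}

# Fraction of [start, end] covered by blocks on one side ("a" or "b").
block_coverage <- function(blocks, start, end, side = "a") {
  if (nrow(blocks) == 0L) return(0)
  s <- blocks[[paste0(side, "_start")]]
  e <- blocks[[paste0(side, "_end")]]
  hit <- s <= end & e >= start
  if (!any(hit)) return(0)
  ir <- IRanges::IRanges(start = pmax(s[hit], start),
                         end = pmin(e[hit], end))
  sum(IRanges::width(IRanges::reduce(ir))) / (end - start + 1L)
}

# Project an `a` coordinate into `b` through the nearest flanking forward
# block's affine map (inverted blocks mirror). Returns NA if no block.
project_coordinate <- function(blocks, pos, from = "a") {
  if (nrow(blocks) == 0L) return(NA_integer_)
  s <- blocks[[paste0(from, "_start")]]
  e <- blocks[[paste0(from, "_end")]]
  to <- if (identical(from, "a")) "b" else "a"
  ts <- blocks[[paste0(to, "_start")]]
  te <- blocks[[paste0(to, "_end")]]
  dist <- pmax(s - pos, pos - e, 0L)
  i <- which.min(dist)
  anchor <- min(max(pos, s[i]), e[i])  # clamp into the block
  off <- anchor - s[i]
  proj <- if (blocks$orientation[i] == "forward") ts[i] + off else te[i] - off
  as.integer(proj + (pos - anchor))
}

count_mismatches <- function(x, y) {
  if (nchar(x) != nchar(y)) return(Inf)
  sum(seq_chars(x) != seq_chars(y))
}

#' Polarize TE insertions between two regions by TSD evidence
#'
#' An element annotated in one region whose span falls outside the shared
#' colinearity blocks is tested for the insertion signature: the
#' `tsd_length` bp immediately flanking the element on both sides must
#' match (the target-site duplication), and the site, projected through
#' the block mapping into the other region, must carry a single copy of
#' the 5-bp target site (the "empty site"). Elements covered by blocks in
#' both regions are shared; incomplete evidence yields `ambiguous`, never
#' an error.
#'
#' @param a,b Annotated [region()] objects.
#' @param blocks Colinearity blocks from [build_colinearity_blocks()].
#' @param tsd_length Target-site duplication length (default 5).
#' @param max_mismatch Mismatches tolerated in the TSD and empty-site
#'   comparisons (default 0; the study system shows exact 5-bp TSDs, but
#'   real flanks decay).
#' @param cover_frac Fraction of an element that must be block-covered to
#'   call it shared (default 0.8).
#' @return Data frame of insertion calls: `element_id`, `status`
#'   (`shared`/`unique_to_A`/`unique_to_B`/`ambiguous`), `tsd_seq`,
#'   `empty_site_coord` (position in the non-carrier region), `tsd_found`,
#'   `empty_site_found`.
#' @export
classify_te_insertions <- function(a, b, blocks, tsd_length = 5L,
                                   max_mismatch = 0L, cover_frac = 0.8) {
  calls <- list()
  sides <- list(list(carrier = a, other = b, side = "a", lab = "A"),
                list(carrier = b, other = a, side = "b", lab = "B"))
  for (sd in sides) {
    tes <- te_annotations(sd$carrier)
    tes <- tes[is.na(tes$parent), , drop = FALSE]
    for (i in seq_len(nrow(tes))) {
      es <- tes$start[i]; ee <- tes$end[i]
      cov <- block_coverage(blocks, es, ee, side = sd$side)
      if (cov >= cover_frac) {
        calls[[length(calls) + 1L]] <- data.frame(
          element_id = tes$id[i], status = "shared",
          tsd_seq = NA_character_, empty_site_coord = NA_integer_,
          tsd_found = NA, empty_site_found = NA,
          stringsAsFactors = FALSE)
        next
      }
      seq_c <- sd$carrier$seq
      tsd_found <- FALSE; empty_found <- FALSE
      tsd_seq <- NA_character_; empty_coord <- NA_integer_
      if (tsd_length > 0L && es - tsd_length >= 1L &&
          ee + tsd_length <= nchar(seq_c)) {
        left <- substr(seq_c, es - tsd_length, es - 1L)
        right <- substr(seq_c, ee + 1L, ee + tsd_length)
        if (count_mismatches(left, right) <= max_mismatch) {
          tsd_found <- TRUE
          tsd_seq <- left
        }
        junction <- es - tsd_length
        proj <- if (identical(sd$side, "a"))
          project_coordinate(blocks, junction, from = "a")
        else project_coordinate(blocks, junction, from = "b")
        if (!is.na(proj) && proj >= 1L &&
            proj + tsd_length - 1L <= nchar(sd$other$seq)) {
          site <- substr(sd$other$seq, proj, proj + tsd_length - 1L)
          if (count_mismatches(site, left) <= max_mismatch) {
            empty_found <- TRUE
            empty_coord <- proj
          }
        }
      } else if (tsd_length == 0L) {
        tsd_found <- TRUE
      }
      status <- if (cov < cover_frac && tsd_found && empty_found)
        paste0("unique_to_", sd$lab) else "ambiguous"
      calls[[length(calls) + 1L]] <- data.frame(
        element_id = tes$id[i], status = status, tsd_seq = tsd_seq,
        empty_site_coord = empty_coord, tsd_found = tsd_found,
        empty_site_found = empty_found, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out)) out <- data.frame(element_id = character(),
                                      status = character(),
                                      tsd_seq = character(),
                                      empty_site_coord = integer(),
                                      tsd_found = logical(),
                                      empty_site_found = logical(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify the structural state of an annotated element
#'
#' Total classification from the annotation geometry: a split fragment
#' (recorded at a rearrangement breakpoint) is `split`; a span equal to
#' one LTR is `solo` (a solo LTR left by unequal recombination between the
#' element's LTRs); a span shorter than the intact element is `truncated`;
#' otherwise `intact`.
#'
#' @param e One annotation row (data frame with `start`, `end`,
#'   `ltr_length`, `full_length`, `state`, `parent`).
#' @return One of `"intact"`, `"solo"`, `"truncated"`, `"split"`.
#' @export
classify_element_state <- function(e) {
  if (!is.na(e$parent) || identical(e$state, "split")) return("split")
  len <- e$end - e$start + 1L
  if (!is.na(e$ltr_length) && len <= e$ltr_length) return("solo")
  if (identical(e$state, "solo")) return("solo")
  if (!is.na(e$full_length) && len < e$full_length) return("truncated")
  if (identical(e$state, "truncated")) return("truncated")
  "intact"
}

#' Call large indels between two regions
#'
#' For each gap between consecutive colinearity blocks, when one region's
#' gap exceeds the other's by at least `min_indel_size` an indel is called
#' on the larger side, listing the annotations it contains. Gaps already
#' explained by a TSD-positive insertion call can be suppressed.
#'
#' @param blocks Blocks from [build_colinearity_blocks()] (sorted by
#'   `a_start`).
#' @param a,b The two [region()] objects (for annotation content).
#' @param min_indel_size Minimum size difference in bp (default 3000,
#'   matching the `> 3 kb` reporting threshold of the study).
#' @param insertion_calls Optional calls from [classify_te_insertions()];
#'   when given with `suppress_insertions = TRUE`, gaps whose size is
#'   explained by TSD-positive unique insertions are not reported.
#' @param suppress_insertions Logical, see above.
#' @return Data frame of calls: `side` (`A`/`B`), `start`, `end`, `size`,
#'   `contents` (comma-separated annotation ids).
#' @export
call_indels <- function(blocks, a, b, min_indel_size = 3000L,
                        insertion_calls = NULL,
                        suppress_insertions = FALSE) {
  out <- list()
  if (nrow(blocks) >= 2L) {
    fb <- blocks[blocks$orientation == "forward", , drop = FALSE]
    fb <- fb[order(fb$a_start), , drop = FALSE]
    for (i in seq_len(nrow(fb) - 1L)) {
      gap_a <- fb$a_start[i + 1L] - fb$a_end[i] - 1L
      gap_b <- fb$b_start[i + 1L] - fb$b_end[i] - 1L
      if (gap_b < 0L) next  # non-monotone in b (e.g. around an inversion)
      delta <- gap_a - gap_b
      if (abs(delta) < min_indel_size) next
      if (delta > 0L) {
        side <- "A"; reg <- a
        start <- fb$a_end[i] + 1L
        end <- fb$a_start[i + 1L] - 1L
      } else {
        side <- "B"; reg <- b
        start <- fb$b_end[i] + 1L
        end <- fb$b_start[i + 1L] - 1L
      }
      if (suppress_insertions && !is.null(insertion_calls)) {
        uniq <- insertion_calls[insertion_calls$tsd_found %in% TRUE &
                                  insertion_calls$status ==
                                  paste0("unique_to_", side), ,
                                drop = FALSE]
        ids <- uniq$element_id
        ann <- reg$ann[reg$ann$id %in% ids, , drop = FALSE]
        explained <- sum(pmax(0L, pmin(ann$end, end) -
                                pmax(ann$start, start) + 1L))
        if (abs(delta) - explained < min_indel_size) next
      }
      inside <- reg$ann[reg$ann$start >= start & reg$ann$end <= end, ,
                        drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        side = side, start = start, end = end, size = abs(delta),
        contents = paste(inside$id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(side = character(), start = integer(),
                                      end = integer(), size = integer(),
                                      contents = character(),
                                      stringsAsFactors = FALSE)
  res
}

#' Call segmental inversions between two regions
#'
#' Maximal runs of inverted-orientation blocks between forward neighbors
#' become inversion calls. Breakpoints are the run's outer coordinates in
#' each region; annotations intersecting a breakpoint (within `tol` bp)
#' are reported, including the parent ids of split element fragments.
#'
#' @param blocks Blocks from [build_colinearity_blocks()].
#' @param a,b The two [region()] objects.
#' @param tol Breakpoint intersection tolerance in bp (default 50).
#' @return Data frame: `a_start`, `a_end`, `b_start`, `b_end` (the
#'   inverted spans), `breakpoint_features` (comma-separated ids).
#' @export
call_inversions <- function(blocks, a, b, tol = 50L) {
  out <- list()
  if (nrow(blocks) > 0L) {
    inv <- blocks$orientation == "inverted"
    runs <- rle(inv)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    for (j in which(runs$values)) {
      g <- blocks[idx_start[j]:idx_end[j], , drop = FALSE]
      a_start <- min(g$a_start); a_end <- max(g$a_end)
      b_start <- min(g$b_start); b_end <- max(g$b_end)
      feats <- character()
      for (sd in list(list(reg = a, bp = c(a_start, a_end)),
                      list(reg = b, bp = c(b_start, b_end)))) {
        for (bp in sd$bp) {
          hit <- sd$reg$ann[sd$reg$ann$start - tol <= bp &
                              sd$reg$ann$end + tol >= bp, , drop = FALSE]
          feats <- c(feats, hit$id, stats::na.omit(hit$parent))
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        a_start = a_start, a_end = a_end, b_start = b_start,
        b_end = b_end,
        breakpoint_features = paste(unique(feats), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(a_start = integer(), a_end = integer(),
                                      b_start = integer(), b_end = integer(),
                                      breakpoint_features = character(),
                                      stringsAsFactors = FALSE)
  res
}
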