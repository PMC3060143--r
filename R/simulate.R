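#' Kimura two-parameter site substitution probabilities
#'
#' Closed-form state-change probabilities for a K2P process after an
#' expected `d` substitutions per site, with transition rate `alpha` and
#' per-transversion rate `beta` scaled so `alpha + 2*beta = 1` and
#' `alpha/(2*beta) = ts_tv_ratio`.
#'
#' @param d Expected substitutions per site (branch length).
#' @param ts_tv_ratio Transition:transversion ratio (default 2).
#' @return Named numeric vector: `same`, `transition`, `transversion_each`.
#' @export
k2p_site_probs <- function(d, ts_tv_ratio = 2) {
  stopifnot(d >= 0, ts_tv_ratio > 0)
  alpha <- ts_tv_ratio / (ts_tv_ratio + 1)
  beta <- 1 / (2 * (ts_tv_ratio + 1))
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  p_tv_each <- 0.25 - 0.25 * exp(-4 * beta * d)
  c(same = 1 - p_ts - 2 * p_tv_each, transition = p_ts,
    transversion_each = p_tv_each)
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

# Draw a K2P mutation batch for a sequence: returns list(positions, to).
draw_k2p_mutations <- function(seq, d, ts_tv_ratio = 2) {
  n <- nchar(seq)
  pr <- k2p_site_probs(d, ts_tv_ratio)
  n_changed <- stats::rbinom(1L, n, 1 - pr[["same"]])
  if (n_changed == 0L)
    return(list(positions = integer(), to = character()))
  positions <- sort(sample.int(n, n_changed))
  from <- substring(seq, positions, positions)
  p_ts_given_change <- pr[["transition"]] / (1 - pr[["same"]])
  is_ts <- stats::runif(n_changed) < p_ts_given_change
  to <- character(n_changed)
  to[is_ts] <- TRANSITION_OF[from[is_ts]]
  if (any(!is_ts)) {
    pick <- stats::runif(sum(!is_ts)) < 0.5
    tv <- from[!is_ts]
    to[!is_ts] <- vapply(seq_along(tv), function(i)
      TRANSVERSIONS_OF[[tv[i]]][if (pick[i]) 1L else 2L], character(1))
  }
  list(positions = positions, to = to)
}

apply_mutations <- function(seq, positions, to) {
  if (length(positions) == 0L) return(seq)
  ch <- seq_chars(seq)
  ch[positions] <- to
  paste(ch, collapse = "")
}

# Evolve a sequence under K2P for branch length d.
evolve_seq_k2p <- function(seq, d, ts_tv_ratio = 2) {
  m <- draw_k2p_mutations(seq, d, ts_tv_ratio)
  apply_mutations(seq, m$positions, m$to)
}

#' LTR-retrotransposon element
#'
#' Constructs a structurally annotated element: two identical long terminal
#' repeats (LTRs) flanking an internal domain. Sequences are random; only
#' the LTR structure matters for the analyses here.
#'
#' @param internal_length Internal domain length in bp.
#' @param ltr_length LTR length in bp.
#' @param id Element identifier.
#' @param seed Optional RNG seed.
#' @return A `te_element`: list with `seq`, `ltr_length`, `id`, `state`.
#' @export
te_element <- function(internal_length = 3000, ltr_length = 1000,
                       id = "te", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(internal_length >= 0, ltr_length > 0)
  ltr <- random_dna(ltr_length)
  internal <- if (internal_length > 0) random_dna(internal_length) else ""
  structure(list(seq = paste0(ltr, internal, ltr),
                 ltr_length = as.integer(ltr_length),
                 id = id, state = "intact"),
            class = "te_element")
}

ltr_pair <- function(element) {
  l <- element$ltr_length
  n <- nchar(element$seq)
  list(ltr5 = substr(element$seq, 1L, l),
       ltr3 = substr(element$seq, n - l + 1L, n))
}

#' Age an element's LTR pair under the K2P clock
#'
#' At insertion the two LTRs are identical; afterwards each accumulates
#' substitutions independently at rate `r` per site per year, so the pair
#' diverges in expectation by `2*r*age` substitutions per site (a true K2P
#' process: multiple hits per site are possible, which the K2P correction
#' used for dating inverts). The internal domain drifts at the same rate.
#'
#' @param element A `te_element` with two LTRs (`state == "intact"`).
#' @param age Insertion age in years.
#' @param r Substitution rate, substitutions/site/year.
#' @param seed Optional RNG seed.
#' @param ts_tv_ratio Transition:transversion ratio (default 2).
#' @return The element with mutated sequence.
#' @export
mutate_ltr_pair <- function(element, age, r, seed = NULL, ts_tv_ratio = 2) {
  if (!is.null(seed)) set.seed(seed)
  if (age < 0 || r < 0) stop("age and rate must be nonnegative")
  if (!identical(element$state, "intact"))
    stop("element must be intact (two LTRs) to age its LTR pair")
  d <- r * age
  l <- element$ltr_length
  n <- nchar(element$seq)
  ltr <- substr(element$seq, 1L, l)
  internal <- if (n > 2L * l) substr(element$seq, l + 1L, n - l) else ""
  ltr5 <- evolve_seq_k2p(ltr, d, ts_tv_ratio)
  ltr3 <- evolve_seq_k2p(ltr, d, ts_tv_ratio)
  if (nchar(internal) > 0)
    internal <- evolve_seq_k2p(internal, d, ts_tv_ratio)
  element$seq <- paste0(ltr5, internal, ltr3)
  element$age <- age
  element
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic region simulator. Defaults
#' emulate the study system: a gene-rich region of two conserved gene
#' clusters separated by a spacer where transposons accumulate, 5-bp
#' target-site duplications, and a molecular clock of
#' 1.3e-8 substitutions/site/year.
#'
#' @param seed RNG seed; a fixed seed makes every output byte-identical.
#' @param region_length Ancestral region length in bp.
#' @param n_genes_per_cluster Genes per conserved cluster.
#' @param gene_length,gene_gap,margin Gene layout parameters in bp.
#' @param min_spacer Minimum inter-cluster spacer in bp.
#' @param tsd_length Target-site duplication length in bp (default 5).
#' @param r Substitution rate, substitutions/site/year.
#' @param ts_tv_ratio Transition:transversion ratio of the K2P process.
#' @param n_ancestral_tes LTR elements planted in the ancestor (shared by
#'   all derived lineages).
#' @param ancestral_te_age Age in years assigned to ancestral elements.
#' @param te_internal_length,te_ltr_length Element geometry in bp.
#' @param lineage_a,lineage_b Per-lineage event specifications passed to
#'   [evolve_lineage()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, region_length = 100000L,
                       n_genes_per_cluster = 6L, gene_length = 2000L,
                       gene_gap = 1000L, margin = 2000L, min_spacer = 5000L,
                       tsd_length = 5L, r = 1.3e-8, ts_tv_ratio = 2,
                       n_ancestral_tes = 0L, ancestral_te_age = 2e6,
                       te_internal_length = 3000L, te_ltr_length = 1000L,
                       lineage_a = NULL, lineage_b = NULL) {
  cfg <- as.list(environment())
  stopifnot(region_length > 0, tsd_length >= 0, n_genes_per_cluster >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the ancestral region
#'
#' Builds a random region carrying two conserved gene clusters (fixed gene
#' order and orientation) separated by an intervening spacer, optionally
#' with ancestral LTR elements planted in the spacer (these become the
#' "shared" elements of every derived lineage).
#'
#' @param config A [sim_config()].
#' @return A [region()] with gene (and optionally TE) annotations.
#' @export
simulate_ancestral_region <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes_per_cluster
  cluster_len <- n * config$gene_length + (n - 1L) * config$gene_gap
  required <- 2L * cluster_len + 2L * config$margin + config$min_spacer
  if (config$region_length < required)
    stop(sprintf("region too short: need >= %d bp to place %d genes per cluster",
                 required, n))
  seq <- random_dna(config$region_length)
  gene_rows <- function(cluster, start0) {
    starts <- start0 + (0:(n - 1L)) * (config$gene_length + config$gene_gap)
    data.frame(id = sprintf("c%dg%d", cluster, seq_len(n)),
               class = "gene", start = as.integer(starts),
               end = as.integer(starts + config$gene_length - 1L),
               strand = "+", stringsAsFactors = FALSE)
  }
  c1 <- gene_rows(1L, config$margin + 1L)
  c2 <- gene_rows(2L, config$region_length - config$margin - cluster_len + 1L)
  ann <- normalize_annotations(rbind(c1, c2))
  anc <- region(seq, ann, name = "ancestor")
  if (config$n_ancestral_tes > 0L) {
    state <- list(seq = anc$seq, ann = anc$ann,
                  anc = seq_len(nchar(anc$seq)))
    spacer <- c(max(c1$end) + 1L, min(c2$start) - 1L)
    for (i in seq_len(config$n_ancestral_tes)) {
      site <- sample_insertion_site(state, config$tsd_length,
                                    within = spacer, pad = 500L,
                                    min_separation = 3000L)
      el <- te_element(config$te_internal_length, config$te_ltr_length,
                       id = sprintf("anc_te_%d", i))
      el <- mutate_ltr_pair(el, config$ancestral_te_age, config$r,
                            ts_tv_ratio = config$ts_tv_ratio)
      state <- apply_te_insert(state, list(
        kind = "te_insert", id = el$id, class = "LTR_retro", site = site,
        element_seq = el$seq, ltr_length = el$ltr_length,
        tsd_length = config$tsd_length, age = config$ancestral_te_age))
    }
    anc <- region(state$seq, state$ann, name = "ancestor")
  }
  anc
}

# -- event application (shared by live evolution and truth-log replay) -------

# A state is list(seq, ann, anc) where anc maps each current position to its
# ancestral coordinate (NA for lineage-specific material).

insert_material <- function(state, pos_after, insert_seq) {
  len <- nchar(insert_seq)
  state$seq <- paste0(substr(state$seq, 1L, pos_after), insert_seq,
                      substr(state$seq, pos_after + 1L, nchar(state$seq)))
  state$anc <- append(state$anc, rep(NA_integer_, len), after = pos_after)
  if (nrow(state$ann) > 0L) {
    sh_s <- state$ann$start > pos_after
    sh_e <- state$ann$end > pos_after
    state$ann$start[sh_s] <- state$ann$start[sh_s] + len
    state$ann$end[sh_e] <- state$ann$end[sh_e] + len
  }
  state
}

delete_material <- function(state, start, end, truncate_state = "truncated") {
  stopifnot(start >= 1L, end <= nchar(state$seq), start <= end)
  len <- end - start + 1L
  state$seq <- paste0(substr(state$seq, 1L, start - 1L),
                      substr(state$seq, end + 1L, nchar(state$seq)))
  state$anc <- state$anc[-(start:end)]
  ann <- state$ann
  if (nrow(ann) > 0L) {
    keep <- rep(TRUE, nrow(ann))
    for (i in seq_len(nrow(ann))) {
      s <- ann$start[i]; e <- ann$end[i]
      if (e < start) next
      if (s > end) { ann$start[i] <- s - len; ann$end[i] <- e - len; next }
      if (s >= start && e <= end) { keep[i] <- FALSE; next }
      clipped_left <- s < start
      clipped_right <- e > end
      ns <- if (clipped_left) s else start
      ne <- if (clipped_right) e - len else start - 1L
      ann$start[i] <- ns; ann$end[i] <- ne
      if (!(clipped_left && clipped_right))
        ann$state[i] <- truncate_state
    }
    state$ann <- ann[keep, , drop = FALSE]
    rownames(state$ann) <- NULL
  }
  state
}

invert_material <- function(state, start, end) {
  stopifnot(start >= 1L, end <= nchar(state$seq), start < end)
  seg <- substr(state$seq, start, end)
  state$seq <- paste0(substr(state$seq, 1L, start - 1L), revcomp(seg),
                      substr(state$seq, end + 1L, nchar(state$seq)))
  state$anc[start:end] <- rev(state$anc[start:end])
  ann <- state$ann
  if (nrow(ann) > 0L) {
    extra <- NULL
    keep <- rep(TRUE, nrow(ann))
    flip <- function(s, e) c(start + (end - e), start + (end - s))
    for (i in seq_len(nrow(ann))) {
      s <- ann$start[i]; e <- ann$end[i]
      if (e < start || s > end) next
      if (s >= start && e <= end) {
        se <- flip(s, e)
        ann$start[i] <- se[1L]; ann$end[i] <- se[2L]
        ann$strand[i] <- if (identical(ann$strand[i], "-")) "+" else "-"
        next
      }
      if (s < start && e > end) next  # spans both breakpoints; left as-is
      # element split by an inversion breakpoint: two fragments
      keep[i] <- FALSE
      if (s < start) {
        out_frag <- ann[i, , drop = FALSE]
        out_frag$id <- paste0(ann$id[i], ".1")
        out_frag$end <- start - 1L
        in_frag <- ann[i, , drop = FALSE]
        in_frag$id <- paste0(ann$id[i], ".2")
        se <- flip(start, e)
        in_frag$start <- se[1L]; in_frag$end <- se[2L]
        in_frag$strand <- if (identical(ann$strand[i], "-")) "+" else "-"
      } else {
        out_frag <- ann[i, , drop = FALSE]
        out_frag$id <- paste0(ann$id[i], ".2")
        out_frag$start <- end + 1L
        in_frag <- ann[i, , drop = FALSE]
        in_frag$id <- paste0(ann$id[i], ".1")
        se <- flip(s, end)
        in_frag$start <- se[1L]; in_frag$end <- se[2L]
        in_frag$strand <- if (identical(ann$strand[i], "-")) "+" else "-"
      }
      out_frag$state <- "split"; in_frag$state <- "split"
      out_frag$parent <- ann$id[i]; in_frag$parent <- ann$id[i]
      extra <- rbind(extra, out_frag, in_frag)
    }
    state$ann <- rbind(ann[keep, , drop = FALSE], extra)
    state$ann <- state$ann[order(state$ann$start), , drop = FALSE]
    rownames(state$ann) <- NULL
  }
  state
}

apply_substitution_batch <- function(state, evt) {
  state$seq <- apply_mutations(state$seq, evt$positions, evt$to)
  state
}

apply_te_insert <- function(state, evt) {
  s <- evt$site
  t <- evt$tsd_length
  elen <- nchar(evt$element_seq)
  site_seq <- if (t > 0) substr(state$seq, s, s + t - 1L) else ""
  state <- insert_material(state, s + t - 1L,
                           paste0(evt$element_seq, site_seq))
  new_row <- normalize_annotations(data.frame(
    id = evt$id, class = evt$class, start = s + t,
    end = s + t + elen - 1L, strand = "+",
    ltr_length = evt$ltr_length, full_length = elen,
    state = "intact", tsd = site_seq, parent = NA_character_,
    stringsAsFactors = FALSE))
  state$ann <- rbind(state$ann, new_row)
  state$ann <- state$ann[order(state$ann$start), , drop = FALSE]
  rownames(state$ann) <- NULL
  state
}

apply_solo_ltr <- function(state, evt) {
  i <- match(evt$id, state$ann$id)
  if (is.na(i)) stop("solo_ltr: unknown element id ", evt$id)
  state <- delete_material(state, evt$del_start, evt$del_end)
  i <- match(evt$id, state$ann$id)
  state$ann$state[i] <- "solo"
  state
}

apply_indel <- function(state, evt) {
  if (identical(evt$type, "del")) {
    delete_material(state, evt$start, evt$end)
  } else {
    insert_material(state, evt$after, evt$insert_seq)
  }
}

apply_inversion_evt <- function(state, evt) {
  invert_material(state, evt$start, evt$end)
}

apply_duplication <- function(state, evt) {
  seg <- substr(state$seq, evt$start, evt$end)
  inside <- state$ann$start >= evt$start & state$ann$end <= evt$end
  copies <- NULL
  insert_after <- evt$end
  for (k in seq_len(evt$times)) {
    offset <- insert_after - evt$start + 1L + (k - 1L) * nchar(seg)
    if (any(inside)) {
      cp <- state$ann[inside, , drop = FALSE]
      cp$id <- paste0(cp$id, "_dup", k)
      cp$start <- cp$start + offset
      cp$end <- cp$end + offset
      copies <- rbind(copies, cp)
    }
  }
  state <- insert_material(state, insert_after,
                           paste(rep(seg, evt$times), collapse = ""))
  if (!is.null(copies)) {
    state$ann <- rbind(state$ann, copies)
    state$ann <- state$ann[order(state$ann$start), , drop = FALSE]
    rownames(state$ann) <- NULL
  }
  state
}

apply_event <- function(state, evt) {
  switch(evt$kind,
         substitution_batch = apply_substitution_batch(state, evt),
         te_insert = apply_te_insert(state, evt),
         solo_ltr = apply_solo_ltr(state, evt),
         indel = apply_indel(state, evt),
         inversion = apply_inversion_evt(state, evt),
         duplication = apply_duplication(state, evt),
         stop("unknown event kind: ", evt$kind))
}

# Sample a TE insertion site (start of the target site) in allowed space.
sample_insertion_site <- function(state, tsd_length, within = NULL,
                                  pad = 500L, min_separation = 3000L,
                                  avoid = NULL) {
  n <- nchar(state$seq)
  ok <- rep(TRUE, n)
  lo <- function(x) max(1L, x)
  hi <- function(x) min(n, x)
  if (nrow(state$ann) > 0L) {
    for (i in seq_len(nrow(state$ann)))
      ok[lo(state$ann$start[i] - pad):hi(state$ann$end[i] + pad)] <- FALSE
  }
  if (!is.null(avoid) && length(avoid) > 0L) {
    for (a in avoid)
      ok[lo(a - min_separation):hi(a + min_separation)] <- FALSE
  }
  ok[hi(n - tsd_length - pad):n] <- FALSE
  ok[1:lo(pad)] <- FALSE
  if (!is.null(within)) {
    mask <- rep(FALSE, n)
    mask[lo(within[1L]):hi(within[2L])] <- TRUE
    ok <- ok & mask
  }
  cand <- which(ok)
  if (length(cand) == 0L)
    stop("conflict: no insertion site available under the requested constraints")
  cand[sample.int(length(cand), 1L)]
}

nearest_anc_coord <- function(anc, pos) {
  i <- pos
  while (i >= 1L && is.na(anc[i])) i <- i - 1L
  if (i >= 1L) anc[i] else NA_integer_
}

#' Evolve a lineage from an ancestral region
#'
#' Applies, in logged order: background substitutions over the lineage age
#' (restricted to ancestral sites by applying them first), TE insertions
#' (each creating a `tsd_length` target-site duplication and carrying an
#' LTR pair aged by its own insertion age), solo-LTR reductions, large
#' indels, a segmental inversion, and a segmental duplication. Every event
#' is recorded in a replayable truth log with coordinates in the derived
#' frame at application time plus the nearest ancestral coordinate.
#'
#' @param ancestor A [region()] (typically from
#'   [simulate_ancestral_region()]).
#' @param lineage_params List of lineage parameters: `lineage` (label),
#'   `age` (years), `r`, `ts_tv_ratio`, `tsd_length`, `substitutions`
#'   (logical), `n_te` or `te` (list of per-element specs with optional
#'   `site`, `age`, `internal_length`, `ltr_length`, `id`, `class`),
#'   `solo_ltr` (element ids, or a count of inserted elements to reduce),
#'   `indels` (list of `list(type = "del"|"ins", size, start = NULL,
#'   allow_genes = FALSE)`), `inversion` (`list(start, end)` or
#'   `list(size, breakpoint_in_element = id)`), `duplication`
#'   (`list(start, end, times)`).
#' @param seed RNG seed for this lineage.
#' @return List with `region` (the derived [region()]), `log` (a
#'   `truth_log`), and `anc` (derived-to-ancestral coordinate map).
#' @export
evolve_lineage <- function(ancestor, lineage_params, seed = NULL) {
  stopifnot(inherits(ancestor, "region"))
  if (!is.null(seed)) set.seed(seed)
  p <- lineage_params
  lineage <- if (is.null(p$lineage)) "derived" else p$lineage
  age <- if (is.null(p$age)) 1e6 else p$age
  r <- if (is.null(p$r)) 1.3e-8 else p$r
  kappa <- if (is.null(p$ts_tv_ratio)) 2 else p$ts_tv_ratio
  tsd_length <- if (is.null(p$tsd_length)) 5L else as.integer(p$tsd_length)
  state <- list(seq = ancestor$seq, ann = ancestor$ann,
                anc = seq_len(nchar(ancestor$seq)))
  events <- list()
  log_event <- function(evt, start = NULL, end = NULL) {
    evt$lineage <- lineage
    if (!is.null(start)) {
      evt$anc_start <- nearest_anc_coord(state$anc, start)
      if (!is.null(end)) evt$anc_end <- nearest_anc_coord(state$anc, end)
    }
    evt
  }

  do_subs <- if (is.null(p$substitutions)) TRUE else isTRUE(p$substitutions)
  if (do_subs && age > 0) {
    m <- draw_k2p_mutations(state$seq, r * age, kappa)
    evt <- log_event(list(kind = "substitution_batch",
                          positions = m$positions, to = m$to,
                          rate = r, age = age))
    state <- apply_event(state, evt)
    events <- c(events, list(evt))
  }

  te_specs <- p$te
  if (is.null(te_specs) && !is.null(p$n_te) && p$n_te > 0L)
    te_specs <- replicate(p$n_te, list(), simplify = FALSE)
  inserted_ids <- character()
  site_pad <- as.integer(p$site_pad %||% 1500L)
  for (i in seq_along(te_specs)) {
    sp <- te_specs[[i]]
    id <- if (is.null(sp$id)) sprintf("%s_te_%d", lineage, i) else sp$id
    cls <- if (is.null(sp$class)) "LTR_retro" else sp$class
    il <- if (is.null(sp$internal_length)) 3000L else as.integer(sp$internal_length)
    ll <- if (is.null(sp$ltr_length)) 1000L else as.integer(sp$ltr_length)
    el_age <- if (is.null(sp$age)) stats::runif(1L, 0, age) else sp$age
    site <- if (is.null(sp$site)) {
      # map cross-lineage avoidance coordinates (ancestral frame) into
      # the current derived frame
      av <- if (is.null(p$avoid_anc)) integer()
      else stats::na.omit(match(p$avoid_anc, state$anc))
      sample_insertion_site(state, tsd_length, pad = site_pad,
                            avoid = av)
    } else sp$site
    el <- te_element(il, ll, id = id)
    if (identical(cls, "LTR_retro"))
      el <- mutate_ltr_pair(el, el_age, r, ts_tv_ratio = kappa)
    evt <- log_event(list(kind = "te_insert", id = id, class = cls,
                          site = site, element_seq = el$seq,
                          ltr_length = if (identical(cls, "LTR_retro")) ll else NA_integer_,
                          tsd_length = tsd_length, age = el_age),
                     start = site)
    state <- apply_event(state, evt)
    events <- c(events, list(evt))
    inserted_ids <- c(inserted_ids, id)
  }

  solo <- p$solo_ltr
  if (!is.null(solo)) {
    ids <- if (is.numeric(solo)) {
      if (solo > length(inserted_ids))
        stop("conflict: fewer inserted elements than solo_ltr count")
      sample(inserted_ids, solo)
    } else solo
    for (id in ids) {
      i <- match(id, state$ann$id)
      if (is.na(i)) stop("solo_ltr: unknown element id ", id)
      s <- state$ann$start[i]; e <- state$ann$end[i]
      l <- state$ann$ltr_length[i]
      if (is.na(l) || e - s + 1L <= l)
        stop("conflict: element ", id, " has no internal span to recombine out")
      evt <- log_event(list(kind = "solo_ltr", id = id,
                            del_start = s + l, del_end = e),
                       start = s + l, end = e)
      state <- apply_event(state, evt)
      events <- c(events, list(evt))
    }
  }

  genes_span_ok <- function(start, end, allow_genes) {
    if (allow_genes) return(TRUE)
    g <- state$ann[state$ann$class == "gene", , drop = FALSE]
    !any(g$start <= end & g$end >= start &
           !(g$start >= start & g$end <= end))
  }

  for (ind in p$indels %||% list()) {
    type <- if (is.null(ind$type)) "del" else ind$type
    allow_genes <- isTRUE(ind$allow_genes)
    if (identical(type, "del")) {
      start <- ind$start
      if (is.null(start)) {
        start <- sample_deletion_start(state, ind$size, allow_genes)
      }
      end <- start + ind$size - 1L
      if (end > nchar(state$seq)) stop("conflict: deletion exceeds region")
      if (!genes_span_ok(start, end, allow_genes))
        stop("conflict: deletion would split a gene (set allow_genes = TRUE)")
      evt <- log_event(list(kind = "indel", type = "del",
                            start = start, end = end, size = ind$size),
                       start = start, end = end)
    } else {
      after <- if (is.null(ind$after))
        sample_insertion_site(state, 0L) else ind$after
      evt <- log_event(list(kind = "indel", type = "ins", after = after,
                            insert_seq = random_dna(ind$size),
                            size = ind$size),
                       start = after)
    }
    state <- apply_event(state, evt)
    events <- c(events, list(evt))
  }

  inv <- p$inversion
  if (!is.null(inv)) {
    if (!is.null(inv$breakpoint_in_element)) {
      i <- match(inv$breakpoint_in_element, state$ann$id)
      if (is.na(i)) stop("conflict: unknown element for inversion breakpoint")
      start <- as.integer(floor((state$ann$start[i] + state$ann$end[i]) / 2))
      end <- if (!is.null(inv$end)) inv$end else start + inv$size - 1L
    } else {
      start <- inv$start; end <- inv$end
    }
    if (end > nchar(state$seq)) stop("conflict: inversion exceeds region")
    if (!genes_span_ok(start, end, isTRUE(inv$allow_genes)))
      stop("conflict: inversion would split a gene (set allow_genes = TRUE)")
    evt <- log_event(list(kind = "inversion", start = start, end = end),
                     start = start, end = end)
    state <- apply_event(state, evt)
    events <- c(events, list(evt))
  }

  dup <- p$duplication
  if (!is.null(dup)) {
    times <- if (is.null(dup$times)) 1L else as.integer(dup$times)
    evt <- log_event(list(kind = "duplication", start = dup$start,
                          end = dup$end, times = times),
                     start = dup$start, end = dup$end)
    state <- apply_event(state, evt)
    events <- c(events, list(evt))
  }

  derived <- region(state$seq, state$ann, name = lineage)
  list(region = derived,
       log = structure(list(lineage = lineage,
                            ancestor_length = nchar(ancestor$seq),
                            events = events),
                       class = "truth_log"),
       anc = state$anc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sample_deletion_start <- function(state, size, allow_genes) {
  n <- nchar(state$seq)
  g <- state$ann[state$ann$class == "gene", , drop = FALSE]
  for (try in 1:200) {
    start <- sample.int(n - size, 1L)
    end <- start + size - 1L
    bad <- !allow_genes && nrow(g) > 0L &&
      any(g$start <= end & g$end >= start)
    if (!bad) return(start)
  }
  stop("conflict: could not place a ", size, "-bp deletion clear of genes")
}

#' @export
print.truth_log <- function(x, ...) {
  kinds <- vapply(x$events, function(e) e$kind, character(1))
  cat(sprintf("<truth_log> lineage %s: %d events\n", x$lineage,
              length(x$events)))
  if (length(kinds)) print(table(kinds))
  invisible(x)
}

#' Replay a truth log against the ancestor
#'
#' Applies the logged events, in order, to the ancestral region. The
#' result reproduces the derived sequence byte-for-byte (the replay
#' contract of the truth log).
#'
#' @param ancestor The ancestral [region()].
#' @param log A `truth_log` from [evolve_lineage()].
#' @return The reconstructed derived [region()].
#' @export
replay_truth_log <- function(ancestor, log) {
  stopifnot(inherits(log, "truth_log"),
            nchar(ancestor$seq) == log$ancestor_length)
  state <- list(seq = ancestor$seq, ann = ancestor$ann,
                anc = seq_len(nchar(ancestor$seq)))
  for (evt in log$events) state <- apply_event(state, evt)
  region(state$seq, state$ann, name = log$lineage)
}

#' Simulate a pair of orthologous regions with known truth
#'
#' Builds the ancestor from `config` and evolves two lineages
#' (`config$lineage_a`, `config$lineage_b`), giving a region pair whose
#' every structural difference is recorded in the two truth logs.
#'
#' @param config A [sim_config()] with `lineage_a`/`lineage_b` set.
#' @return List of class `region_pair_sim`: `ancestor`, `a`, `b` (each a
#'   list `region`/`log`/`anc`), and `config`.
#' @export
simulate_region_pair <- function(config) {
  ancestor <- simulate_ancestral_region(config)
  pa <- config$lineage_a %||% list()
  pb <- config$lineage_b %||% list()
  pa$lineage <- pa$lineage %||% "A"
  pb$lineage <- pb$lineage %||% "B"
  pa$tsd_length <- pa$tsd_length %||% config$tsd_length
  pb$tsd_length <- pb$tsd_length %||% config$tsd_length
  pa$r <- pa$r %||% config$r
  pb$r <- pb$r %||% config$r
  a <- evolve_lineage(ancestor, pa, seed = config$seed + 1L)
  # keep lineage B's sampled insertion sites clear of lineage A's (in the
  # ancestral frame), so every lineage-specific insertion faces a clean
  # empty target site in the other region - the configuration TSD
  # polarization is built for; co-occupied sites are undecidable by TSD
  # evidence
  a_sites <- unlist(lapply(a$log$events, function(e)
    if (identical(e$kind, "te_insert")) e$anc_start else NULL))
  if (length(a_sites) && is.null(pb$avoid_anc))
    pb$avoid_anc <- a_sites
  b <- evolve_lineage(ancestor, pb, seed = config$seed + 2L)
  structure(list(ancestor = ancestor, a = a, b = b, config = config),
            class = "region_pair_sim")
}

#' Planted-insertion truth table of a simulated region pair
#'
#' @param sim A `region_pair_sim`.
#' @return Data frame: `id`, `lineage` (`A`, `B` or `ancestral`), derived
#'   `start`/`end` in the carrier region, `class`.
#' @export
truth_insertions <- function(sim) {
  stopifnot(inherits(sim, "region_pair_sim"))
  rows <- list()
  for (side in c("a", "b")) {
    lin <- toupper(side)
    for (evt in sim[[side]]$log$events) {
      if (!identical(evt$kind, "te_insert")) next
      i <- match(evt$id, sim[[side]]$region$ann$id)
      if (is.na(i)) next  # later removed by a deletion
      rows[[length(rows) + 1L]] <- data.frame(
        id = evt$id, lineage = lin,
        start = sim[[side]]$region$ann$start[i],
        end = sim[[side]]$region$ann$end[i],
        class = evt$class, stringsAsFactors = FALSE)
    }
  }
  anc_tes <- te_annotations(sim$ancestor)
  for (i in seq_len(nrow(anc_tes))) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = anc_tes$id[i], lineage = "ancestral",
      start = anc_tes$start[i], end = anc_tes$end[i],
      class = anc_tes$class[i], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows) %||% data.frame()
}

#' Add post-divergence flank noise to both regions of a pair
#'
#' Applies an extra, independent K2P substitution load of `d/2` per region
#' (so the pair gains `d` substitutions/site of divergence), emulating
#' sequence decay of flanks and target sites in real comparisons.
#'
#' @param sim A `region_pair_sim`.
#' @param d Added pairwise divergence, substitutions/site.
#' @param seed RNG seed.
#' @return The pair with noisy sequences (annotations unchanged).
#' @export
add_flank_divergence <- function(sim, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim$a$region$seq <- evolve_seq_k2p(sim$a$region$seq, d / 2,
                                     sim$config$ts_tv_ratio)
  sim$b$region$seq <- evolve_seq_k2p(sim$b$region$seq, d / 2,
                                     sim$config$ts_tv_ratio)
  sim
}
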