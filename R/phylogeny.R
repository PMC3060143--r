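#' K2P distance matrix for a set of aligned sequences
#'
#' @param seqs Named character vector of aligned sequences (equal length,
#'   at least 3).
#' @param min_sites Minimum usable columns per pair.
#' @return Symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
pairwise_distance_matrix <- function(seqs, min_sites = 50L) {
  stopifnot(length(seqs) >= 3L, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned to equal length")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k2p_distance(seqs[[i]], seqs[[j]], min_sites = min_sites)
      if (!k$valid)
        stop(sprintf("invalid (saturated or short) pair: %s vs %s",
                     names(seqs)[i], names(seqs)[j]))
      d[i, j] <- d[j, i] <- k$K
    }
  }
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must be labeled")
  if (any(!is.finite(d))) stop("distance matrix must be finite")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  invisible(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration: at each step the pair
#' minimizing the Q criterion `Q_ij = (n-2) d_ij - r_i - r_j` is joined,
#' with deterministic tie-breaking (the lowest index pair in the current
#' node ordering). Negative branch lengths are clamped to zero in the
#' returned tree; the raw values are retained in the
#' `raw_edge_length` attribute.
#'
#' @param d Labeled symmetric distance matrix (n >= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  fmt <- function(x) sprintf("%.15g", x)
  reps <- rownames(d)
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    hits <- which(q == min(q), arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    urep <- sprintf("(%s:%s,%s:%s)", reps[i], fmt(li), reps[j], fmt(lj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    reps <- c(reps[keep], urep)
    rownames(d2) <- colnames(d2) <- as.character(seq_len(n - 1L))
    d <- d2
    n <- n - 1L
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", reps[1], fmt(l1), reps[2],
                 fmt(l2), reps[3], fmt(l3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "raw_edge_length") <- tree$edge.length
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

# Descendant tip indices for every node of a phylo tree.
node_descendants <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(po)))
    desc[[po[r, 1L]]] <- c(desc[[po[r, 1L]]], desc[[po[r, 2L]]])
  desc
}

# Does `tips` (character) form one side of a bipartition of the unrooted
# tree, supported by an edge longer than min_support?
is_split <- function(tree, tips, min_support = 0) {
  labs <- tree$tip.label
  want <- sort(match(tips, labs))
  if (anyNA(want)) stop("unknown tip labels")
  n <- length(labs)
  all_tips <- seq_len(n)
  desc <- node_descendants(tree)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(1, nrow(tree$edge))
  for (r in seq_len(nrow(tree$edge))) {
    v <- tree$edge[r, 2L]
    s <- sort(desc[[v]])
    if (identical(s, want) || identical(sort(setdiff(all_tips, s)), want)) {
      if (el[r] > min_support) return(TRUE)
    }
  }
  FALSE
}

#' Classify gene-duplication timing relative to a speciation split
#'
#' Formalizes reading a duplicated-gene tree: the duplication predates the
#' speciation split when each paralog class forms its own clade containing
#' multiple species (the paralog clades each recapitulate the species
#' split); it postdates the split when leaves group by species
#' (within-species paralog pairs). Anything else - including clades
#' supported only by zero-length branches - is `unresolved`, never a
#' forced call.
#'
#' @param tree An `ape::phylo` tree of the duplicated gene copies.
#' @param species_of_leaf,paralog_of_leaf Named character vectors over
#'   `tree$tip.label`.
#' @param min_support Minimum supporting branch length for a clade
#'   (default 0, i.e. strictly positive).
#' @return `"before_split"`, `"after_split"` or `"unresolved"`.
#' @export
classify_duplication_timing <- function(tree, species_of_leaf,
                                        paralog_of_leaf,
                                        min_support = 0) {
  labs <- tree$tip.label
  if (!all(labs %in% names(species_of_leaf)) ||
      !all(labs %in% names(paralog_of_leaf)))
    stop("leaf metadata missing for some tips")
  sp <- species_of_leaf[labs]
  pg <- paralog_of_leaf[labs]
  if (length(unique(pg)) < 2L || length(unique(sp)) < 2L)
    stop("need >= 2 paralog classes across >= 2 species")
  paralog_clades <- vapply(unique(pg), function(cl) {
    tips <- labs[pg == cl]
    length(unique(sp[pg == cl])) >= 2L &&
      (length(tips) == length(labs) - 1L ||
         is_split(tree, tips, min_support))
  }, logical(1))
  if (all(paralog_clades)) return("before_split")
  species_clades <- vapply(unique(sp), function(s) {
    tips <- labs[sp == s]
    length(unique(pg[sp == s])) >= 2L &&
      (length(tips) == length(labs) - 1L ||
         is_split(tree, tips, min_support))
  }, logical(1))
  if (all(species_clades)) return("after_split")
  "unresolved"
}

find_branch <- function(tree, clade_tips, desc = node_descendants(tree)) {
  want <- sort(match(clade_tips, tree$tip.label))
  if (anyNA(want)) stop("unknown tip in branch specification")
  for (r in seq_len(nrow(tree$edge))) {
    if (identical(sort(desc[[tree$edge[r, 2L]]]), want)) return(r)
  }
  stop("no branch leads to clade {", paste(clade_tips, collapse = ","), "}")
}

# Leaf presence pattern implied by toggling a gene on `edges` of a rooted
# tree, starting absent at the root.
pattern_from_edges <- function(tree, edges, desc = node_descendants(tree)) {
  n <- length(tree$tip.label)
  state <- rep(0L, n)
  for (r in edges) {
    tips <- desc[[tree$edge[r, 2L]]]
    state[tips] <- 1L - state[tips]
  }
  stats::setNames(state, tree$tip.label)
}

#' Score gene gain/loss scenarios on a species tree
#'
#' Each scenario is a list of events, every event a gain or loss of one or
#' more genes on a named branch of the species tree; a scenario may also
#' declare genes present in the root ancestor (`ancestral`), which costs
#' no event. A scenario is feasible when replaying its events from the
#' root reproduces the observed gene-presence table; feasible scenarios
#' are ranked by event count. The minimum achievable count is also
#' computed by exhaustive search over node state assignments (root state
#' free), merging same-branch same-direction changes into single
#' (segmental) events; instances beyond `max_states` assignments are
#' rejected.
#'
#' @param table Binary genes x taxa matrix (rownames genes, colnames
#'   matching tree tips; every gene present somewhere).
#' @param species_tree Rooted `ape::phylo` species tree.
#' @param scenarios Named list; each scenario either a plain list of
#'   events `list(type = "gain"|"loss", branch = <tip labels of the clade
#'   below the branch>, genes = <gene ids>)`, or
#'   `list(ancestral = <gene ids present at the root>, events = <event
#'   list>)`.
#' @param max_states Exhaustive-search size guard (default 2e5).
#' @return Data frame ranked by event count: `scenario`, `n_events`,
#'   `feasible`, `rank`; attribute `min_events` holds the exhaustive
#'   minimum.
#' @export
score_gain_loss_scenarios <- function(table, species_tree, scenarios,
                                      max_states = 2e5) {
  table <- as.matrix(table)
  mode(table) <- "integer"
  if (any(rowSums(table) == 0L))
    stop("every gene must be present in at least one taxon")
  tips <- species_tree$tip.label
  if (!all(colnames(table) %in% tips))
    stop("table taxa must match species tree tips")
  table <- table[, tips, drop = FALSE]
  desc <- node_descendants(species_tree)

  check_scenario <- function(sc) {
    ancestral <- character()
    if (!is.null(sc$events) || !is.null(sc$ancestral)) {
      ancestral <- sc$ancestral %||% character()
      sc <- sc$events %||% list()
    }
    state <- matrix(0L, nrow(table), length(tips),
                    dimnames = list(rownames(table), tips))
    if (length(ancestral)) {
      g0 <- match(ancestral, rownames(table))
      if (anyNA(g0)) stop("unknown gene in ancestral set")
      state[g0, ] <- 1L
    }
    for (ev in sc) {
      r <- find_branch(species_tree, ev$branch, desc)
      g <- match(ev$genes, rownames(table))
      if (anyNA(g)) stop("unknown gene in scenario event")
      clade <- desc[[species_tree$edge[r, 2L]]]
      delta <- if (identical(ev$type, "gain")) 1L else -1L
      state[g, clade] <- state[g, clade] + delta
    }
    feasible <- all((state > 0L) == (table > 0L)) &&
      all(state %in% c(0L, 1L))
    list(feasible = feasible, n_events = length(sc))
  }

  res <- do.call(rbind, lapply(names(scenarios), function(nm) {
    ck <- check_scenario(scenarios[[nm]])
    data.frame(scenario = nm, n_events = ck$n_events,
               feasible = ck$feasible, stringsAsFactors = FALSE)
  }))
  res <- res[order(!res$feasible, res$n_events), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  attr(res, "min_events") <- exhaustive_min_events(table, species_tree,
                                                   desc, max_states)
  rownames(res) <- NULL
  res
}

exhaustive_min_events <- function(table, tree, desc, max_states) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  free <- (n + 1L):(n + m)  # all internal nodes, root state included
  patterns <- unique(apply(table, 1L, paste, collapse = ""))
  n_assign <- 2^length(free)
  if (n_assign^length(patterns) > max_states)
    stop("instance too large for exhaustive parsimony search")
  # per pattern: the set of (edge, direction) changes for each assignment
  per_pattern <- lapply(patterns, function(p) {
    leaf <- as.integer(strsplit(p, "")[[1L]])
    lapply(seq_len(n_assign) - 1L, function(code) {
      st <- integer(n + m)
      st[seq_len(n)] <- leaf
      st[free] <- bitwAnd(bitwShiftR(code, seq_along(free) - 1L), 1L)
      ch <- which(st[tree$edge[, 1L]] != st[tree$edge[, 2L]])
      if (length(ch) == 0L) return(character(0))
      dir <- ifelse(st[tree$edge[, 2L]] == 1L, "gain", "loss")
      paste0(ch, ":", dir[ch])
    })
  })
  combos <- expand.grid(lapply(per_pattern, seq_along))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    ev <- unique(unlist(lapply(seq_along(per_pattern), function(i)
      per_pattern[[i]][[combos[r, i]]])))
    best <- min(best, length(ev))
  }
  as.integer(best)
}
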