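random_additive_case <- function(n = 6) {
  tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1)))
  d <- stats::cophenetic(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

test_that("distance matrices are symmetric and delegate to K2P", {
  s <- rand_seq(400, seed = 1)
  seqs <- c(x = s, y = s, z = s)
  d0 <- pairwise_distance_matrix(seqs)
  expect_true(all(d0 == 0))
  set.seed(2)
  mut <- function(s, k) {
    v <- chars(s)
    i <- sample(length(v), k)
    for (j in i) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
    paste(v, collapse = "")
  }
  seqs2 <- c(x = s, y = mut(s, 12), z = mut(s, 30))
  d <- pairwise_distance_matrix(seqs2)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))
  # column-count oracle for one off-diagonal entry
  k <- k2p_distance(seqs2["y"], seqs2["z"])
  expect_equal(d["y", "z"], k$K)
  # a saturated pair fails loudly, naming the labels
  seqs3 <- c(a = paste(rep("A", 100), collapse = ""),
             b = paste(rep("G", 100), collapse = ""),
             c = s1 <- rand_seq(100))
  expect_error(pairwise_distance_matrix(seqs3), "a vs b")
})

test_that("neighbor joining gives the three-point closed form at n = 3", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["a"]], 1)  # (3 + 4 - 5) / 2
  expect_equal(lens[["b"]], 2)
  expect_equal(lens[["c"]], 3)
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(3)
  for (i in 1:25) {
    cs <- random_additive_case(6)
    mine <- neighbor_joining(cs$d)
    expect_equal(phangorn::RF.dist(mine, cs$tree), 0)
    dd <- stats::cophenetic(mine)[rownames(cs$d), colnames(cs$d)]
    expect_lt(max(abs(dd - cs$d)), 1e-9)
  }
})

test_that("n = 4 additive topology matches the four-point condition", {
  set.seed(4)
  for (i in 1:10) {
    cs <- random_additive_case(4)
    d <- cs$d
    labs <- rownames(d)
    sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
    pairing <- which.min(sums)  # the split pairs with the smallest sum
    mine <- neighbor_joining(d)
    split_pairs <- list(c(labs[1], labs[2]), c(labs[1], labs[3]),
                        c(labs[1], labs[4]))
    expect_true(tips_monophyletic(mine, split_pairs[[pairing]]))
  }
})

test_that("NJ topology is invariant under label permutation and validates input", {
  set.seed(5)
  cs <- random_additive_case(6)
  p <- sample(nrow(cs$d))
  t1 <- neighbor_joining(cs$d)
  t2 <- neighbor_joining(cs$d[p, p])
  expect_equal(phangorn::RF.dist(t1, t2), 0)
  bad <- cs$d; bad[1, 2] <- bad[1, 2] + 1  # asymmetric
  expect_error(neighbor_joining(bad), "symmetric")
  bad2 <- cs$d; bad2[1, 2] <- bad2[2, 1] <- Inf
  expect_error(neighbor_joining(bad2), "finite")
})

test_that("negative NJ branch lengths are clamped with raw values retained", {
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0) + 0, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 5.9  # forces a tiny negative internal fit
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  raw <- attr(tr, "raw_edge_length")
  expect_equal(length(raw), length(tr$edge.length))
})

test_that("duplication timing classifies before/after/unresolved", {
  sp <- c(s1_p1 = "s1", s2_p1 = "s2", s1_p2 = "s1", s2_p2 = "s2")
  pg <- c(s1_p1 = "p1", s2_p1 = "p1", s1_p2 = "p2", s2_p2 = "p2")
  before <- ape::unroot(ape::read.tree(
    text = "((s1_p1:0.1,s2_p1:0.1):0.5,(s1_p2:0.1,s2_p2:0.1):0.5);"))
  expect_identical(classify_duplication_timing(before, sp, pg),
                   "before_split")
  after <- ape::unroot(ape::read.tree(
    text = "((s1_p1:0.1,s1_p2:0.1):0.5,(s2_p1:0.1,s2_p2:0.1):0.5);"))
  expect_identical(classify_duplication_timing(after, sp, pg),
                   "after_split")
  # zero-length support: degrade to unresolved, never a wrong call
  star <- ape::unroot(ape::read.tree(
    text = "((s1_p1:0.1,s2_p1:0.1):0.0,(s1_p2:0.1,s2_p2:0.1):0.0);"))
  expect_identical(classify_duplication_timing(star, sp, pg),
                   "unresolved")
  expect_error(classify_duplication_timing(before, sp[-1], pg),
               "metadata")
})

test_that("duplication timing agrees with simulated gene histories", {
  set.seed(6)
  r <- 1e-8
  evolve <- function(s, d) retroscape:::evolve_seq_k2p(s, d)
  for (i in 1:5) {
    anc <- rand_seq(1200)
    # duplication before speciation: paralogs split first, then species
    p1 <- evolve(anc, 0.05); p2 <- evolve(anc, 0.05)
    seqs_before <- c(s1_p1 = evolve(p1, 0.01), s2_p1 = evolve(p1, 0.01),
                     s1_p2 = evolve(p2, 0.01), s2_p2 = evolve(p2, 0.01))
    # duplication after speciation: species split first, then paralogs
    l1 <- evolve(anc, 0.05); l2 <- evolve(anc, 0.05)
    seqs_after <- c(s1_p1 = evolve(l1, 0.01), s1_p2 = evolve(l1, 0.01),
                    s2_p1 = evolve(l2, 0.01), s2_p2 = evolve(l2, 0.01))
    sp <- c(s1_p1 = "s1", s2_p1 = "s2", s1_p2 = "s1", s2_p2 = "s2")
    pg <- c(s1_p1 = "p1", s2_p1 = "p1", s1_p2 = "p2", s2_p2 = "p2")
    tb <- neighbor_joining(pairwise_distance_matrix(seqs_before))
    ta <- neighbor_joining(pairwise_distance_matrix(seqs_after))
    expect_identical(classify_duplication_timing(tb, sp, pg),
                     "before_split")
    expect_identical(classify_duplication_timing(ta, sp, pg),
                     "after_split")
  }
})

test_that("scenario scoring ranks the lineage-gain history as most parsimonious", {
  inst <- gene_presence_instance()
  res <- score_gain_loss_scenarios(inst$table, inst$tree, inst$scenarios)
  expect_true(all(res$feasible))
  expect_identical(res$scenario[1], "aa_lineage_gains")
  expect_lt(res$n_events[res$scenario == "aa_lineage_gains"],
            res$n_events[res$scenario == "presplit_gains_bb_losses"])
  expect_lte(attr(res, "min_events"), min(res$n_events[res$feasible]))
})

test_that("a gene present everywhere needs zero events; infeasible scenarios flagged", {
  st <- ape::read.tree(text = "((t1,t2),t3);")
  tab <- matrix(1L, 1, 3, dimnames = list("g", c("t1", "t2", "t3")))
  sc <- list(ancestral_presence = list(ancestral = "g", events = list()))
  res <- score_gain_loss_scenarios(tab, st, sc)
  expect_true(res$feasible[1])
  expect_equal(res$n_events[1], 0L)
  expect_equal(attr(res, "min_events"), 0L)
  bad <- list(wrong = list(list(type = "gain", branch = "t1",
                                genes = "g")))
  res2 <- score_gain_loss_scenarios(tab, st, bad)
  expect_false(res2$feasible[1])
})

test_that("exhaustive minimum is never beaten by a feasible scenario on random tables", {
  set.seed(7)
  st <- ape::read.tree(text = "(((t1,t2),t3),t4);")
  for (i in 1:10) {
    tab <- matrix(sample(0:1, 8, replace = TRUE), 2, 4,
                  dimnames = list(c("g1", "g2"),
                                  c("t1", "t2", "t3", "t4")))
    if (any(rowSums(tab) == 0)) next
    # a naive feasible scenario: one gain per present tip per gene
    events <- list()
    for (g in rownames(tab)) for (t in colnames(tab)[tab[g, ] == 1])
      events[[length(events) + 1]] <- list(type = "gain", branch = t,
                                           genes = g)
    res <- score_gain_loss_scenarios(tab, st,
                                     list(tipwise = events))
    expect_true(res$feasible[1])
    expect_lte(attr(res, "min_events"), res$n_events[1])
  }
})
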