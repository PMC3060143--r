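test_that("block construction handles identity, insertion and inversion", {
  s <- rand_seq(30000, seed = 1)
  b0 <- build_colinearity_blocks(s, s)
  expect_equal(nrow(b0), 1)
  expect_equal(b0$a_start, 1); expect_equal(b0$a_end, 30000)
  expect_equal(b0$orientation, "forward")
  expect_equal(b0$identity, 1.0)

  ins <- rand_seq(3000)
  s2 <- paste0(substr(s, 1, 15000), ins, substr(s, 15001, 30000))
  b1 <- build_colinearity_blocks(s, s2)
  expect_equal(nrow(b1), 2)
  expect_equal(b1$b_start[2] - b1$b_end[1] - 1, 3000)
  expect_equal(b1$a_start[2] - b1$a_end[1] - 1, 0)

  s3 <- paste0(substr(s, 1, 10000), rc(substr(s, 10001, 20000)),
               substr(s, 20001, 30000))
  b2 <- build_colinearity_blocks(s, s3)
  expect_equal(nrow(b2), 3)
  expect_equal(b2$orientation, c("forward", "inverted", "forward"))

  expect_equal(nrow(build_colinearity_blocks(rand_seq(2000, 2),
                                             rand_seq(2000, 3))), 0)
})

test_that("blocks are non-overlapping and forward runs monotone in both regions", {
  for (seed in c(51, 52)) {
    sim <- noiseless_pair(seed, n_a = 5, n_b = 4, n_ancestral = 4)
    bl <- build_colinearity_blocks(sim$a$region, sim$b$region)
    expect_gt(nrow(bl), 1)
    expect_true(all(diff(bl$a_start) > 0))
    for (side in c("a", "b")) {
      ss <- bl[[paste0(side, "_start")]]; ee <- bl[[paste0(side, "_end")]]
      o <- order(ss)
      expect_true(all(ss[o][-1] > ee[o][-length(ee)]))
    }
    fwd <- bl[bl$orientation == "forward", ]
    expect_true(all(diff(fwd$b_start) > 0))
  }
})

test_that("TSD polarization matches the truth log exactly on noiseless pairs", {
  sim <- noiseless_pair(seed = 7, n_a = 7, n_b = 5, n_ancestral = 6)
  res <- polarization_concordance(sim)
  expect_equal(res$accuracy, 1.0)
  expect_gte(res$n, 7 + 5 + 2 * 6)
})

test_that("a substituted TSD copy at max_mismatch 0 yields ambiguous, tolerated at 1", {
  sim <- noiseless_pair(seed = 8, n_a = 1, n_b = 0, n_ancestral = 0,
                        region_length = 120000L)
  ann <- sim$a$region$ann
  i <- match("A_te_1", ann$id)
  # substitute one base of the right TSD copy
  pos <- ann$end[i] + 2L
  sq <- sim$a$region$seq
  old <- substr(sq, pos, pos)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(sq, pos, pos) <- new
  sim$a$region$seq <- sq
  bl <- build_colinearity_blocks(sim$a$region, sim$b$region)
  strict <- classify_te_insertions(sim$a$region, sim$b$region, bl,
                                   max_mismatch = 0)
  loose <- classify_te_insertions(sim$a$region, sim$b$region, bl,
                                  max_mismatch = 1)
  row_s <- strict[strict$element_id == "A_te_1", ]
  row_l <- loose[loose$element_id == "A_te_1", ]
  expect_identical(row_s$status, "ambiguous")
  expect_false(row_s$tsd_found)
  expect_identical(row_l$status, "unique_to_A")
})

test_that("polarization stays above 95% under 2% flank divergence", {
  acc <- 0; n <- 0
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed * 100, region_length = 400000,
                      n_ancestral_tes = 6,
                      lineage_a = list(age = 0, n_te = 15,
                                       substitutions = FALSE),
                      lineage_b = list(age = 0, n_te = 15,
                                       substitutions = FALSE))
    sim <- add_flank_divergence(simulate_region_pair(cfg), 0.02,
                                seed = seed)
    res <- polarization_concordance(sim, max_mismatch = 1)
    acc <- acc + res$accuracy * res$n
    n <- n + res$n
  }
  expect_gte(n, 100)
  expect_gte(acc / n, 0.95)
})

test_that("element states classify totally: intact, solo, truncated, split", {
  sim <- simulate_region_pair(sim_config(
    seed = 13, region_length = 250000, n_ancestral_tes = 4,
    lineage_a = list(age = 0, substitutions = FALSE, n_te = 2,
                     solo_ltr = "A_te_2"),
    lineage_b = list(age = 0, substitutions = FALSE,
                     inversion = list(size = 15000,
                                      breakpoint_in_element = "anc_te_2"))))
  ann_a <- sim$a$region$ann
  expect_identical(
    classify_element_state(ann_a[match("A_te_1", ann_a$id), ]), "intact")
  expect_identical(
    classify_element_state(ann_a[match("A_te_2", ann_a$id), ]), "solo")
  ann_b <- sim$b$region$ann
  frag <- ann_b[ann_b$parent %in% "anc_te_2", ][1, ]
  expect_identical(classify_element_state(frag), "split")
  trunc <- ann_a[match("A_te_1", ann_a$id), ]
  trunc$end <- trunc$start + 1999L  # lost its 3' half
  expect_identical(classify_element_state(trunc), "truncated")
})

test_that("large deletions are called with exact size and contents; threshold respected", {
  cfg <- sim_config(seed = 11, region_length = 300000, n_ancestral_tes = 10,
                    lineage_a = list(age = 0, substitutions = FALSE),
                    lineage_b = list(age = 0, substitutions = FALSE,
                                     indels = list(list(type = "del",
                                                        size = 37000,
                                                        start = 60000))))
  sim <- simulate_region_pair(cfg)
  bl <- build_colinearity_blocks(sim$a$region, sim$b$region)
  ind <- call_indels(bl, sim$a$region, sim$b$region)
  expect_equal(nrow(ind), 1)
  expect_identical(ind$side, "A")  # material present in A, deleted in B
  expect_equal(ind$size, 37000)
  contents <- strsplit(ind$contents, ",")[[1]]
  inside <- sim$a$region$ann[sim$a$region$ann$start >= ind$start &
                               sim$a$region$ann$end <= ind$end, ]
  expect_setequal(contents, inside$id)

  # a 2,999-bp difference stays below the default threshold
  cfg2 <- sim_config(seed = 12, region_length = 150000,
                     lineage_a = list(age = 0, substitutions = FALSE),
                     lineage_b = list(age = 0, substitutions = FALSE,
                                      indels = list(list(type = "del",
                                                         size = 2999,
                                                         start = 60000))))
  sim2 <- simulate_region_pair(cfg2)
  bl2 <- build_colinearity_blocks(sim2$a$region, sim2$b$region)
  expect_equal(nrow(call_indels(bl2, sim2$a$region, sim2$b$region)), 0)
  expect_equal(nrow(call_indels(bl2, sim2$a$region, sim2$b$region,
                                min_indel_size = 2999)), 1)

  # identical regions: no indels
  same <- build_colinearity_blocks(sim2$a$region, sim2$a$region)
  expect_equal(nrow(call_indels(same, sim2$a$region, sim2$a$region)), 0)
})

test_that("TSD-positive insertion gaps can be suppressed from indel calls", {
  sim <- noiseless_pair(seed = 14, n_a = 2, n_b = 0, n_ancestral = 0,
                        region_length = 150000L)
  bl <- build_colinearity_blocks(sim$a$region, sim$b$region)
  calls <- classify_te_insertions(sim$a$region, sim$b$region, bl)
  plain <- call_indels(bl, sim$a$region, sim$b$region)
  expect_equal(nrow(plain), 2)  # each 5-kb element exceeds the threshold
  suppressed <- call_indels(bl, sim$a$region, sim$b$region,
                            insertion_calls = calls,
                            suppress_insertions = TRUE)
  expect_equal(nrow(suppressed), 0)
})

test_that("inversions are recovered with near-exact breakpoints and split features", {
  cfg <- sim_config(seed = 11, region_length = 300000, n_ancestral_tes = 10,
                    lineage_a = list(age = 0, substitutions = FALSE),
                    lineage_b = list(age = 0, substitutions = FALSE,
                                     inversion = list(
                                       size = 20000,
                                       breakpoint_in_element = "anc_te_8")))
  sim <- simulate_region_pair(cfg)
  bl <- build_colinearity_blocks(sim$a$region, sim$b$region)
  inv <- call_inversions(bl, sim$a$region, sim$b$region)
  expect_equal(nrow(inv), 1)
  ev <- Filter(function(e) e$kind == "inversion", sim$b$log$events)[[1]]
  expect_lte(abs(inv$b_start - ev$start), 10)
  expect_lte(abs(inv$b_end - ev$end), 10)
  feats <- strsplit(inv$breakpoint_features, ",")[[1]]
  expect_true("anc_te_8" %in% feats)
  # no inverted blocks -> no calls
  same <- build_colinearity_blocks(sim$a$region, sim$a$region)
  expect_equal(nrow(call_inversions(same, sim$a$region, sim$a$region)), 0)
})
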