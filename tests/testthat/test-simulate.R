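test_that("ancestral region carries two gene clusters and is deterministic", {
  cfg <- sim_config(seed = 1, region_length = 100000,
                    n_genes_per_cluster = 6)
  r1 <- simulate_ancestral_region(cfg)
  expect_equal(region_length(r1), 100000)
  g <- gene_annotations(r1)
  expect_equal(nrow(g), 12)
  # two blocks: six genes left of the spacer midline, six right of it
  expect_equal(sum(g$end < 50000), 6)
  expect_equal(sum(g$start > 50000), 6)
  expect_true(all(diff(g$start) > 0))
  r2 <- simulate_ancestral_region(cfg)
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$ann, r2$ann)
  expect_error(
    simulate_ancestral_region(sim_config(region_length = 500,
                                         n_genes_per_cluster = 6)),
    "too short")
})

test_that("TE insertion creates the TSD arithmetic the annotation promises", {
  anc <- simulate_ancestral_region(sim_config(seed = 2))
  ev <- evolve_lineage(anc, list(lineage = "A", age = 0,
                                 substitutions = FALSE,
                                 te = list(list(internal_length = 3000,
                                                ltr_length = 1000)),
                                 tsd_length = 5),
                       seed = 3)
  expect_equal(region_length(ev$region), region_length(anc) + 5000 + 5)
  ins <- Filter(function(e) e$kind == "te_insert", ev$log$events)[[1]]
  i <- match(ins$id, ev$region$ann$id)
  es <- ev$region$ann$start[i]; ee <- ev$region$ann$end[i]
  left <- substr(ev$region$seq, es - 5, es - 1)
  right <- substr(ev$region$seq, ee + 1, ee + 5)
  expect_identical(left, right)
  # the single-copy site in the ancestor equals the duplicated site
  expect_identical(left, substr(anc$seq, ins$site, ins$site + 4))
})

test_that("truth logs replay to the exact derived sequence", {
  anc <- simulate_ancestral_region(sim_config(seed = 5,
                                              region_length = 150000,
                                              n_ancestral_tes = 2))
  ev <- evolve_lineage(anc, list(
    lineage = "A", age = 8e5, n_te = 3, solo_ltr = 1,
    indels = list(list(type = "del", size = 4000),
                  list(type = "ins", size = 3500)),
    inversion = list(size = 12000, breakpoint_in_element = "anc_te_1"),
    duplication = list(start = 30000, end = 34000, times = 2)),
    seed = 6)
  replayed <- replay_truth_log(anc, ev$log)
  expect_identical(replayed$seq, ev$region$seq)
  expect_identical(replayed$ann, ev$region$ann)
})

test_that("derived length reconciles with the logged events", {
  anc <- simulate_ancestral_region(sim_config(seed = 7))
  ev <- evolve_lineage(anc, list(lineage = "A", age = 5e5, n_te = 4,
                                 indels = list(list(type = "del",
                                                    size = 6000))),
                       seed = 8)
  delta <- 0L
  for (e in ev$log$events) {
    delta <- delta + switch(e$kind,
      te_insert = nchar(e$element_seq) + e$tsd_length,
      solo_ltr = -(e$del_end - e$del_start + 1L),
      indel = if (identical(e$type, "del")) -e$size else e$size,
      0L)
  }
  expect_equal(region_length(ev$region), region_length(anc) + delta)
})

test_that("solo-LTR reduction leaves one LTR flanked by the original TSD pair", {
  anc <- simulate_ancestral_region(sim_config(seed = 9))
  ev <- evolve_lineage(anc, list(lineage = "A", age = 0,
                                 substitutions = FALSE, n_te = 2,
                                 solo_ltr = "A_te_1"),
                       seed = 10)
  ann <- ev$region$ann
  i <- match("A_te_1", ann$id)
  expect_identical(ann$state[i], "solo")
  expect_equal(ann$end[i] - ann$start[i] + 1L, ann$ltr_length[i])
  left <- substr(ev$region$seq, ann$start[i] - 5, ann$start[i] - 1)
  right <- substr(ev$region$seq, ann$end[i] + 1, ann$end[i] + 5)
  expect_identical(left, right)
  expect_identical(left, ann$tsd[i])
})

test_that("an inversion breakpoint inside an element splits its annotation", {
  anc <- simulate_ancestral_region(sim_config(seed = 11,
                                              region_length = 200000,
                                              n_ancestral_tes = 4))
  ev <- evolve_lineage(anc, list(
    lineage = "B", age = 0, substitutions = FALSE,
    inversion = list(size = 15000, breakpoint_in_element = "anc_te_2")),
    seed = 12)
  frags <- ev$region$ann[ev$region$ann$parent %in% "anc_te_2", ,
                         drop = FALSE]
  expect_equal(nrow(frags), 2)
  expect_setequal(frags$id, c("anc_te_2.1", "anc_te_2.2"))
  expect_true(all(frags$state == "split"))
  inv <- Filter(function(e) e$kind == "inversion", ev$log$events)[[1]]
  # fragments sit on opposite flanks of the inverted segment
  expect_true(min(frags$end) < inv$start && max(frags$start) > inv$start ||
                min(frags$end) <= inv$end && max(frags$start) > inv$end)
})

test_that("LTR-pair divergence is calibrated to the K2P clock", {
  set.seed(42)
  age <- 2.1e6; r <- 1.3e-8; L <- 1000L; nrep <- 200L
  d_total <- 2 * r * age  # 0.0546
  raw <- numeric(nrep); K <- numeric(nrep)
  for (i in seq_len(nrep)) {
    el <- mutate_ltr_pair(te_element(0, L, id = "e"), age, r)
    ltrs <- substring(el$seq, c(1, L + 1), c(L, 2 * L))
    raw[i] <- mean(chars(ltrs[1]) != chars(ltrs[2]))
    K[i] <- k2p_distance(ltrs[1], ltrs[2])$K
  }
  # closed-form expected raw divergence of the K2P process at d = 0.0546
  # with ts:tv 2:1 (alpha = 2/3, beta = 1/6), frozen:
  # 1 - p_same = 3/4 - 1/4 exp(-2d/3) - 1/2 exp(-5d/3)
  expected_raw <- 3 / 4 - exp(-2 * d_total / 3) / 4 -
    exp(-5 * d_total / 3) / 2
  expect_equal(expected_raw, 0.0524275, tolerance = 1e-6)
  se <- stats::sd(raw) / sqrt(nrep)
  expect_lt(abs(mean(raw) - expected_raw), 2 * se)
  # the K2P correction recovers the true divergence (and hence the age)
  seK <- stats::sd(K) / sqrt(nrep)
  expect_lt(abs(mean(K) - d_total), 2 * seK)
})

test_that("older elements show larger LTR divergence; age zero means identity", {
  set.seed(43)
  div_of <- function(age, n = 60) {
    mean(vapply(seq_len(n), function(i) {
      el <- mutate_ltr_pair(te_element(0, 1000, id = "e"), age, 1.3e-8)
      ltrs <- substring(el$seq, c(1, 1001), c(1000, 2000))
      mean(chars(ltrs[1]) != chars(ltrs[2]))
    }, numeric(1)))
  }
  el0 <- mutate_ltr_pair(te_element(0, 500, id = "e"), 0, 1.3e-8)
  expect_identical(substr(el0$seq, 1, 500), substr(el0$seq, 501, 1000))
  expect_gt(div_of(2.1e6), div_of(1.2e6))
  expect_error(mutate_ltr_pair(te_element(0, 500, id = "e"), -1, 1.3e-8),
               "nonnegative")
})

test_that("population sampling respects frequencies and separability", {
  mk <- c("m1", "m2")
  fixed <- generate_population(mk, list(groups = list(
    list(name = "g", n = 10, freq = c(m1 = 1, m2 = 1)))), seed = 1)
  expect_true(all(fixed == 1L))
  expect_error(generate_population(mk, list(groups = list(
    list(name = "g", n = 2, freq = c(m1 = 1.2, m2 = 0))))),
    "frequencies")
  # diagnostic markers separate two groups with zero overlap
  f <- two_group_freqs()
  diag6 <- f$markers[1:6]
  m <- generate_population(f$markers, list(groups = list(
    list(name = "g1", n = 20, freq = f$g1),
    list(name = "g2", n = 20, freq = f$g2))), seed = 2)
  gr <- attr(m, "groups")
  expect_true(all(m[gr == "g1", diag6] == 1L))
  expect_true(all(m[gr == "g2", diag6] == 0L))
  # binomial sampling calibration at freq 0.5
  m2 <- generate_population("m1", list(groups = list(
    list(name = "g", n = 1000, freq = c(m1 = 0.5)))), seed = 3)
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(mean(m2) - 0.5), 2 * se)
})

test_that("seed determinism holds across the whole pair simulation", {
  cfg <- sim_config(seed = 21, region_length = 120000, n_ancestral_tes = 2,
                    lineage_a = list(age = 3e5, n_te = 2),
                    lineage_b = list(age = 3e5, n_te = 1))
  s1 <- simulate_region_pair(cfg)
  s2 <- simulate_region_pair(cfg)
  expect_identical(s1$a$region$seq, s2$a$region$seq)
  expect_identical(s1$b$region$seq, s2$b$region$seq)
  expect_identical(s1$a$log$events, s2$a$log$events)
})
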