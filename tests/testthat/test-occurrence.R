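test_that("depth filtering removes strictly sub-threshold samples only", {
  m <- toy_table()           # S1: 7800, S2: 5000, S3: 7500 total reads
  kept <- filter_low_depth(m, 5000)
  expect_identical(colnames(kept), c("S1", "S2", "S3"))  # 5000 is kept ("fewer than")
  m2 <- m
  m2["OTU_3", "S2"] <- 0L    # S2 drops to 4,999 total reads
  kept2 <- filter_low_depth(m2, 5000)
  expect_identical(colnames(kept2), c("S1", "S3"))
  expect_false("OTU_3" %in% rownames(kept2))  # all-zero after sample removal
  expect_identical(filter_low_depth(m, 0), m) # identity on samples
})

test_that("dominant/rare labels follow the 1% relative-abundance threshold", {
  m <- matrix(c(2624L, 2L, 7374L, 100L, 9900L, 0L), nrow = 3,
              dimnames = list(c("OTU_1", "OTU_2", "OTU_3"), c("S1", "S2")))
  st <- label_status(m, 0.01)
  expect_equal(colSums(st$rel), c(S1 = 1, S2 = 1))
  expect_identical(st$status["OTU_1", "S1"], "dominant")  # 26.24%
  expect_identical(st$status["OTU_2", "S1"], "rare")      # 0.02%
  expect_identical(st$status["OTU_2", "S2"], "dominant")  # exactly 1.00%
  expect_identical(st$status["OTU_3", "S2"], "absent")
  zero <- m; zero[, "S2"] <- 0L
  expect_error(label_status(zero), "filter_low_depth")
})

test_that("shared/disappeared/appeared partition every observed OTU exactly once", {
  subs <- matrix(c(1L, 1L, 0L, 5L, 0L, 0L, 0L, 3L, 0L), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("S1", "S2", "S3")))
  part <- partition_raw_vs_subs(c("A", "C", "D"), subs)
  expect_identical(part$shared, "A")        # raw and 2 subs
  expect_identical(sort(part$disappeared), c("C", "D"))  # raw only (C has no reads)
  expect_identical(part$appeared, "B")      # subs only
  universe <- c("A", "B", "C", "D")
  expect_setequal(unlist(part), universe)
  expect_identical(sum(lengths(part)), length(universe))
})

test_that("turnover classes cross raw status with sub status", {
  m <- matrix(c(600L, 200L, 150L, 5L,
                10L, 45L, 44L, 1L), nrow = 4,
              dimnames = list(c("D1", "A1", "D2", "R1"), c("S1", "S2")))
  st <- label_status(m, 0.01)
  # raw: D1 and D2 dominant; A1 appeared (raw-rare); R1 raw-rare
  tv <- classify_turnover(c("D1", "D2"), st)
  rec <- tv$records
  cls <- function(otu, s) rec$class[rec$otu == otu & rec$sample == s]
  expect_identical(cls("D1", "S1"), "D-to-D")
  expect_identical(cls("A1", "S1"), "R-to-D")  # appeared OTU dominant in sub
  expect_identical(cls("R1", "S1"), "R-to-R")
  expect_identical(cls("D2", "S2"), "D-to-D")
  # every occurrence has exactly one class; shares sum to covered abundance
  expect_identical(nrow(rec), sum(st$status != "absent"))
  shares <- tv$samples[, c("D-to-D", "R-to-D", "D-to-R", "R-to-R")]
  expect_equal(unname(rowSums(shares)), c(1, 1))
  # S1: D-to-D 0.785 vs R-to-D 0.209 -> D-to-D sub-community
  expect_identical(tv$samples$label[tv$samples$sample == "S1"], "D-to-D")
  # S2: D-to-D 0.54 vs R-to-D 0.45 -> D-to-D
  expect_identical(tv$samples$label[tv$samples$sample == "S2"], "D-to-D")
})

test_that("tied D-to-D and R-to-D shares label the sample R-to-D", {
  m <- matrix(c(50L, 50L), nrow = 2,
              dimnames = list(c("D1", "R1"), "S1"))
  tv <- classify_turnover("D1", label_status(m))
  expect_identical(tv$samples$label, "R-to-D")
})

test_that("dominance-frequency groups partition the OTU universe", {
  st <- structure(list(
    status = matrix("rare", 3, 12,
                    dimnames = list(c("A1", "B1", "C1"), paste0("S", 1:12))),
    rel = matrix(1 / 3, 3, 12,
                 dimnames = list(c("A1", "B1", "C1"), paste0("S", 1:12))),
    threshold = 0.01), class = "community_status")
  st$status["A1", ] <- "dominant"              # dominant in 12
  st$status["B1", 1:3] <- "dominant"           # dominant in 3
  grp <- group_by_dominance_frequency(st, raw = c("A1", "C1", "D1"))
  g <- setNames(grp$group, grp$otu)
  expect_identical(g[["A1"]], "A")
  expect_identical(g[["B1"]], "B")
  expect_identical(g[["C1"]], "C")             # present, never dominant
  expect_identical(g[["D1"]], "D")             # raw only
  expect_identical(sort(unique(grp$group)), c("A", "B", "C", "D"))
  # dominant + rare = appearances, for every OTU
  expect_identical(grp$dominant_count + grp$rare_count, grp$appearances)
})

test_that("POC reproduces the worked occurrence counts", {
  a <- compute_poc(801, 125)
  expect_equal(a$value, 125 / 676)
  expect_identical(a$display, 0.18)
  b <- compute_poc(151, 125)
  expect_equal(b$value, 125 / 26)
  expect_identical(b$display, 4.81)
  expect_identical(compute_poc(10, 10)$value, Inf)
  expect_identical(compute_poc(10, 0)$value, 0)
  expect_error(compute_poc(10, 11), "impossible")
  expect_error(compute_poc(0, 0), "positive")
})

test_that("the five POC categories are assigned per definition", {
  expect_identical(categorize_poc(c(0, 0.5, 1, 4.81, Inf)),
                   c("complete exclusion", "exclusion preference",
                     "neutral interaction", "coexistence preference",
                     "complete coexistence"))
})

test_that("pair universe uses a strict occurrence filter and ordered-pair counts", {
  pres <- matrix(1L, 169, 12,
                 dimnames = list(sprintf("OTU_%03d", 1:169), paste0("S", 1:12)))
  pu <- pair_universe(pres, 10)       # all occur in 12 > 10 sub-communities
  expect_identical(length(pu$otus), 169L)
  expect_identical(pu$n_pairs, 28392L)
  pres2 <- pres[1:3, , drop = FALSE]
  pres2[3, ] <- c(rep(1L, 10), 0L, 0L)   # occurs in exactly 10: excluded
  expect_identical(pair_universe(pres2, 10)$n_pairs, 2L)
  expect_identical(pair_universe(pres2[3, , drop = FALSE], 10)$n_pairs, 0L)
})

test_that("interaction types combine the two directed POC signs", {
  expect_identical(classify_pair_interaction(4.81, 0.18), "positive + negative")
  expect_identical(classify_pair_interaction(2, 3), "positive + positive")
  expect_identical(classify_pair_interaction(0.5, 0.2), "negative + negative")
  expect_identical(classify_pair_interaction(Inf, 1), "positive + positive")
  expect_identical(classify_pair_interaction(0, 1.2), "negative + positive")
})

test_that("poc_table matches a brute-force per-sample recount (oracle)", {
  set.seed(101)
  for (rep in 1:20) {
    pres <- matrix(runif(20 * 50) < runif(1, 0.1, 0.6), 20, 50,
                   dimnames = list(sprintf("OTU_%02d", 1:20),
                                   sprintf("S%02d", 1:50)))
    pres <- pres[rowSums(pres) > 0, , drop = FALSE]
    tbl <- poc_table(pres * 1L, otus = rownames(pres))
    oracle <- brute_force_poc(pres)
    key <- function(d) paste(d$focal, d$other)
    tbl <- tbl[order(key(tbl)), ]
    oracle <- oracle[order(key(oracle)), ]
    expect_identical(tbl$occ_focal, as.double(oracle$occ_focal))
    expect_identical(tbl$co_occ, as.double(oracle$co_occ))
    expect_identical(tbl$value, oracle$value)
    # categories partition the pair universe
    expect_identical(sum(table(tbl$category)), nrow(tbl))
  }
})

test_that("category anti-symmetry: positive + negative iff the signs split", {
  set.seed(7)
  pres <- matrix(runif(15 * 40) < 0.4, 15, 40,
                 dimnames = list(sprintf("OTU_%02d", 1:15),
                                 sprintf("S%02d", 1:40)))
  tbl <- poc_table(pres * 1L, min_occurrence = 0)
  pairs <- pair_interactions(tbl)
  split_sign <- pairs$poc_ab >= 1 & pairs$poc_ba < 1
  expect_identical(split_sign, pairs$type == "positive + negative")
  rev_sign <- pairs$poc_ab < 1 & pairs$poc_ba >= 1
  expect_identical(rev_sign, pairs$type == "negative + positive")
})

test_that("within-sample ranking is deterministic and tallies Top1 wins", {
  rel <- matrix(c(0.7, 0.2, 0.1,
                  0.5, 0.5, 0,
                  0.3, 0.3, 0.4), nrow = 3,
                dimnames = list(c("OTU_B", "OTU_A", "OTU_C"),
                                c("S1", "S2", "S3")))
  tops <- rank_top_n(rel, n = 5)
  r <- tops$ranks
  expect_identical(r$otu[r$sample == "S1" & r$rank == 1], "OTU_B")
  expect_identical(r$share[r$sample == "S1" & r$rank == 1], 0.7)
  # tie at 0.5: lexicographically smaller OTU ID wins
  expect_identical(r$otu[r$sample == "S2" & r$rank == 1], "OTU_A")
  expect_identical(r$otu[r$sample == "S3" & r$rank == 1], "OTU_C")
  expect_identical(sum(tops$top1_tally$wins), 3L)
  # absent OTUs are never ranked
  expect_false(any(r$otu[r$sample == "S2"] == "OTU_C"))
})
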