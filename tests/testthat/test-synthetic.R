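test_that("raw community hits the dominant structure exactly and reproducibly", {
  spec <- raw_community_spec(seed = 1)
  raw <- generate_raw_community(spec)
  p <- raw$abundance
  expect_length(p, 674)
  expect_lt(abs(sum(p) - 1), 1e-9)
  expect_identical(sum(p >= 0.01), 16L)
  expect_lt(abs(sum(p[p >= 0.01]) - 0.6859), 0.03)
  expect_true(any(!raw$detected))          # an undetected ("appeared") pool exists
  expect_identical(p, generate_raw_community(spec)$abundance)

  # smallest feasible single-dominant case: the 11 other taxa can just
  # carry the remaining 10% while each staying below 1%
  tiny <- generate_raw_community(
    raw_community_spec(n_otus = 12, n_dominant = 1,
                       dominant_total_share = 0.9, seed = 3))
  expect_length(tiny$abundance, 12)
  expect_lt(abs(sum(tiny$abundance) - 1), 1e-9)
  expect_identical(sum(tiny$abundance >= 0.01), 1L)
})

test_that("infeasible raw-community specs are rejected with parameter errors", {
  # 100 dominants above 1% cannot sum to 50%
  expect_error(raw_community_spec(n_otus = 200, n_dominant = 100,
                                  dominant_total_share = 0.5), "infeasible")
  # 26 non-dominants below 1% cannot carry 50%
  expect_error(raw_community_spec(n_otus = 30, n_dominant = 4,
                                  dominant_total_share = 0.5), "infeasible")
  expect_error(raw_community_spec(n_dominant = 700), "n_dominant")
  expect_error(dilution_spec(inoculum_cells = c(-1, 1, 1)), "positive")
  expect_error(dilution_spec(dilution_factors = c(1e-4, 1e-5),
                             wells_per_factor = 96), "equal length")
})

test_that("inoculation follows the Poisson dilution contract", {
  raw <- generate_raw_community(
    raw_community_spec(n_otus = 12, n_dominant = 1,
                       dominant_total_share = 0.9, seed = 3))
  # taxon at 90% abundance, 2 cells expected per well: mean count ~ 1.8
  dil <- dilution_spec(dilution_factors = 1, wells_per_factor = 4000,
                       inoculum_cells = 2, seed = 9)
  inoc <- sample_inocula(raw, dil)
  lam <- 2 * raw$abundance[1]
  expect_lt(abs(mean(inoc$counts[1, ]) - lam), 4 * sqrt(lam / 4000))
  expect_true(all(inoc$counts >= 0))
  expect_true(all(inoc$counts == round(inoc$counts)))
})

test_that("the default plate layout yields 1,056 uniquely identified wells", {
  raw <- generate_raw_community(raw_community_spec(seed = 1))
  inoc <- sample_inocula(raw, dilution_spec(seed = 2))
  expect_identical(ncol(inoc$counts), 1056L)
  expect_identical(anyDuplicated(inoc$wells$well_id), 0L)
  expect_identical(range(inoc$wells$plate), c(1L, 11L))
  expect_identical(as.integer(table(inoc$wells$dilution_factor)[
    as.character(c(1e-4, 0.5e-4, 1e-5))]), c(288L, 384L, 384L))
  expect_identical(inoc$wells$well_id[1], "P01_A1")
})

test_that("stronger dilution stochastically strips taxa from wells", {
  raw <- generate_raw_community(raw_community_spec(seed = 1))
  dil <- dilution_spec(dilution_factors = c(1e-4, 1e-5),
                       wells_per_factor = c(60, 60),
                       inoculum_cells = c(500, 50), seed = 4)
  inoc <- sample_inocula(raw, dil)
  richness <- colSums(inoc$counts > 0)
  hi <- richness[inoc$wells$dilution_factor == 1e-4]
  lo <- richness[inoc$wells$dilution_factor == 1e-5]
  expect_gt(median(hi), median(lo))
})

test_that("cultivation and sequencing respect well composition and depth", {
  counts <- matrix(c(7L, 0L, 0L, 0L, 3L, 5L, 0L, 0L, 0L),
                   nrow = 3,
                   dimnames = list(paste0("OTU_", 1:3), paste0("W", 1:3)))
  cult <- cultivation_spec(seed = 5)
  res <- cultivate_and_sequence(as_inocula(counts), cult)
  expect_identical(colSums(res$table), setNames(as.double(res$wells$depth),
                                                colnames(counts)))
  # single-taxon well: all reads belong to that taxon
  expect_identical(sum(res$table[, "W1"] > 0), 1L)
  expect_identical(res$table["OTU_1", "W1"], res$wells$depth[1])
  # empty well yields a zero-read sample
  expect_identical(sum(res$table[, "W3"]), 0L)
  expect_identical(res$wells$depth[3], 0L)
  # determinism
  res2 <- cultivate_and_sequence(as_inocula(counts), cult)
  expect_identical(res$table, res2$table)
  expect_error(cultivate_and_sequence(as_inocula(counts * 0L), cult), "empty")
})

test_that("lottery cultivation produces steep dominance hierarchies", {
  camp <- small_campaign()
  kept <- filter_low_depth(camp$table)
  st <- label_status(kept)
  n_dom <- colSums(st$status == "dominant")
  expect_gt(mean(n_dom >= 1 & n_dom <= 6), 0.5)
})

test_that("sub-5,000-read wells arise at the rate of the configured depth distribution", {
  camp <- small_campaign()
  removed <- mean(camp$wells$depth < 5000)
  expected <- pnbinom(4999, size = 1.5, mu = 20000)
  expect_lt(abs(removed - expected),
            4 * sqrt(expected * (1 - expected) / nrow(camp$wells)) + 0.01)
})

test_that("taxa undetected in the raw census can still occur in wells", {
  camp <- simulate_campaign(
    raw_community_spec(seed = 1),
    dilution_spec(dilution_factors = 1e-4, wells_per_factor = 60,
                  inoculum_cells = 500),
    cultivation_spec(), seed = 13)
  undet <- names(camp$raw$abundance)[!camp$raw$detected]
  expect_gt(sum(camp$inocula$counts[undet, ]), 0)
})

test_that("the campaign is seed-deterministic end to end", {
  a <- small_campaign(seed = 21)
  b <- small_campaign(seed = 21)
  expect_identical(a$table, b$table)
  expect_identical(a$wells, b$wells)
  c <- small_campaign(seed = 22)
  expect_false(identical(a$table, c$table))
})

test_that("crm cultivation mode integrates present taxa to final shares", {
  camp <- simulate_campaign(
    raw_community_spec(n_otus = 60, n_dominant = 4,
                       dominant_total_share = 0.5, seed = 1),
    dilution_spec(dilution_factors = 1e-4, wells_per_factor = 4,
                  inoculum_cells = 100),
    cultivation_spec(mode = "crm", crm_config = crm_config(n_resources = 5)),
    seed = 5)
  expect_identical(colSums(camp$table), setNames(as.double(camp$wells$depth),
                                                 colnames(camp$table)))
  # taxa absent from a well's inoculum get no reads
  expect_true(all(camp$table[camp$inocula$counts == 0L] == 0L))
})
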