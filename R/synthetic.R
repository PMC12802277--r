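#' Generate a heavy-tailed raw community profile
#'
#' Draws a log-normal rank-abundance profile over `n_otus` taxa and rescales
#' it so that exactly `n_dominant` taxa exceed the dominance threshold and
#' jointly hold `dominant_total_share` of the community. The remaining taxa
#' share the rest of the abundance; any of them that would cross the
#' threshold after rescaling is capped just below it and its surplus is
#' redistributed down the tail, preserving the long-tail structure. Taxa
#' whose relative abundance falls below `detection_floor` are flagged as
#' undetected: they model the extremely rare members that a raw sequencing
#' census misses but that dilution-cultivation can still retrieve (the
#' "appeared" pool).
#'
#' Taxa are named `OTU_1 ... OTU_n` in decreasing order of raw abundance.
#'
#' @param spec a [raw_community_spec()].
#'
#' @return An object of class `raw_community`: a list with elements
#'   `abundance` (named relative abundances summing to 1), `detected`
#'   (named logical), and `spec`.
#' @examples
#' raw <- generate_raw_community(raw_community_spec(seed = 1))
#' sum(raw$abundance >= 0.01)        # 16 dominant taxa
#' sum(raw$abundance[raw$abundance >= 0.01])  # ~0.6859
#' @export
generate_raw_community <- function(spec) {
  stopifnot(inherits(spec, "raw_community_spec"))
  thr <- spec$dominance_threshold
  with_seed(spec$seed, {
    x <- sort(stats::rlnorm(spec$n_otus, 0, spec$abundance_shape),
              decreasing = TRUE)
    nd <- spec$n_dominant
    # dominants: affine map keeps proportions of the sorted draw but pins
    # every dominant strictly above the threshold and their sum exactly on
    # dominant_total_share
    base <- thr * 1.1
    w <- x[seq_len(nd)] / sum(x[seq_len(nd)])
    dom <- base + (spec$dominant_total_share - nd * base) * w
    rest <- x[-seq_len(nd)]
    rest <- rest / sum(rest) * (1 - spec$dominant_total_share)
    # cap stragglers below the threshold, pushing surplus down the tail
    repeat {
      over <- rest >= thr * 0.95
      if (!any(over)) break
      surplus <- sum(rest[over] - thr * 0.9)
      rest[over] <- thr * 0.9
      rest[!over] <- rest[!over] * (1 + surplus / sum(rest[!over]))
    }
    ab <- c(dom, rest)
    names(ab) <- paste0("OTU_", seq_along(ab))
    structure(list(abundance = ab,
                   detected = ab >= spec$detection_floor,
                   spec = spec),
              class = "raw_community")
  })
}

#' @export
print.raw_community <- function(x, ...) {
  thr <- x$spec$dominance_threshold
  cat("Raw community:", length(x$abundance), "taxa,",
      sum(x$abundance >= thr), "dominant (>=", thr * 100, "%) holding",
      sprintf("%.2f%%;", 100 * sum(x$abundance[x$abundance >= thr])),
      sum(!x$detected), "taxa below the detection floor\n")
  invisible(x)
}

# 96-well plate identifiers P01_A1 ... : rows A-H, columns 1-12
well_ids <- function(n) {
  idx <- seq_len(n) - 1L
  plate <- idx %/% 96L + 1L
  within <- idx %% 96L
  sprintf("P%02d_%s%d", plate, LETTERS[within %/% 12L + 1L], within %% 12L + 1L)
}

#' Inoculate wells by dilution-to-extinction sampling
#'
#' Each well receives an independent Poisson number of cells of every taxon
#' with mean `inoculum_cells x relative abundance`, the standard stochastic
#' model of dilution-to-extinction: a taxon's chance of entering a well
#' depends only on its raw abundance and the dilution strength, so stronger
#' dilution strips the rare tail first while dominants persist.
#'
#' @param raw a `raw_community` from [generate_raw_community()].
#' @param dil a [dilution_spec()].
#'
#' @return An object of class `inocula`: a list with `counts` (integer
#'   matrix, taxa x wells, dimnames set) and `wells` (data.frame with
#'   `well_id`, `plate`, `dilution_factor`, `inoculum_cells`).
#' @export
sample_inocula <- function(raw, dil) {
  stopifnot(inherits(raw, "raw_community"), inherits(dil, "dilution_spec"))
  p <- raw$abundance
  if (abs(sum(p) - 1) > 1e-9) stop_param("raw abundances must sum to 1")
  n <- length(p)
  with_seed(dil$seed, {
    blocks <- lapply(seq_along(dil$dilution_factors), function(f) {
      w <- dil$wells_per_factor[f]
      matrix(stats::rpois(n * w, lambda = rep(dil$inoculum_cells[f] * p, w)),
             nrow = n)
    })
    counts <- do.call(cbind, blocks)
    ids <- well_ids(ncol(counts))
    dimnames(counts) <- list(names(p), ids)
    wells <- data.frame(
      well_id = ids,
      plate = (seq_len(ncol(counts)) - 1L) %/% 96L + 1L,
      dilution_factor = rep(dil$dilution_factors, dil$wells_per_factor),
      inoculum_cells = rep(dil$inoculum_cells, dil$wells_per_factor),
      stringsAsFactors = FALSE
    )
    structure(list(counts = counts, wells = wells), class = "inocula")
  })
}

# final community shares for the taxa present in one well
compete_well <- function(cnt_present, cult, traits = NULL) {
  if (cult$mode == "lottery") {
    sh <- cnt_present * stats::rlnorm(length(cnt_present), 0,
                                      cult$lottery_concentration)
    return(sh / sum(sh))
  }
  # crm mode: integrate the consumer-resource ODE for the present taxa,
  # biomass initialised in proportion to inoculum counts
  pool <- traits[names(cnt_present)]
  res <- simulate_crm(pool, cult$crm_config,
                      initial_biomass = cnt_present / sum(cnt_present))
  res$rel_abundance
}

#' Cultivate inoculated wells and sequence the outcome
#'
#' Taxa present in each well compete for two weeks' worth of growth, then
#' the well is sequenced. In `"lottery"` mode each present taxon draws a
#' log-normal competitive fitness and its final share is proportional to
#' inoculum count x fitness, which yields the steep dominance hierarchies
#' seen in cultivated wells (typically 1-6 taxa above 1\%) while retaining
#' a fat tail of low-abundance survivors. In `"crm"` mode every taxon is
#' assigned consumer-resource traits once per campaign (random functional
#' group, see [sample_traits()]) and each well integrates the community ODE.
#' Read counts are a multinomial draw of a well-specific negative-binomial
#' depth from the final shares; wells with an empty inoculum yield zero-read
#' samples.
#'
#' @param inocula an `inocula` object from [sample_inocula()].
#' @param cult a [cultivation_spec()].
#'
#' @return A list with `table` (integer read-count matrix, taxa x wells) and
#'   `wells` (the inoculum well table with a `depth` column of drawn
#'   sequencing depths).
#' @export
cultivate_and_sequence <- function(inocula, cult) {
  stopifnot(inherits(inocula, "inocula"), inherits(cult, "cultivation_spec"))
  counts <- inocula$counts
  if (all(counts == 0)) stop_param("all wells are empty")
  with_seed(cult$seed, {
    traits <- NULL
    if (cult$mode == "crm") {
      groups <- sample(c("HH", "HL", "LH", "LL"), nrow(counts), replace = TRUE)
      traits <- lapply(groups, sample_traits,
                       n_resources = cult$crm_config$n_resources)
      names(traits) <- rownames(counts)
    }
    depths <- as.integer(stats::rnbinom(ncol(counts),
                                        size = cult$depth_dispersion,
                                        mu = cult$depth_mean))
    reads <- matrix(0L, nrow(counts), ncol(counts), dimnames = dimnames(counts))
    for (j in seq_len(ncol(counts))) {
      pres <- which(counts[, j] > 0L)
      if (!length(pres)) { depths[j] <- 0L; next }
      sh <- compete_well(counts[pres, j], cult, traits)
      reads[pres, j] <- stats::rmultinom(1, depths[j], sh)[, 1]
    }
    wells <- inocula$wells
    wells$depth <- depths
    list(table = reads, wells = wells)
  })
}

#' Run the full synthetic dilution-cultivation campaign
#'
#' Convenience wrapper chaining [generate_raw_community()],
#' [sample_inocula()] and [cultivate_and_sequence()], with per-stage seeds
#' spawned deterministically from one master seed (seeds given inside the
#' individual specs take precedence).
#'
#' @param raw_spec,dil_spec,cult_spec stage specifications; see
#'   [raw_community_spec()], [dilution_spec()], [cultivation_spec()].
#' @param seed master seed.
#'
#' @return A list with `raw` (the `raw_community`), `inocula`, `table`
#'   (read-count matrix) and `wells` (well metadata with depths).
#' @export
simulate_campaign <- function(raw_spec = raw_community_spec(),
                              dil_spec = dilution_spec(),
                              cult_spec = cultivation_spec(),
                              seed = NULL) {
  seeds <- spawn_seeds(seed %||% stats::runif(1, 1, 2^30), 3)
  raw_spec$seed <- raw_spec$seed %||% seeds[1]
  dil_spec$seed <- dil_spec$seed %||% seeds[2]
  cult_spec$seed <- cult_spec$seed %||% seeds[3]
  raw <- generate_raw_community(raw_spec)
  inoc <- sample_inocula(raw, dil_spec)
  cs <- cultivate_and_sequence(inoc, cult_spec)
  list(raw = raw, inocula = inoc, table = cs$table, wells = cs$wells)
}
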