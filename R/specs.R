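#' Specification of a synthetic raw community
#'
#' Describes the heavy-tailed relative-abundance profile of the undiluted
#' ("raw") community from which sub-communities are inoculated. Defaults
#' emulate a wheat-rhizosphere soil census of 674 observed OTUs in which the
#' 16 dominant OTUs (each above 1\% relative abundance) jointly hold 68.59\%
#' of the reads.
#'
#' @param n_otus total number of taxa in the community.
#' @param n_dominant number of taxa that each exceed the 1\% dominance
#'   threshold.
#' @param dominant_total_share summed relative abundance of the dominant
#'   taxa, in (0, 1).
#' @param abundance_shape log-scale standard deviation of the log-normal
#'   rank-abundance draw controlling how heavy the rare tail is.
#' @param detection_floor relative abundance below which a taxon is treated
#'   as undetected by the raw census (default one read in ~50,000); such
#'   taxa are still real members and may later appear in cultivated wells.
#' @param dominance_threshold relative abundance defining a dominant taxon.
#' @param seed RNG seed; the same seed reproduces the identical profile.
#'
#' @return An object of class `raw_community_spec`.
#' @seealso [generate_raw_community()]
#' @export
raw_community_spec <- function(n_otus = 674, n_dominant = 16,
                               dominant_total_share = 0.6859,
                               abundance_shape = 2,
                               detection_floor = 2e-5,
                               dominance_threshold = 0.01,
                               seed = NULL) {
  if (n_otus < 2 || n_dominant < 1 || n_dominant >= n_otus)
    stop_param("need 1 <= n_dominant < n_otus")
  if (dominant_total_share <= 0 || dominant_total_share >= 1)
    stop_param("dominant_total_share must lie in (0, 1)")
  if (n_dominant * dominance_threshold >= dominant_total_share)
    stop_param("infeasible: ", n_dominant, " taxa above ",
               dominance_threshold * 100, "% cannot sum to ",
               dominant_total_share)
  if ((n_otus - n_dominant) * dominance_threshold <= 1 - dominant_total_share)
    stop_param("infeasible: the ", n_otus - n_dominant,
               " non-dominant taxa cannot all stay below the threshold")
  structure(list(n_otus = as.integer(n_otus),
                 n_dominant = as.integer(n_dominant),
                 dominant_total_share = dominant_total_share,
                 abundance_shape = abundance_shape,
                 detection_floor = detection_floor,
                 dominance_threshold = dominance_threshold,
                 seed = seed),
            class = "raw_community_spec")
}

#' Specification of a dilution-to-extinction inoculation layout
#'
#' Defaults reproduce the study layout: three dilution factors
#' (1.0e-4, 0.5e-4, 1.0e-5) inoculated into 3, 4 and 4 full 96-well plates,
#' i.e. 288 + 384 + 384 = 1,056 wells. `inoculum_cells` is the expected
#' total number of cells delivered to one well at each factor; by default it
#' scales linearly with the dilution factor (5e6 cells x factor).
#'
#' @param dilution_factors positive dilution factors, strongest first or in
#'   any order.
#' @param wells_per_factor number of wells inoculated at each factor.
#' @param inoculum_cells expected cells per well at each factor.
#' @param seed RNG seed for the inoculation draws.
#'
#' @return An object of class `dilution_spec`.
#' @seealso [sample_inocula()]
#' @export
dilution_spec <- function(dilution_factors = c(1e-4, 0.5e-4, 1e-5),
                          wells_per_factor = c(288L, 384L, 384L),
                          inoculum_cells = 5e6 * dilution_factors,
                          seed = NULL) {
  if (length(dilution_factors) != length(wells_per_factor) ||
      length(dilution_factors) != length(inoculum_cells))
    stop_param("dilution_factors, wells_per_factor and inoculum_cells ",
               "must have equal length")
  if (any(dilution_factors <= 0)) stop_param("dilution factors must be positive")
  if (any(inoculum_cells <= 0)) stop_param("inoculum_cells must be positive")
  if (any(wells_per_factor < 1)) stop_param("wells_per_factor must be >= 1")
  structure(list(dilution_factors = dilution_factors,
                 wells_per_factor = as.integer(wells_per_factor),
                 inoculum_cells = inoculum_cells,
                 seed = seed),
            class = "dilution_spec")
}

#' Specification of the cultivation and sequencing stage
#'
#' Two competition modes are available for turning per-well inocula into
#' final community compositions. `"lottery"` (default) draws each present
#' taxon a log-normal competitive fitness and sets its final share
#' proportional to inoculum count x fitness; `lottery_concentration` is the
#' log-scale standard deviation, larger values giving steeper winner-take-
#' most hierarchies. `"crm"` maps each present taxon to sampled consumer-
#' resource traits and integrates the community ODE of [simulate_crm()].
#' Sequencing depth per well is negative-binomial with mean `depth_mean`
#' and size `depth_dispersion`, producing a realistic sub-5,000-read tail.
#'
#' @param mode `"lottery"` or `"crm"`.
#' @param lottery_concentration positive skew parameter (lottery mode).
#' @param crm_config a [crm_config()] object (crm mode).
#' @param depth_mean,depth_dispersion negative-binomial mean and size of the
#'   per-well read depth.
#' @param seed RNG seed for cultivation and sequencing draws.
#'
#' @return An object of class `cultivation_spec`.
#' @seealso [cultivate_and_sequence()]
#' @export
cultivation_spec <- function(mode = c("lottery", "crm"),
                             lottery_concentration = 5,
                             crm_config = NULL,
                             depth_mean = 20000,
                             depth_dispersion = 1.5,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (depth_mean <= 0 || depth_dispersion <= 0)
    stop_param("depth_mean and depth_dispersion must be positive")
  if (mode == "lottery" && (!is.numeric(lottery_concentration) ||
                            lottery_concentration <= 0))
    stop_param("lottery_concentration must be a positive number")
  if (mode == "crm" && is.null(crm_config)) crm_config <- crm_config()
  structure(list(mode = mode,
                 lottery_concentration = lottery_concentration,
                 crm_config = crm_config,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 seed = seed),
            class = "cultivation_spec")
}
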