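# Consumer-resource model: species biomass N_i grows at
#   dN_i/dt = N_i * (g_i * sum_j U_ij R_j - m)
# while resources deplete at
#   dR_j/dt = -R_j * sum_i g_i N_i U_ij
# with growth rate g_i, uptake matrix U and a uniform per-capita
# maintenance cost m. With m = 0 total biomass + total resource is
# conserved exactly, which anchors the numerical tests.

#' Configuration of a consumer-resource simulation
#'
#' @param n_resources number of resource types.
#' @param t_end integration horizon in model time units.
#' @param maintenance uniform per-capita maintenance cost `m`.
#' @param total_resource total initial resource, split equally over the
#'   `n_resources` types unless `initial_resource` is given; keeping the
#'   total fixed makes runs comparable across resource-richness levels.
#' @param initial_resource optional explicit vector of initial resource
#'   concentrations.
#' @param extinction_floor species whose final biomass falls below this
#'   fraction of the total initial biomass are reported extinct.
#' @param rtol,atol relative and absolute solver tolerances.
#'
#' @return An object of class `crm_config`.
#' @export
crm_config <- function(n_resources = 10, t_end = 100, maintenance = 0.1,
                       total_resource = 10, initial_resource = NULL,
                       extinction_floor = 1e-9,
                       rtol = 1e-8, atol = 1e-10) {
  if (n_resources < 1) stop_param("n_resources must be >= 1")
  if (t_end <= 0) stop_param("t_end must be positive")
  if (maintenance < 0) stop_param("maintenance must be >= 0")
  R0 <- initial_resource %||% rep(total_resource / n_resources, n_resources)
  if (length(R0) != n_resources || any(R0 < 0))
    stop_param("initial_resource must be ", n_resources, " non-negative values")
  structure(list(n_resources = as.integer(n_resources), t_end = t_end,
                 maintenance = maintenance, initial_resource = R0,
                 extinction_floor = extinction_floor,
                 rtol = rtol, atol = atol),
            class = "crm_config")
}

#' Sample consumer-resource traits for one species
#'
#' Functional groups cross a growth-rate stratum with a metabolic-
#' flexibility (resource-use breadth) stratum: `HH` high growth + high
#' flexibility, `HL` high growth + low flexibility, `LH` low growth + high
#' flexibility, `LL` low + low. The strata are disjoint so group membership
#' is meaningful: growth is Uniform(0.8, 1.2) (high) vs Uniform(0.2, 0.4)
#' (low); breadth is a Uniform(60, 90)\% (high) vs Uniform(10, 30)\% (low)
#' fraction of the available resources, with a floor of one resource.
#' Uptake coefficients are Uniform(0.5, 1.5) on the usable resources and
#' zero elsewhere.
#'
#' @param group one of `"HH"`, `"HL"`, `"LH"`, `"LL"`.
#' @param n_resources number of resource types in the environment.
#'
#' @return A list with `group`, `growth`, `usable` (resource indices) and
#'   `uptake` (length-`n_resources` vector).
#' @export
sample_traits <- function(group = c("HH", "HL", "LH", "LL"), n_resources) {
  group <- match.arg(group)
  if (n_resources < 1) stop_param("n_resources must be >= 1")
  hi_growth <- substr(group, 1, 1) == "H"
  hi_breadth <- substr(group, 2, 2) == "H"
  growth <- if (hi_growth) stats::runif(1, 0.8, 1.2) else stats::runif(1, 0.2, 0.4)
  frac <- if (hi_breadth) stats::runif(1, 0.6, 0.9) else stats::runif(1, 0.1, 0.3)
  b <- max(1L, round(frac * n_resources))
  usable <- sort(sample.int(n_resources, b))
  uptake <- numeric(n_resources)
  uptake[usable] <- stats::runif(b, 0.5, 1.5)
  list(group = group, growth = growth, usable = usable, uptake = uptake)
}

#' Sample a community pool of species traits
#'
#' @param n_per_group species per functional group.
#' @param n_resources number of resource types.
#' @param groups functional groups to include.
#' @return A named list of traits (see [sample_traits()]); species IDs are
#'   `<group>_<index>`.
#' @export
sample_species_pool <- function(n_per_group = 20, n_resources,
                                groups = c("HH", "HL", "LH", "LL")) {
  pool <- list()
  for (grp in groups)
    for (i in seq_len(n_per_group))
      pool[[sprintf("%s_%02d", grp, i)]] <- sample_traits(grp, n_resources)
  pool
}

#' Right-hand side of the consumer-resource ODE system
#'
#' Returns the instantaneous rates `dN_i = N_i (g_i sum_j U_ij R_j - m)`
#' and `dR_j = -R_j sum_i g_i N_i U_ij`. Maintenance is per-capita, so
#' `N = 0` is absorbing, and with `m = 0` the identity
#' `sum(dN) + sum(dR) = 0` holds exactly.
#'
#' @param N species biomasses (length n).
#' @param R resource concentrations (length k).
#' @param growth growth rates `g` (length n).
#' @param uptake uptake matrix `U` (n x k).
#' @param maintenance per-capita maintenance cost `m`.
#'
#' @return list with elements `dN` and `dR`.
#' @export
crm_rhs <- function(N, R, growth, uptake, maintenance) {
  if (!is.matrix(uptake) || nrow(uptake) != length(N) ||
      ncol(uptake) != length(R) || length(growth) != length(N))
    stop_param("dimension mismatch between N, R, growth and uptake")
  gain <- growth * as.vector(uptake %*% R)
  list(dN = N * (gain - maintenance),
       dR = -R * as.vector(crossprod(uptake, growth * N)))
}

#' Integrate a consumer-resource community to its final composition
#'
#' Integrates the community ODE over `[0, t_end]` with an adaptive
#' stiff-capable solver (`deSolve::lsoda`). States are clamped at zero
#' inside the right-hand side and after integration to absorb round-off;
#' species ending below `extinction_floor` of the total initial biomass are
#' reported extinct and excluded from the relative abundances.
#'
#' @param pool named list of species traits (see [sample_traits()] /
#'   [sample_species_pool()]).
#' @param config a [crm_config()].
#' @param initial_biomass initial biomass per species: a single total split
#'   equally, or a full (optionally named) vector. Default: total 1, equal
#'   shares.
#' @param times optional vector of output times; when given, the full
#'   trajectory matrix is returned in `$trajectory`.
#'
#' @return An object of class `crm_result`: list with `N_final`, `R_final`,
#'   `survivors`, `rel_abundance` (over survivors, summing to 1 when any
#'   species survives), `group_shares`, `top1` (species ID of the most
#'   abundant survivor) and optionally `trajectory`.
#' @export
simulate_crm <- function(pool, config = crm_config(), initial_biomass = NULL,
                         times = NULL) {
  stopifnot(inherits(config, "crm_config"))
  n <- length(pool)
  k <- config$n_resources
  ids <- names(pool) %||% paste0("sp_", seq_len(n))
  g <- vapply(pool, `[[`, numeric(1), "growth")
  U <- do.call(rbind, lapply(pool, `[[`, "uptake"))
  if (ncol(U) != k) stop_param("trait uptake vectors do not match n_resources")
  N0 <- initial_biomass %||% 1
  if (length(N0) == 1L) N0 <- rep(N0 / n, n)
  if (length(N0) != n || any(N0 < 0)) stop_param("bad initial_biomass")
  m <- config$maintenance
  rhs <- function(t, y, p) {
    N <- pmax(y[seq_len(n)], 0)
    R <- pmax(y[n + seq_len(k)], 0)
    d <- crm_rhs(N, R, g, U, m)
    list(c(d$dN, d$dR))
  }
  tout <- times %||% c(0, config$t_end)
  out <- deSolve::ode(y = c(N0, config$initial_resource), times = tout,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = config$rtol, atol = config$atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("consumer-resource integration failed (istate = ", istate[1],
         ", steps = ", istate[2], ", rhs evals = ", istate[3], ")",
         call. = FALSE)
  fin <- pmax(out[nrow(out), -1], 0)
  N <- fin[seq_len(n)]
  R <- fin[n + seq_len(k)]
  names(N) <- ids
  surv <- N >= config$extinction_floor * sum(N0)
  rel <- setNames(numeric(n), ids)
  if (any(surv)) rel[surv] <- N[surv] / sum(N[surv])
  grp <- vapply(pool, `[[`, character(1), "group")
  res <- list(N_final = N, R_final = unname(R), survivors = ids[surv],
              rel_abundance = rel,
              group_shares = tapply(rel, grp, sum),
              top1 = if (any(surv)) ids[which.max(rel)] else NA_character_)
  if (!is.null(times)) res$trajectory <- out
  structure(res, class = "crm_result")
}

#' Trait-based nomination experiment (Step 1)
#'
#' Simulates community assembly across resource-richness levels: at each
#' level and replicate a fresh pool of species (`n_per_group` per functional
#' group) is drawn, all species start with equal biomass, and the community
#' is integrated to `t_end`. The summed relative abundance of each
#' functional group measures how strongly that trait combination is
#' "nominated" by competition; high-growth/high-flexibility (HH) species
#' are expected to dominate increasingly with resource complexity.
#'
#' @param replicates replicate communities per resource level.
#' @param resource_levels numbers of resource types to assemble under.
#' @param n_per_group species per functional group.
#' @param config a [crm_config()]; its `n_resources` is overridden per
#'   level while the total initial resource stays fixed.
#' @param seed master seed (one per-replicate child seed is spawned per
#'   level x replicate).
#'
#' @return An object of class `nomination_summary`: list with `shares`
#'   (data.frame: `level`, `replicate`, one column per group) and `summary`
#'   (per-level group means and standard deviations).
#' @export
run_nomination <- function(replicates = 100,
                           resource_levels = c(1, 5, 10, 20),
                           n_per_group = 20,
                           config = crm_config(), seed = NULL) {
  groups <- c("HH", "HL", "LH", "LL")
  seeds <- matrix(spawn_seeds(seed %||% stats::runif(1, 1, 2^30),
                              replicates * length(resource_levels)),
                  nrow = replicates)
  rows <- list()
  for (li in seq_along(resource_levels)) {
    k <- resource_levels[li]
    cfg <- config
    cfg$n_resources <- as.integer(k)
    cfg$initial_resource <- rep(sum(config$initial_resource) / k, k)
    for (r in seq_len(replicates)) {
      sim <- with_seed(seeds[r, li], {
        pool <- sample_species_pool(n_per_group, k, groups)
        simulate_crm(pool, cfg)
      })
      rows[[length(rows) + 1L]] <-
        data.frame(level = k, replicate = r,
                   as.list(sim$group_shares[groups]),
                   stringsAsFactors = FALSE)
    }
  }
  shares <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(shares, shares$level), function(d) {
    data.frame(level = d$level[1], group = groups,
               mean_share = vapply(groups, function(g) mean(d[[g]]), 0),
               sd_share = vapply(groups, function(g) stats::sd(d[[g]]), 0),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(shares = shares, summary = agg,
                 resource_levels = resource_levels, replicates = replicates),
            class = "nomination_summary")
}

#' Fixed pool of trait-equalised HH dominant candidates
#'
#' Builds the candidate pool used by the voting experiments. All candidates
#' share an identical growth rate, identical breadth and unit uptake —
#' uniform intrinsic competitiveness — and differ only in which resources
#' they use. Resource subsets are assigned by a balanced greedy design
#' (each candidate takes the currently least-used resources, random
#' tie-breaks, duplicate subsets rejected), so every resource supports the
#' same number of candidates and, absent any rare background, all
#' candidates tie exactly. Whatever asymmetry decides the winner must then
#' come from the rare taxa.
#'
#' @param n_candidates number of candidate species.
#' @param n_resources number of resource types.
#' @param breadth_frac fraction of resources each candidate uses (floor 1).
#' @param growth common growth rate (centre of the high stratum).
#' @param seed RNG seed fixing the candidate pool.
#'
#' @return Named list of traits (`HH_01`, `HH_02`, ...).
#' @export
hh_candidates <- function(n_candidates = 20, n_resources = 10,
                          breadth_frac = 0.7, growth = 1, seed = NULL) {
  k <- n_resources
  b <- max(1L, min(k, round(breadth_frac * k)))
  # cyclic-family construction: family f uses offset pattern
  # {step_f * j mod k, j = 0..b-1} shifted by every start 0..k-1, so each
  # full family covers every resource exactly b times and subsets within a
  # family are distinct; different (coprime) steps keep families apart
  steps <- Filter(function(s) {
    g <- function(a, bb) if (bb == 0) a else g(bb, a %% bb)
    g(s, k) == 1
  }, seq_len(max(k - 1, 1)))
  with_seed(seed, {
    relabel <- sample.int(k)
    subsets <- list()
    f <- 1L
    while (length(subsets) < n_candidates) {
      step <- steps[(f - 1L) %% length(steps) + 1L]
      offs <- unique((step * (seq_len(b) - 1L)) %% k)
      for (start in seq_len(k) - 1L) {
        sel <- sort(relabel[(start + offs) %% k + 1L])
        key <- paste(sel, collapse = ",")
        if (!key %in% names(subsets)) subsets[[key]] <- sel
        if (length(subsets) >= n_candidates) break
      }
      f <- f + 1L
      if (f > 4L * length(steps)) break    # exhausted distinct subsets
    }
    # rare degenerate shapes (e.g. b = k): pad with duplicates of the design
    while (length(subsets) < n_candidates)
      subsets[[length(subsets) + 1L]] <- subsets[[1L]]
    subsets <- subsets[sample.int(n_candidates)]
    pool <- list()
    for (i in seq_len(n_candidates)) {
      sel <- subsets[[i]]
      uptake <- numeric(k)
      uptake[sel] <- 1
      pool[[sprintf("HH_%02d", i)]] <-
        list(group = "HH", growth = growth, usable = sel, uptake = uptake)
    }
    pool
  })
}

# one rare background species; when targeted_sets is non-empty the species
# picks one targeted candidate and draws its usable resources preferentially
# (probability `bias`) from that candidate's resource set
sample_rare_species <- function(n_resources, groups = c("HL", "LH", "LL"),
                                targeted_sets = list(), bias = 0.9) {
  grp <- sample(groups, 1)
  tr <- sample_traits(grp, n_resources)
  if (length(targeted_sets)) {
    cset <- targeted_sets[[sample.int(length(targeted_sets), 1)]]
    b <- length(tr$usable)
    w <- rep((1 - bias) / max(1, n_resources - length(cset)), n_resources)
    w[cset] <- bias / length(cset)
    tr$usable <- sort(sample.int(n_resources, b, prob = w))
    tr$uptake <- numeric(n_resources)
    tr$uptake[tr$usable] <- stats::runif(b, 0.5, 1.5)
  }
  tr
}

# shared campaign loop for the voting experiments
vote_campaign <- function(cands, replicates, n_rare, config, seeds,
                          candidate_biomass, targeted_sets = list(),
                          bias = 0.9, rare_groups = c("HL", "LH", "LL")) {
  n_c <- length(cands)
  top1 <- character(replicates)
  for (r in seq_len(replicates)) {
    sim <- with_seed(seeds[r], {
      rare <- lapply(seq_len(n_rare), function(i)
        sample_rare_species(config$n_resources, rare_groups,
                            targeted_sets, bias))
      names(rare) <- sprintf("rare_%02d", seq_len(n_rare))
      N0 <- c(rep(candidate_biomass / n_c, n_c),
              rep((1 - candidate_biomass) / n_rare, n_rare))
      simulate_crm(c(cands, rare), config, initial_biomass = N0)
    })
    top1[r] <- sim$top1
  }
  wins <- setNames(integer(n_c), names(cands))
  tab <- table(top1)
  wins[intersect(names(tab), names(wins))] <-
    as.integer(tab[intersect(names(tab), names(wins))])
  list(top1 = top1,
       tally = data.frame(candidate = names(wins), wins = unname(wins),
                          stringsAsFactors = FALSE))
}

#' Rare-background voting experiment (Step 2)
#'
#' Fixes one pool of trait-equalised HH dominant candidates (see
#' [hh_candidates()]) and, in each replicate, adds a fresh random rare
#' background of `n_rare` species drawn from the HL/LH/LL groups. Initial
#' biomass is heavily skewed: `candidate_biomass` (default 95\%) is split
#' equally among the candidates and the remainder equally among the rare
#' species. The most abundant species at `t_end` (Top1) is recorded per
#' replicate; because the candidates are intrinsically equivalent, the
#' distribution of Top1 identities measures the "voting power" of the rare
#' background.
#'
#' @param replicates number of replicate communities.
#' @param n_candidates,n_rare pool sizes.
#' @param candidate_biomass initial biomass fraction given to candidates.
#' @param config a [crm_config()] (default: 10-resource environment).
#' @param even_split draw the rare background evenly from HL/LH/LL instead
#'   of uniformly at random.
#' @param seed master seed; the candidate pool uses a dedicated child seed
#'   so it is identical across replicates.
#'
#' @return An object of class `voting_summary`: list with `top1` (winner ID
#'   per replicate), `tally` (wins per candidate; totals equal `replicates`
#'   whenever every winner is a candidate), and `candidates`.
#' @export
run_voting <- function(replicates = 100, n_candidates = 20, n_rare = 60,
                       candidate_biomass = 0.95, config = crm_config(),
                       even_split = FALSE, seed = NULL) {
  seeds <- spawn_seeds(seed %||% stats::runif(1, 1, 2^30), replicates + 1)
  cands <- hh_candidates(n_candidates, config$n_resources, seed = seeds[1])
  groups <- if (even_split) rep(c("HL", "LH", "LL"), length.out = n_rare) else
    c("HL", "LH", "LL")
  camp <- vote_campaign(cands, replicates, n_rare, config, seeds[-1],
                        candidate_biomass, rare_groups = groups)
  structure(c(camp, list(candidates = cands, replicates = replicates)),
            class = "voting_summary")
}

#' Structured-rare-background experiment (Step 3)
#'
#' Contrasts two scenarios over the same fixed candidate pool and the same
#' per-replicate seeds: a random rare background (as in [run_voting()]) and
#' a structured one in which every rare species preferentially overlaps the
#' resource profile of one of the first `targeted` candidates (each rare
#' species picks a targeted candidate and draws its usable resources with
#' probability `bias` from that candidate's resource set). The targeted
#' candidates face elevated interference; the remaining ("shielded")
#' candidates are expected to win Top1 more often, shifting the Top1
#' frequency distribution relative to the random scenario.
#'
#' @inheritParams run_voting
#' @param targeted number of candidates the rare background is biased
#'   toward (the first `targeted` candidate IDs). `0` applies no bias and
#'   reproduces the random scenario exactly.
#' @param bias probability mass a structured rare species places on its
#'   target's resource set.
#'
#' @return A list with `random` and `structured` campaign results (each
#'   with `top1` and `tally`), `targeted_ids`, `shielded_ids`,
#'   `targeted_wins` / `shielded_wins` (structured scenario), and `tv`, the
#'   total-variation distance between the two Top1 frequency vectors.
#' @export
run_structured <- function(replicates = 100, targeted = 10, bias = 0.9,
                           n_candidates = 20, n_rare = 60,
                           candidate_biomass = 0.95, config = crm_config(),
                           seed = NULL) {
  if (targeted > n_candidates)
    stop_param("targeted exceeds the number of candidates")
  seeds <- spawn_seeds(seed %||% stats::runif(1, 1, 2^30), replicates + 1)
  cands <- hh_candidates(n_candidates, config$n_resources, seed = seeds[1])
  targeted_ids <- names(cands)[seq_len(targeted)]
  shielded_ids <- setdiff(names(cands), targeted_ids)
  tsets <- lapply(cands[targeted_ids], `[[`, "usable")
  random <- vote_campaign(cands, replicates, n_rare, config, seeds[-1],
                          candidate_biomass)
  structured <- vote_campaign(cands, replicates, n_rare, config, seeds[-1],
                              candidate_biomass, targeted_sets = tsets,
                              bias = bias)
  winners <- union(random$top1, structured$top1)
  freq <- function(x) table(factor(x, winners)) / length(x)
  list(random = random, structured = structured,
       targeted_ids = targeted_ids, shielded_ids = shielded_ids,
       targeted_wins = sum(structured$top1 %in% targeted_ids),
       shielded_wins = sum(structured$top1 %in% shielded_ids),
       tv = 0.5 * sum(abs(freq(random$top1) - freq(structured$top1))),
       replicates = replicates)
}
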