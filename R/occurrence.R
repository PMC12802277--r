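# The empirical analysis stage. An OTU table is a non-negative integer
# matrix with taxa as rows and samples (wells) as columns, both dimnames set.

check_otu_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop_param("an OTU table must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop_param("OTU table needs OTU row names and sample column names")
  if (anyDuplicated(rownames(table)) || anyDuplicated(colnames(table)))
    stop_param("duplicate OTU or sample IDs")
  if (any(table < 0) || any(table != round(table)))
    stop_param("read counts must be non-negative integers")
  invisible(table)
}

# presence = at least one read (no per-OTU count floor within retained samples)
otu_presence <- function(x) {
  if (inherits(x, "community_status")) return(x$status != "absent")
  check_otu_table(x) >= 1
}

present_otus <- function(x) {
  if (inherits(x, "raw_community")) return(names(x$abundance)[x$detected])
  if (is.character(x)) return(x)
  rownames(x)[rowSums(otu_presence(x)) > 0]
}

#' Remove samples with insufficient sequencing depth
#'
#' Drops every sample whose total read count is strictly below `min_reads`
#' (the study cut-off of 5,000 reads balances diversity retention against
#' sample size), then drops OTUs left with zero reads everywhere. Sample and
#' OTU order is otherwise preserved.
#'
#' @param table OTU count matrix (taxa x samples).
#' @param min_reads minimum total reads for a sample to be retained.
#'
#' @return The filtered count matrix (possibly with zero columns).
#' @export
filter_low_depth <- function(table, min_reads = 5000) {
  check_otu_table(table)
  if (min_reads < 0) stop_param("min_reads must be >= 0")
  kept <- table[, colSums(table) >= min_reads, drop = FALSE]
  kept[rowSums(kept) > 0, , drop = FALSE]
}

#' Label every OTU occurrence as dominant, rare or absent
#'
#' Converts counts to within-sample relative abundances and assigns each
#' OTU a status per sample: `absent` (zero reads), `dominant` (relative
#' abundance at or above `threshold`, by convention 1.0\%), or `rare`.
#'
#' @param table OTU count matrix with no zero-total samples (depth-filter
#'   first; see [filter_low_depth()]).
#' @param threshold dominance threshold on relative abundance.
#'
#' @return An object of class `community_status`: list with `rel` (relative
#'   abundance matrix, columns summing to 1), `status` (character matrix in
#'   `absent`/`rare`/`dominant`), and `threshold`.
#' @export
label_status <- function(table, threshold = 0.01) {
  check_otu_table(table)
  tot <- colSums(table)
  if (any(tot == 0))
    stop_param("zero-total sample(s) ",
               paste(colnames(table)[tot == 0][1:min(3, sum(tot == 0))],
                     collapse = ", "),
               "; remove them with filter_low_depth() first")
  rel <- sweep(table, 2, tot, "/")
  status <- matrix("rare", nrow(rel), ncol(rel), dimnames = dimnames(rel))
  status[rel == 0] <- "absent"
  status[rel >= threshold] <- "dominant"
  structure(list(rel = rel, status = status, threshold = threshold),
            class = "community_status")
}

#' @export
print.community_status <- function(x, ...) {
  cat("Community status:", nrow(x$rel), "OTUs x", ncol(x$rel), "samples,",
      "dominance threshold", x$threshold * 100, "%\n")
  print(table(factor(x$status, c("absent", "rare", "dominant"))))
  invisible(x)
}

#' Partition OTUs into shared, disappeared and appeared sets
#'
#' Compares the raw community with the pooled sub-communities: `shared`
#' OTUs occur in both, `disappeared` OTUs occur only in the raw community,
#' and `appeared` OTUs occur only in sub-communities — typically extremely
#' rare members that the raw census missed but dilution-cultivation
#' retrieved. The three sets are disjoint and cover every observed OTU.
#'
#' @param raw the raw community: a `raw_community` object, a character
#'   vector of present OTU IDs, or a one-sample OTU table.
#' @param subs the sub-communities: an OTU table or `community_status`.
#'
#' @return A list of character vectors `shared`, `disappeared`, `appeared`.
#' @export
partition_raw_vs_subs <- function(raw, subs) {
  raw_in <- present_otus(raw)
  sub_in <- present_otus(subs)
  list(shared = intersect(raw_in, sub_in),
       disappeared = setdiff(raw_in, sub_in),
       appeared = setdiff(sub_in, raw_in))
}

# raw status over a universe of OTU ids: dominant / rare; OTUs undetected in
# the raw community (the appeared pool) count as raw-rare
raw_status_vector <- function(raw, universe) {
  out <- setNames(rep("rare", length(universe)), universe)
  if (inherits(raw, "raw_community")) {
    thr <- raw$spec$dominance_threshold
    dom <- names(raw$abundance)[raw$detected & raw$abundance >= thr]
  } else if (is.character(raw)) {
    dom <- raw
  } else {
    st <- label_status(raw)
    dom <- rownames(st$status)[st$status[, 1] == "dominant"]
  }
  out[universe %in% dom] <- "dominant"
  out
}

#' Classify dominance turnover from the raw community to sub-communities
#'
#' Every occurrence of an OTU in a sub-community is assigned one of four
#' turnover classes by crossing its raw-community status with its
#' sub-community status: `D-to-D` (dominant to dominant), `R-to-D` (rare to
#' dominant), `D-to-R` and `R-to-R`. Newly appeared OTUs count as raw-rare.
#' Per sample, the summed relative abundance of each class is reported, and
#' the sample is labelled a `D-to-D` sub-community when the D-to-D share
#' strictly exceeds the R-to-D share, otherwise an `R-to-D` sub-community.
#'
#' @param raw the raw community (as in [partition_raw_vs_subs()]); if a
#'   character vector it is interpreted as the raw-dominant OTU IDs.
#' @param status a `community_status` for the sub-communities.
#'
#' @return A list with `records` (data.frame: `otu`, `sample`, `class`) and
#'   `samples` (data.frame: per-sample shares of the four classes and the
#'   sub-community `label`).
#' @export
classify_turnover <- function(raw, status) {
  stopifnot(inherits(status, "community_status"))
  st <- status$status
  raw_st <- raw_status_vector(raw, rownames(st))
  idx <- which(st != "absent", arr.ind = TRUE)
  cls <- paste0(ifelse(raw_st[rownames(st)[idx[, 1]]] == "dominant", "D", "R"),
                "-to-",
                ifelse(st[idx] == "dominant", "D", "R"))
  records <- data.frame(otu = rownames(st)[idx[, 1]],
                        sample = colnames(st)[idx[, 2]],
                        class = cls, stringsAsFactors = FALSE)
  share_of <- function(code) {
    m <- status$rel
    m[st == "absent" | matrix(raw_st[rownames(st)] == "dominant",
                              nrow(st), ncol(st)) != startsWith(code, "D") |
        (st == "dominant") != endsWith(code, "D")] <- 0
    colSums(m)
  }
  classes <- c("D-to-D", "R-to-D", "D-to-R", "R-to-R")
  shares <- vapply(classes, share_of, numeric(ncol(st)))
  if (ncol(st) == 1L) shares <- matrix(shares, nrow = 1,
                                       dimnames = list(colnames(st), classes))
  samples <- data.frame(sample = colnames(st),
                        shares,
                        check.names = FALSE, stringsAsFactors = FALSE)
  samples$label <- ifelse(samples[["D-to-D"]] > samples[["R-to-D"]],
                          "D-to-D", "R-to-D")
  rownames(samples) <- NULL
  list(records = records, samples = samples)
}

#' Group OTUs by how often they achieve dominance
#'
#' Assigns every OTU of the study (union of raw-community and
#' sub-community OTUs) to one of four frequency groups: `A` — dominant in
#' 10 or more sub-communities; `B` — dominant in 1-9; `C` — present
#' somewhere but never dominant; `D` — absent from all sub-communities
#' (disappeared). The groups partition the OTU universe, and for every OTU
#' `dominant_count + rare_count = appearances`.
#'
#' @param status a `community_status` for the sub-communities.
#' @param raw optional raw community (adds disappeared OTUs to the
#'   universe); any form accepted by [partition_raw_vs_subs()].
#' @param min_dominant minimum dominant count for group A.
#'
#' @return data.frame with `otu`, `appearances`, `dominant_count`,
#'   `rare_count`, `group`.
#' @export
group_by_dominance_frequency <- function(status, raw = NULL,
                                         min_dominant = 10) {
  stopifnot(inherits(status, "community_status"))
  st <- status$status
  universe <- rownames(st)
  if (!is.null(raw)) universe <- union(universe, present_otus(raw))
  app <- dom <- setNames(integer(length(universe)), universe)
  app[rownames(st)] <- rowSums(st != "absent")
  dom[rownames(st)] <- rowSums(st == "dominant")
  group <- ifelse(dom >= min_dominant, "A",
                  ifelse(dom >= 1, "B",
                         ifelse(app > 0, "C", "D")))
  data.frame(otu = universe, appearances = app, dominant_count = dom,
             rare_count = app - dom, group = group,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Directed possibility of coexistence (POC) for an ordered OTU pair
#'
#' For a focal OTU occurring in `occ_focal` sub-communities and co-occurring
#' with another OTU in `co_occ` of them, the directed POC is
#' `co_occ / (occ_focal - co_occ)`: the odds that a sub-community containing
#' the focal OTU also contains the other. `co_occ = occ_focal` gives `Inf`
#' (the other OTU is present wherever the focal one is — complete
#' coexistence) and `co_occ = 0` gives `0` (complete exclusion).
#'
#' @param occ_focal number of sub-communities the focal OTU occurs in
#'   (must be positive).
#' @param co_occ number of sub-communities containing both OTUs.
#'
#' @return data.frame with `occ_focal`, `co_occ`, `value`, `display`
#'   (value rounded to 2 decimals) and `category` (see [categorize_poc()]).
#'   Vectorised over its arguments.
#' @examples
#' compute_poc(801, 125)$display  # 0.18
#' compute_poc(151, 125)$display  # 4.81
#' @export
compute_poc <- function(occ_focal, co_occ) {
  if (any(occ_focal <= 0)) stop_param("occ_focal must be positive")
  if (any(co_occ < 0) || any(co_occ > occ_focal))
    stop_param("impossible counts: need 0 <= co_occ <= occ_focal")
  value <- ifelse(co_occ == occ_focal, Inf, co_occ / (occ_focal - co_occ))
  data.frame(occ_focal = occ_focal, co_occ = co_occ, value = value,
             display = round(value, 2), category = categorize_poc(value),
             stringsAsFactors = FALSE)
}

#' Classify a POC value into its five coexistence categories
#'
#' `complete exclusion` (POC = 0), `exclusion preference` (0 < POC < 1),
#' `neutral interaction` (POC = 1), `coexistence preference` (POC > 1), and
#' `complete coexistence` (POC = +Inf).
#'
#' @param value non-negative POC value(s), possibly `Inf`.
#' @return character vector of categories.
#' @export
categorize_poc <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop_param("POC values must be >= 0")
  ifelse(is.infinite(value), "complete coexistence",
         ifelse(value == 0, "complete exclusion",
                ifelse(value == 1, "neutral interaction",
                       ifelse(value > 1, "coexistence preference",
                              "exclusion preference"))))
}

#' Restrict the pair analysis to frequently occurring OTUs
#'
#' To reduce dilution-induced stochastic noise, the pairwise analysis keeps
#' only OTUs occurring in strictly more than `min_occurrence`
#' sub-communities. With `n` OTUs retained there are `n * (n - 1)` ordered
#' pairs (both directions of every unordered pair).
#'
#' @param subs OTU table or `community_status` of the sub-communities.
#' @param min_occurrence strict lower bound on occurrence count.
#'
#' @return list with `otus` (retained IDs) and `n_pairs`.
#' @export
pair_universe <- function(subs, min_occurrence = 10) {
  occ <- rowSums(otu_presence(subs))
  otus <- names(occ)[occ > min_occurrence]
  list(otus = otus, n_pairs = length(otus) * (length(otus) - 1L))
}

#' Directed POC values for all ordered pairs of a pair universe
#'
#' Tallies occurrence and co-occurrence counts across sub-communities and
#' computes [compute_poc()] for every ordered pair of retained OTUs.
#'
#' @inheritParams pair_universe
#' @param otus optional explicit OTU universe (overrides the occurrence
#'   filter).
#'
#' @return data.frame with one row per ordered pair: `focal`, `other`,
#'   `occ_focal`, `co_occ`, `value`, `display`, `category`.
#' @export
poc_table <- function(subs, min_occurrence = 10, otus = NULL) {
  pres <- otu_presence(subs)
  if (is.null(otus)) otus <- pair_universe(subs, min_occurrence)$otus
  if (length(otus) < 2)
    return(data.frame(focal = character(), other = character(),
                      occ_focal = integer(), co_occ = integer(),
                      value = numeric(), display = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  pres <- pres[otus, , drop = FALSE]
  occ <- rowSums(pres)
  co <- tcrossprod(pres * 1)          # co-occurrence counts, otus x otus
  pair <- which(row(co) != col(co), arr.ind = TRUE)  # ordered, no self-pairs
  poc <- compute_poc(occ[pair[, 1]], co[pair])
  data.frame(focal = otus[pair[, 1]], other = otus[pair[, 2]],
             poc, row.names = NULL, stringsAsFactors = FALSE)
}

#' Interaction type of an unordered OTU pair from its two directed POCs
#'
#' A direction is `positive` when its POC value is at least 1 (including
#' complete coexistence) and `negative` otherwise. The pair's type combines
#' the two directions, e.g. `"positive + negative"` for the asymmetric case
#' where one OTU favours the other's presence but not vice versa.
#'
#' @param poc_ab,poc_ba the two directed POC values (numeric, vectorised).
#' @return character vector of interaction types.
#' @export
classify_pair_interaction <- function(poc_ab, poc_ba) {
  dir <- function(v) ifelse(v >= 1, "positive", "negative")
  paste(dir(poc_ab), "+", dir(poc_ba))
}

#' Tabulate interaction types for all unordered pairs
#'
#' @param poc a directed POC table from [poc_table()].
#' @return data.frame with `otu_a`, `otu_b` (`otu_a` < `otu_b`), `poc_ab`
#'   (focal = `otu_a`), `poc_ba` (focal = `otu_b`) and `type`.
#' @export
pair_interactions <- function(poc) {
  fwd <- poc[poc$focal < poc$other, c("focal", "other", "value")]
  key <- paste(fwd$focal, fwd$other)
  rev <- poc[poc$focal > poc$other, ]
  rev_val <- setNames(rev$value, paste(rev$other, rev$focal))
  data.frame(otu_a = fwd$focal, otu_b = fwd$other,
             poc_ab = fwd$value, poc_ba = unname(rev_val[key]),
             type = classify_pair_interaction(fwd$value, rev_val[key]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank OTUs within each sample and tally Top1 identities
#'
#' Sorts each sample's OTUs by relative abundance (descending, ties broken
#' by OTU ID so results are deterministic) and records the top `n`. The
#' Top1 tally counts, for every OTU, the number of samples in which it was
#' the single most abundant taxon.
#'
#' @param status a `community_status` (or relative-abundance matrix).
#' @param n number of ranks to keep per sample.
#'
#' @return list with `ranks` (data.frame: `sample`, `rank`, `otu`, `share`)
#'   and `top1_tally` (data.frame: `otu`, `wins`, decreasing).
#' @export
rank_top_n <- function(status, n = 5) {
  rel <- if (inherits(status, "community_status")) status$rel else status
  res <- lapply(colnames(rel), function(s) {
    v <- rel[, s]
    v <- v[v > 0]
    if (!length(v)) return(NULL)
    ord <- order(-v, names(v))
    k <- min(n, length(v))
    data.frame(sample = s, rank = seq_len(k), otu = names(v)[ord[seq_len(k)]],
               share = unname(v[ord[seq_len(k)]]), stringsAsFactors = FALSE)
  })
  ranks <- do.call(rbind, res)
  top1 <- ranks[ranks$rank == 1L, ]
  tab <- sort(table(top1$otu), decreasing = TRUE)
  list(ranks = ranks,
       top1_tally = data.frame(otu = names(tab), wins = as.integer(tab),
                               stringsAsFactors = FALSE))
}
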