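# End-to-end driver: generate -> filter -> label -> partition -> turnover ->
# POC -> Top-N (-> optional consumer-resource experiments), with a
# machine-readable manifest.

#' Assemble a pipeline configuration
#'
#' A single flat configuration drives [run_pipeline()]. It can also be read
#' from a YAML file with sections `thresholds`, `raw_community`, `dilution`,
#' `cultivation`, `crm`; every field is optional and defaults to the study
#' conditions.
#'
#' @param min_reads sequencing-depth filter (reads).
#' @param dominance_threshold relative-abundance threshold for dominants.
#' @param min_occurrence strict occurrence filter for the pair universe.
#' @param raw_spec,dil_spec,cult_spec generator specifications.
#' @param run_crm if TRUE, the nomination/voting/structured experiments are
#'   run as pipeline stages.
#' @param crm_replicates replicates for those experiments.
#' @param seed master seed; all stage seeds are spawned from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_reads = 5000, dominance_threshold = 0.01,
                            min_occurrence = 10,
                            raw_spec = raw_community_spec(),
                            dil_spec = dilution_spec(),
                            cult_spec = cultivation_spec(),
                            run_crm = FALSE, crm_replicates = 100,
                            seed = 1) {
  if (min_reads < 0 || min_occurrence < 0 ||
      dominance_threshold <= 0 || dominance_threshold >= 1)
    stop_param("thresholds out of range")
  structure(list(min_reads = min_reads,
                 dominance_threshold = dominance_threshold,
                 min_occurrence = min_occurrence,
                 raw_spec = raw_spec, dil_spec = dil_spec,
                 cult_spec = cult_spec,
                 run_crm = run_crm, crm_replicates = crm_replicates,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with optional sections `thresholds`,
#'   `raw_community`, `dilution`, `cultivation`, `crm` and a top-level
#'   `seed`.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- y$thresholds %||% list()
  args <- list(
    min_reads = thr$min_reads %||% 5000,
    dominance_threshold = thr$dominance_threshold %||% 0.01,
    min_occurrence = thr$min_occurrence %||% 10,
    raw_spec = do.call(raw_community_spec, y$raw_community %||% list()),
    dil_spec = do.call(dilution_spec, y$dilution %||% list()),
    cult_spec = do.call(cultivation_spec, y$cultivation %||% list()),
    run_crm = isTRUE((y$crm %||% list())$run),
    crm_replicates = (y$crm %||% list())$replicates %||% 100,
    seed = y$seed %||% 1
  )
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the study stages in order — synthetic campaign generation,
#' depth filtering, dominant/rare labelling, raw-vs-sub partition, turnover
#' classification, dominance-frequency grouping, directed POC and pair
#' interactions, Top-N ranking, and optionally the consumer-resource
#' experiments — writing one TSV per stage plus a JSON manifest recording
#' seeds, thresholds and per-stage row counts. Re-running with the same
#' configuration reproduces byte-identical numerical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly (a named list, also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("nomvote")),
                   seed = config$seed,
                   thresholds = list(min_reads = config$min_reads,
                                     dominance_threshold = config$dominance_threshold,
                                     min_occurrence = config$min_occurrence),
                   stages = list())
  save_manifest <- function()
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      save_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- res$info
    res$value
  }

  camp <- stage("generate", {
    camp <- simulate_campaign(config$raw_spec, config$dil_spec,
                              config$cult_spec, seed = config$seed)
    write_tsv(data.frame(OTU_ID = names(camp$raw$abundance),
                         abundance = camp$raw$abundance,
                         detected = camp$raw$detected),
              file.path(out_dir, "raw_community.tsv"))
    write_otu_table(camp$table, file.path(out_dir, "otu_table.tsv"))
    write_tsv(camp$wells, file.path(out_dir, "wells.tsv"))
    list(value = camp, info = list(status = "ok", n_otus = nrow(camp$table),
                                   n_wells = ncol(camp$table)))
  })

  filtered <- stage("filter", {
    f <- filter_low_depth(camp$table, config$min_reads)
    write_otu_table(f, file.path(out_dir, "otu_table_filtered.tsv"))
    list(value = f,
         info = list(status = "ok", samples_kept = ncol(f),
                     samples_removed = ncol(camp$table) - ncol(f)))
  })

  status <- stage("label", {
    st <- label_status(filtered, config$dominance_threshold)
    long <- data.frame(otu = rep(rownames(st$status), ncol(st$status)),
                       sample = rep(colnames(st$status),
                                    each = nrow(st$status)),
                       rel_abundance = as.vector(st$rel),
                       status = as.vector(st$status))
    write_tsv(long[long$status != "absent", ],
              file.path(out_dir, "profiles.tsv"))
    list(value = st, info = list(status = "ok",
                                 occurrences = sum(st$status != "absent")))
  })

  stage("partition", {
    part <- partition_raw_vs_subs(camp$raw, filtered)
    write_tsv(data.frame(otu = unlist(part, use.names = FALSE),
                         part = rep(names(part), lengths(part))),
              file.path(out_dir, "partition.tsv"))
    list(value = part, info = c(list(status = "ok"), lapply(part, length)))
  })

  turn <- stage("turnover", {
    tv <- classify_turnover(camp$raw, status)
    write_tsv(tv$records, file.path(out_dir, "turnover_records.tsv"))
    write_tsv(tv$samples, file.path(out_dir, "turnover_samples.tsv"))
    list(value = tv, info = list(status = "ok", records = nrow(tv$records)))
  })

  stage("groups", {
    grp <- group_by_dominance_frequency(status, camp$raw)
    write_tsv(grp, file.path(out_dir, "dominance_groups.tsv"))
    list(value = grp,
         info = c(list(status = "ok"),
                  as.list(table(factor(grp$group, c("A", "B", "C", "D"))))))
  })

  stage("poc", {
    poc <- poc_table(status, config$min_occurrence)
    write_tsv(poc, file.path(out_dir, "poc.tsv"))
    pairs <- if (nrow(poc)) pair_interactions(poc) else poc
    write_tsv(pairs, file.path(out_dir, "pair_interactions.tsv"))
    list(value = poc, info = list(status = "ok",
                                  universe = length(unique(poc$focal)),
                                  ordered_pairs = nrow(poc)))
  })

  stage("top_n", {
    tops <- rank_top_n(status)
    write_tsv(tops$ranks, file.path(out_dir, "top_ranks.tsv"))
    write_tsv(tops$top1_tally, file.path(out_dir, "top1_tally.tsv"))
    list(value = tops, info = list(status = "ok",
                                   distinct_top1 = nrow(tops$top1_tally)))
  })

  if (config$run_crm) {
    crm_seeds <- spawn_seeds(config$seed + 1, 3)
    stage("crm_nomination", {
      nom <- run_nomination(replicates = config$crm_replicates,
                            seed = crm_seeds[1])
      write_tsv(nom$shares, file.path(out_dir, "crm_nomination_shares.tsv"))
      write_tsv(nom$summary, file.path(out_dir, "crm_nomination_summary.tsv"))
      list(value = nom, info = list(status = "ok"))
    })
    stage("crm_voting", {
      vote <- run_voting(replicates = config$crm_replicates,
                         seed = crm_seeds[2])
      write_tsv(vote$tally, file.path(out_dir, "crm_voting_tally.tsv"))
      list(value = vote, info = list(status = "ok",
                                     distinct_top1 = length(unique(vote$top1))))
    })
    stage("crm_structured", {
      st3 <- run_structured(replicates = config$crm_replicates,
                            seed = crm_seeds[3])
      write_tsv(data.frame(candidate = st3$random$tally$candidate,
                           random_wins = st3$random$tally$wins,
                           structured_wins = st3$structured$tally$wins),
                file.path(out_dir, "crm_structured_tally.tsv"))
      list(value = st3, info = list(status = "ok", tv = st3$tv,
                                    targeted_wins = st3$targeted_wins,
                                    shielded_wins = st3$shielded_wins))
    })
  }

  save_manifest()
  invisible(manifest)
}
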