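# shared fixtures and independent oracles, built in code

# tiny OTU table with hand-checkable counts
toy_table <- function() {
  m <- matrix(c(5200, 4999, 5000,
                2600, 0, 2500,
                0, 1, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("OTU_1", "OTU_2", "OTU_3"),
                              c("S1", "S2", "S3")))
  storage.mode(m) <- "integer"
  m
}

# wrap a presence/absence matrix so cultivation helpers are bypassed
as_inocula <- function(counts, dilution_factor = 1e-4) {
  structure(list(counts = counts,
                 wells = data.frame(well_id = colnames(counts),
                                    plate = 1L,
                                    dilution_factor = dilution_factor,
                                    inoculum_cells = colSums(counts))),
            class = "inocula")
}

# brute-force POC oracle: per-sample recount over all ordered pairs,
# independent of the tallied-count path in poc_table()
brute_force_poc <- function(pres) {
  otus <- rownames(pres)
  out <- list()
  for (f in otus) for (o in setdiff(otus, f)) {
    occ <- 0L; co <- 0L
    for (s in seq_len(ncol(pres))) {
      if (pres[f, s]) {
        occ <- occ + 1L
        if (pres[o, s]) co <- co + 1L
      }
    }
    if (occ > 0L)
      out[[length(out) + 1L]] <-
        data.frame(focal = f, other = o, occ_focal = occ, co_occ = co,
                   value = if (co == occ) Inf else co / (occ - co),
                   stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# a small but non-trivial synthetic campaign reused across tests
small_campaign <- function(seed = 11) {
  simulate_campaign(
    raw_community_spec(n_otus = 120, n_dominant = 8,
                       dominant_total_share = 0.6, seed = seed),
    dilution_spec(dilution_factors = c(1e-4, 1e-5),
                  wells_per_factor = c(48, 48),
                  inoculum_cells = c(300, 30)),
    cultivation_spec(),
    seed = seed
  )
}
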