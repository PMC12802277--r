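# Readers and writers for the tab-separated OTU table format (first column
# "OTU_ID", one column per sample, integer read counts) and BIOM-JSON.

#' Read an OTU count table
#'
#' @param path input file.
#' @param format `"tsv"` (first column `OTU_ID`, integer counts) or
#'   `"biom"` (BIOM-format JSON flavour; requires the biomformat package).
#'
#' @return Validated integer count matrix (taxa x samples).
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_param("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_param("BIOM import needs the biomformat package")
    m <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
    storage.mode(m) <- "integer"
    return(check_otu_table(m))
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "OTU_ID")
    stop_param(path, ": expected a tab-separated table whose first column ",
               "is 'OTU_ID'")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop_param(path, ": duplicate OTU_ID '",
                                     ids[duplicated(ids)][1], "'")
  m <- matrix(0L, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, names(df)[-1]))
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop_param(path, ": cell (", ids[bad[1]], ", ", names(df)[j],
                 ") = '", df[[j]][bad[1]],
                 "' is not a non-negative integer count")
    m[, j - 1L] <- as.integer(v)
  }
  check_otu_table(m)
}

#' Write an OTU count table
#'
#' @param table count matrix (taxa x samples).
#' @param path output file.
#' @param format `"tsv"` or `"biom"` (BIOM-JSON; requires biomformat).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  check_otu_table(table)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_param("BIOM export needs the biomformat package")
    biomformat::write_biom(biomformat::make_biom(table), path)
    return(invisible(path))
  }
  df <- data.frame(OTU_ID = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
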