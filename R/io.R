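#' Read / write ASV count tables as TSV
#'
#' The on-disk dialect is tab-delimited UTF-8 with `.` decimals: rows are
#' ASV ids (first column `asv_id`), columns are sample ids, cells are
#' integer counts. Optional companion TSVs carry taxonomy (`asv_id`,
#' `lineage`) and annotations (`asv_id`, `flag`, `trophic_group`,
#' `domain`). Reading validates the table and rejects duplicate ids,
#' negative and non-integer cells with errors naming the offending
#' row/column.
#'
#' @param path TSV file of counts.
#' @param marker `"16S"` or `"18S"`.
#' @param taxonomy_path,annotations_path optional companion TSVs.
#' @return `read_asv_table` returns an [asv_table()];
#'   `write_asv_table` returns `path` invisibly.
#' @export
read_asv_table <- function(path, marker = c("16S", "18S"),
                           taxonomy_path = NULL, annotations_path = NULL) {
  marker <- match.arg(marker)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  fc_assert(ncol(df) >= 2 && names(df)[1] == "asv_id",
            "malformed header: first column must be 'asv_id'",
            "fc_parse_error")
  fc_assert(!anyDuplicated(df$asv_id),
            paste("duplicate ASV id(s):",
                  paste(unique(df$asv_id[duplicated(df$asv_id)]),
                        collapse = ", ")),
            "fc_parse_error")
  fc_assert(!anyDuplicated(names(df)[-1]),
            "duplicate sample id(s) in header", "fc_parse_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    fc_stop(sprintf(
      "invalid count at ASV '%s', sample '%s' (must be a non-negative integer)",
      df$asv_id[bad[1, 1]], colnames(m)[bad[1, 2]]),
      "fc_parse_error")
  }
  counts <- t(m)
  colnames(counts) <- df$asv_id
  taxonomy <- if (!is.null(taxonomy_path)) {
    utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  }
  annotations <- if (!is.null(annotations_path)) {
    utils::read.delim(annotations_path, stringsAsFactors = FALSE)
  }
  asv_table(counts, marker = marker, taxonomy = taxonomy,
            annotations = annotations)
}

#' @rdname read_asv_table
#' @param t an [asv_table()].
#' @export
write_asv_table <- function(t, path) {
  df <- data.frame(asv_id = colnames(t$counts), t(t$counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write sample metadata as TSV
#'
#' @param meta metadata data frame (see [generate_site_network()]).
#' @param path TSV file path.
#' @return `read_sample_metadata` returns the metadata data frame;
#'   `write_sample_metadata` returns `path` invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  fc_assert(all(c("site_id", "fjord") %in% names(meta)),
            "metadata must have site_id and fjord columns", "fc_parse_error")
  fc_assert(!anyDuplicated(meta$site_id), "duplicate site_id in metadata",
            "fc_parse_error")
  if ("representative" %in% names(meta)) {
    meta$representative <- as.logical(meta$representative)
  }
  rownames(meta) <- meta$site_id
  meta
}
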