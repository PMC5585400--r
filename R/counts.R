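#' Read isoform-diagnostic count tables
#'
#' The count table holds, per event and sample, the number of reads
#' diagnostic of the distal-donor isoform (`n_distal`) and of the
#' proximal-donor isoform (`n_proximal`). `write_counts()` is its inverse;
#' write-then-read is an identity on valid tables.
#'
#' @param path TSV with header `event_id`, `sample_id`, `n_distal`,
#'   `n_proximal`.
#' @return A data.frame with those four columns; counts are non-negative
#'   integers.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("event_id", "sample_id", "n_distal", "n_proximal")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("counts table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (fld in c("n_distal", "n_proximal")) {
    raw <- df[[fld]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val != floor(val) | val < 0)
    if (length(bad)) {
      stop("non-integer or negative ", fld, " ('", raw[bad[1]],
           "') at line ", bad[1] + 1L, " of ", path, call. = FALSE)
    }
    df[[fld]] <- as.integer(val)
  }
  df[, need]
}

#' @rdname read_counts
#' @param counts a data.frame as returned by [read_counts()].
#' @export
write_counts <- function(counts, path) {
  need <- c("event_id", "sample_id", "n_distal", "n_proximal")
  stopifnot(all(need %in% names(counts)))
  utils::write.table(counts[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
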