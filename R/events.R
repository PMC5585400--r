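#' Tandem-donor event tables
#'
#' An alternative 5' splice site (A5SS) event of the tandem-donor kind has two
#' competing donors that share one downstream acceptor. The *intron-distal*
#' donor is the upstream donor in transcript orientation (its selection
#' truncates the exon-terminal segment); the *intron-proximal* donor is
#' downstream (its selection retains it). Each donor is anchored at a single
#' 0-based genomic coordinate: the first intronic base of that donor.
#'
#' On the plus strand `proximal_donor - distal_donor == offset`; on the minus
#' strand `distal_donor - proximal_donor == offset`, with `offset >= 1` the
#' transcript-orientation distance between the donors.
#'
#' @param event_id character vector of unique event identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per event.
#' @param distal_donor,proximal_donor 0-based coordinates of the first
#'   intronic base of each donor.
#' @param acceptor optional 0-based coordinate of the shared acceptor
#'   (`NA` allowed).
#' @return A `data.frame` of class `"tandem_events"` with the above columns
#'   plus `offset`.
#' @export
tandem_events <- function(event_id, chrom, strand, distal_donor,
                          proximal_donor, acceptor = NA_integer_) {
  acceptor <- rep_len(as.integer(acceptor), length(event_id))
  df <- data.frame(
    event_id = as.character(event_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    distal_donor = as.integer(distal_donor),
    proximal_donor = as.integer(proximal_donor),
    acceptor = as.integer(acceptor),
    stringsAsFactors = FALSE
  )
  validate_tandem_events(df)
}

validate_tandem_events <- function(df) {
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("invalid strand (must be '+' or '-') in record(s) ",
         paste(bad_strand, collapse = ", "), call. = FALSE)
  }
  offset <- ifelse(df$strand == "+",
                   df$proximal_donor - df$distal_donor,
                   df$distal_donor - df$proximal_donor)
  bad_off <- which(!is.finite(offset) | offset < 1L)
  if (length(bad_off)) {
    stop("donor offset must be >= 1 nt in transcript orientation; violated ",
         "in record(s) ", paste(bad_off, collapse = ", "),
         " (field distal_donor/proximal_donor)", call. = FALSE)
  }
  if (anyDuplicated(df$event_id)) {
    stop("duplicate event_id values", call. = FALSE)
  }
  df$offset <- as.integer(offset)
  class(df) <- c("tandem_events", "data.frame")
  df
}

#' Read a tandem-donor event table
#'
#' Reads the BED-like event TSV with columns `chrom`, `distal_donor`,
#' `proximal_donor`, `strand`, `event_id` and optionally `acceptor`.
#' Coordinates are 0-based (each donor is its first intronic base).
#' A header line is recognized by its first field being `chrom`; headerless
#' files with columns in the above order are also accepted.
#'
#' @param path path to the TSV.
#' @return A `"tandem_events"` data.frame (see [tandem_events()]).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- length(first) && grepl("^chrom\\b", first)
  cols <- c("chrom", "distal_donor", "proximal_donor", "strand", "event_id",
            "acceptor")
  df <- utils::read.delim(path, header = has_header,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < 5L) {
      stop("event table needs at least 5 columns (chrom, distal_donor, ",
           "proximal_donor, strand, event_id)", call. = FALSE)
    }
    names(df) <- cols[seq_len(min(ncol(df), 6L))]
  }
  missing <- setdiff(cols[1:5], names(df))
  if (length(missing)) {
    stop("event table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"acceptor" %in% names(df)) df$acceptor <- NA_character_
  for (fld in c("distal_donor", "proximal_donor")) {
    val <- suppressWarnings(as.integer(df[[fld]]))
    bad <- which(is.na(val) & !is.na(df[[fld]]))
    if (length(bad)) {
      stop("non-integer ", fld, " at line ", bad[1] + has_header,
           " of ", path, call. = FALSE)
    }
    df[[fld]] <- val
  }
  df$acceptor <- suppressWarnings(as.integer(df$acceptor))
  tryCatch(
    tandem_events(df$event_id, df$chrom, df$strand, df$distal_donor,
                  df$proximal_donor, df$acceptor),
    error = function(e) stop("in ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
}

#' Write a tandem-donor event table
#'
#' @param events a `"tandem_events"` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "tandem_events"))
  out <- events[, c("chrom", "distal_donor", "proximal_donor", "strand",
                    "event_id", "acceptor")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
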