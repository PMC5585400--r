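#' Scoring matrices and k-mer model tables
#'
#' Two dialects of scoring model are supported:
#' \itemize{
#'   \item position matrices (`kind` `"ese_pwm"` or `"donor_wmm"`): one score
#'     per (position, base) over the DNA alphabet, applied additively to a
#'     window of length `width`;
#'   \item 9-mer lookups (`kind` `"kmer_lookup"`): a table mapping splice
#'     donor 9-mers (3 exonic + 6 intronic bases) to a precomputed score,
#'     e.g. a maximum-entropy donor model distributed as a score table.
#' }
#'
#' @param entries for matrices: a `width x 4` numeric matrix with columns
#'   `A`, `C`, `G`, `T`.
#' @param kind one of `"ese_pwm"`, `"donor_wmm"`, `"kmer_lookup"`.
#' @param lookup for `kind = "kmer_lookup"`: a named numeric vector keyed by
#'   9-mers over `{A,C,G,T}`.
#' @param threshold optional reporting cutoff carried as metadata; not
#'   applied by any scan unless requested.
#' @return An object of class `"scoring_matrix"`.
#' @export
scoring_matrix <- function(entries = NULL, kind = "ese_pwm", lookup = NULL,
                           threshold = NULL) {
  kind <- match.arg(kind, c("ese_pwm", "donor_wmm", "kmer_lookup"))
  if (kind == "kmer_lookup") {
    stopifnot(is.numeric(lookup), !is.null(names(lookup)))
    keys <- names(lookup)
    if (any(nchar(keys) != 9L) || any(grepl("[^ACGT]", keys))) {
      stop("kmer_lookup keys must be 9-mers over {A,C,G,T}", call. = FALSE)
    }
    if (anyDuplicated(keys)) stop("duplicate 9-mer keys", call. = FALSE)
    obj <- list(kind = kind, width = 9L, lookup = lookup,
                threshold = threshold)
  } else {
    entries <- as.matrix(entries)
    if (!all(c("A", "C", "G", "T") %in% colnames(entries))) {
      stop("matrix must have columns A, C, G, T", call. = FALSE)
    }
    entries <- entries[, c("A", "C", "G", "T"), drop = FALSE]
    if (!all(is.finite(entries))) stop("non-finite matrix entry",
                                       call. = FALSE)
    obj <- list(kind = kind, width = nrow(entries), entries = entries,
                threshold = threshold)
  }
  structure(obj, class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("scoring_matrix kind =", x$kind, "width =", x$width, "\n")
  invisible(x)
}

#' Read a scoring matrix or 9-mer model table
#'
#' The dialect is selected by the header: a `kmer`/`score` header yields a
#' `kmer_lookup`; a header containing columns `A`, `C`, `G`, `T` (optionally
#' preceded by a position column) yields a position matrix.
#'
#' @param path TSV path.
#' @param kind kind to assign to a position matrix (`"ese_pwm"`, default, or
#'   `"donor_wmm"`); ignored for the lookup dialect.
#' @return A `"scoring_matrix"`.
#' @export
read_matrix <- function(path, kind = "ese_pwm") {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("kmer" %in% names(df)) {
    if (!"score" %in% names(df)) {
      stop("kmer table missing 'score' column", call. = FALSE)
    }
    if (anyDuplicated(df$kmer)) {
      stop("duplicate 9-mer keys in ", path, call. = FALSE)
    }
    lk <- stats::setNames(as.numeric(df$score), toupper(df$kmer))
    return(scoring_matrix(kind = "kmer_lookup", lookup = lk))
  }
  missing <- setdiff(c("A", "C", "G", "T"), names(df))
  if (length(missing)) {
    stop("matrix file ", path, " missing base column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scoring_matrix(entries = as.matrix(df[, c("A", "C", "G", "T")]),
                 kind = kind)
}

#' @rdname read_matrix
#' @param m a `"scoring_matrix"` to write.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "scoring_matrix"))
  if (m$kind == "kmer_lookup") {
    df <- data.frame(kmer = names(m$lookup), score = unname(m$lookup))
  } else {
    df <- as.data.frame(m$entries)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Look up a 9-mer score in a k-mer model table
#'
#' @param m a `"scoring_matrix"` of kind `kmer_lookup`.
#' @param kmer a 9-mer (RNA `U` is accepted and mapped to `T`).
#' @return The table score, or `NA_real_` when the 9-mer is absent from the
#'   table — absence is reported as missing, never as a zero score.
#' @export
kmer_score <- function(m, kmer) {
  stopifnot(inherits(m, "scoring_matrix"), m$kind == "kmer_lookup")
  kmer <- normalize_seq(kmer)
  if (nchar(kmer) != 9L) stop("donor 9-mer must have length 9", call. = FALSE)
  unname(m$lookup[kmer])
}

# RNA -> DNA alphabet; uppercase; validate.
normalize_seq <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  if (any(grepl("[^ACGT]", s))) {
    stop("sequence contains characters outside {A,C,G,T,U}", call. = FALSE)
  }
  s
}
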