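#' Per-base coverage tracks
#'
#' A coverage track maps (chromosome, 0-based position) to a non-negative
#' tag coverage. It is stored run-length encoded (one [S4Vectors::Rle] per
#' chromosome); positions not covered by any interval read as zero, matching
#' BedGraph semantics where gaps mean no signal.
#'
#' @param rle_list a named list (or `RleList`) of per-chromosome `Rle`
#'   coverage vectors, index 1 corresponding to genomic position 0.
#' @return An object of class `"coverage_track"`.
#' @export
coverage_track <- function(rle_list) {
  if (is(rle_list, "RleList")) rle_list <- as.list(rle_list)
  stopifnot(is.list(rle_list), !is.null(names(rle_list)))
  rle_list <- lapply(rle_list, function(x) {
    if (!is(x, "Rle")) x <- S4Vectors::Rle(as.numeric(x))
    if (any(S4Vectors::runValue(x) < 0)) {
      stop("negative coverage value in track", call. = FALSE)
    }
    x
  })
  structure(list(cov = rle_list), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track over", length(x$cov), "chromosome(s):",
      paste(names(x$cov), collapse = ", "), "\n")
  invisible(x)
}

#' Query coverage at 0-based positions
#'
#' @param track a `"coverage_track"`.
#' @param chrom chromosome name.
#' @param pos integer vector of 0-based positions; positions outside every
#'   interval (including on absent chromosomes) return 0.
#' @return Numeric vector of coverage values.
#' @export
coverage_at <- function(track, chrom, pos) {
  stopifnot(inherits(track, "coverage_track"))
  if (any(pos < 0)) stop("negative genomic position", call. = FALSE)
  r <- track$cov[[chrom]]
  out <- numeric(length(pos))
  if (is.null(r)) return(out)
  inside <- pos < length(r)
  if (any(inside)) out[inside] <- as.numeric(r[pos[inside] + 1L])
  out
}

#' Read a 4-column BedGraph file into a coverage track
#'
#' Intervals are 0-based half-open. Overlapping intervals on one chromosome
#' are rejected (the per-base coverage would be ambiguous), as are negative
#' values. Positions not covered by any interval read as zero.
#'
#' @param path BedGraph file path.
#' @return A `"coverage_track"`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("BedGraph not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) {
    stop("negative coverage value in ", path, call. = FALSE)
  }
  if (!GenomicRanges::isDisjoint(gr, ignore.strand = TRUE)) {
    stop("overlapping BedGraph intervals in ", path,
         ": per-base coverage is ambiguous", call. = FALSE)
  }
  cov <- GenomicRanges::coverage(gr, weight = "score")
  coverage_track(as.list(cov))
}

#' Write a coverage track as BedGraph
#'
#' Zero-coverage runs are omitted (gaps read back as zero).
#'
#' @param track a `"coverage_track"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  rows <- lapply(names(track$cov), function(chrom) {
    r <- track$cov[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)  # 0-based half-open
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
               value = vals[keep], stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(chrom = character(), start = integer(),
                       end = integer(), value = numeric())
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
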