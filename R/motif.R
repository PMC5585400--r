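#' Additive PWM score of one window
#'
#' Scores a window whose length equals the matrix width by summing the
#' per-(position, base) entries — the scoring rule used by ESE finders for
#' SR-protein motifs such as the SRSF1 heptamer matrix shipped in
#' `inst/extdata/esefinder_srsf1_pwm.tsv`. RNA input (`U`) is mapped to `T`.
#'
#' @param seq a character scalar over `{A,C,G,T,U}` of length equal to
#'   `m$width`.
#' @param m a `"scoring_matrix"` of kind `ese_pwm` or `donor_wmm`.
#' @return The additive score (numeric scalar).
#' @export
pwm_score <- function(seq, m) {
  stopifnot(inherits(m, "scoring_matrix"), m$kind != "kmer_lookup")
  s <- normalize_seq(seq)
  if (nchar(s) != m$width) {
    stop("sequence length ", nchar(s), " != matrix width ", m$width,
         call. = FALSE)
  }
  b <- strsplit(s, "")[[1]]
  sum(m$entries[cbind(seq_len(m$width), match(b, c("A", "C", "G", "T")))])
}

#' Scan a sequence with a PWM
#'
#' Scores every window of width `m$width`; the maximal window(s) are
#' flagged, with ties marked.
#'
#' @inheritParams pwm_score
#' @param seq a sequence at least as long as the matrix width.
#' @return A data.frame with one row per window: `start` (1-based within
#'   `seq`), `window`, `score`, `is_max`, `tie` (TRUE on all rows when the
#'   maximum is shared).
#' @export
pwm_scan <- function(seq, m) {
  stopifnot(inherits(m, "scoring_matrix"), m$kind != "kmer_lookup")
  s <- normalize_seq(seq)
  w <- m$width
  if (nchar(s) < w) {
    stop("sequence (length ", nchar(s), ") shorter than matrix width ", w,
         call. = FALSE)
  }
  starts <- seq_len(nchar(s) - w + 1L)
  windows <- substring(s, starts, starts + w - 1L)
  scores <- vapply(windows, pwm_score, numeric(1), m = m, USE.NAMES = FALSE)
  is_max <- scores == max(scores)
  data.frame(start = starts, window = windows, score = scores,
             is_max = is_max, tie = sum(is_max) > 1L,
             stringsAsFactors = FALSE)
}

#' Score a splice-donor 9-mer
#'
#' The donor 9-mer is 3 exonic + 6 intronic bases; positions 4-5 are the
#' donor dinucleotide (flagged when not GT). Three scores are supported:
#' \itemize{
#'   \item `wmm_score`: log2-odds of a position weight matrix whose entries
#'     are per-position base probabilities, against a background
#'     distribution: `sum(log2(f_i(b_i) / bg(b_i)))`. Invariant to jointly
#'     rescaling frequencies and background; 0 when the matrix equals the
#'     background everywhere.
#'   \item `maxent_score`: lookup in a 9-mer score table (e.g. a
#'     maximum-entropy donor model distributed as a table);
#'   \item `sd_score`: lookup in a genome-wide donor-frequency score table.
#' }
#' A lookup table that is not provided, or a 9-mer absent from a provided
#' table, yields `NA` — score unavailable, never 0.
#'
#' @param nine_mer the donor 9-mer (RNA accepted).
#' @param wmm optional `"scoring_matrix"` of width 9 holding per-position
#'   base probabilities.
#' @param background base frequencies, named `A`,`C`,`G`,`T`, strictly
#'   positive, summing to 1.
#' @param maxent_table,sd_table optional `"scoring_matrix"` objects of kind
#'   `kmer_lookup`.
#' @return An object of class `"donor_score"`: `nine_mer`, `gt_donor`,
#'   `wmm_score`, `maxent_score`, `sd_score` (each `NA` when its model is
#'   absent or the 9-mer is missing from a lookup).
#' @export
donor_score <- function(nine_mer, wmm = NULL,
                        background = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25),
                        maxent_table = NULL, sd_table = NULL) {
  s <- normalize_seq(nine_mer)
  if (nchar(s) != 9L) stop("donor 9-mer must have length 9", call. = FALSE)
  stopifnot(all(c("A", "C", "G", "T") %in% names(background)))
  bg <- background[c("A", "C", "G", "T")]
  if (any(bg <= 0)) stop("background frequencies must be positive",
                         call. = FALSE)
  if (abs(sum(bg) - 1) > 1e-6) stop("background must sum to 1",
                                    call. = FALSE)
  b <- strsplit(s, "")[[1]]
  wmm_score <- NA_real_
  if (!is.null(wmm)) {
    stopifnot(inherits(wmm, "scoring_matrix"), wmm$kind != "kmer_lookup")
    if (wmm$width != 9L) stop("donor weight matrix must have width 9",
                              call. = FALSE)
    f <- wmm$entries[cbind(1:9, match(b, c("A", "C", "G", "T")))]
    wmm_score <- sum(log2(f / bg[b]))
  }
  structure(list(
    nine_mer = s,
    gt_donor = substr(s, 4, 5) == "GT",
    wmm_score = wmm_score,
    maxent_score = if (is.null(maxent_table)) NA_real_ else
      kmer_score(maxent_table, s),
    sd_score = if (is.null(sd_table)) NA_real_ else kmer_score(sd_table, s)
  ), class = "donor_score")
}

#' @export
print.donor_score <- function(x, ...) {
  cat(sprintf("donor %s%s: wmm %.3f, maxent %s, sd %s\n", x$nine_mer,
              if (x$gt_donor) "" else " [non-GT]", x$wmm_score,
              format(x$maxent_score), format(x$sd_score)))
  invisible(x)
}

#' Splicing-neutral heterologous block sequences
#'
#' The standard 15-nt splicing-neutral block used in block-scanning
#' mutagenesis of splicing reporters, plus its 19-nt extension for a longer
#' terminal block.
#'
#' @return Named character vector with elements `block15` and `block19`.
#' @export
neutral_block_sequences <- function() {
  c(block15 = "TCAGTATGACTCTCA", block19 = "TCAGTATGACTCTCAGTAT")
}

#' Design block-scanning mutants
#'
#' Substitutes each block of a sequence, one at a time, with a heterologous
#' replacement (e.g. [neutral_block_sequences()]), producing one mutant per
#' block. When an ESE matrix is supplied, each mutant is annotated with the
#' change in the maximal ESE scan score, supporting the check that a
#' substitution does not gain a binding site de novo.
#'
#' @param seq the wild-type sequence.
#' @param blocks data.frame with 1-based inclusive `start` and `end`
#'   columns; blocks must be non-overlapping and within `seq`.
#' @param replacement a single replacement sequence recycled over blocks, or
#'   one per block (lengths may differ from the block length; the mutant
#'   length changes accordingly).
#' @param ese_matrix optional `"scoring_matrix"` for the delta-max-ESE
#'   annotation.
#' @return A data.frame with one row per block: `block`, `start`, `end`,
#'   `replacement`, `mutant_seq`, `length_change`, and (with `ese_matrix`)
#'   `max_ese_wt`, `max_ese_mut`, `delta_max_ese`.
#' @export
block_scan_mutants <- function(seq, blocks, replacement,
                               ese_matrix = NULL) {
  s <- normalize_seq(seq)
  stopifnot(is.data.frame(blocks), all(c("start", "end") %in% names(blocks)))
  nb <- nrow(blocks)
  o <- order(blocks$start)
  bs <- blocks$start[o]; be <- blocks$end[o]
  if (any(bs < 1L) || any(be > nchar(s)) || any(be < bs)) {
    stop("blocks must satisfy 1 <= start <= end <= nchar(seq)",
         call. = FALSE)
  }
  if (nb > 1L && any(bs[-1L] <= be[-nb])) {
    stop("blocks overlap", call. = FALSE)
  }
  repl <- normalize_seq(rep_len(replacement, nb))
  max_wt <- if (!is.null(ese_matrix)) max(pwm_scan(s, ese_matrix)$score)
  rows <- lapply(seq_len(nb), function(i) {
    st <- blocks$start[i]; en <- blocks$end[i]
    mut <- paste0(substr(s, 1L, st - 1L), repl[i],
                  substr(s, en + 1L, nchar(s)))
    row <- data.frame(
      block = i, start = st, end = en, replacement = repl[i],
      mutant_seq = mut,
      length_change = nchar(repl[i]) - (en - st + 1L),
      stringsAsFactors = FALSE
    )
    if (!is.null(ese_matrix)) {
      row$max_ese_wt <- max_wt
      row$max_ese_mut <- max(pwm_scan(mut, ese_matrix)$score)
      row$delta_max_ese <- row$max_ese_mut - max_wt
    }
    row
  })
  do.call(rbind, rows)
}
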