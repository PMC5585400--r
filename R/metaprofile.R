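#' Extract a normalized 400-nt CLIP profile around one donor
#'
#' The analysis window covers relative positions `r = -200 .. +199` in
#' transcript orientation, with `r = 0` the donor's first intronic base
#' (negative `r` is the exonic/upstream side). For plus-strand events
#' `raw[r] = coverage(anchor + r)`; for minus-strand events
#' `raw[r] = coverage(anchor - r)`, so profiles are strand-equivariant.
#' The normalized density divides each position's coverage by the total
#' coverage in the window; events with zero total coverage are flagged
#' (the density is undefined there) and excluded downstream.
#'
#' @param track a `"coverage_track"`, or a named list of tracks keyed by
#'   strand (`"+"`, `"-"`) when the CLIP signal is strand-separated.
#' @param event one row of a `"tandem_events"` table (data.frame row or
#'   list).
#' @param anchor `"distal"` or `"proximal"`: which donor to center on.
#' @return An object of class `"clip_profile"`: `rel` (-200..199), `raw`,
#'   `density` (NULL when `total == 0`), `total`, `zero_coverage`.
#' @export
extract_profile <- function(track, event, anchor = c("distal", "proximal")) {
  anchor <- match.arg(anchor)
  track <- resolve_strand_track(track, event$strand)
  pos0 <- if (anchor == "distal") event$distal_donor else event$proximal_donor
  rel <- -200L:199L
  gpos <- if (event$strand == "+") pos0 + rel else pos0 - rel
  if (any(gpos < 0)) {
    stop("analysis window of event ", event$event_id,
         " extends past the chromosome start", call. = FALSE)
  }
  raw <- coverage_at(track, event$chrom, gpos)
  total <- sum(raw)
  structure(list(
    event_id = event$event_id, anchor = anchor, strand = event$strand,
    rel = rel, raw = raw,
    density = if (total > 0) raw / total else NULL,
    total = total, zero_coverage = total == 0
  ), class = "clip_profile")
}

resolve_strand_track <- function(track, strand) {
  if (inherits(track, "coverage_track")) return(track)
  if (is.list(track) && strand %in% names(track)) return(track[[strand]])
  stop("track must be a coverage_track or a list keyed by strand",
       call. = FALSE)
}

#' Aggregate per-event densities into a metaprofile
#'
#' Positionwise mean and standard error (sample SD / sqrt(n)) of the
#' normalized densities over events with nonzero total coverage;
#' zero-coverage events are excluded and counted, so
#' `n_used + n_zero == length(profiles)`.
#'
#' @param profiles a list of `"clip_profile"` objects sharing one anchor.
#' @return An object of class `"meta_profile"`: `rel`, `mean`, `se`,
#'   `n_used`, `n_zero`. The mean density sums to 1.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) > 0)
  use <- Filter(function(p) !p$zero_coverage, profiles)
  n_zero <- length(profiles) - length(use)
  if (!length(use)) {
    stop("no profiles with nonzero coverage to aggregate", call. = FALSE)
  }
  d <- do.call(rbind, lapply(use, `[[`, "density"))
  n <- nrow(d)
  mu <- colMeans(d)
  se <- if (n > 1) apply(d, 2, stats::sd) / sqrt(n) else numeric(ncol(d))
  structure(list(
    anchor = use[[1]]$anchor, rel = use[[1]]$rel,
    mean = mu, se = se, n_used = n, n_zero = n_zero
  ), class = "meta_profile")
}

#' Eight-section argmax report
#'
#' Tiles the 400-nt window into eight 50-nt sections, section `k` spanning
#' `r` in `[-200 + 50(k-1), -200 + 50k)`; section 4 is the 50 nt immediately
#' upstream (exonic side) of the donor, `r` in `[-50, 0)`. Per event the
#' section with the highest summed raw coverage is reported; ties go to the
#' lowest section index and are flagged. Zero-coverage events are excluded
#' from the histogram.
#'
#' @param profiles a list of `"clip_profile"` objects.
#' @param section_width section width in nt (must divide 400; default 50).
#' @return A list of class `"section_report"`: `per_event` data.frame
#'   (`event_id`, `argmax_section`, `tie`), `histogram` (counts per
#'   section), `section4` (count for the section containing `r = -1`),
#'   `n_zero`.
#' @export
section_argmax <- function(profiles, section_width = 50L) {
  stopifnot(length(profiles) > 0, 400L %% section_width == 0L)
  n_sections <- 400L %/% section_width
  use <- Filter(function(p) !p$zero_coverage, profiles)
  n_zero <- length(profiles) - length(use)
  per <- lapply(use, function(p) {
    sec <- factor((p$rel + 200L) %/% section_width + 1L,
                  levels = seq_len(n_sections))
    sums <- tapply(p$raw, sec, sum)
    best <- which(sums == max(sums))
    data.frame(event_id = p$event_id,
               argmax_section = as.integer(names(sums)[best[1]]),
               tie = length(best) > 1L,
               stringsAsFactors = FALSE)
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(event_id = character(), argmax_section = integer(),
               tie = logical())
  hist <- tabulate(per$argmax_section, nbins = n_sections)
  names(hist) <- paste0("section", seq_len(n_sections))
  upstream_section <- (200L - 1L) %/% section_width + 1L  # contains r = -1
  structure(list(per_event = per, histogram = hist,
                 section4 = unname(hist[upstream_section]),
                 n_zero = n_zero),
            class = "section_report")
}

#' Class-by-anchor metaprofile report
#'
#' Builds the 2 x 2 grid of metaprofiles (response class x donor anchor)
#' plus section reports: for each of the `distal_activated` and
#' `proximal_activated` classes, profiles are extracted around both the
#' distal and the proximal donor. Empty classes (or classes with only
#' zero-coverage events) yield an absent panel, not an error.
#'
#' @param events a `"tandem_events"` table.
#' @param classified result of [classify_events()] (or its `events`
#'   data.frame with a `direction` column).
#' @param track coverage track(s); see [extract_profile()].
#' @param classes response classes to report.
#' @param anchors donor anchors to report.
#' @param section_width see [section_argmax()].
#' @return A list of class `"metaprofile_report"`: `panels` (named
#'   `"<class>.<anchor>"`, each with `meta` and `sections` or `NULL` when
#'   absent), `meta_table` (tidy data.frame: class, anchor, rel, mean, se),
#'   `section_table` (class, anchor, section, count).
#' @export
metaprofile_report <- function(events, classified, track,
                               classes = c("distal_activated",
                                           "proximal_activated"),
                               anchors = c("distal", "proximal"),
                               section_width = 50L) {
  cls_df <- if (is.list(classified) && !is.data.frame(classified) &&
                  !is.null(classified$events)) classified$events else classified
  stopifnot("direction" %in% names(cls_df))
  panels <- list()
  meta_rows <- list()
  sec_rows <- list()
  for (cl in classes) {
    ids <- cls_df$event_id[cls_df$direction == cl]
    ev <- events[events$event_id %in% ids, , drop = FALSE]
    for (an in anchors) {
      key <- paste(cl, an, sep = ".")
      if (!nrow(ev)) { panels[key] <- list(NULL); next }
      profs <- lapply(seq_len(nrow(ev)), function(i)
        extract_profile(track, ev[i, ], anchor = an))
      usable <- sum(!vapply(profs, `[[`, logical(1), "zero_coverage"))
      if (usable == 0) { panels[key] <- list(NULL); next }
      meta <- aggregate_profiles(profs)
      secs <- section_argmax(profs, section_width)
      panels[[key]] <- list(class = cl, anchor = an, meta = meta,
                            sections = secs)
      meta_rows[[key]] <- data.frame(class = cl, anchor = an,
                                     rel = meta$rel, mean = meta$mean,
                                     se = meta$se, stringsAsFactors = FALSE)
      sec_rows[[key]] <- data.frame(class = cl, anchor = an,
                                    section = seq_along(secs$histogram),
                                    count = as.integer(secs$histogram),
                                    stringsAsFactors = FALSE)
    }
  }
  structure(list(
    panels = panels,
    meta_table = if (length(meta_rows)) do.call(rbind, c(meta_rows,
      make.row.names = FALSE)) else NULL,
    section_table = if (length(sec_rows)) do.call(rbind, c(sec_rows,
      make.row.names = FALSE)) else NULL
  ), class = "metaprofile_report")
}
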