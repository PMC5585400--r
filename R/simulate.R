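#' Simulation configuration for tandem-donor cohorts
#'
#' The generator emulates the downstream products of a two-condition splicing
#' perturbation experiment paired with a CLIP-seq binding map: a cohort of
#' tandem-donor A5SS events with known inclusion fractions in a control and a
#' knockdown condition, isoform-diagnostic junction counts, and per-base CLIP
#' coverage with binding peaks planted at a configurable position relative to
#' the intron-distal donor over Poisson background.
#'
#' Events are placed on a synthetic chromosome in non-overlapping 400-nt
#' analysis windows. Each event is assigned a true response class; by default
#' 35% of events shift toward the distal donor under knockdown
#' (`frac_distal`), 35% toward the proximal donor (`frac_proximal`), the rest
#' are unchanged, each shifted class moving inclusion by `effect_size`. The
#' stored ground-truth `direction` is always derived from the realized
#' `psi_knockdown - psi_control` against the 0.2 threshold used downstream,
#' so truth labels and classifier semantics cannot drift apart.
#'
#' @param n_events number of events.
#' @param offset donor spacing in nt: a single value (default 11, the
#'   canonical tandem-donor spacing this pipeline models) or a length-2
#'   integer range sampled uniformly.
#' @param psi_control,psi_knockdown optional true inclusion fractions
#'   (scalar or length `n_events`); when `NULL` they are drawn per response
#'   class (see Details).
#' @param frac_distal,frac_proximal fraction of events whose knockdown
#'   response activates the distal (negative delta-psi) or proximal
#'   (positive delta-psi) donor.
#' @param effect_size |delta psi| planted in responding classes.
#' @param depth mean diagnostic reads per event per sample (Poisson).
#' @param l_inc,l_exc effective lengths (distinct diagnostic read placements)
#'   for the inclusion/exclusion isoform; equal lengths (default) mean pure
#'   junction-read counting.
#' @param peak_fraction fraction of peak-eligible events receiving a CLIP
#'   peak.
#' @param peak_class which events are peak-eligible: `"distal_activated"`
#'   (default), `"proximal_activated"`, `"unchanged"`, or `"all"`.
#' @param peak_center_offset peak center relative to the distal donor in
#'   transcript orientation (nt; negative = exonic/upstream side; default
#'   -25, inside the 50 nt immediately upstream of the donor).
#' @param peak_width,peak_height rectangular peak width (nt) and height
#'   (tags/nt).
#' @param peak_shape `"rect"` (default; makes section ground truth exact) or
#'   `"gauss"` (same mass, sd = width/4).
#' @param background_rate mean Poisson background (tags/nt) inside analysis
#'   windows.
#' @param strand_mix fraction of minus-strand events.
#' @param chrom synthetic chromosome name.
#' @param spacing distance between consecutive event anchors (must leave the
#'   400-nt windows non-overlapping).
#' @param chrom_length optional chromosome length; events that do not fit are
#'   an error. `NULL` sizes the chromosome to fit.
#' @param seed integer seed fixing all randomness.
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_events = 200L,
                              offset = 11L,
                              psi_control = NULL,
                              psi_knockdown = NULL,
                              frac_distal = 0.35,
                              frac_proximal = 0.35,
                              effect_size = 0.4,
                              depth = 200,
                              l_inc = 1,
                              l_exc = 1,
                              peak_fraction = 1,
                              peak_class = "distal_activated",
                              peak_center_offset = -25L,
                              peak_width = 30L,
                              peak_height = 10,
                              peak_shape = c("rect", "gauss"),
                              background_rate = 1,
                              strand_mix = 0.5,
                              chrom = "chrS",
                              spacing = 1000L,
                              chrom_length = NULL,
                              seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  peak_class <- match.arg(peak_class, c("distal_activated",
                                        "proximal_activated",
                                        "unchanged", "all"))
  probs <- c(frac_distal, frac_proximal, strand_mix, peak_fraction,
             psi_control, psi_knockdown)
  if (any(probs < 0 | probs > 1)) {
    stop("fractions and psi values must lie in [0, 1]", call. = FALSE)
  }
  if (frac_distal + frac_proximal > 1) {
    stop("frac_distal + frac_proximal must be <= 1", call. = FALSE)
  }
  if (depth < 0 || background_rate < 0 || peak_height < 0 ||
      peak_width < 0 || l_inc <= 0 || l_exc <= 0) {
    stop("depth, rates and widths must be non-negative; effective lengths ",
         "positive", call. = FALSE)
  }
  offset <- as.integer(offset)
  if (!length(offset) %in% c(1L, 2L) || any(offset < 1L)) {
    stop("offset must be a single value or range, each >= 1", call. = FALSE)
  }
  # peak must fall inside the [-200, 200) window around the distal donor
  pk_lo <- peak_center_offset - peak_width %/% 2L
  if (peak_width > 0 && (pk_lo < -200L || pk_lo + peak_width > 200L)) {
    stop("planted peak extends outside the 400-nt analysis window",
         call. = FALSE)
  }
  structure(list(
    n_events = as.integer(n_events), offset = offset,
    psi_control = psi_control, psi_knockdown = psi_knockdown,
    frac_distal = frac_distal, frac_proximal = frac_proximal,
    effect_size = effect_size, depth = depth, l_inc = l_inc, l_exc = l_exc,
    peak_fraction = peak_fraction, peak_class = peak_class,
    peak_center_offset = as.integer(peak_center_offset),
    peak_width = as.integer(peak_width), peak_height = peak_height,
    peak_shape = peak_shape, background_rate = background_rate,
    strand_mix = strand_mix, chrom = chrom, spacing = as.integer(spacing),
    chrom_length = chrom_length, seed = as.integer(seed)
  ), class = "sim_config")
}

sim_margin <- 500L

#' Simulate a cohort of tandem-donor events with ground truth
#'
#' @param config a [simulation_config()].
#' @return A list with elements `events` (a `"tandem_events"` data.frame) and
#'   `truth` (per-event data.frame: true psi in both conditions, delta psi,
#'   response `direction` consistent with the 0.2 threshold, peak flags and
#'   the genomic peak interval, 0-based half-open).
#' @export
simulate_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_events
  empty <- list(
    events = tandem_events(character(), character(), character(),
                           integer(), integer())[0, ],
    truth = data.frame(event_id = character(), psi_control = numeric(),
                       psi_knockdown = numeric(), delta_psi = numeric(),
                       direction = character(), strand = character(),
                       peak_planted = logical(),
                       peak_center_offset = integer(),
                       peak_start = integer(), peak_end = integer())
  )
  if (n == 0L) return(empty)
  set.seed(config$seed)

  offs <- if (length(config$offset) == 1L) rep(config$offset, n) else
    sample(config$offset[1]:config$offset[2], n, replace = TRUE)
  max_off <- max(offs)
  if (config$spacing < 400L + max_off) {
    stop("spacing too small: 400-nt windows around the two donors overlap ",
         "between events", call. = FALSE)
  }
  anchors <- sim_margin + (seq_len(n) - 1L) * config$spacing
  needed <- anchors[n] + max_off + 400L + sim_margin
  if (!is.null(config$chrom_length) && config$chrom_length < needed) {
    stop("chromosome length ", config$chrom_length, " too short to place ",
         n, " non-overlapping 400-nt windows (need ", needed, ")",
         call. = FALSE)
  }
  minus <- stats::runif(n) < config$strand_mix
  distal <- ifelse(minus, anchors + offs, anchors)
  proximal <- ifelse(minus, anchors, anchors + offs)

  events <- tandem_events(
    event_id = sprintf("ev%04d", seq_len(n)),
    chrom = config$chrom,
    strand = ifelse(minus, "-", "+"),
    distal_donor = distal,
    proximal_donor = proximal
  )

  cls <- sample(c("distal_activated", "proximal_activated", "unchanged"),
                n, replace = TRUE,
                prob = c(config$frac_distal, config$frac_proximal,
                         1 - config$frac_distal - config$frac_proximal))
  eff <- config$effect_size
  if (is.null(config$psi_control)) {
    psi1 <- stats::runif(n, 0.05, 0.95)
    psi1[cls == "distal_activated"] <-
      stats::runif(sum(cls == "distal_activated"), min(eff + 0.05, 0.95), 0.95)
    psi1[cls == "proximal_activated"] <-
      stats::runif(sum(cls == "proximal_activated"), 0.05,
                   max(0.95 - eff, 0.05))
  } else {
    psi1 <- rep_len(config$psi_control, n)
  }
  if (is.null(config$psi_knockdown)) {
    psi2 <- psi1
    psi2[cls == "distal_activated"] <-
      pmax(0, psi1[cls == "distal_activated"] - eff)
    psi2[cls == "proximal_activated"] <-
      pmin(1, psi1[cls == "proximal_activated"] + eff)
  } else {
    psi2 <- rep_len(config$psi_knockdown, n)
  }
  dpsi <- psi2 - psi1
  direction <- ifelse(dpsi <= -0.2, "distal_activated",
                      ifelse(dpsi >= 0.2, "proximal_activated", "unchanged"))

  eligible <- if (config$peak_class == "all") rep(TRUE, n) else
    direction == config$peak_class
  planted <- eligible & stats::runif(n) < config$peak_fraction &
    config$peak_width > 0 & config$peak_height > 0
  pk <- peak_genomic_interval(distal, events$strand,
                              config$peak_center_offset, config$peak_width)

  truth <- data.frame(
    event_id = events$event_id,
    psi_control = psi1, psi_knockdown = psi2, delta_psi = dpsi,
    direction = direction, strand = events$strand,
    peak_planted = planted,
    peak_center_offset = ifelse(planted, config$peak_center_offset,
                                NA_integer_),
    peak_start = ifelse(planted, pk$start, NA_integer_),
    peak_end = ifelse(planted, pk$end, NA_integer_),
    stringsAsFactors = FALSE
  )
  list(events = events, truth = truth)
}

# Genomic half-open interval covered by a rectangular peak whose transcript-
# orientation offsets relative to the distal donor are
# [center - w %/% 2, center - w %/% 2 + w).
peak_genomic_interval <- function(distal, strand, center, width) {
  r0 <- center - width %/% 2L          # first transcript offset
  r1 <- r0 + width - 1L                # last transcript offset
  start <- ifelse(strand == "+", distal + r0, distal - r1)
  end <- ifelse(strand == "+", distal + r1 + 1L, distal - r0 + 1L)
  list(start = as.integer(start), end = as.integer(end))
}

#' Simulate two-condition diagnostic counts under known psi
#'
#' For each event and condition, the total diagnostic depth is
#' `N ~ Poisson(depth)` and `n_proximal ~ Binomial(N, p)` with
#' `p = psi * l_inc / (psi * l_inc + (1 - psi) * l_exc)` — the same
#' effective-length weighting the estimator inverts; with equal lengths
#' `p = psi`.
#'
#' @param events,truth as returned by [simulate_events()].
#' @param config the same [simulation_config()].
#' @param samples names of the two conditions, control first.
#' @return A counts data.frame (see [read_counts()]).
#' @export
simulate_counts <- function(events, truth, config,
                            samples = c("ctrl", "kd")) {
  stopifnot(inherits(config, "sim_config"), length(samples) == 2L)
  if (!all(events$event_id %in% truth$event_id)) {
    stop("truth does not cover all events", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  truth <- truth[match(events$event_id, truth$event_id), ]
  out <- lapply(seq_along(samples), function(k) {
    psi <- if (k == 1L) truth$psi_control else truth$psi_knockdown
    p <- psi * config$l_inc / (psi * config$l_inc + (1 - psi) * config$l_exc)
    n <- stats::rpois(nrow(events), config$depth)
    npx <- stats::rbinom(nrow(events), n, p)
    data.frame(event_id = events$event_id, sample_id = samples[k],
               n_distal = n - npx, n_proximal = npx,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate CLIP coverage with planted binding peaks
#'
#' Per-base coverage inside each event's analysis region is Poisson
#' background plus, for peak-planted events, a peak of `peak_height` over
#' `peak_width` nt centered `peak_center_offset` nt from the distal donor in
#' transcript orientation (genomically mirrored on minus-strand events).
#'
#' @inheritParams simulate_counts
#' @return A `"coverage_track"`.
#' @export
simulate_clip <- function(events, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  len <- if (!is.null(config$chrom_length)) config$chrom_length else
    if (nrow(events)) max(events$distal_donor, events$proximal_donor) +
      401L + sim_margin else 1000L
  cov <- numeric(len)
  truth <- truth[match(events$event_id, truth$event_id), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    # one base of slack so minus-strand windows (r = -200 maps to
    # anchor + 200) still see background at their genomic edge
    lo <- max(0L, min(events$distal_donor[i], events$proximal_donor[i]) - 201L)
    hi <- max(events$distal_donor[i], events$proximal_donor[i]) + 201L
    idx <- (lo:(hi - 1L)) + 1L
    cov[idx] <- cov[idx] + stats::rpois(length(idx), config$background_rate)
    if (isTRUE(truth$peak_planted[i])) {
      ps <- truth$peak_start[i]; pe <- truth$peak_end[i]
      if (config$peak_shape == "rect") {
        cov[(ps:(pe - 1L)) + 1L] <- cov[(ps:(pe - 1L)) + 1L] +
          config$peak_height
      } else {
        ctr <- (ps + pe - 1L) / 2
        g <- ps:(pe - 1L)
        cov[g + 1L] <- cov[g + 1L] +
          config$peak_height * exp(-(g - ctr)^2 / (2 * (config$peak_width / 4)^2))
      }
    }
  }
  coverage_track(stats::setNames(list(S4Vectors::Rle(cov)), config$chrom))
}

#' Simulate a full dataset and write it to disk
#'
#' Writes `events.tsv`, `counts.tsv`, `clip.bedgraph` and `truth.json` under
#' `outdir`; a fixed seed gives byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_events(config)
  counts <- simulate_counts(sim$events, sim$truth, config)
  clip <- simulate_clip(sim$events, sim$truth, config)
  paths <- list(
    events = file.path(outdir, "events.tsv"),
    counts = file.path(outdir, "counts.tsv"),
    clip = file.path(outdir, "clip.bedgraph"),
    truth = file.path(outdir, "truth.json")
  )
  write_events(sim$events, paths$events)
  write_counts(counts, paths$counts)
  write_bedgraph(clip, paths$clip)
  jsonlite::write_json(sim$truth, paths$truth, digits = NA, na = "null")
  invisible(list(events = sim$events, truth = sim$truth, counts = counts,
                 clip = clip, paths = paths))
}
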