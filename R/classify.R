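#' Classify events by perturbation response
#'
#' Partitions events into three exhaustive, exclusive classes using the
#' stated sign convention (psi = proximal/inclusion usage):
#' \itemize{
#'   \item `distal_activated`: significant and `delta_psi <= -0.2` —
#'     inclusion falls, so the perturbation activates the intron-distal
#'     donor;
#'   \item `proximal_activated`: significant and `delta_psi >= +0.2`;
#'   \item `unchanged`: everything else.
#' }
#'
#' @param results the per-event data.frame from [analyze_counts()] (columns
#'   `event_id`, `delta_psi`, `bayes_factor`, `significant`).
#' @param delta_threshold the |delta psi| cut used for the direction call;
#'   defaults to the threshold stored on `results`, else 0.2.
#' @return A list with `events` (data.frame adding a `direction` column) and
#'   `counts` (named integer vector over the three classes; sums to
#'   `nrow(results)`).
#' @export
classify_events <- function(results, delta_threshold = NULL) {
  need <- c("event_id", "delta_psi", "bayes_factor", "significant")
  stopifnot(all(need %in% names(results)))
  if (is.null(delta_threshold)) {
    th <- attr(results, "thresholds")
    delta_threshold <- if (!is.null(th)) th$delta_psi else 0.2
  }
  direction <- rep("unchanged", nrow(results))
  sig <- results$significant %in% TRUE
  direction[sig & results$delta_psi <= -delta_threshold] <- "distal_activated"
  direction[sig & results$delta_psi >= delta_threshold] <- "proximal_activated"
  events <- cbind(results,
                  data.frame(direction = direction, stringsAsFactors = FALSE))
  counts <- c(
    distal_activated = sum(direction == "distal_activated"),
    proximal_activated = sum(direction == "proximal_activated"),
    unchanged = sum(direction == "unchanged")
  )
  list(events = events, counts = counts)
}

#' One-line class summary
#'
#' @param classified result of [classify_events()].
#' @return A character scalar like
#'   `"distal_activated: 12  proximal_activated: 7  unchanged: 181"`.
#' @export
class_summary <- function(classified) {
  paste(sprintf("%s: %d", names(classified$counts), classified$counts),
        collapse = "  ")
}
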