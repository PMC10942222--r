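INTERVAL_STREAMS <- c("all", "left", "right")
INTERVAL_STATS <- c("mean", "max", "min", "sd")

#' Names of the features produced by [extract_features()]
#'
#' Under the default taxonomy this is 63 names: 20 per-category counts
#' (`count.*`), 20 per-category total durations in seconds (`dur.*`), 12
#' inter-event interval statistics (`int.<stream>.<stat>`, seconds, for the
#' all/left/right event streams), 3 gesture shift frequencies
#' (`shift.<stream>`, per minute), 7 dissection/exposure summary items
#' (`de.*`), and the manipulation time in minutes (`manip_time`). In
#' general the length is `2C + 12 + 3 + 7 + 1` for `C` tracked categories.
#'
#' @param taxonomy A `surgesture_taxonomy`.
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(taxonomy = default_taxonomy()) {
  cats <- taxonomy_categories(taxonomy)
  c(paste0("count.", cats),
    paste0("dur.", cats),
    paste0("int.", rep(INTERVAL_STREAMS, each = 4L), ".", INTERVAL_STATS),
    paste0("shift.", INTERVAL_STREAMS),
    paste0("de.", c("count_D", "count_E", "dur_D", "dur_E", "count_ratio",
                    "dur_ratio", "shift")),
    "manip_time")
}

#' Per-category count and duration features
#'
#' For each tracked category (gesture x hand for per-hand gestures, gesture
#' alone otherwise): the number of events and their total duration in
#' seconds, pooled over the MHT and DGB phases.
#'
#' @param case A `surgesture_case`.
#' @param taxonomy A `surgesture_taxonomy`.
#' @return Named numeric vector, `2C` values (`count.*` then `dur.*`).
#' @export
count_and_duration_features <- function(case, taxonomy = default_taxonomy()) {
  cats <- taxonomy_categories(taxonomy)
  ev <- case$events
  counts <- stats::setNames(numeric(length(cats)), paste0("count.", cats))
  durs <- stats::setNames(numeric(length(cats)), paste0("dur.", cats))
  if (nrow(ev) > 0L) {
    cat_of <- event_category(ev$label, ev$hand, taxonomy)
    tab <- tapply(rep(1, nrow(ev)), cat_of, sum)
    dtab <- tapply(ev$end_s - ev$start_s, cat_of, sum)
    counts[paste0("count.", names(tab))] <- tab
    durs[paste0("dur.", names(dtab))] <- dtab
  }
  c(counts, durs)
}

# gaps between consecutive events of one stream, per phase (no cross-phase
# gaps); negative gaps (overlapping hands in the pooled stream) clamp to 0
stream_gaps <- function(ev) {
  gaps <- numeric()
  for (p in unique(ev$phase)) {
    e <- ev[ev$phase == p, , drop = FALSE]
    if (nrow(e) < 2L) next
    o <- order(e$start_s, e$end_s)
    g <- e$start_s[o][-1L] - e$end_s[o][-nrow(e)]
    gaps <- c(gaps, pmax(g, 0))
  }
  gaps
}

stream_events <- function(case, stream) {
  ev <- case$events
  switch(stream,
         all = ev,
         left = ev[ev$hand == "left", , drop = FALSE],
         right = ev[ev$hand == "right", , drop = FALSE],
         stop("unknown stream: ", stream, call. = FALSE))
}

#' Inter-event interval features
#'
#' For each of the three event streams (all events, left-hand events,
#' right-hand events): the gaps between the end of one event and the start
#' of the next within each phase, summarized by mean, max, min and sample
#' standard deviation (seconds). Streams with fewer than two events report
#' all four statistics as 0 with a warning; single-gap streams report SD 0.
#'
#' @inheritParams count_and_duration_features
#' @return Named numeric vector of 12 values `int.<stream>.<stat>`.
#' @export
interval_features <- function(case, taxonomy = default_taxonomy()) {
  out <- numeric(0)
  for (s in INTERVAL_STREAMS) {
    ev <- stream_events(case, s)
    nm <- paste0("int.", s, ".", INTERVAL_STATS)
    gaps <- stream_gaps(ev)
    if (length(gaps) == 0L) {
      warning("interval stream '", s, "' of video ", case$video_id,
              " has fewer than 2 events in every phase; interval ",
              "statistics set to 0", call. = FALSE)
      vals <- c(0, 0, 0, 0)
    } else {
      sdv <- if (length(gaps) > 1L) stats::sd(gaps) else 0
      vals <- c(mean(gaps), max(gaps), min(gaps), sdv)
    }
    out <- c(out, stats::setNames(vals, nm))
  }
  out
}

#' Gesture shift frequency of one stream
#'
#' Number of label changes between consecutive events of the time-sorted
#' stream (counted within each phase, never across the phase boundary),
#' divided by the manipulation time in minutes.
#'
#' @inheritParams count_and_duration_features
#' @param stream `"all"`, `"left"` or `"right"`.
#' @return Shifts per minute (scalar).
#' @export
shift_frequency <- function(case, stream = "all",
                            taxonomy = default_taxonomy()) {
  mt <- manipulation_time_min(case)
  if (mt <= 0) stop("manipulation time must be positive", call. = FALSE)
  ev <- stream_events(case, stream)
  n_shift <- 0L
  for (p in unique(ev$phase)) {
    e <- ev[ev$phase == p, , drop = FALSE]
    if (nrow(e) < 2L) next
    lab <- e$label[order(e$start_s, e$end_s)]
    n_shift <- n_shift + sum(lab[-1L] != lab[-length(lab)])
  }
  n_shift / mt
}

#' Dissection/exposure (D/E) summary features
#'
#' Counts and total durations of dissection-class and exposure-class
#' gestures, their ratios, and the rate of D<->E class changes along the
#' all-events stream (per minute). A ratio with a zero denominator is
#' computed against a floor of 1 event / 1 second (with a warning) so the
#' feature matrix stays finite.
#'
#' @inheritParams count_and_duration_features
#' @return Named numeric vector of 7 values `de.*`.
#' @export
de_features <- function(case, taxonomy = default_taxonomy()) {
  ev <- case$events
  cls <- gesture_class(ev$label, taxonomy)
  dur <- ev$end_s - ev$start_s
  count_D <- sum(cls == "dissection")
  count_E <- sum(cls == "exposure")
  dur_D <- sum(dur[cls == "dissection"])
  dur_E <- sum(dur[cls == "exposure"])
  if (count_E == 0 || dur_E == 0)
    warning("no exposure events in video ", case$video_id,
            "; D/E ratio denominators floored at 1 event / 1 s",
            call. = FALSE)
  count_ratio <- count_D / max(count_E, 1)
  dur_ratio <- dur_D / max(dur_E, 1)
  n_shift <- 0L
  for (p in unique(ev$phase)) {
    idx <- ev$phase == p
    if (sum(idx) < 2L) next
    e_cls <- cls[idx][order(ev$start_s[idx], ev$end_s[idx])]
    n_shift <- n_shift + sum(e_cls[-1L] != e_cls[-length(e_cls)])
  }
  c(de.count_D = count_D, de.count_E = count_E,
    de.dur_D = dur_D, de.dur_E = dur_E,
    de.count_ratio = count_ratio, de.dur_ratio = dur_ratio,
    de.shift = n_shift / manipulation_time_min(case))
}

#' Extract the full feature vector of one case
#'
#' Concatenates the per-category count and duration features, the interval
#' statistics, the shift frequencies, the D/E summary items and the
#' manipulation time (minutes). Under the default 14-gesture taxonomy the
#' result has exactly 63 entries; it is a pure function of its inputs.
#'
#' @inheritParams count_and_duration_features
#' @return Named numeric vector in the order of [feature_names()].
#' @examples
#' case <- worked_fixture()$cases[[1]]
#' fv <- extract_features(case)
#' length(fv)  # 63
#' @export
extract_features <- function(case, taxonomy = default_taxonomy()) {
  out <- c(count_and_duration_features(case, taxonomy),
           interval_features(case, taxonomy),
           stats::setNames(
             vapply(INTERVAL_STREAMS, shift_frequency, numeric(1),
                    case = case, taxonomy = taxonomy),
             paste0("shift.", INTERVAL_STREAMS)),
           de_features(case, taxonomy),
           manip_time = manipulation_time_min(case))
  stopifnot(identical(names(out), feature_names(taxonomy)))
  out
}

#' Extract a feature matrix from a list of cases
#'
#' @param cases List of `surgesture_case`.
#' @param taxonomy A `surgesture_taxonomy`.
#' @param quiet Suppress degenerate-stream warnings during bulk extraction.
#' @return `data.frame` with `video_id`, `surgeon_id` and one column per
#'   feature (63 under the default taxonomy), one row per case.
#' @export
extract_feature_matrix <- function(cases, taxonomy = default_taxonomy(),
                                   quiet = FALSE) {
  rows <- lapply(cases, function(cs) {
    fv <- if (quiet) suppressWarnings(extract_features(cs, taxonomy))
          else extract_features(cs, taxonomy)
    cbind(data.frame(video_id = cs$video_id, surgeon_id = cs$surgeon_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
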