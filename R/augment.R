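#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals
#' never perturb user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Augmentation parameters
#'
#' Stochastic timeline perturbations analogous to the synonym-replacement /
#' random-deletion / random-insertion family of text augmentations, applied
#' to gesture event streams: boundary jitter by a truncated Gaussian,
#' independent event deletion, and event duplication-with-jitter. Gesture
#' labels are never altered.
#'
#' @param jitter_sd_s Standard deviation of the boundary jitter, seconds
#'   (>= 0).
#' @param p_delete Per-event deletion probability in \[0, 1).
#' @param p_duplicate Per-event duplication probability in \[0, 1).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An `augment_params` list.
#' @export
augment_params <- function(jitter_sd_s = 2, p_delete = 0.05,
                           p_duplicate = 0.05, seed = 1L) {
  if (jitter_sd_s < 0) stop("jitter_sd_s must be >= 0", call. = FALSE)
  if (p_delete < 0 || p_delete >= 1)
    stop("p_delete must lie in [0, 1): p_delete = 1 would empty the ",
         "timeline", call. = FALSE)
  if (p_duplicate < 0 || p_duplicate >= 1)
    stop("p_duplicate must lie in [0, 1)", call. = FALSE)
  if (is.null(seed) || is.na(seed))
    stop("an integer seed is required", call. = FALSE)
  structure(list(jitter_sd_s = jitter_sd_s, p_delete = p_delete,
                 p_duplicate = p_duplicate, seed = as.integer(seed)),
            class = "augment_params")
}

# truncated-normal jitter: |draw| capped at 3 sd to preserve order locally
rjitter <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  pmin(pmax(stats::rnorm(n, 0, sd), -3 * sd), 3 * sd)
}

#' Augment one case timeline
#'
#' Applies jitter/delete/duplicate per [augment_params()], then restores
#' validity: event boundaries are clipped to the phase duration, durations
#' kept positive, and same-hand overlaps removed by clipping each event's
#' start to the previous same-hand event's end. Deterministic given
#' `params$seed`.
#'
#' @param case A valid `surgesture_case`.
#' @param params An `augment_params`.
#' @param taxonomy Taxonomy used to re-validate the result.
#' @return A new valid `surgesture_case` (video id suffixed `.aug`).
#' @export
augment_timeline <- function(case, params, taxonomy = default_taxonomy()) {
  stopifnot(inherits(case, "surgesture_case"),
            inherits(params, "augment_params"))
  with_seed(params$seed, {
    ev <- case$events
    n <- nrow(ev)
    if (n > 0L) {
      keep <- stats::runif(n) >= params$p_delete
      dup <- stats::runif(n) < params$p_duplicate
      ev <- rbind(ev[keep, , drop = FALSE], ev[dup, , drop = FALSE])
      n2 <- nrow(ev)
      if (n2 > 0L) {
        ev$start_s <- ev$start_s + rjitter(n2, params$jitter_sd_s)
        ev$end_s <- ev$end_s + rjitter(n2, params$jitter_sd_s)
        ev <- repair_events(ev, case$phase_durations)
      }
    }
    out <- case_timeline(paste0(case$video_id, ".aug"), case$surgeon_id,
                         ev, phase_durations = case$phase_durations,
                         metadata = case$metadata, taxonomy = taxonomy)
    out$provenance <- case$video_id
    out
  })
}

# clip jittered events back into a valid configuration
repair_events <- function(ev, phase_durations) {
  min_dur <- 0.05
  ev$start_s <- pmax(ev$start_s, 0)
  ev$end_s <- pmax(ev$end_s, ev$start_s + min_dur)
  pd <- phase_durations[ev$phase]
  ev$end_s <- pmin(ev$end_s, pd)
  ev$start_s <- pmin(ev$start_s, ev$end_s - min_dur)
  ev <- ev[ev$start_s >= 0 & ev$end_s > ev$start_s, , drop = FALSE]
  # same-hand non-overlap by forward clipping within each phase
  out <- list()
  for (p in unique(ev$phase)) {
    for (h in unique(ev$hand)) {
      e <- ev[ev$phase == p & ev$hand == h, , drop = FALSE]
      if (h %in% c("left", "right") && nrow(e) > 1L) {
        e <- e[order(e$start_s, e$end_s), , drop = FALSE]
        for (i in 2:nrow(e)) {
          if (e$start_s[i] < e$end_s[i - 1L])
            e$start_s[i] <- e$end_s[i - 1L]
          if (e$end_s[i] < e$start_s[i] + min_dur)
            e$end_s[i] <- e$start_s[i] + min_dur
        }
        pd_p <- phase_durations[[p]]
        e <- e[e$end_s <= pd_p + 1e-9 & e$start_s < pd_p, , drop = FALSE]
        e$end_s <- pmin(e$end_s, pd_p)
      }
      out[[length(out) + 1L]] <- e
    }
  }
  do.call(rbind, out)
}

#' Oversample the minority class by timeline augmentation
#'
#' Adds augmented copies of randomly chosen minority-class cases until both
#' classes have equal counts. Each synthetic case records its source case
#' (provenance), and every synthetic case passes full timeline validation.
#'
#' @param cases List of `surgesture_case`.
#' @param labels Binary labels aligned with `cases` (2 levels, both
#'   present).
#' @param params An `augment_params`; per-copy seeds are derived from
#'   `params$seed`.
#' @param taxonomy Taxonomy for validation.
#' @return List with `cases`, `labels`, and `provenance` (`data.frame`
#'   `synthetic_id`, `source_id`; empty when already balanced).
#' @export
balance_classes <- function(cases, labels, params,
                            taxonomy = default_taxonomy()) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("balance_classes needs both classes present", call. = FALSE)
  if (length(tab) > 2L)
    stop("balance_classes expects binary labels", call. = FALSE)
  n_add <- abs(tab[[1L]] - tab[[2L]])
  prov <- data.frame(synthetic_id = character(), source_id = character(),
                     stringsAsFactors = FALSE)
  if (n_add == 0L)
    return(list(cases = cases, labels = labels, provenance = prov))
  minority <- names(tab)[which.min(tab)]
  src_idx <- which(labels == minority)
  picks <- with_seed(params$seed,
                     sample(src_idx, n_add, replace = TRUE))
  for (i in seq_len(n_add)) {
    p_i <- params
    p_i$seed <- as.integer((params$seed + 7919 * i) %% .Machine$integer.max)
    aug <- augment_timeline(cases[[picks[i]]], p_i, taxonomy)
    aug$video_id <- sprintf("%s.aug%03d", cases[[picks[i]]]$video_id, i)
    cases[[length(cases) + 1L]] <- aug
    labels <- c(labels, minority)
    prov <- rbind(prov, data.frame(synthetic_id = aug$video_id,
                                   source_id = aug$provenance,
                                   stringsAsFactors = FALSE))
  }
  list(cases = cases, labels = labels, provenance = prov)
}
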