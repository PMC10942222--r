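#' Synthetic cohort configuration
#'
#' Parameters of the semi-Markov cohort generator. Group contrasts are each
#' a directly configured parameter, expressed as incompetent/competent
#' ratios unless stated otherwise: inefficient-gesture sampling weight
#' (`inefficient_rate_ratio`), event duration scale
#' (`duration_scale_ratio`, which also lengthens the operation), gesture
#' transition intensity (`shift_rate_ratio`), the competent/incompetent
#' fold of the expected dissection/exposure duration ratio
#' (`de_ratio_fold`), and per-group vascular-injury probabilities. Defaults
#' mirror the published cohort: 33 surgeons, 26/75 of videos from
#' bottom-quartile surgeons, injury probabilities 6.1% / 30.8%, a 1.6-fold
#' D/E contrast, and an operation length centred near 11 minutes.
#'
#' @param n_surgeons Number of surgeons.
#' @param videos_per_surgeon Integer range `c(min, max)` of videos each
#'   surgeon submits.
#' @param incompetent_fraction Probability that a surgeon belongs to the
#'   incompetent (bottom) group.
#' @param seed Integer seed (mandatory).
#' @param inefficient_rate_ratio,duration_scale_ratio,shift_rate_ratio
#'   Effect ratios (> 0); 1 switches the effect off.
#' @param de_ratio_fold Competent/incompetent fold of the expected D/E
#'   duration ratio (> 0); 1 switches the effect off.
#' @param injury_probs Named numeric `c(competent = , incompetent = )`.
#' @param rating_noise_sd SD of the per-rater Gaussian noise added to the
#'   latent item score before rounding/clipping to 1-5.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_surgeons = 33L,
                          videos_per_surgeon = c(1L, 4L),
                          incompetent_fraction = 26 / 75,
                          seed = NULL,
                          inefficient_rate_ratio = 2,
                          duration_scale_ratio = 1.5,
                          shift_rate_ratio = 2,
                          de_ratio_fold = 1.6,
                          injury_probs = c(competent = 0.061,
                                           incompetent = 0.308),
                          rating_noise_sd = 0.35) {
  if (is.null(seed) || is.na(seed))
    stop("cohort_config requires an integer seed", call. = FALSE)
  if (incompetent_fraction <= 0 || incompetent_fraction >= 1)
    stop("incompetent_fraction must lie in (0, 1)", call. = FALSE)
  for (r in c(inefficient_rate_ratio, duration_scale_ratio,
              shift_rate_ratio, de_ratio_fold))
    if (r <= 0) stop("effect ratios must be > 0", call. = FALSE)
  if (any(injury_probs < 0 | injury_probs > 1) ||
      !all(c("competent", "incompetent") %in% names(injury_probs)))
    stop("injury_probs must be named probabilities for competent and ",
         "incompetent", call. = FALSE)
  if (rating_noise_sd < 0) stop("rating_noise_sd must be >= 0",
                                call. = FALSE)
  structure(list(
    n_surgeons = as.integer(n_surgeons),
    videos_per_surgeon = as.integer(videos_per_surgeon),
    incompetent_fraction = incompetent_fraction,
    seed = as.integer(seed),
    inefficient_rate_ratio = inefficient_rate_ratio,
    duration_scale_ratio = duration_scale_ratio,
    shift_rate_ratio = shift_rate_ratio,
    de_ratio_fold = de_ratio_fold,
    injury_probs = injury_probs,
    rating_noise_sd = rating_noise_sd), class = "cohort_config")
}

# fixed generator baselines (competent group); group effects multiply these
GEN_BASE <- list(
  phase_mean_s = c(MHT = 330, DGB = 230),  # ~9.3 min total, lognormal
  phase_sdlog = 0.22,
  block_mean_s = 35,          # mean semi-Markov block length
  de_block_ratio = 1.4,       # competent D:E block-time ratio
  event_meanlog = log(3.5),   # lognormal event duration, ~3.5 s
  event_sdlog = 0.5,
  gap_mean_s = 1.5,           # exponential inter-event gap
  p_change = 0.35,            # within-block label-change probability
  ineff_weight = 0.6,         # sampling weight of inefficient variants
  skill_mean = c(competent = 4.35, incompetent = 2.9),
  skill_sd = c(competent = 0.35, incompetent = 0.45),
  item_sd = 0.3,              # item-specific offset around surgeon skill
  p_thermal = 0.9, p_broken = 0.067, p_parkland2 = 0.147)

#' Generate a synthetic surgeon cohort
#'
#' Draws surgeons with latent skill by group, then per video a two-phase
#' alternating dissection/exposure semi-Markov event stream, two simulated
#' raters' mGOALS item scores, and a binary vascular-injury outcome. All
#' group contrasts come from the effect block of [cohort_config()]; with
#' all ratios at 1 and equal injury probabilities the two groups are
#' exchangeable (a null cohort). All generated timelines pass full
#' validation, and output is deterministic given the config seed.
#'
#' @param config A `cohort_config`.
#' @param taxonomy Taxonomy whose vocabulary the generator draws from.
#' @param include_timelines Set `FALSE` to generate only ratings and
#'   outcomes (fast path for large outcome-only simulations).
#' @return List: `cases` (list of `surgesture_case`, or `NULL`),
#'   `ratings` (two raters x videos), `outcomes` (`data.frame` with
#'   `video_id`, `surgeon_id`, `group`, `vascular_injury`, `cvs_score`,
#'   `parkland_grade`), and `config`.
#' @export
generate_cohort <- function(config, taxonomy = default_taxonomy(),
                            include_timelines = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    b <- GEN_BASE
    surgeons <- sprintf("S%03d", seq_len(config$n_surgeons))
    grp <- ifelse(stats::runif(config$n_surgeons) <
                    config$incompetent_fraction,
                  "incompetent", "competent")
    nvid <- sample(seq(config$videos_per_surgeon[1L],
                       config$videos_per_surgeon[2L]),
                   config$n_surgeons, replace = TRUE)
    # per-surgeon latent item means, clipped to the 1-5 scale
    skill <- lapply(seq_len(config$n_surgeons), function(i) {
      base <- stats::rnorm(1, b$skill_mean[[grp[i]]], b$skill_sd[[grp[i]]])
      pmin(pmax(base + stats::rnorm(4, 0, b$item_sd), 1), 5)
    })
    cases <- list(); rating_rows <- list(); outcome_rows <- list()
    for (i in seq_len(config$n_surgeons)) {
      for (v in seq_len(nvid[i])) {
        vid <- sprintf("%s.V%02d", surgeons[i], v)
        injured <- stats::runif(1) < config$injury_probs[[grp[i]]]
        meta <- list(
          parkland_grade = if (stats::runif(1) < b$p_parkland2) 2L else 1L,
          cvs_score = sample(0:6, 1L,
                             prob = c(0.1, 0.2, 0.3, 0.2, 0.1, 0.05,
                                      0.05)),
          intraop_events = c(
            if (injured) "cholecystic_vascular_injury",
            if (stats::runif(1) < b$p_thermal) "liver_thermal_injury",
            if (stats::runif(1) < b$p_broken) "gallbladder_broken"))
        if (include_timelines) {
          ev <- rbind(gen_phase("MHT", grp[i], config, taxonomy, b),
                      gen_phase("DGB", grp[i], config, taxonomy, b))
          pd <- vapply(PHASES, function(p) {
            e <- ev$end_s[ev$phase == p]
            if (length(e)) max(e) + 1 else 1
          }, numeric(1))
          cases[[length(cases) + 1L]] <- case_timeline(
            vid, surgeons[i], ev, phase_durations = pd, metadata = meta,
            taxonomy = taxonomy, validate = FALSE)
        }
        for (rater in c("R1", "R2")) {
          items <- pmin(pmax(round(
            skill[[i]] + stats::rnorm(4, 0, config$rating_noise_sd)), 1), 5)
          rating_rows[[length(rating_rows) + 1L]] <- data.frame(
            video_id = vid, rater_id = rater,
            depth_perception = items[1L], bimanual_dexterity = items[2L],
            efficiency = items[3L], tissue_handling = items[4L],
            stringsAsFactors = FALSE)
        }
        outcome_rows[[length(outcome_rows) + 1L]] <- data.frame(
          video_id = vid, surgeon_id = surgeons[i], group = grp[i],
          vascular_injury = injured, cvs_score = meta$cvs_score,
          parkland_grade = meta$parkland_grade, stringsAsFactors = FALSE)
      }
    }
    list(cases = if (include_timelines) cases,
         ratings = do.call(rbind, rating_rows),
         outcomes = do.call(rbind, outcome_rows),
         config = config)
  })
}

# one phase: alternating exposure/dissection blocks; block lengths are
# exponential (shorter for high shift intensity), D:E mean block length
# controls the expected D/E duration ratio, events fill each block
gen_phase <- function(phase, group, config, taxonomy, b) {
  inc <- group == "incompetent"
  dur_scale <- if (inc) config$duration_scale_ratio else 1
  shift_scale <- if (inc) config$shift_rate_ratio else 1
  de_ratio <- if (inc) b$de_block_ratio / config$de_ratio_fold
              else b$de_block_ratio
  target <- stats::rlnorm(1, log(b$phase_mean_s[[phase]]),
                          b$phase_sdlog) * dur_scale
  mean_E <- 2 * b$block_mean_s / (1 + de_ratio) / shift_scale
  mean_D <- de_ratio * mean_E
  # alternating block schedule until the phase target is filled
  cls <- character(); lens <- numeric(); tot <- 0; cur <- "exposure"
  while (tot < target) {
    len <- stats::rexp(1, 1 / (if (cur == "exposure") mean_E else mean_D))
    len <- min(len, target - tot)
    # blocks too short to hold an event become untracked pauses
    if (len > 2) { cls <- c(cls, cur); lens <- c(lens, len) }
    tot <- tot + len
    cur <- if (cur == "exposure") "dissection" else "exposure"
  }
  if (length(cls) == 0L) { cls <- "exposure"; lens <- target }
  vocab <- split(taxonomy$name, taxonomy$functional_class)
  wts <- lapply(vocab, function(nm) {
    eff <- taxonomy$efficiency[match(nm, taxonomy$name)]
    w <- ifelse(eff == "inefficient",
                b$ineff_weight *
                  (if (inc) config$inefficient_rate_ratio else 1), 1)
    w / sum(w)
  })
  p_change <- min(0.95, b$p_change * shift_scale)
  t0 <- 0; out <- vector("list", length(cls))
  for (k in seq_along(cls)) {
    nm <- vocab[[cls[k]]]; w <- wts[[cls[k]]]
    n_ev <- max(1L, stats::rpois(
      1, lens[k] / (exp(b$event_meanlog + b$event_sdlog^2 / 2) * dur_scale +
                      b$gap_mean_s)))
    d <- stats::rlnorm(n_ev, b$event_meanlog, b$event_sdlog) * dur_scale
    g <- stats::rexp(n_ev, 1 / b$gap_mean_s)
    sc <- lens[k] / (sum(d) + sum(g))  # fit the block exactly
    d <- d * sc; g <- g * sc
    lab <- character(n_ev)
    lab[1L] <- sample(nm, 1L, prob = w)
    if (n_ev > 1L) for (j in 2:n_ev) {
      lab[j] <- if (stats::runif(1) < p_change) sample(nm, 1L, prob = w)
                else lab[j - 1L]
    }
    per_hand <- taxonomy$per_hand[match(lab, taxonomy$name)]
    hand <- rep("unattributed", n_ev)
    p_left <- if (cls[k] == "exposure") 0.75 else 0.2
    hand[per_hand] <- ifelse(stats::runif(sum(per_hand)) < p_left,
                             "left", "right")
    start <- t0 + cumsum(g) + c(0, cumsum(d[-n_ev]))
    out[[k]] <- data.frame(phase = phase, label = lab, hand = hand,
                           start_s = start, end_s = start + d,
                           stringsAsFactors = FALSE)
    t0 <- t0 + lens[k]
  }
  do.call(rbind, out)
}

#' The worked micro-cohort fixture
#'
#' A deterministic 12-video cohort whose timelines are small hand-written
#' files shipped with the package (`inst/extdata/worked_fixture/`). It
#' exercises every parser and feature branch: per-hand gestures, single
#' -event and empty hand streams, back-to-back events, and an
#' all-dissection case that triggers the D/E denominator floor.
#'
#' @return List: `cases` (12 `surgesture_case`), `ratings`, `outcomes`.
#' @export
worked_fixture <- function() {
  dir <- system.file("extdata", "worked_fixture", package = "surgesture")
  if (dir == "") stop("worked fixture data not installed", call. = FALSE)
  cases <- read_timeline_dir(file.path(dir, "timelines"))
  ratings <- read_ratings(file.path(dir, "ratings.csv"))
  outcomes <- utils::read.csv(file.path(dir, "outcomes.csv"),
                              colClasses = c(video_id = "character",
                                             surgeon_id = "character"))
  list(cases = cases, ratings = ratings, outcomes = outcomes)
}

#' Write a generated cohort to a directory
#'
#' Materializes a cohort as files: one timeline CSV per video under
#' `timelines/`, plus `ratings.csv` and `outcomes.csv`. Deterministic:
#' the same cohort writes byte-identical files.
#'
#' @param cohort Result of [generate_cohort()] (timelines included).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  tdir <- file.path(dir, "timelines")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  for (cs in cohort$cases)
    write_timeline(cs, file.path(tdir, paste0(cs$video_id, ".csv")))
  write_ratings(cohort$ratings, file.path(dir, "ratings.csv"))
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
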