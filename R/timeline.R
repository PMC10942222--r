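PHASES <- c("MHT", "DGB")
HANDS <- c("left", "right", "unattributed")

#' Construct a case timeline
#'
#' One annotated video: an ordered stream of gesture events over the two
#' critical phases of laparoscopic cholecystectomy (MHT, mobilizing the
#' hepatocystic triangle; DGB, dissecting the gallbladder from the liver
#' bed), plus surgeon and clinical metadata. Times are in seconds, relative
#' to the start of each phase, as half-open intervals `[start_s, end_s)`:
#' an event may start exactly when the previous one of the same hand ends,
#' and events of different hands may overlap (bimanual work).
#'
#' @param video_id,surgeon_id Identifier strings.
#' @param events `data.frame` with columns `phase` (`"MHT"`/`"DGB"`),
#'   `label` (gesture name from the taxonomy), `hand`
#'   (`"left"`/`"right"`/`"unattributed"`), `start_s`, `end_s`.
#' @param phase_durations Named numeric, seconds per phase; defaults to the
#'   largest `end_s` seen in each phase.
#' @param metadata List with optional `parkland_grade` (1-5), `cvs_score`
#'   (0-6), `intraop_events` (character vector of named events such as
#'   `"cholecystic_vascular_injury"`).
#' @param taxonomy Taxonomy used for label validation; default vocabulary
#'   if `NULL`.
#' @param validate Set `FALSE` to skip validation when the caller
#'   guarantees validity (e.g. the cohort generator).
#' @return A `surgesture_case` object. Events are re-sorted into the
#'   canonical deterministic order (phase, start time, hand, label), so
#'   permuting input rows never changes the resulting object.
#' @export
case_timeline <- function(video_id, surgeon_id, events,
                          phase_durations = NULL,
                          metadata = list(), taxonomy = NULL,
                          validate = TRUE) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events) == 0L) {
    events <- data.frame(phase = character(), label = character(),
                         hand = character(), start_s = numeric(),
                         end_s = numeric(), stringsAsFactors = FALSE)
  }
  events <- events[, c("phase", "label", "hand", "start_s", "end_s")]
  events$start_s <- as.numeric(events$start_s)
  events$end_s <- as.numeric(events$end_s)
  if (is.null(phase_durations)) {
    phase_durations <- vapply(PHASES, function(p) {
      e <- events$end_s[events$phase == p]
      if (length(e) == 0L) 0 else max(e)
    }, numeric(1))
  }
  phase_durations <- phase_durations[order(match(names(phase_durations),
                                                 PHASES))]
  events <- sort_events(events)
  case <- structure(
    list(video_id = as.character(video_id),
         surgeon_id = as.character(surgeon_id),
         events = events,
         phase_durations = phase_durations,
         metadata = normalize_metadata(metadata)),
    class = "surgesture_case")
  if (validate) validate_case(case, taxonomy %||% default_taxonomy())
  case
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_metadata <- function(m) {
  list(parkland_grade = if (is.null(m$parkland_grade)) NA_integer_
                        else as.integer(m$parkland_grade),
       cvs_score = if (is.null(m$cvs_score)) NA_integer_
                   else as.integer(m$cvs_score),
       intraop_events = sort(unique(as.character(
         m$intraop_events %||% character()))))
}

# total deterministic order: phase (MHT before DGB), start, hand, label
sort_events <- function(events) {
  o <- order(match(events$phase, PHASES), events$start_s,
             match(events$hand, HANDS), events$label)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Validate a case timeline
#'
#' Checks label membership in the taxonomy, hand attribution rules,
#' positive durations, same-hand non-overlap (half-open intervals), event
#' containment within the phase duration, and positive manipulation time.
#' Errors list the offending event rows (in canonical sort order).
#'
#' @param case A `surgesture_case`.
#' @param taxonomy A `surgesture_taxonomy`.
#' @return The case, invisibly, if valid; otherwise an error.
#' @export
validate_case <- function(case, taxonomy = default_taxonomy()) {
  ev <- case$events
  problems <- character()
  row_ids <- function(idx) paste(idx, collapse = ", ")

  bad <- which(!ev$phase %in% PHASES)
  if (length(bad)) problems <- c(problems,
    sprintf("unknown phase at row(s) %s", row_ids(bad)))
  bad <- which(!ev$label %in% taxonomy$name)
  if (length(bad)) problems <- c(problems,
    sprintf("unknown gesture label at row(s) %s (%s)", row_ids(bad),
            paste(unique(ev$label[bad]), collapse = ", ")))
  bad <- which(!ev$hand %in% HANDS)
  if (length(bad)) problems <- c(problems,
    sprintf("invalid hand at row(s) %s", row_ids(bad)))

  known <- ev$label %in% taxonomy$name
  per_hand <- rep(FALSE, nrow(ev))
  per_hand[known] <- taxonomy$per_hand[match(ev$label[known], taxonomy$name)]
  bad <- which(per_hand & !ev$hand %in% c("left", "right"))
  if (length(bad)) problems <- c(problems,
    sprintf("per-hand gesture without hand attribution at row(s) %s",
            row_ids(bad)))

  bad <- which(!(ev$end_s > ev$start_s & ev$start_s >= 0))
  if (length(bad)) problems <- c(problems,
    sprintf("non-positive duration or negative start at row(s) %s",
            row_ids(bad)))

  # same-hand overlap, half-open semantics, within phase
  for (p in unique(ev$phase)) {
    for (h in c("left", "right")) {
      idx <- which(ev$phase == p & ev$hand == h)
      if (length(idx) > 1L) {
        s <- ev$start_s[idx]; e <- ev$end_s[idx]
        o <- order(s, e)
        ov <- which(s[o][-1L] < e[o][-length(o)])
        if (length(ov)) problems <- c(problems,
          sprintf("same-hand (%s) overlapping events in phase %s at row(s) %s",
                  h, p, row_ids(idx[o][ov + 1L])))
      }
    }
  }

  pd <- case$phase_durations
  in_phase <- ev$phase %in% names(pd)
  bad <- which(in_phase & ev$end_s > pd[ev$phase] + 1e-9)
  if (length(bad)) problems <- c(problems,
    sprintf("event extends beyond phase duration at row(s) %s", row_ids(bad)))

  if (!all(PHASES %in% names(pd)) || sum(pd[PHASES]) <= 0)
    problems <- c(problems,
      "manipulation time (sum of MHT and DGB durations) must be positive")

  if (length(problems))
    stop("invalid timeline '", case$video_id, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  invisible(case)
}

#' Manipulation time of a case, in minutes
#' @param case A `surgesture_case`.
#' @export
manipulation_time_min <- function(case) {
  sum(case$phase_durations[PHASES], na.rm = TRUE) / 60
}

#' @export
print.surgesture_case <- function(x, ...) {
  cat(sprintf("<surgesture_case> video %s, surgeon %s: %d events, %.1f min\n",
              x$video_id, x$surgeon_id, nrow(x$events),
              manipulation_time_min(x)))
  invisible(x)
}

fmt_num <- function(x) {
  # shortest decimal string that parses back to the same double, so writes
  # are byte-stable and read-write round trips are exact
  vapply(x, function(v) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

#' Read a case timeline from disk
#'
#' Two on-disk dialects are supported, chosen by file extension. CSV: header
#' `video_id,surgeon_id,phase,label,hand,start_s,end_s`, one event per row,
#' with optional leading `#`-comment lines carrying phase durations and
#' metadata (`# phase_duration <phase> <seconds>`, `# parkland_grade <n>`,
#' `# cvs_score <n>`, `# intraop_events a,b`). JSON: one object per case
#' with `events` array and `metadata` object. Files written by
#' [write_timeline()] round-trip to an identical structure.
#'
#' @param path File path (`.csv` or `.json`).
#' @param taxonomy Taxonomy for validation.
#' @return A validated `surgesture_case`.
#' @export
read_timeline <- function(path, taxonomy = default_taxonomy()) {
  if (!file.exists(path)) stop("timeline file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    read_timeline_json(path, taxonomy)
  } else {
    read_timeline_csv(path, taxonomy)
  }
}

read_timeline_csv <- function(path, taxonomy) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L || !startsWith(body[1L],
      "video_id,surgeon_id,phase,label,hand,start_s,end_s"))
    stop("timeline CSV '", path, "' lacks the expected header", call. = FALSE)
  ev <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = c(video_id = "character",
                                       surgeon_id = "character",
                                       phase = "character",
                                       label = "character",
                                       hand = "character",
                                       start_s = "numeric",
                                       end_s = "numeric"))
  pd <- NULL
  meta <- list()
  for (ml in meta_lines) {
    tok <- strsplit(sub("^#\\s*", "", ml), "\\s+")[[1L]]
    if (length(tok) < 2L) next
    key <- tok[1L]
    if (key == "phase_duration" && length(tok) >= 3L) {
      pd <- c(pd, stats::setNames(as.numeric(tok[3L]), tok[2L]))
    } else if (key == "parkland_grade") {
      meta$parkland_grade <- as.integer(tok[2L])
    } else if (key == "cvs_score") {
      meta$cvs_score <- as.integer(tok[2L])
    } else if (key == "intraop_events") {
      meta$intraop_events <- strsplit(tok[2L], ",")[[1L]]
    }
  }
  ids <- unique(ev[, c("video_id", "surgeon_id")])
  if (nrow(ids) > 1L)
    stop("timeline CSV '", path, "' mixes multiple video/surgeon ids",
         call. = FALSE)
  vid <- if (nrow(ids) == 1L) ids$video_id else
    sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  sid <- if (nrow(ids) == 1L) ids$surgeon_id else NA_character_
  case_timeline(vid, sid, ev[, c("phase", "label", "hand", "start_s",
                                 "end_s")],
                phase_durations = pd, metadata = meta, taxonomy = taxonomy)
}

read_timeline_json <- function(path, taxonomy) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- obj$events
  if (is.null(ev) || length(ev) == 0L) {
    ev <- data.frame(phase = character(), label = character(),
                     hand = character(), start_s = numeric(),
                     end_s = numeric())
  }
  pd <- unlist(obj$phase_durations)
  case_timeline(obj$video_id, obj$surgeon_id, ev, phase_durations = pd,
                metadata = as.list(obj$metadata), taxonomy = taxonomy)
}

#' Write a case timeline to disk
#'
#' Inverse of [read_timeline()]; dispatches on extension. Field order and
#' number formatting are fixed, so writing the same case twice produces
#' byte-identical files.
#'
#' @param case A valid `surgesture_case`.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_timeline <- function(case, path) {
  stopifnot(inherits(case, "surgesture_case"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    write_timeline_json(case, path)
  } else {
    write_timeline_csv(case, path)
  }
  invisible(path)
}

write_timeline_csv <- function(case, path) {
  ev <- case$events
  lines <- c(
    sprintf("# phase_duration %s %s", names(case$phase_durations),
            fmt_num(unname(case$phase_durations))),
    if (!is.na(case$metadata$parkland_grade))
      sprintf("# parkland_grade %d", case$metadata$parkland_grade),
    if (!is.na(case$metadata$cvs_score))
      sprintf("# cvs_score %d", case$metadata$cvs_score),
    if (length(case$metadata$intraop_events))
      sprintf("# intraop_events %s",
              paste(case$metadata$intraop_events, collapse = ",")),
    "video_id,surgeon_id,phase,label,hand,start_s,end_s",
    if (nrow(ev) > 0L)
      sprintf("%s,%s,%s,%s,%s,%s,%s", case$video_id, case$surgeon_id,
              ev$phase, ev$label, ev$hand, fmt_num(ev$start_s),
              fmt_num(ev$end_s))
  )
  writeLines(lines, path)
}

write_timeline_json <- function(case, path) {
  obj <- list(
    video_id = case$video_id,
    surgeon_id = case$surgeon_id,
    phase_durations = as.list(case$phase_durations),
    metadata = case$metadata,
    events = case$events
  )
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
}

#' Read every timeline file in a directory
#'
#' @param dir Directory containing `.csv`/`.json` timeline files (one case
#'   per file).
#' @param taxonomy Taxonomy for validation.
#' @return List of `surgesture_case`, ordered by file name.
#' @export
read_timeline_dir <- function(dir, taxonomy = default_taxonomy()) {
  files <- sort(list.files(dir, pattern = "\\.(csv|json)$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no timeline files (*.csv, *.json) in ", dir, call. = FALSE)
  lapply(files, read_timeline, taxonomy = taxonomy)
}
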