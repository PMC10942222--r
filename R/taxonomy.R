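#' Surgesture taxonomy
#'
#' A taxonomy describes the gesture vocabulary used to annotate laparoscopic
#' cholecystectomy videos: each elementary functional gesture ("Surgesture")
#' has a functional class (`dissection` or `exposure`), an efficiency flag
#' (`effective` or `inefficient`), and a `per_hand` flag saying whether the
#' left and right hand are tracked as separate feature categories.
#'
#' The default vocabulary has 14 gestures of which 6 are per-hand, giving
#' 2 x 6 + 8 = 20 tracked categories. Only six gesture names (hook,
#' inefficient hook, grasp, inefficient grasp, push, blunt dissection) are
#' fixed by the published figures; the remaining names are documented
#' placeholders and can be overridden with a YAML/JSON config via
#' [load_taxonomy()].
#'
#' @return A `surgesture_taxonomy` object: a data.frame with columns
#'   `name`, `functional_class`, `efficiency`, `per_hand`.
#' @examples
#' tax <- default_taxonomy()
#' nrow(tax)                  # 14 gestures
#' length(taxonomy_categories(tax))  # 20 tracked categories
#' @export
default_taxonomy <- function() {
  per_hand <- c("grasp", "inefficient_grasp", "push", "pull", "spread",
                "retract")
  single <- c("hook", "inefficient_hook", "blunt_dissection", "cut", "clip",
              "coagulate", "suction", "irrigate")
  dissection <- c("hook", "inefficient_hook", "blunt_dissection", "cut",
                  "clip", "coagulate", "spread")
  inefficient <- c("inefficient_hook", "inefficient_grasp")
  g <- data.frame(
    name = c(per_hand, single),
    functional_class = ifelse(c(per_hand, single) %in% dissection,
                              "dissection", "exposure"),
    efficiency = ifelse(c(per_hand, single) %in% inefficient,
                        "inefficient", "effective"),
    per_hand = c(per_hand, single) %in% per_hand,
    stringsAsFactors = FALSE
  )
  new_taxonomy(g)
}

new_taxonomy <- function(gestures) {
  validate_taxonomy(gestures)
  # canonical row order: per-hand gestures first, then single, alphabetical
  # within block, so derived feature names are deterministic
  gestures <- gestures[order(!gestures$per_hand, gestures$name), ,
                       drop = FALSE]
  rownames(gestures) <- NULL
  structure(gestures, class = c("surgesture_taxonomy", "data.frame"))
}

validate_taxonomy <- function(g) {
  required <- c("name", "functional_class", "efficiency", "per_hand")
  missing <- setdiff(required, names(g))
  if (length(missing) > 0L)
    stop("taxonomy config is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(g) == 0L)
    stop("taxonomy config defines no gestures", call. = FALSE)
  if (anyDuplicated(g$name))
    stop("taxonomy config has duplicated gesture name(s): ",
         paste(unique(g$name[duplicated(g$name)]), collapse = ", "),
         call. = FALSE)
  bad_class <- setdiff(unique(g$functional_class), c("dissection", "exposure"))
  if (length(bad_class) > 0L)
    stop("taxonomy field 'functional_class' must be 'dissection' or ",
         "'exposure'; got: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  bad_eff <- setdiff(unique(g$efficiency), c("effective", "inefficient"))
  if (length(bad_eff) > 0L)
    stop("taxonomy field 'efficiency' must be 'effective' or 'inefficient'; ",
         "got: ", paste(bad_eff, collapse = ", "), call. = FALSE)
  if (!is.logical(g$per_hand) || anyNA(g$per_hand))
    stop("taxonomy field 'per_hand' must be TRUE/FALSE", call. = FALSE)
  invisible(g)
}

#' Load a taxonomy from a YAML or JSON config file
#'
#' The config holds a `gestures:` list of records with fields `name`,
#' `functional_class` (`dissection`/`exposure`), `efficiency`
#' (`effective`/`inefficient`) and `per_hand` (logical). With `path = NULL`
#' the built-in default 14-gesture vocabulary is returned.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config, or `NULL`.
#' @return A validated `surgesture_taxonomy`.
#' @export
load_taxonomy <- function(path = NULL) {
  if (is.null(path)) return(default_taxonomy())
  if (!file.exists(path))
    stop("taxonomy config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$gestures))
    stop("taxonomy config is missing field(s): gestures", call. = FALSE)
  g <- cfg$gestures
  if (!is.data.frame(g)) {
    g <- tryCatch(
      do.call(rbind, lapply(g, function(r) as.data.frame(r,
        stringsAsFactors = FALSE))),
      error = function(e) stop("malformed 'gestures' list in taxonomy ",
                               "config: ", conditionMessage(e),
                               call. = FALSE))
  }
  if (!is.null(g$per_hand)) g$per_hand <- as.logical(g$per_hand)
  new_taxonomy(g)
}

#' Tracked feature categories of a taxonomy
#'
#' Per-hand gestures contribute one category per hand (`<name>.L`,
#' `<name>.R`); single-stream gestures contribute one category. The default
#' taxonomy yields 20 categories, the basis of the 20 count and 20 duration
#' features.
#'
#' @param tax A `surgesture_taxonomy`.
#' @return Character vector of category names, deterministic given the
#'   taxonomy.
#' @export
taxonomy_categories <- function(tax) {
  stopifnot(inherits(tax, "surgesture_taxonomy"))
  unlist(lapply(seq_len(nrow(tax)), function(i) {
    if (tax$per_hand[i]) paste0(tax$name[i], c(".L", ".R")) else tax$name[i]
  }), use.names = FALSE)
}

#' Map an event to its tracked category
#' @noRd
event_category <- function(label, hand, tax) {
  per_hand <- tax$per_hand[match(label, tax$name)]
  ifelse(per_hand,
         paste0(label, ".", ifelse(hand == "left", "L", "R")),
         label)
}

#' Functional class lookup
#' @noRd
gesture_class <- function(label, tax) {
  tax$functional_class[match(label, tax$name)]
}
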