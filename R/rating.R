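MGOALS_ITEMS <- c("depth_perception", "bimanual_dexterity", "efficiency",
                  "tissue_handling")
MGOALS_CSV_CODES <- c(depth_perception = "dp", bimanual_dexterity = "bd",
                      efficiency = "eff", tissue_handling = "th")

#' Validate a table of mGOALS ratings
#'
#' Modified GOALS: four items (depth perception, bimanual dexterity,
#' efficiency, tissue handling), each an integer 1-5; the autonomy item of
#' full GOALS is excluded. One row per (video, rater).
#'
#' @param ratings `data.frame` with columns `video_id`, `rater_id` and the
#'   four item columns.
#' @return The validated ratings, invisibly.
#' @export
validate_ratings <- function(ratings) {
  need <- c("video_id", "rater_id", MGOALS_ITEMS)
  missing <- setdiff(need, names(ratings))
  if (length(missing))
    stop("ratings table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (it in MGOALS_ITEMS) {
    v <- ratings[[it]]
    bad <- which(is.na(v) | v < 1 | v > 5 | v != round(v))
    if (length(bad))
      stop("mGOALS item '", it, "' out of range 1-5 at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ratings[, c("video_id", "rater_id")]))
    stop("duplicated (video_id, rater_id) rating rows", call. = FALSE)
  invisible(ratings)
}

#' Per-video mGOALS case scores
#'
#' The case score of a video is the mean across raters of the per-rater
#' item sums (range 4-20). Per-item means across raters are retained for
#' item-level classification targets.
#'
#' @inheritParams validate_ratings
#' @return `data.frame` with one row per video: `video_id`, `n_raters`,
#'   `score`, and the four per-item mean columns.
#' @export
case_scores <- function(ratings) {
  validate_ratings(ratings)
  totals <- rowSums(ratings[, MGOALS_ITEMS])
  agg <- stats::aggregate(cbind(ratings[, MGOALS_ITEMS], score = totals),
                          by = list(video_id = ratings$video_id), FUN = mean)
  n <- stats::aggregate(list(n_raters = ratings$rater_id),
                        by = list(video_id = ratings$video_id), FUN = length)
  out <- merge(n, agg, by = "video_id", sort = TRUE)
  out[, c("video_id", "n_raters", "score", MGOALS_ITEMS)]
}

#' Intraclass correlation coefficient, two-way random, absolute agreement
#'
#' Single-measure ICC(2,1) from the two-way ANOVA mean squares of a
#' complete raters x videos score matrix; the convention used to qualify
#' rater consistency (qualified when ICC exceeds 0.75).
#'
#' @param scores Numeric matrix, raters in rows, videos in columns,
#'   complete (no missing cells), at least 2 raters and 2 videos.
#' @param threshold Qualification threshold, default 0.75.
#' @return List with `icc`, `qualified`, and the mean squares
#'   (`msr` subjects, `msc` raters, `mse` residual). A constant matrix has
#'   undefined ICC and returns `icc = NA` with `degenerate = TRUE`.
#' @export
icc_absolute_agreement <- function(scores, threshold = 0.75) {
  scores <- as.matrix(scores)
  k <- nrow(scores)  # raters
  n <- ncol(scores)  # videos (subjects)
  if (k < 2L || n < 2L)
    stop("ICC needs at least 2 raters and 2 videos", call. = FALSE)
  if (anyNA(scores)) stop("ICC needs a complete score matrix", call. = FALSE)
  grand <- mean(scores)
  subj_means <- colMeans(scores)
  rater_means <- rowMeans(scores)
  ss_total <- sum((scores - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_err <- ss_total - ss_subj - ss_rater
  msr <- ss_subj / (n - 1)
  msc <- ss_rater / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total < 1e-12) {
    warning("constant score matrix: ICC undefined", call. = FALSE)
    return(list(icc = NA_real_, qualified = NA, degenerate = TRUE,
                msr = msr, msc = msc, mse = mse))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, qualified = icc > threshold, degenerate = FALSE,
       msr = msr, msc = msc, mse = mse)
}

#' Kendall's coefficient of concordance W
#'
#' Agreement of m raters ranking n videos, with midrank ties and the
#' standard tie correction. W = 1 under identical rankings; W = 0 when
#' rank sums are all equal (e.g. two exactly reversed rankings).
#'
#' @param scores Numeric matrix, raters in rows, videos in columns. Raw
#'   scores are converted to within-rater midranks.
#' @return W in \[0, 1\].
#' @export
kendalls_w <- function(scores) {
  scores <- as.matrix(scores)
  m <- nrow(scores)
  n <- ncol(scores)
  if (m < 2L) stop("Kendall's W needs at least 2 raters", call. = FALSE)
  if (n < 2L) stop("Kendall's W needs at least 2 videos", call. = FALSE)
  ranks <- t(apply(scores, 1L, rank))  # midranks
  rank_sums <- colSums(ranks)
  s <- sum((rank_sums - m * (n + 1) / 2)^2)
  ties <- sum(apply(ranks, 1L, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * ties
  if (denom <= 0) {
    warning("all raters assign fully tied ranks: W undefined, returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  12 * s / denom
}

#' Quantile-based skill grouping
#'
#' Surgeons are stratified by mGOALS score into bottom (below the lower
#' quantile cut), top (above the upper cut) and medium (between, inclusive
#' of the cuts), then binarized: competent = top or medium, incompetent =
#' bottom. Cuts use the linear-interpolation empirical quantile
#' (`stats::quantile`, type 7).
#'
#' @param scores Named numeric vector of per-surgeon scores (use the mean
#'   of a surgeon's case scores when a surgeon has several videos).
#' @param q_low,q_high Quantile probabilities for the cuts (defaults 0.25,
#'   0.75).
#' @return A `skill_grouping` object: list with `q1_cut`, `q3_cut`, and a
#'   `groups` data.frame (`surgeon_id`, `score`, `group`, `binary`).
#' @export
quantile_grouping <- function(scores, q_low = 0.25, q_high = 0.75) {
  if (length(scores) < 4L)
    stop("quantile grouping needs at least 4 surgeons", call. = FALSE)
  if (is.null(names(scores)))
    names(scores) <- as.character(seq_along(scores))
  cuts <- stats::quantile(scores, c(q_low, q_high), names = FALSE, type = 7)
  if (diff(range(scores)) < 1e-12)
    warning("all scores identical: single-group (medium) degenerate output",
            call. = FALSE)
  group <- ifelse(scores < cuts[1L], "bottom",
                  ifelse(scores > cuts[2L], "top", "medium"))
  structure(
    list(q1_cut = cuts[1L], q3_cut = cuts[2L],
         groups = data.frame(
           surgeon_id = names(scores), score = unname(scores),
           group = unname(group),
           binary = ifelse(unname(group) == "bottom", "incompetent",
                           "competent"),
           stringsAsFactors = FALSE)),
    class = "skill_grouping")
}

#' @export
print.skill_grouping <- function(x, ...) {
  tab <- table(x$groups$group)
  cat(sprintf("<skill_grouping> cuts %.3g / %.3g; %s\n", x$q1_cut, x$q3_cut,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Propagate surgeon-level skill labels to videos
#'
#' @param grouping A `skill_grouping` (per surgeon).
#' @param video_surgeon `data.frame` with `video_id`, `surgeon_id`.
#' @return `data.frame` `video_id`, `surgeon_id`, `group`, `binary`.
#' @export
video_labels <- function(grouping, video_surgeon) {
  m <- merge(video_surgeon, grouping$groups[, c("surgeon_id", "group",
                                                "binary")],
             by = "surgeon_id", sort = FALSE)
  if (nrow(m) != nrow(video_surgeon))
    stop("some videos reference surgeons absent from the grouping",
         call. = FALSE)
  m <- m[order(m$video_id), c("video_id", "surgeon_id", "group", "binary")]
  rownames(m) <- NULL
  m
}

#' Binary item-level competence labels
#'
#' Classification targets for the four individual mGOALS skill items:
#' videos whose per-item mean score falls below the item's `q`-quantile are
#' labeled incompetent on that item. Labels are invariant to monotone
#' rescaling of the scores.
#'
#' @param item_scores Named numeric vector, one per-item score per video.
#' @param q Quantile cut, default 0.25.
#' @return Named logical vector: `TRUE` = incompetent on the item.
#' @export
item_binarize <- function(item_scores, q = 0.25) {
  if (length(item_scores) < 4L)
    stop("item binarization needs at least 4 videos", call. = FALSE)
  cut <- stats::quantile(item_scores, q, names = FALSE, type = 7)
  lab <- item_scores < cut
  if (!any(lab))
    warning("no video falls below the item quantile cut: degenerate ",
            "(all-negative) item target", call. = FALSE)
  lab
}

#' Read / write mGOALS ratings CSV
#'
#' Dialect: header `video_id,rater_id,dp,bd,eff,th` with the four item
#' codes dp = depth perception, bd = bimanual dexterity, eff = efficiency,
#' th = tissue handling.
#'
#' @param path CSV path.
#' @return `read_ratings`: validated ratings `data.frame` with full item
#'   column names.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, colClasses = c(video_id = "character",
                                             rater_id = "character"))
  need <- c("video_id", "rater_id", unname(MGOALS_CSV_CODES))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("ratings CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  names(df)[match(MGOALS_CSV_CODES, names(df))] <- names(MGOALS_CSV_CODES)
  validate_ratings(df)
  df
}

#' @rdname read_ratings
#' @param ratings Ratings table with full item column names.
#' @export
write_ratings <- function(ratings, path) {
  validate_ratings(ratings)
  out <- ratings[, c("video_id", "rater_id", MGOALS_ITEMS)]
  names(out)[match(names(MGOALS_CSV_CODES), names(out))] <-
    unname(MGOALS_CSV_CODES)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
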