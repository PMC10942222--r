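# Independent brute-force oracles, deliberately written as plain loops over
# the definitions, separate from the package implementation paths.

# pairwise Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Pearson chi-square by the O-E loop
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in 1:nrow(tab)) for (j in 1:ncol(tab)) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

# ICC(2,1) by explicit two-way ANOVA decomposition (raters x videos)
oracle_icc <- function(m) {
  k <- nrow(m); n <- ncol(m)
  grand <- mean(m)
  ss_subj <- 0
  for (j in 1:n) ss_subj <- ss_subj + k * (mean(m[, j]) - grand)^2
  ss_rater <- 0
  for (i in 1:k) ss_rater <- ss_rater + n * (mean(m[i, ]) - grand)^2
  ss_tot <- 0
  for (i in 1:k) for (j in 1:n) ss_tot <- ss_tot + (m[i, j] - grand)^2
  msr <- ss_subj / (n - 1)
  msc <- ss_rater / (k - 1)
  mse <- (ss_tot - ss_subj - ss_rater) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Spearman rho via the rank formula (sum over squared rank differences on
# tie-free data; covariance of midranks otherwise)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (!anyDuplicated(rx) && !anyDuplicated(ry)) {
    n <- length(x)
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else {
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
}

# feature vector recomputed from first principles, event by event
oracle_features <- function(case, tax = default_taxonomy()) {
  ev <- case$events
  cats <- character()
  for (i in seq_len(nrow(tax))) {
    if (tax$per_hand[i]) cats <- c(cats, paste0(tax$name[i], ".L"),
                                   paste0(tax$name[i], ".R"))
    else cats <- c(cats, tax$name[i])
  }
  counts <- setNames(rep(0, length(cats)), cats)
  durs <- setNames(rep(0, length(cats)), cats)
  for (r in seq_len(nrow(ev))) {
    lab <- ev$label[r]
    ph <- tax$per_hand[tax$name == lab]
    cat_r <- if (ph) paste0(lab, ifelse(ev$hand[r] == "left", ".L", ".R"))
             else lab
    counts[cat_r] <- counts[cat_r] + 1
    durs[cat_r] <- durs[cat_r] + (ev$end_s[r] - ev$start_s[r])
  }
  intervals <- numeric(); shifts <- numeric()
  for (stream in c("all", "left", "right")) {
    sub <- switch(stream, all = ev,
                  left = ev[ev$hand == "left", , drop = FALSE],
                  right = ev[ev$hand == "right", , drop = FALSE])
    gaps <- numeric(); n_shift <- 0
    for (p in c("MHT", "DGB")) {
      e <- sub[sub$phase == p, , drop = FALSE]
      if (nrow(e) < 2) next
      e <- e[order(e$start_s, e$end_s), , drop = FALSE]
      for (i in 2:nrow(e)) {
        gaps <- c(gaps, max(e$start_s[i] - e$end_s[i - 1], 0))
        if (e$label[i] != e$label[i - 1]) n_shift <- n_shift + 1
      }
    }
    if (length(gaps) == 0) st <- c(0, 0, 0, 0)
    else {
      m <- sum(gaps) / length(gaps)
      sdv <- if (length(gaps) > 1)
        sqrt(sum((gaps - m)^2) / (length(gaps) - 1)) else 0
      st <- c(m, max(gaps), min(gaps), sdv)
    }
    intervals <- c(intervals, st)
    shifts <- c(shifts, n_shift)
  }
  manip_min <- sum(case$phase_durations[c("MHT", "DGB")]) / 60
  cls <- sapply(ev$label, function(l) tax$functional_class[tax$name == l])
  d_idx <- which(cls == "dissection"); e_idx <- which(cls == "exposure")
  count_D <- length(d_idx); count_E <- length(e_idx)
  dur_D <- sum(ev$end_s[d_idx] - ev$start_s[d_idx])
  dur_E <- sum(ev$end_s[e_idx] - ev$start_s[e_idx])
  de_sh <- 0
  for (p in c("MHT", "DGB")) {
    e <- ev[ev$phase == p, , drop = FALSE]
    if (nrow(e) < 2) next
    e <- e[order(e$start_s, e$end_s), , drop = FALSE]
    ec <- sapply(e$label, function(l) tax$functional_class[tax$name == l])
    for (i in 2:nrow(e)) if (ec[i] != ec[i - 1]) de_sh <- de_sh + 1
  }
  out <- c(counts, durs, intervals, shifts / manip_min,
           count_D, count_E, dur_D, dur_E,
           count_D / max(count_E, 1), dur_D / max(dur_E, 1),
           de_sh / manip_min, manip_min)
  names(out) <- c(paste0("count.", cats), paste0("dur.", cats),
                  paste0("int.", rep(c("all", "left", "right"), each = 4),
                         ".", c("mean", "max", "min", "sd")),
                  paste0("shift.", c("all", "left", "right")),
                  paste0("de.", c("count_D", "count_E", "dur_D", "dur_E",
                                  "count_ratio", "dur_ratio", "shift")),
                  "manip_time")
  out
}

# random valid timeline: sequential per-hand placement guarantees the
# same-hand non-overlap invariant
random_case <- function(seed, n_events = NULL, taxonomy = default_taxonomy()) {
  set.seed(seed)
  if (is.null(n_events)) n_events <- sample(4:30, 1)
  rows <- list()
  t_hand <- list()  # running clock per (phase, hand)
  for (i in seq_len(n_events)) {
    gi <- sample(nrow(taxonomy), 1)
    lab <- taxonomy$name[gi]
    hand <- if (taxonomy$per_hand[gi]) sample(c("left", "right"), 1)
            else sample(c("unattributed", "unattributed", "left"), 1)
    phase <- sample(c("MHT", "DGB"), 1)
    key <- paste(phase, hand)
    t0 <- if (is.null(t_hand[[key]])) 0 else t_hand[[key]]
    start <- t0 + round(runif(1, 0, 8), 2)
    end <- start + round(runif(1, 0.5, 12), 2)
    t_hand[[key]] <- end
    rows[[i]] <- data.frame(phase = phase, label = lab, hand = hand,
                            start_s = start, end_s = end,
                            stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  pd <- sapply(c("MHT", "DGB"), function(p) {
    e <- ev$end_s[ev$phase == p]
    (if (length(e)) max(e) else 0) + round(runif(1, 1, 20), 2)
  })
  case_timeline(sprintf("rnd%04d", seed), sprintf("S%02d", seed %% 7 + 1),
                ev, phase_durations = pd,
                metadata = list(parkland_grade = 1, cvs_score = 2),
                taxonomy = taxonomy)
}

# small helper used across files: a minimal single-stream timeline from
# (start, end) pairs of unattributed hook events
hook_case <- function(intervals, phase_s = NULL, labels = NULL,
                      phase = "MHT") {
  n <- nrow(intervals)
  ev <- data.frame(phase = phase,
                   label = if (is.null(labels)) rep("hook", n) else labels,
                   hand = "unattributed",
                   start_s = intervals[, 1], end_s = intervals[, 2],
                   stringsAsFactors = FALSE)
  pd <- c(MHT = 0, DGB = 0)
  pd[phase] <- if (is.null(phase_s)) max(intervals[, 2]) else phase_s
  other <- setdiff(c("MHT", "DGB"), phase)
  pd[other] <- 0
  case_timeline("t1", "s1", ev, phase_durations = pd)
}
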