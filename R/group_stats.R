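#' Pearson chi-square test of independence on a 2x2 table
#'
#' The uncorrected Pearson statistic sum((O-E)^2/E) with 1 degree of
#' freedom (no Yates continuity correction), the convention that reproduces
#' the published contingency analyses of intraoperative events by skill
#' group. A warning is attached when any expected count is below 5.
#'
#' @param table 2x2 matrix of non-negative integer counts; rows = skill
#'   group, columns = outcome yes/no.
#' @return List with `statistic`, `dof` (1), `p_value`, `expected`, and
#'   `low_expected` (TRUE when some expected cell < 5).
#' @examples
#' pearson_chi2(matrix(c(46, 3, 18, 8), 2, 2, byrow = TRUE))$statistic
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("pearson_chi2 expects a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("table cells must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero row or column marginal", call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  low <- any(expected < 5)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (low)
    warning("some expected counts are below 5; the chi-square ",
            "approximation may be inaccurate", call. = FALSE)
  list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
       p_value = ht$p.value, expected = expected, low_expected = low)
}

#' Per-feature two-group comparisons
#'
#' For every feature column: a two-sided rank test (Kruskal-Wallis, which
#' for two groups is the tie-corrected Mann-Whitney test) and a Welch
#' t-test, with the effect direction (difference of group means). Constant
#' features are skipped with a note. No multiple-testing adjustment is
#' applied by default; set `adjust = "BH"` for Benjamini-Hochberg adjusted
#' columns.
#'
#' @param features Numeric matrix or data.frame of feature columns (rows =
#'   videos).
#' @param labels Binary group labels, length `nrow(features)` (factor,
#'   character or logical; exactly 2 levels present).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame`: `feature`, `mean_group1`, `mean_group2`,
#'   `direction`, `kw_stat`, `kw_p`, `t_stat`, `t_p`, `skipped` (plus
#'   `kw_p_adj`, `t_p_adj` when adjusted).
#' @export
group_feature_tests <- function(features, labels, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  features <- as.data.frame(features)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must contain exactly 2 groups, both non-empty",
         call. = FALSE)
  labels <- droplevels(labels)
  g1 <- levels(labels)[1L]; g2 <- levels(labels)[2L]
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    m1 <- mean(x[labels == g1]); m2 <- mean(x[labels == g2])
    if (stats::var(x) < 1e-24) {
      return(data.frame(feature = f, mean_group1 = m1, mean_group2 = m2,
                        direction = 0, kw_stat = NA_real_, kw_p = NA_real_,
                        t_stat = NA_real_, t_p = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    kw <- stats::kruskal.test(x, labels)
    tt <- stats::t.test(x ~ labels)
    data.frame(feature = f, mean_group1 = m1, mean_group2 = m2,
               direction = sign(m1 - m2),
               kw_stat = unname(kw$statistic), kw_p = kw$p.value,
               t_stat = unname(tt$statistic), t_p = tt$p.value,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- c(g1, g2)
  if (adjust == "BH") {
    out$kw_p_adj <- stats::p.adjust(out$kw_p, method = "BH")
    out$t_p_adj <- stats::p.adjust(out$t_p, method = "BH")
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties, used to relate gesture features to
#' mGOALS scores.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\]; `NA` with a warning when either vector is
#'   constant.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("spearman_cor needs at least 3 observations",
                           call. = FALSE)
  if (stats::var(x) < 1e-24 || stats::var(y) < 1e-24) {
    warning("constant input vector: Spearman correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}
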