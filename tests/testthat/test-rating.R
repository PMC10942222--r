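mk_ratings <- function(video, scores_by_rater) {
  do.call(rbind, lapply(seq_along(scores_by_rater), function(i) {
    s <- scores_by_rater[[i]]
    data.frame(video_id = video, rater_id = paste0("R", i),
               depth_perception = s[1], bimanual_dexterity = s[2],
               efficiency = s[3], tissue_handling = s[4])
  }))
}

test_that("case scores are rater means of item sums", {
  r <- mk_ratings("v1", list(c(5, 5, 5, 5), c(4, 4, 4, 4)))
  cs <- case_scores(r)
  expect_equal(cs$score, 18)
  expect_equal(cs$n_raters, 2L)

  expect_equal(case_scores(mk_ratings("v1", list(c(3, 4, 4, 4))))$score, 15)

  r3 <- mk_ratings("v1", list(c(1, 2, 3, 4), c(5, 5, 5, 5), c(2, 2, 2, 2)))
  expect_equal(case_scores(r3)$score, mean(c(10, 20, 8)))
  expect_equal(case_scores(r3)$depth_perception, mean(c(1, 5, 2)))

  bad <- mk_ratings("v1", list(c(0, 4, 4, 4)))
  expect_error(case_scores(bad), "out of range")
})

test_that("ICC(2,1) equals its ANOVA oracle and behaves at the extremes", {
  m <- matrix(c(3, 5, 2, 4,
                2, 5, 1, 3), nrow = 2, byrow = TRUE)
  res <- icc_absolute_agreement(m)
  expect_equal(res$icc, oracle_icc(m), tolerance = 1e-12)

  # identical non-constant columns -> perfect agreement
  same <- rbind(c(1, 3, 5, 2), c(1, 3, 5, 2))
  expect_equal(icc_absolute_agreement(same)$icc, 1)
  expect_true(icc_absolute_agreement(same)$qualified)

  # independent noise swamps agreement -> ICC near 0
  set.seed(42)
  base <- rnorm(10000)
  noisy <- rbind(base, rnorm(10000, sd = 20))
  expect_lt(abs(icc_absolute_agreement(noisy)$icc), 0.05)

  expect_warning(icc_absolute_agreement(matrix(3, 2, 5)), "constant")
  expect_error(icc_absolute_agreement(matrix(1:3, 1)), "at least 2")
})

test_that("ICC decreases monotonically with rater noise", {
  set.seed(7)
  truth <- rnorm(800, 15, 2.5)
  iccs <- sapply(c(0.2, 1, 3, 8), function(sd) {
    m <- rbind(truth + rnorm(800, sd = sd), truth + rnorm(800, sd = sd))
    icc_absolute_agreement(m)$icc
  })
  expect_true(all(diff(iccs) < 0))
  expect_gt(iccs[1], 0.95)
})

test_that("Kendall's W spans perfect agreement to reversal", {
  same <- rbind(c(1, 2, 3, 4, 5), c(10, 20, 30, 40, 50))
  expect_equal(kendalls_w(same), 1)
  rev2 <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(kendalls_w(rev2), 0)
  # under independent rankings W concentrates near 1/m
  set.seed(3)
  rnd2 <- matrix(rnorm(2 * 2000), nrow = 2)
  expect_lt(abs(kendalls_w(rnd2) - 0.5), 0.05)
  rnd10 <- matrix(rnorm(10 * 2000), nrow = 10)
  expect_lt(kendalls_w(rnd10), 0.15)
  expect_error(kendalls_w(matrix(1:3, 1)), "at least 2 raters")
})

test_that("quantile grouping matches the quantile oracle and is monotone", {
  s <- c(10, 12, 14, 16, 18, 20, 20, 20)
  names(s) <- paste0("S", 1:8)
  g <- quantile_grouping(s)
  q <- quantile(s, c(0.25, 0.75), type = 7)
  expect_equal(g$q1_cut, unname(q[1]))
  expect_equal(g$q3_cut, unname(q[2]))
  expect_equal(g$groups$group[g$groups$score < g$q1_cut],
               rep("bottom", sum(s < q[1])))
  expect_equal(g$groups$group[g$groups$score > g$q3_cut],
               rep("top", sum(s > q[2])))
  # boundary scores are medium
  expect_true(all(g$groups$group[g$groups$score == g$q1_cut] == "medium"))
  # binary partition is exhaustive
  expect_equal(sum(g$groups$binary == "competent") +
                 sum(g$groups$binary == "incompetent"), 8L)

  # monotone: raising one surgeon's score never lowers their group
  rank_of <- c(bottom = 1, medium = 2, top = 3)
  set.seed(9)
  for (i in 1:20) {
    sc <- setNames(runif(12, 4, 20), paste0("S", 1:12))
    g1 <- quantile_grouping(sc)
    j <- sample(12, 1)
    sc[j] <- sc[j] + runif(1, 0, 6)
    g2 <- quantile_grouping(sc)
    expect_gte(rank_of[[g2$groups$group[j]]] -
                 rank_of[[g1$groups$group[j]]] , 0)
  }
})

test_that("uniform scores split roughly 25/50/25", {
  set.seed(5)
  s <- setNames(runif(100), paste0("S", 1:100))
  g <- quantile_grouping(s)
  tab <- table(g$groups$group)
  expect_lt(abs(tab[["bottom"]] - 25), 5)
  expect_lt(abs(tab[["top"]] - 25), 5)
  expect_lt(abs(tab[["medium"]] - 50), 5)
})

test_that("item binarization flags the bottom quantile, scale-invariantly", {
  s <- setNames(as.numeric(1:8), paste0("v", 1:8))
  lab <- item_binarize(s, q = 0.25)
  expect_equal(unname(which(lab)), 1:2)
  expect_warning(item_binarize(setNames(rep(5, 6), paste0("v", 1:6))),
                 "degenerate")
  # invariant to monotone rescaling
  expect_equal(item_binarize(s^3), lab)
  expect_equal(item_binarize(10 + 2 * s), lab)
})

test_that("surgeon-level grouping propagates to videos", {
  s <- setNames(c(10, 14, 17, 20), paste0("S", 1:4))
  g <- quantile_grouping(s)
  vs <- data.frame(video_id = paste0("v", 1:6),
                   surgeon_id = c("S1", "S1", "S2", "S3", "S4", "S4"))
  vl <- video_labels(g, vs)
  expect_equal(nrow(vl), 6L)
  expect_equal(vl$binary[vl$surgeon_id == "S1"], rep("incompetent", 2))
  expect_error(video_labels(g, data.frame(video_id = "x",
                                          surgeon_id = "S9")),
               "absent")
})

test_that("ratings CSV round trips through the dialect", {
  r <- rbind(mk_ratings("v1", list(c(5, 4, 5, 4), c(4, 4, 4, 4))),
             mk_ratings("v2", list(c(2, 3, 2, 3), c(3, 3, 2, 2))))
  p <- tempfile(fileext = ".csv")
  write_ratings(r, p)
  expect_equal(read_ratings(p), r)
})
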