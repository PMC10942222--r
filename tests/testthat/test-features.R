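test_that("counts and durations track categories, split by hand", {
  tri <- hook_case(cbind(c(0, 10, 20), c(5, 15, 25)), phase_s = 30)
  fv <- count_and_duration_features(tri)
  expect_equal(unname(fv["count.hook"]), 3)
  expect_equal(unname(fv["dur.hook"]), 15)
  expect_equal(sum(fv[grep("^count\\.", names(fv))]), 3)

  ev <- data.frame(phase = "MHT", label = "grasp",
                   hand = c("left", "right"),
                   start_s = c(0, 2), end_s = c(10, 6))
  case <- case_timeline("v", "s", ev, c(MHT = 15, DGB = 0))
  fv <- count_and_duration_features(case)
  expect_equal(unname(fv[c("count.grasp.L", "count.grasp.R",
                           "dur.grasp.L", "dur.grasp.R")]),
               c(1, 1, 10, 4))
})

test_that("empty timeline gives zero counts/durations and the manip time", {
  case <- case_timeline("e", "s", data.frame(),
                        phase_durations = c(MHT = 60, DGB = 60))
  fv <- suppressWarnings(extract_features(case))
  expect_length(fv, 63L)
  expect_equal(unname(fv["manip_time"]), 2)
  expect_true(all(fv[setdiff(names(fv), "manip_time")] == 0))
})

test_that("interval statistics match hand-computed gaps", {
  case <- hook_case(cbind(c(0, 20, 50), c(10, 30, 60)), phase_s = 70)
  fv <- suppressWarnings(interval_features(case))
  # gaps {10, 20}: mean 15, max 20, min 10, sample SD sqrt(50)
  expect_equal(unname(fv[c("int.all.mean", "int.all.max", "int.all.min",
                           "int.all.sd")]),
               c(15, 20, 10, sqrt(50)), tolerance = 1e-12)
  # hand streams are empty -> zeros with a warning
  expect_warning(interval_features(case), "fewer than 2 events")
  expect_equal(unname(fv[c("int.left.mean", "int.right.sd")]), c(0, 0))

  b2b <- hook_case(cbind(c(0, 10, 20), c(10, 20, 30)), phase_s = 30)
  fvb <- suppressWarnings(interval_features(b2b))
  expect_equal(unname(fvb[paste0("int.all.",
                                 c("mean", "max", "min", "sd"))]),
               c(0, 0, 0, 0))
})

test_that("shift frequency counts label changes per minute", {
  # A,A,B,A over a 2-minute manipulation: 2 changes -> 1.0 per min
  case <- hook_case(cbind(c(0, 10, 20, 30), c(5, 15, 25, 35)),
                    phase_s = 120,
                    labels = c("hook", "hook", "blunt_dissection", "hook"))
  expect_equal(shift_frequency(case, "all"), 1.0)

  same <- hook_case(cbind(c(0, 10), c(5, 15)), phase_s = 60)
  expect_equal(shift_frequency(same, "all"), 0)

  # alternating n events -> (n-1)/manip_min
  for (n in c(4, 9)) {
    alt <- hook_case(cbind(seq(0, by = 10, length.out = n),
                           seq(5, by = 10, length.out = n)),
                     phase_s = 300,
                     labels = rep(c("hook", "clip"), length.out = n))
    expect_equal(shift_frequency(alt, "all"), (n - 1) / 5)
  }
})

test_that("D/E features follow the ratio and floor rules", {
  # dissection 90 s, exposure 60 s -> dur ratio 1.5
  ev <- data.frame(
    phase = "MHT",
    label = c("hook", "blunt_dissection", "grasp", "push"),
    hand = c("unattributed", "unattributed", "left", "right"),
    start_s = c(0, 50, 100, 140), end_s = c(40, 100, 130, 170))
  case <- case_timeline("v", "s", ev, c(MHT = 180, DGB = 0))
  fv <- de_features(case)
  expect_equal(unname(fv["de.dur_ratio"]), 1.5)
  expect_equal(unname(fv[c("de.count_D", "de.count_E")]), c(2, 2))

  # all-dissection: floor applied, no class changes
  allD <- hook_case(cbind(c(0, 10), c(5, 15)), phase_s = 120)
  fvd <- suppressWarnings(de_features(allD))
  expect_warning(de_features(allD), "floor")
  expect_equal(unname(fvd["de.count_E"]), 0)
  expect_equal(unname(fvd["de.count_ratio"]), 2)  # 2 / max(0, 1)
  expect_equal(unname(fvd["de.shift"]), 0)

  # D,E,D,E,E,D over 2 min -> 4 class changes -> 2.0/min
  ev3 <- data.frame(
    phase = "MHT",
    label = c("hook", "grasp", "clip", "push", "suction", "cut"),
    hand = c("unattributed", "left", "unattributed", "right",
             "unattributed", "unattributed"),
    start_s = seq(0, 50, 10), end_s = seq(5, 55, 10))
  seqc <- case_timeline("t1", "s1", ev3, c(MHT = 120, DGB = 0))
  expect_equal(unname(de_features(seqc)["de.shift"]), 2.0)
})

test_that("full vectors have 63 entries and general cardinality 2C+23", {
  case <- random_case(3)
  expect_length(extract_features(case), 63L)
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "gestures:",
    "  - {name: a, functional_class: dissection, efficiency: effective, per_hand: true}",
    "  - {name: b, functional_class: exposure, efficiency: effective, per_hand: false}"),
    cfg)
  tax3 <- load_taxonomy(cfg)
  expect_length(feature_names(tax3), 2 * 3 + 12 + 3 + 7 + 1)
})

test_that("feature extraction matches the brute-force oracle", {
  for (seed in 1:12) {
    case <- random_case(seed)
    fv <- suppressWarnings(extract_features(case))
    expect_equal(fv, oracle_features(case), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("doubling event durations doubles durations, fixes counts", {
  case <- random_case(21)
  ev2 <- case$events
  ev2$start_s <- ev2$start_s * 2
  ev2$end_s <- ev2$end_s * 2
  case2 <- case_timeline(case$video_id, case$surgeon_id, ev2,
                         phase_durations = case$phase_durations * 2,
                         metadata = case$metadata)
  f1 <- suppressWarnings(extract_features(case))
  f2 <- suppressWarnings(extract_features(case2))
  dur_cols <- grep("^dur\\.|^de\\.dur_[DE]$", names(f1), value = TRUE)
  cnt_cols <- grep("^count\\.|^de\\.count", names(f1), value = TRUE)
  expect_equal(unname(f2[dur_cols]), unname(2 * f1[dur_cols]),
               tolerance = 1e-12)
  expect_equal(f2[cnt_cols], f1[cnt_cols])
  expect_equal(unname(f2["de.dur_ratio"]), unname(f1["de.dur_ratio"]),
               tolerance = 1e-12)
})

test_that("features are invariant to a within-phase time shift", {
  case <- hook_case(cbind(c(0, 12, 30), c(6, 20, 40)), phase_s = 200,
                    labels = c("hook", "clip", "hook"))
  ev2 <- case$events
  ev2$start_s <- ev2$start_s + 25
  ev2$end_s <- ev2$end_s + 25
  case2 <- case_timeline("t1", "s1", ev2,
                         phase_durations = case$phase_durations)
  f1 <- suppressWarnings(extract_features(case))
  f2 <- suppressWarnings(extract_features(case2))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("the worked fixture reproduces its oracle-computed golden file", {
  fx <- worked_fixture()
  expect_length(fx$cases, 12L)
  golden <- utils::read.csv(system.file("extdata", "worked_fixture",
                                        "golden_features.csv",
                                        package = "surgesture"),
                            check.names = FALSE)
  fm <- extract_feature_matrix(fx$cases, quiet = TRUE)
  expect_equal(fm$video_id, golden$video_id)
  expect_equal(as.matrix(fm[, -(1:2)]), as.matrix(golden[, -(1:2)]),
               tolerance = 1e-9)
})
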