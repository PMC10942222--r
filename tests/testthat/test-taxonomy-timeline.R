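test_that("default taxonomy has the published cardinalities", {
  tax <- default_taxonomy()
  expect_equal(nrow(tax), 14L)
  expect_equal(sum(tax$per_hand), 6L)
  expect_equal(length(taxonomy_categories(tax)), 20L)
  expect_setequal(unique(tax$functional_class), c("dissection", "exposure"))
  expect_false(anyDuplicated(tax$name) > 0)
})

test_that("taxonomy configs load, with category arithmetic and rejection", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "gestures:",
    "  - {name: a, functional_class: dissection, efficiency: effective, per_hand: true}",
    "  - {name: b, functional_class: exposure, efficiency: effective, per_hand: true}",
    "  - {name: c, functional_class: dissection, efficiency: inefficient, per_hand: false}"),
    cfg)
  tax <- load_taxonomy(cfg)
  expect_equal(length(taxonomy_categories(tax)), 5L)  # 2x2 + 1

  dup <- tempfile(fileext = ".yaml")
  writeLines(c(
    "gestures:",
    "  - {name: a, functional_class: dissection, efficiency: effective, per_hand: false}",
    "  - {name: a, functional_class: exposure, efficiency: effective, per_hand: false}"),
    dup)
  expect_error(load_taxonomy(dup), "duplicated")

  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "gestures:",
    "  - {name: a, functional_class: cutting, efficiency: effective, per_hand: false}"),
    bad)
  expect_error(load_taxonomy(bad), "functional_class")
  expect_error(load_taxonomy(tempfile()), "not found")
})

test_that("timelines read, validate, and reject malformed rows", {
  dir <- tempfile(); dir.create(dir)
  p <- file.path(dir, "v1.csv")
  ev <- sprintf("V1,S1,MHT,hook,unattributed,%d,%d", seq(0, 90, 10),
                seq(5, 95, 10))
  writeLines(c("# phase_duration MHT 100", "# phase_duration DGB 10",
               "video_id,surgeon_id,phase,label,hand,start_s,end_s", ev), p)
  case <- read_timeline(p)
  expect_s3_class(case, "surgesture_case")
  expect_equal(nrow(case$events), 10L)
  expect_equal(unname(case$phase_durations["MHT"]), 100)

  bad <- file.path(dir, "v2.csv")
  writeLines(c("video_id,surgeon_id,phase,label,hand,start_s,end_s",
               "V2,S1,MHT,hook,unattributed,10,5"), bad)
  expect_error(read_timeline(bad), "row")

  unk <- file.path(dir, "v3.csv")
  writeLines(c("video_id,surgeon_id,phase,label,hand,start_s,end_s",
               "V3,S1,MHT,zorble,unattributed,0,5"), unk)
  expect_error(read_timeline(unk), "unknown gesture")
})

test_that("same-hand overlap is rejected, cross-hand overlap allowed", {
  ev <- data.frame(phase = "MHT", label = "grasp",
                   hand = c("left", "left"), start_s = c(0, 5),
                   end_s = c(10, 12))
  expect_error(case_timeline("v", "s", ev, c(MHT = 20, DGB = 0)),
               "overlap")
  ev$hand <- c("left", "right")
  expect_s3_class(case_timeline("v", "s", ev, c(MHT = 20, DGB = 0)),
                  "surgesture_case")
  # half-open: touching events of one hand are fine
  ev2 <- data.frame(phase = "MHT", label = "grasp", hand = "left",
                    start_s = c(0, 10), end_s = c(10, 15))
  expect_s3_class(case_timeline("v", "s", ev2, c(MHT = 20, DGB = 0)),
                  "surgesture_case")
})

test_that("per-hand gestures need a hand; events must fit their phase", {
  ev <- data.frame(phase = "MHT", label = "grasp", hand = "unattributed",
                   start_s = 0, end_s = 5)
  expect_error(case_timeline("v", "s", ev, c(MHT = 10, DGB = 0)),
               "hand attribution")
  ev2 <- data.frame(phase = "MHT", label = "hook", hand = "unattributed",
                    start_s = 0, end_s = 50)
  expect_error(case_timeline("v", "s", ev2, c(MHT = 10, DGB = 5)),
               "beyond phase duration")
})

test_that("write-read round trips are identity and writes are byte-stable", {
  for (seed in c(1, 2, 3, 11)) {
    case <- random_case(seed)
    for (ext in c(".csv", ".json")) {
      p <- tempfile(fileext = ext)
      write_timeline(case, p)
      back <- read_timeline(p)
      expect_equal(back$events, case$events)
      expect_equal(back$phase_durations, case$phase_durations)
      expect_equal(back$metadata, case$metadata)
      expect_equal(back$video_id, case$video_id)
      p2 <- tempfile(fileext = ext)
      write_timeline(case, p2)
      expect_identical(unname(tools::md5sum(p)), unname(tools::md5sum(p2)))
    }
  }
})

test_that("parsed timelines are invariant to input row order", {
  case <- random_case(7)
  p <- tempfile(fileext = ".csv")
  write_timeline(case, p)
  lines <- readLines(p)
  hdr <- grep("^#|^video_id", lines)
  body <- setdiff(seq_along(lines), hdr)
  set.seed(1)
  shuffled <- c(lines[hdr], sample(lines[body]))
  p2 <- tempfile(fileext = ".csv")
  writeLines(shuffled, p2)
  expect_equal(read_timeline(p2)$events, case$events)
})

test_that("empty-events case writes a valid header-only file", {
  case <- case_timeline("e", "s", data.frame(),
                        phase_durations = c(MHT = 60, DGB = 60))
  p <- tempfile(fileext = ".csv")
  write_timeline(case, p)
  back <- read_timeline(p)
  expect_equal(nrow(back$events), 0L)
  expect_equal(back$phase_durations, case$phase_durations)
})
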