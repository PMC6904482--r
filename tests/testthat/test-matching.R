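test_that("IoU matches hand-computed areas", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150)
  # symmetry and touching edges (zero-area intersection)
  expect_equal(box_iou(c(5, 0, 15, 10), c(0, 0, 10, 10)), 50 / 150)
  expect_equal(box_iou(c(0, 0, 10, 10), c(10, 0, 20, 10)), 0)
  expect_error(box_iou(c(0, 0, 0, 10), c(0, 0, 10, 10)),
               class = "reprocad_error_malformed_box")
})

test_that("greedy assignment follows confidence order, not IoU order", {
  les <- data.frame(lesion_id = "L1", x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  det <- data.frame(x_min = c(1, 0), y_min = c(1, 0), x_max = c(11, 10),
                    y_max = c(11, 10), confidence = c(0.9, 0.8))
  m <- match_exam(les, det)
  # the confident detection claims the lesion even though the other overlaps perfectly
  expect_equal(m$hits$detection, 1L)
  expect_equal(m$hits$iou, 81 / 119)
  expect_equal(m$false_positives$detection, 2L)
  expect_length(m$missed, 0L)
})

test_that("no detections means every lesion is missed and nothing is false", {
  les <- data.frame(lesion_id = c("L1", "L2"),
                    x_min = c(0, 50), y_min = c(0, 50),
                    x_max = c(10, 60), y_max = c(10, 60))
  det <- data.frame(x_min = double(), y_min = double(), x_max = double(),
                    y_max = double(), confidence = double())
  m <- match_exam(les, det)
  expect_equal(nrow(m$hits), 0L)
  expect_equal(nrow(m$false_positives), 0L)
  expect_setequal(m$missed, c("L1", "L2"))
})

test_that("IoU exactly at the threshold is a miss under strict matching", {
  les <- data.frame(lesion_id = "L1", x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  det <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 5, confidence = 0.9)
  expect_equal(box_iou(les, det), 0.5)
  strict <- match_exam(les, det, iou_threshold = 0.5, strict = TRUE)
  expect_equal(nrow(strict$hits), 0L)
  expect_equal(nrow(strict$false_positives), 1L)
  lax <- match_exam(les, det, iou_threshold = 0.5, strict = FALSE)
  expect_equal(nrow(lax$hits), 1L)
})

test_that("mixed exam ids are rejected", {
  les <- data.frame(exam_id = "E1", lesion_id = "L1",
                    x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  det <- data.frame(exam_id = "E2", x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                    confidence = 0.5)
  expect_error(match_exam(les, det), class = "reprocad_error_mixed_exams")
})

test_that("thresholded counts behave at the extremes and on the worked case", {
  les <- data.frame(lesion_id = "L1", x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  det <- data.frame(x_min = c(1, 0), y_min = c(1, 0), x_max = c(11, 10),
                    y_max = c(11, 10), confidence = c(0.9, 0.8))
  m <- match_exam(les, det)
  expect_equal(counts_at_threshold(m, 0), c(tp = 1L, fp = 1L, fn = 0L))
  expect_equal(counts_at_threshold(m, 0.85), c(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(counts_at_threshold(m, 1.1), c(tp = 0L, fp = 0L, fn = 1L))
})

test_that("tp is non-increasing and fn non-decreasing as tau rises", {
  withr::local_seed(421)
  for (rep in 1:50) {
    inst <- random_match_instance()
    m <- match_exam(inst$lesions, inst$detections)
    taus <- sort(runif(8))
    counts <- vapply(taus, function(t) counts_at_threshold(m, t), numeric(3))
    expect_true(all(diff(counts["tp", ]) <= 0))
    expect_true(all(diff(counts["fn", ]) >= 0))
    expect_equal(counts["tp", ] + counts["fn", ], rep(nrow(inst$lesions), 8),
                 ignore_attr = TRUE)
  }
})

test_that("every detection and lesion is accounted for exactly once", {
  withr::local_seed(99)
  for (rep in 1:50) {
    inst <- random_match_instance()
    m <- match_exam(inst$lesions, inst$detections)
    expect_equal(nrow(m$hits) + nrow(m$false_positives), nrow(inst$detections))
    expect_equal(nrow(m$hits) + length(m$missed), nrow(inst$lesions))
    expect_false(anyDuplicated(m$hits$lesion_id) > 0)
    expect_false(anyDuplicated(m$hits$detection) > 0)
    expect_true(all(m$hits$iou > 0.5))
  }
})

test_that("matching is deterministic under confidence ties", {
  les <- data.frame(lesion_id = c("L1", "L2"),
                    x_min = c(0, 100), y_min = c(0, 0),
                    x_max = c(10, 110), y_max = c(10, 10))
  det <- data.frame(x_min = c(1, 101), y_min = c(0, 0), x_max = c(11, 111),
                    y_max = c(10, 10), confidence = c(0.5, 0.5))
  m1 <- match_exam(les, det)
  m2 <- match_exam(les, det)
  expect_identical(m1$hits, m2$hits)
  expect_equal(nrow(m1$hits), 2L)
})

test_that("match_dataset agrees with per-exam matching", {
  ds <- simulate_paired_detections(sim_config(n_pairs = 8, seed = 5))$dataset
  ms <- match_dataset(ds)
  for (eid in ds$exams$exam_id) {
    les <- ds$lesions[ds$lesions$exam_id == eid, ]
    det <- ds$detections[ds$detections$exam_id == eid, ]
    single <- match_exam(les, det)
    expect_equal(sort(ms[[eid]]$hits$lesion_id), sort(single$hits$lesion_id))
    expect_equal(nrow(ms[[eid]]$false_positives), nrow(single$false_positives))
  }
})
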