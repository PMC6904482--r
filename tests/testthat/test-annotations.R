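test_that("CSV and JSON serialization round-trip the dataset exactly", {
  sim <- simulate_paired_detections(sim_config(n_pairs = 10, seed = 7))
  ds <- sim$dataset
  for (ext in c("csv", "json")) {
    gt <- withr::local_tempfile(fileext = paste0(".", ext))
    de <- withr::local_tempfile(fileext = paste0(".", ext))
    write_cad_dataset(ds, gt, de)
    back <- read_cad_dataset(gt, de)
    expect_equal(back$exams, ds$exams)
    expect_equal(back$lesions, ds$lesions)
    expect_equal(back$detections, ds$detections)
  }
})

test_that("writing the same dataset twice produces identical bytes", {
  ds <- simulate_paired_detections(sim_config(n_pairs = 5, seed = 3))$dataset
  f1 <- withr::local_tempfile(fileext = ".csv"); f2 <- withr::local_tempfile(fileext = ".csv")
  d1 <- withr::local_tempfile(fileext = ".csv"); d2 <- withr::local_tempfile(fileext = ".csv")
  write_cad_dataset(ds, f1, d1)
  write_cad_dataset(ds, f2, d2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(d1), readLines(d2))
})

test_that("unicode patient identifiers survive the round trip", {
  ds <- tiny_dataset()
  ds$exams$patient_id <- rep(c("pätient-ß", "患者2"), each = 2)
  ds <- cad_dataset(ds$exams, ds$lesions, ds$detections)
  for (ext in c("csv", "json")) {
    gt <- withr::local_tempfile(fileext = paste0(".", ext))
    de <- withr::local_tempfile(fileext = paste0(".", ext))
    write_cad_dataset(ds, gt, de)
    back <- read_cad_dataset(gt, de)
    expect_equal(back$exams$patient_id, ds$exams$patient_id)
    expect_equal(exam_pairs(back), exam_pairs(ds))
  }
})

test_that("an empty dataset writes header-only files that load back", {
  ds <- cad_dataset(
    exams = tibble::tibble(patient_id = character(), exam_id = character(),
                           role = character()),
    lesions = tibble::tibble(exam_id = character(), lesion_id = character(),
                             x_min = double(), y_min = double(),
                             x_max = double(), y_max = double()),
    detections = tibble::tibble(exam_id = character(), x_min = double(),
                                y_min = double(), x_max = double(),
                                y_max = double(), confidence = double())
  )
  gt <- withr::local_tempfile(fileext = ".csv")
  de <- withr::local_tempfile(fileext = ".csv")
  write_cad_dataset(ds, gt, de)
  expect_length(readLines(gt), 1L)  # header only
  back <- read_cad_dataset(gt, de)
  expect_equal(nrow(back$exams), 0L)
})

test_that("each type-invariant violation raises its own named error", {
  ds <- tiny_dataset()

  bad_box <- ds$lesions
  bad_box$x_max[1] <- bad_box$x_min[1]  # degenerate rectangle
  expect_error(cad_dataset(ds$exams, bad_box, ds$detections),
               class = "reprocad_error_malformed_box")

  dup <- ds$exams
  dup$exam_id[2] <- dup$exam_id[1]
  expect_error(cad_dataset(dup, ds$lesions, ds$detections),
               class = "reprocad_error_duplicate_exam")

  expect_error(cad_dataset(ds$exams[c("patient_id", "exam_id")], ds$lesions, ds$detections),
               class = "reprocad_error_missing_column")

  orphan <- ds$lesions[ds$lesions$exam_id != "A-F", ]  # lesion only in initial exam
  expect_error(cad_dataset(ds$exams, orphan, ds$detections),
               class = "reprocad_error_unpaired_lesion")

  stray <- ds$detections
  stray$exam_id[1] <- "nowhere"
  expect_error(cad_dataset(ds$exams, ds$lesions, stray),
               class = "reprocad_error_unknown_exam")

  unpaired <- ds$exams[-2, ]  # patient A loses its follow-up exam
  expect_error(cad_dataset(unpaired, ds$lesions[ds$lesions$exam_id != "A-F", ],
                           ds$detections),
               class = "reprocad_error_bad_pair")

  nonfinite <- ds$detections
  nonfinite$confidence[1] <- NaN
  expect_error(cad_dataset(ds$exams, ds$lesions, nonfinite),
               class = "reprocad_error_bad_confidence")
})

test_that("a loaded file with a lesion in only one exam is rejected", {
  ds <- tiny_dataset()
  gt <- withr::local_tempfile(fileext = ".csv")
  de <- withr::local_tempfile(fileext = ".csv")
  write_cad_dataset(ds, gt, de)
  rows <- readLines(gt)
  # blank out patient B's follow-up lesion, keeping the exam declared
  rows <- sub("^B,B-F,followup,L1,.*$", "B,B-F,followup,,,,,,,100,100", rows)
  writeLines(rows, gt)
  expect_error(read_cad_dataset(gt, de), class = "reprocad_error_unpaired_lesion")
})
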