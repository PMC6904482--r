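#' Assemble and validate a paired-exam detection dataset
#'
#' The container holding everything the evaluation needs: the exams (paired
#' initial / follow-up radiographs of each patient), the ground-truth lesion
#' boxes per exam, and the detector output per exam. Lesion correspondence
#' across an exam pair is carried explicitly by `lesion_id`: the same
#' identifier must appear in the ground truth of both exams of a pair.
#'
#' @param exams Tibble with columns `patient_id`, `exam_id`,
#'   `role` (`"initial"` or `"followup"`), and optionally `width`, `height`
#'   (image size in pixels, `NA` allowed).
#' @param lesions Tibble with columns `exam_id`, `lesion_id`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, and optionally `size_mm` (positive or `NA`).
#' @param detections Tibble with columns `exam_id`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `confidence`. Confidences are finite scores, higher =
#'   more suspicious; only their ordering is used downstream, but by
#'   convention they live in `[0, 1]`.
#' @return A validated `cad_dataset` object.
#' @seealso [read_cad_dataset()], [write_cad_dataset()], [exam_pairs()]
#' @export
cad_dataset <- function(exams, lesions, detections) {
  exams <- tibble::as_tibble(exams)
  lesions <- tibble::as_tibble(lesions)
  detections <- tibble::as_tibble(detections)

  require_columns(exams, c("patient_id", "exam_id", "role"), "exams")
  require_columns(lesions, c("exam_id", "lesion_id", "x_min", "y_min", "x_max", "y_max"), "lesions")
  require_columns(detections, c("exam_id", "x_min", "y_min", "x_max", "y_max", "confidence"), "detections")

  if (!"width" %in% names(exams)) exams$width <- NA_real_
  if (!"height" %in% names(exams)) exams$height <- NA_real_
  if (!"size_mm" %in% names(lesions)) lesions$size_mm <- NA_real_

  exams <- dplyr::mutate(
    exams,
    patient_id = as.character(.data$patient_id),
    exam_id = as.character(.data$exam_id),
    role = as.character(.data$role),
    width = as.numeric(.data$width),
    height = as.numeric(.data$height)
  )
  lesions <- dplyr::mutate(
    lesions,
    exam_id = as.character(.data$exam_id),
    lesion_id = as.character(.data$lesion_id),
    dplyr::across(c("x_min", "y_min", "x_max", "y_max", "size_mm"), as.numeric)
  )
  detections <- dplyr::mutate(
    detections,
    exam_id = as.character(.data$exam_id),
    dplyr::across(c("x_min", "y_min", "x_max", "y_max", "confidence"), as.numeric)
  )

  exams <- exams[c("patient_id", "exam_id", "role", "width", "height")]
  lesions <- lesions[c("exam_id", "lesion_id", "x_min", "y_min", "x_max", "y_max", "size_mm")]
  detections <- detections[c("exam_id", "x_min", "y_min", "x_max", "y_max", "confidence")]

  # canonical ordering (C-locale) so that construction, serialization and
  # re-reading all converge on one representation; detection row order is
  # preserved as given — it is a deterministic tie-breaker in matching
  exams <- dplyr::arrange(exams, .data$patient_id, .data$role != "initial")
  lesions <- dplyr::arrange(lesions, .data$exam_id, .data$lesion_id)
  # group detections by exam (exam order as above) but keep their relative
  # order within an exam — it is the matching tie-breaker
  detections <- detections[order(match(detections$exam_id, exams$exam_id)), , drop = FALSE]

  out <- structure(
    list(exams = exams, lesions = lesions, detections = detections),
    class = "cad_dataset"
  )
  validate_cad_dataset(out)
}

#' @export
print.cad_dataset <- function(x, ...) {
  pairs <- exam_pairs(x)
  cat(sprintf(
    "<cad_dataset> %d patients (%d exams), %d lesion annotations, %d detections\n",
    nrow(pairs), nrow(x$exams), nrow(x$lesions), nrow(x$detections)
  ))
  invisible(x)
}

# Full invariant check; returns the dataset invisibly or signals a classed error.
validate_cad_dataset <- function(x) {
  exams <- x$exams; lesions <- x$lesions; detections <- x$detections

  if (anyDuplicated(exams$exam_id)) {
    stop_reprocad("duplicate_exam", paste0(
      "duplicate exam_id: ",
      paste(unique(exams$exam_id[duplicated(exams$exam_id)]), collapse = ", ")
    ))
  }
  if (!all(exams$role %in% c("initial", "followup"))) {
    stop_reprocad("bad_role", "exam role must be 'initial' or 'followup'")
  }
  dims <- c(exams$width, exams$height)
  if (any(!is.na(dims) & dims <= 0)) {
    stop_reprocad("bad_dimension", "exam width/height must be positive when given")
  }

  # pairing: each patient contributes exactly one initial and one follow-up exam
  tab <- table(exams$patient_id, exams$role)
  complete <- ncol(tab) == 2L && all(tab == 1L)
  if (nrow(exams) > 0L && !complete) {
    stop_reprocad("bad_pair", "every patient needs exactly one 'initial' and one 'followup' exam")
  }

  for (df in list(lesions, detections)) {
    if (nrow(df) > 0L) as_box_matrix(df)  # signals reprocad_error_malformed_box
    unknown <- setdiff(df$exam_id, exams$exam_id)
    if (length(unknown)) {
      stop_reprocad("unknown_exam", paste0(
        "exam_id not declared in exams: ", paste(unknown, collapse = ", ")
      ))
    }
  }
  if (anyDuplicated(lesions[c("exam_id", "lesion_id")])) {
    stop_reprocad("duplicate_lesion", "lesion_id must be unique within an exam")
  }
  if (any(!is.na(lesions$size_mm) & lesions$size_mm <= 0)) {
    stop_reprocad("bad_size", "size_mm must be positive when given")
  }
  if (any(!is.finite(detections$confidence))) {
    stop_reprocad("bad_confidence", "detection confidence must be finite")
  }

  # lesion correspondence: identical lesion_id sets in both exams of a pair
  if (nrow(lesions) > 0L) {
    les <- dplyr::left_join(lesions, exams[c("exam_id", "patient_id", "role")], by = "exam_id")
    per_lesion <- table(paste(les$patient_id, les$lesion_id, sep = "\r"))
    if (any(per_lesion != 2L)) {
      bad <- sub("\r", "/", names(per_lesion)[per_lesion != 2L])
      stop_reprocad("unpaired_lesion", paste0(
        "lesion_id present in only one exam of the pair (patient/lesion): ",
        paste(bad, collapse = ", ")
      ))
    }
  }
  invisible(x)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_reprocad("missing_column", paste0(
      what, " is missing required column(s): ", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' List the initial/follow-up exam pairs of a dataset
#'
#' @param dataset A [cad_dataset()].
#' @return Tibble with one row per patient: `patient_id`, `initial_exam_id`,
#'   `followup_exam_id`, and `n_lesions` (shared lesion identities).
#' @export
exam_pairs <- function(dataset) {
  stopifnot(inherits(dataset, "cad_dataset"))
  ex <- dataset$exams
  ini <- ex[ex$role == "initial", c("patient_id", "exam_id")]
  fu <- ex[ex$role == "followup", c("patient_id", "exam_id")]
  names(ini)[2] <- "initial_exam_id"
  names(fu)[2] <- "followup_exam_id"
  pairs <- dplyr::inner_join(ini, fu, by = "patient_id")
  nles <- table(dataset$lesions$exam_id)
  pairs$n_lesions <- as.integer(nles[pairs$initial_exam_id])
  pairs$n_lesions[is.na(pairs$n_lesions)] <- 0L
  dplyr::arrange(pairs, .data$patient_id)
}

#' Read a paired-exam dataset from annotation files
#'
#' The ground-truth file carries one row (CSV) or entry (JSON) per lesion
#' box with columns `patient_id`, `exam_id`, `role`, `lesion_id`, `x_min`,
#' `y_min`, `x_max`, `y_max` and optional `size_mm`, `width`, `height`; a row
#' with a blank `lesion_id` declares an exam without lesions. The detections
#' file carries `exam_id`, box coordinates and `confidence`. The format is
#' chosen by file extension: `.csv` or `.json`.
#'
#' @param gt_path Path to the ground-truth file.
#' @param det_path Path to the detections file.
#' @return A validated [cad_dataset()].
#' @export
read_cad_dataset <- function(gt_path, det_path) {
  if (!file.exists(gt_path)) stop_reprocad("missing_file", paste0("no such file: ", gt_path))
  if (!file.exists(det_path)) stop_reprocad("missing_file", paste0("no such file: ", det_path))

  if (file_format(gt_path) == "json") {
    gt <- jsonlite::fromJSON(gt_path, simplifyVector = TRUE)
    exams <- tibble::as_tibble(gt$exams)
    lesion_tabs <- exams$lesions
    exams$lesions <- NULL
    lesions <- dplyr::bind_rows(lapply(seq_along(lesion_tabs), function(i) {
      li <- lesion_tabs[[i]]
      if (is.null(li) || NROW(li) == 0L) return(NULL)
      li <- tibble::as_tibble(li)
      li$exam_id <- exams$exam_id[i]
      li
    }))
    if (is.null(lesions) || nrow(lesions) == 0L) lesions <- empty_lesions()
  } else {
    gt <- readr::read_csv(gt_path, col_types = readr::cols(
      patient_id = readr::col_character(), exam_id = readr::col_character(),
      role = readr::col_character(), lesion_id = readr::col_character(),
      .default = readr::col_double()
    ))
    require_columns(gt, c("patient_id", "exam_id", "role", "lesion_id",
                          "x_min", "y_min", "x_max", "y_max"), "ground truth file")
    exam_cols <- intersect(c("patient_id", "exam_id", "role", "width", "height"), names(gt))
    exams <- dplyr::distinct(gt[exam_cols])
    lesions <- gt[!is.na(gt$lesion_id) & gt$lesion_id != "",
                  intersect(c("exam_id", "lesion_id", "x_min", "y_min", "x_max", "y_max", "size_mm"), names(gt))]
  }

  if (file_format(det_path) == "json") {
    de <- jsonlite::fromJSON(det_path, simplifyVector = TRUE)
    det_tabs <- de$exams$detections
    det_ids <- de$exams$exam_id
    detections <- dplyr::bind_rows(lapply(seq_along(det_tabs), function(i) {
      di <- det_tabs[[i]]
      if (is.null(di) || NROW(di) == 0L) return(NULL)
      di <- tibble::as_tibble(di)
      di$exam_id <- det_ids[i]
      di
    }))
    if (is.null(detections) || nrow(detections) == 0L) detections <- empty_detections()
  } else {
    detections <- readr::read_csv(det_path, col_types = readr::cols(
      exam_id = readr::col_character(), .default = readr::col_double()
    ))
    require_columns(detections, c("exam_id", "x_min", "y_min", "x_max", "y_max", "confidence"),
                    "detections file")
  }

  cad_dataset(exams, lesions, detections)
}

#' Write a paired-exam dataset to annotation files
#'
#' Inverse of [read_cad_dataset()]: `read_cad_dataset()` applied to the two
#' written files reproduces the dataset exactly. Format follows the file
#' extension (`.csv` or `.json`).
#'
#' @param dataset A [cad_dataset()].
#' @param gt_path,det_path Output paths for ground truth and detections.
#' @return The dataset, invisibly.
#' @export
write_cad_dataset <- function(dataset, gt_path, det_path) {
  stopifnot(inherits(dataset, "cad_dataset"))

  if (file_format(gt_path) == "json") {
    ex <- dataset$exams
    ex$lesions <- lapply(ex$exam_id, function(id) {
      li <- dataset$lesions[dataset$lesions$exam_id == id, , drop = FALSE]
      li$exam_id <- NULL
      li
    })
    jsonlite::write_json(list(exams = ex), gt_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else {
    gt <- dplyr::left_join(dataset$lesions, dataset$exams, by = "exam_id")
    gt <- gt[c("patient_id", "exam_id", "role", "lesion_id",
               "x_min", "y_min", "x_max", "y_max", "size_mm", "width", "height")]
    bare <- dataset$exams[!dataset$exams$exam_id %in% dataset$lesions$exam_id, , drop = FALSE]
    if (nrow(bare)) {
      bare$lesion_id <- NA_character_
      bare[c("x_min", "y_min", "x_max", "y_max", "size_mm")] <- NA_real_
      gt <- dplyr::bind_rows(gt, bare[names(gt)])
    }
    readr::write_csv(gt, gt_path, na = "")
  }

  if (file_format(det_path) == "json") {
    ex <- dataset$exams["exam_id"]
    ex$detections <- lapply(ex$exam_id, function(id) {
      di <- dataset$detections[dataset$detections$exam_id == id, , drop = FALSE]
      di$exam_id <- NULL
      di
    })
    jsonlite::write_json(list(exams = ex), det_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else {
    readr::write_csv(dataset$detections, det_path, na = "")
  }
  invisible(dataset)
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("csv", "json")) {
    stop_reprocad("bad_format", paste0("unsupported annotation format '.", ext, "' (use .csv or .json)"))
  }
  ext
}

empty_lesions <- function() {
  tibble::tibble(exam_id = character(), lesion_id = character(),
                 x_min = double(), y_min = double(), x_max = double(), y_max = double(),
                 size_mm = double())
}

empty_detections <- function() {
  tibble::tibble(exam_id = character(), x_min = double(), y_min = double(),
                 x_max = double(), y_max = double(), confidence = double())
}
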