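#' Match detections to ground-truth lesions in one exam
#'
#' Implements the hit criterion used throughout the package: a detection is a
#' hit when its intersection-over-union with a ground-truth lesion box
#' exceeds `iou_threshold` (strictly, by default). Assignment is greedy and
#' one-to-one: detections are visited in order of decreasing confidence and
#' each claims the still-unclaimed lesion of highest IoU among those above
#' the threshold. Ties in confidence are broken by higher best-available IoU,
#' then by input order, so reruns are deterministic.
#'
#' @param lesions Ground-truth lesions of one exam: data frame with
#'   `lesion_id` and box columns.
#' @param detections Detections of the same exam: data frame with box
#'   columns and `confidence`.
#' @param iou_threshold Hit threshold in (0, 1); default 0.5.
#' @param strict If `TRUE` (default) the IoU must exceed the threshold;
#'   `FALSE` accepts equality.
#' @return An `exam_match` object: list with tibbles `hits` (`lesion_id`,
#'   `detection` row index, `iou`, `confidence`), `false_positives`
#'   (`detection`, `confidence`), character vector `missed`, and counts.
#' @export
match_exam <- function(lesions, detections, iou_threshold = 0.5, strict = TRUE) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  ids <- unique(c(
    if ("exam_id" %in% names(lesions)) lesions$exam_id,
    if ("exam_id" %in% names(detections)) detections$exam_id
  ))
  if (length(ids) > 1L) {
    stop_reprocad("mixed_exams", "lesions and detections must belong to a single exam")
  }

  m <- match_boxes(
    les_box = as_box_matrix(lesions[c("x_min", "y_min", "x_max", "y_max")]),
    det_box = as_box_matrix(detections[c("x_min", "y_min", "x_max", "y_max")]),
    conf = as.numeric(detections$confidence),
    iou_threshold = iou_threshold, strict = strict
  )

  lesion_id <- as.character(lesions$lesion_id)
  hit <- !is.na(m$det_of_lesion)
  structure(list(
    exam_id = if (length(ids)) ids else NA_character_,
    hits = tibble::tibble(
      lesion_id = lesion_id[hit],
      detection = m$det_of_lesion[hit],
      iou = m$iou_of_lesion[hit],
      confidence = detections$confidence[m$det_of_lesion[hit]]
    ),
    false_positives = tibble::tibble(
      detection = m$fp,
      confidence = detections$confidence[m$fp]
    ),
    missed = lesion_id[!hit],
    n_lesions = nrow(lesions),
    n_detections = nrow(detections)
  ), class = "exam_match")
}

#' @export
print.exam_match <- function(x, ...) {
  cat(sprintf("<exam_match> %d/%d lesions hit, %d false positives\n",
              nrow(x$hits), x$n_lesions, nrow(x$false_positives)))
  invisible(x)
}

# Core greedy assignment on bare matrices; kept free of data-frame overhead
# because it runs once per exam across large simulations.
match_boxes <- function(les_box, det_box, conf, iou_threshold, strict) {
  n_les <- nrow(les_box); n_det <- nrow(det_box)
  det_of_lesion <- rep(NA_integer_, n_les)
  iou_of_lesion <- rep(NA_real_, n_les)
  if (n_det == 0L) {
    return(list(det_of_lesion = det_of_lesion, iou_of_lesion = iou_of_lesion, fp = integer()))
  }
  if (n_les == 0L) {
    return(list(det_of_lesion = det_of_lesion, iou_of_lesion = iou_of_lesion, fp = seq_len(n_det)))
  }
  iou <- iou_matrix(det_box, les_box)          # n_det x n_les
  eligible <- if (strict) iou > iou_threshold else iou >= iou_threshold
  best <- iou[cbind(seq_len(n_det), max.col(iou, ties.method = "first"))]
  ord <- order(-conf, -best, seq_len(n_det))
  claimed <- logical(n_les)
  matched_det <- logical(n_det)
  for (i in ord) {
    cand <- which(eligible[i, ] & !claimed)
    if (!length(cand)) next
    j <- cand[which.max(iou[i, cand])]
    claimed[j] <- TRUE
    matched_det[i] <- TRUE
    det_of_lesion[j] <- i
    iou_of_lesion[j] <- iou[i, j]
  }
  list(det_of_lesion = det_of_lesion, iou_of_lesion = iou_of_lesion,
       fp = which(!matched_det))
}

#' Threshold a match result at a confidence cut-off
#'
#' Keeps the assignment fixed and discards detections below `tau`: a hit
#' whose detection falls below the cut-off becomes a miss, a false positive
#' below it disappears.
#'
#' @param match An `exam_match` from [match_exam()].
#' @param tau Confidence threshold; detections with `confidence >= tau` survive.
#' @return Named integer vector `c(tp, fp, fn)` with `tp + fn` equal to the
#'   number of lesions.
#' @export
counts_at_threshold <- function(match, tau) {
  stopifnot(inherits(match, "exam_match"), is.numeric(tau), length(tau) == 1L, !is.na(tau))
  tp <- sum(match$hits$confidence >= tau)
  c(tp = tp,
    fp = sum(match$false_positives$confidence >= tau),
    fn = match$n_lesions - tp)
}

#' Match every exam of a dataset
#'
#' @param dataset A [cad_dataset()].
#' @inheritParams match_exam
#' @return Named list of `exam_match` objects, one per exam (all exams, in
#'   dataset order), named by `exam_id`.
#' @export
match_dataset <- function(dataset, iou_threshold = 0.5, strict = TRUE) {
  stopifnot(inherits(dataset, "cad_dataset"))
  exam_ids <- dataset$exams$exam_id
  les_idx <- split(seq_len(nrow(dataset$lesions)),
                   factor(dataset$lesions$exam_id, levels = exam_ids))
  det_idx <- split(seq_len(nrow(dataset$detections)),
                   factor(dataset$detections$exam_id, levels = exam_ids))
  les_box <- as.matrix(dataset$lesions[c("x_min", "y_min", "x_max", "y_max")])
  det_box <- as.matrix(dataset$detections[c("x_min", "y_min", "x_max", "y_max")])
  conf <- dataset$detections$confidence
  lesion_id <- dataset$lesions$lesion_id

  out <- vector("list", length(exam_ids))
  names(out) <- exam_ids
  for (k in seq_along(exam_ids)) {
    li <- les_idx[[k]]; di <- det_idx[[k]]
    m <- match_boxes(les_box[li, , drop = FALSE], det_box[di, , drop = FALSE],
                     conf[di], iou_threshold, strict)
    hit <- which(!is.na(m$det_of_lesion))
    ids <- lesion_id[li]
    conf_k <- conf[di]
    hit_det <- m$det_of_lesion[hit]
    out[[k]] <- structure(list(
      exam_id = exam_ids[k],
      hits = tibble::new_tibble(list(
        lesion_id = ids[hit],
        detection = di[hit_det],
        iou = m$iou_of_lesion[hit],
        confidence = conf_k[hit_det]
      ), nrow = length(hit)),
      false_positives = tibble::new_tibble(list(
        detection = di[m$fp],
        confidence = conf_k[m$fp]
      ), nrow = length(m$fp)),
      missed = if (length(hit)) ids[-hit] else ids,
      n_lesions = length(li),
      n_detections = length(di)
    ), class = "exam_match")
  }
  out
}
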