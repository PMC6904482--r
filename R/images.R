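#' Render a synthetic exam pair as grayscale images
#'
#' Draws each lesion as a bright Gaussian-profile blob on a noisy
#' background; the follow-up image re-renders the same lesions at their
#' jittered follow-up positions with fresh, inflated noise
#' (`followup_noise_factor`), emulating the poorer acquisition conditions of
#' unscheduled follow-up radiographs. Intended as an end-to-end exercise for
#' the evaluation pipeline together with [toy_blob_detector()], not as a
#' realistic chest-image model.
#'
#' @param config A [sim_config()]; `n_pairs` is ignored (one pair is rendered).
#' @param background Background intensity level.
#' @param noise_sd Standard deviation of the Gaussian pixel noise in the
#'   initial image.
#' @param amplitude Peak intensity added at a lesion centre.
#' @return List with matrices `initial` and `followup` (values in `[0, 1]`,
#'   `image_size[1]` columns x `image_size[2]` rows), tibbles `exams` and
#'   `lesions` in the annotation schema, and the `patient_id`.
#' @export
render_pair_images <- function(config, background = 0.2, noise_sd = 0.03,
                               amplitude = 0.55) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    one <- sim_config(
      n_pairs = 1L, extra_lesion_prob = config$extra_lesion_prob,
      image_size = config$image_size, sensitivity = 1, rho = 1, fp_rate = 0,
      box_jitter = config$box_jitter, lesion_size_px = config$lesion_size_px,
      followup_noise_factor = config$followup_noise_factor,
      seed = config$seed
    )
    sim <- simulate_paired_detections_impl(one)
    ds <- sim$dataset
    render_one <- function(exam_id, sd_factor) {
      les <- ds$lesions[ds$lesions$exam_id == exam_id, , drop = FALSE]
      img <- matrix(rnorm(prod(config$image_size), background,
                          noise_sd * sd_factor),
                    nrow = config$image_size[2], ncol = config$image_size[1])
      for (i in seq_len(nrow(les))) {
        img <- add_blob(img,
                        cx = (les$x_min[i] + les$x_max[i]) / 2,
                        cy = (les$y_min[i] + les$y_max[i]) / 2,
                        sigma_x = (les$x_max[i] - les$x_min[i]) / 4,
                        sigma_y = (les$y_max[i] - les$y_min[i]) / 4,
                        amplitude = amplitude)
      }
      pmin(pmax(img, 0), 1)
    }
    pairs <- exam_pairs(ds)
    list(
      initial = render_one(pairs$initial_exam_id, 1),
      followup = render_one(pairs$followup_exam_id, config$followup_noise_factor),
      exams = ds$exams,
      lesions = ds$lesions,
      patient_id = pairs$patient_id
    )
  })
}

# Add a separable Gaussian bump; image indexed [row = y, col = x].
add_blob <- function(img, cx, cy, sigma_x, sigma_y, amplitude) {
  gx <- exp(-0.5 * ((seq_len(ncol(img)) - 0.5 - cx) / sigma_x)^2)
  gy <- exp(-0.5 * ((seq_len(nrow(img)) - 0.5 - cy) / sigma_y)^2)
  img + amplitude * outer(gy, gx)
}

#' Multiscale difference-of-Gaussians blob detector
#'
#' A deliberately simple detector standing in for a trained model: the image
#' is blurred at a geometric ladder of scales, consecutive blurs are
#' subtracted (difference of Gaussians, an approximation to the
#' scale-normalized Laplacian), and local maxima of the response across
#' space and scale above `floor` become detections. Each maximum yields a
#' box of half-width `sqrt(2) * sigma` at its scale; overlapping detections
#' are reduced by non-maximum suppression. Confidence is the DoG response
#' mapped through `min(1, response / saturation)` — monotone in response, so
#' downstream rank-based analyses are unaffected by the scaling.
#'
#' @param image Numeric matrix (grayscale, rows = y).
#' @param sigmas Increasing vector of blur scales in pixels.
#' @param floor Minimum DoG response for a candidate maximum.
#' @param saturation Response at which confidence saturates at 1.
#' @param nms_iou Boxes overlapping a stronger detection above this IoU are
#'   suppressed.
#' @return Tibble in the detections schema (without `exam_id`): box
#'   coordinates and `confidence`, ordered by decreasing confidence.
#' @export
toy_blob_detector <- function(image, sigmas = 2 * 2^seq(0, 5, by = 0.5),
                              floor = 0.02, saturation = 0.25, nms_iou = 0.3) {
  stopifnot(is.matrix(image), is.numeric(image))
  empty <- tibble::tibble(x_min = double(), y_min = double(),
                          x_max = double(), y_max = double(),
                          confidence = double())
  if (length(image) == 0L) return(empty)
  sigmas <- sort(sigmas)
  usable <- sigmas[2 * ceiling(3 * sigmas) + 1 < min(dim(image))]
  if (length(usable) < 2L) return(empty)
  blurred <- lapply(usable, function(s) EBImage::gblur(image, sigma = s))
  dog <- lapply(seq_len(length(usable) - 1L),
                function(i) blurred[[i]] - blurred[[i + 1L]])

  cands <- list()
  for (k in seq_along(dog)) {
    peaks <- local_maxima(dog[[k]], floor)
    if (!nrow(peaks)) next
    resp <- dog[[k]][peaks]
    # keep only maxima that also dominate the neighbouring scales
    keep <- rep(TRUE, nrow(peaks))
    if (k > 1L) keep <- keep & resp >= dog[[k - 1L]][peaks]
    if (k < length(dog)) keep <- keep & resp >= dog[[k + 1L]][peaks]
    if (!any(keep)) next
    sigma <- sqrt(usable[k] * usable[k + 1L])   # geometric mean of the pair
    half <- 2 * sigma   # a rendered blob of scale sigma fills a box of side ~4 sigma
    cands[[length(cands) + 1L]] <- tibble::tibble(
      x_min = peaks[keep, 2L] - 0.5 - half, y_min = peaks[keep, 1L] - 0.5 - half,
      x_max = peaks[keep, 2L] - 0.5 + half, y_max = peaks[keep, 1L] - 0.5 + half,
      confidence = pmin(1, resp[keep] / saturation)
    )
  }
  if (!length(cands)) return(empty)
  det <- dplyr::bind_rows(cands)
  det <- det[order(-det$confidence), , drop = FALSE]
  det[nms_keep(det, nms_iou), , drop = FALSE]
}

# strict local maxima over a 3x3 neighbourhood, response above `floor`;
# returns a matrix of (row, col) indices, border excluded
local_maxima <- function(x, floor) {
  nr <- nrow(x); nc <- ncol(x)
  if (nr < 3L || nc < 3L) return(cbind(row = integer(), col = integer()))
  core <- x[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  is_max <- core > floor
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- x[2:(nr - 1) + dr, 2:(nc - 1) + dc, drop = FALSE]
    is_max <- is_max & core >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  cbind(row = idx[, 1L] + 1L, col = idx[, 2L] + 1L)
}

# greedy non-maximum suppression; `det` ordered by decreasing confidence
nms_keep <- function(det, nms_iou) {
  n <- nrow(det)
  if (n <= 1L) return(seq_len(n))
  boxes <- as_box_matrix(det)
  keep <- logical(n)
  for (i in seq_len(n)) {
    prior <- which(keep)
    if (!length(prior)) { keep[i] <- TRUE; next }
    ious <- box_iou(boxes[rep(i, length(prior)), , drop = FALSE],
                    boxes[prior, , drop = FALSE])
    keep[i] <- all(ious <= nms_iou)
  }
  which(keep)
}

#' Simulate a fully rendered image dataset and run the toy detector
#'
#' End-to-end harness: renders every exam pair of the configuration as
#' images, runs [toy_blob_detector()] on each image, and assembles the
#' results into a [cad_dataset()] ready for [evaluate_dataset()].
#'
#' @param config A [sim_config()].
#' @param ... Passed on to [toy_blob_detector()].
#' @return A [cad_dataset()].
#' @export
simulate_image_dataset <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  parts <- lapply(seq_len(config$n_pairs), function(k) {
    cfg_k <- config
    cfg_k$seed <- as.integer((config$seed + 104729 * k) %% .Machine$integer.max)
    pair <- render_pair_images(cfg_k)
    pair$exams$patient_id <- sprintf("P%05d", k)
    pair$exams$exam_id <- sub("^P00001", sprintf("P%05d", k), pair$exams$exam_id)
    pair$lesions$exam_id <- sub("^P00001", sprintf("P%05d", k), pair$lesions$exam_id)
    det <- dplyr::bind_rows(
      dplyr::mutate(toy_blob_detector(pair$initial, ...),
                    exam_id = pair$exams$exam_id[pair$exams$role == "initial"]),
      dplyr::mutate(toy_blob_detector(pair$followup, ...),
                    exam_id = pair$exams$exam_id[pair$exams$role == "followup"])
    )
    list(exams = pair$exams, lesions = pair$lesions, detections = det)
  })
  cad_dataset(
    exams = dplyr::bind_rows(lapply(parts, `[[`, "exams")),
    lesions = dplyr::bind_rows(lapply(parts, `[[`, "lesions")),
    detections = dplyr::bind_rows(lapply(parts, `[[`, "detections"))
  )
}
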