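#' Configuration for the paired-detection simulator
#'
#' Describes a synthetic study of paired chest exams: each patient has an
#' initial and a follow-up exam sharing the same lesions, a detector with
#' per-lesion sensitivity `s` whose detection events on the two exams are
#' correlated, and Poisson-distributed false positives. Defaults mirror a
#' validation setting of 121 exam pairs where most patients carry a single
#' lesion and roughly one patient in nine carries a second one, a detector
#' of sensitivity around 0.8, and about one raw false positive per image so
#' that thresholding can realize operating points between 0.1 and 0.5
#' average false positives.
#'
#' @param n_pairs Number of exam pairs (patients).
#' @param extra_lesion_prob Probability that a patient carries a second
#'   lesion (lesion count is `1 + Bernoulli(extra_lesion_prob)`).
#' @param image_size Image side lengths in pixels, `c(width, height)`.
#' @param sensitivity Per-lesion, per-exam detection probability `s` in `[0, 1]`.
#' @param rho Between-exam correlation in `[0, 1]`: with probability `rho`
#'   a lesion's two detection events are one shared Bernoulli draw, with
#'   probability `1 - rho` they are drawn independently.
#' @param fp_rate Mean number of false positives per image (Poisson).
#' @param tp_score,fp_score Functions `n -> n` confidences in `[0, 1]` for
#'   true- and false-positive detections; defaults skew true positives high
#'   (`Beta(6, 2)`) and false positives low (`Beta(2, 6)`).
#' @param box_jitter Maximum detection-box displacement per axis as a
#'   fraction of the box side, in `[0, 0.18]`; within this range a jittered
#'   box always keeps IoU above 0.5 with its lesion, so jitter never breaks
#'   the hit criterion.
#' @param lesion_size_px Range of lesion box side lengths in pixels.
#' @param followup_noise_factor Multiplier (>= 1) on background noise in the
#'   rendered follow-up image, emulating the poorer acquisition conditions
#'   of unscheduled follow-up radiographs.
#' @param seed Integer seed; the simulation is a pure function of the config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_pairs = 121L,
                       extra_lesion_prob = 13 / 121,
                       image_size = c(1024L, 1024L),
                       sensitivity = 0.8,
                       rho = 0.5,
                       fp_rate = 1,
                       tp_score = function(n) rbeta(n, 6, 2),
                       fp_score = function(n) rbeta(n, 2, 6),
                       box_jitter = 0.12,
                       lesion_size_px = c(48, 160),
                       followup_noise_factor = 1.5,
                       seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs), extra_lesion_prob = extra_lesion_prob,
              image_size = as.integer(rep_len(image_size, 2L)),
              sensitivity = sensitivity, rho = rho, fp_rate = fp_rate,
              tp_score = tp_score, fp_score = fp_score, box_jitter = box_jitter,
              lesion_size_px = as.numeric(lesion_size_px),
              followup_noise_factor = followup_noise_factor,
              seed = as.integer(seed))
  stopifnot(
    cfg$n_pairs >= 1L,
    cfg$extra_lesion_prob >= 0, cfg$extra_lesion_prob <= 1,
    all(cfg$image_size > 0L),
    cfg$sensitivity >= 0, cfg$sensitivity <= 1,
    cfg$rho >= 0, cfg$rho <= 1,
    cfg$fp_rate >= 0,
    is.function(cfg$tp_score), is.function(cfg$fp_score),
    cfg$box_jitter >= 0, cfg$box_jitter <= 0.18,
    length(cfg$lesion_size_px) == 2L, all(cfg$lesion_size_px > 0),
    diff(cfg$lesion_size_px) >= 0,
    cfg$followup_noise_factor >= 1
  )
  if (max(cfg$lesion_size_px) * 3 > min(cfg$image_size)) {
    stop_reprocad("infeasible_geometry",
                  "image too small to place non-overlapping lesions of the requested size")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a paired-exam dataset with known reproducibility structure
#'
#' For each lesion the two per-exam detection events follow a shared-draw
#' mixture: with probability `rho` both exams reuse one Bernoulli(`s`) draw,
#' otherwise each exam draws independently. Detected lesions emit a
#' detection whose box is a jittered copy of the lesion box (jitter bounded
#' so the IoU hit criterion at 0.5 always holds) with a `tp_score`
#' confidence; each exam additionally receives `Poisson(fp_rate)` false
#' positives at locations kept clear of every lesion, with `fp_score`
#' confidences. Under this mechanism the expected percent positive
#' agreement has the closed form given by [expected_ppa()].
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a [cad_dataset()]) and `truth` (a
#'   `sim_truth`: the config plus the per-lesion latent detection events).
#' @export
simulate_paired_detections <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_paired_detections_impl(config))
}

simulate_paired_detections_impl <- function(config) {
  n <- config$n_pairs
  W <- config$image_size[1]; H <- config$image_size[2]
  patient_id <- sprintf("P%05d", seq_len(n))
  exam_i <- paste0(patient_id, "-I")
  exam_f <- paste0(patient_id, "-F")
  exams <- tibble::tibble(
    patient_id = rep(patient_id, each = 2L),
    exam_id = as.vector(rbind(exam_i, exam_f)),
    role = rep(c("initial", "followup"), times = n),
    width = as.numeric(W), height = as.numeric(H)
  )

  n_les <- 1L + rbinom(n, 1L, config$extra_lesion_prob)
  pair_of <- rep.int(seq_len(n), n_les)
  L <- length(pair_of)
  lesion_id <- unlist(lapply(n_les, function(k) paste0("L", seq_len(k))), use.names = FALSE)

  # lesion geometry in the initial exam; second lesions re-drawn until the
  # two boxes of a pair are disjoint with a clear margin
  w <- runif(L, config$lesion_size_px[1], config$lesion_size_px[2])
  h <- runif(L, config$lesion_size_px[1], config$lesion_size_px[2])
  cx <- runif(L, w / 2, W - w / 2)
  cy <- runif(L, h / 2, H - h / 2)
  second <- which(duplicated(pair_of))
  for (i in second) {
    first <- match(pair_of[i], pair_of)
    repeat {
      gap_x <- abs(cx[i] - cx[first]) - (w[i] + w[first]) / 2
      gap_y <- abs(cy[i] - cy[first]) - (h[i] + h[first]) / 2
      if (max(gap_x, gap_y) > 0.25 * max(w[i], h[i])) break
      cx[i] <- runif(1, w[i] / 2, W - w[i] / 2)
      cy[i] <- runif(1, h[i] / 2, H - h[i] / 2)
    }
  }
  box_i <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  # follow-up ground truth: same lesions, slightly displaced acquisition
  box_f <- jitter_boxes(box_i, config$box_jitter, W, H)

  lesions <- tibble::tibble(
    exam_id = c(exam_i[pair_of], exam_f[pair_of]),
    lesion_id = rep(lesion_id, 2L),
    x_min = c(box_i[, 1], box_f[, 1]), y_min = c(box_i[, 2], box_f[, 2]),
    x_max = c(box_i[, 3], box_f[, 3]), y_max = c(box_i[, 4], box_f[, 4]),
    size_mm = rep(round(pmax(w, h) * 0.25, 1), 2L)
  )

  # latent detection events: shared-draw mixture
  s <- config$sensitivity
  z_shared <- rbinom(L, 1L, s)
  shared <- runif(L) < config$rho
  z_i <- ifelse(shared, z_shared, rbinom(L, 1L, s)) == 1L
  z_f <- ifelse(shared, z_shared, rbinom(L, 1L, s)) == 1L

  tp <- function(z, gt_box, exam_ids) {
    k <- which(z)
    if (!length(k)) return(empty_detections())
    tibble::tibble(
      exam_id = exam_ids[k],
      as_box_tibble(jitter_boxes(gt_box[k, , drop = FALSE], config$box_jitter, W, H)),
      confidence = clamp01(config$tp_score(length(k)))
    )
  }
  det_tp <- dplyr::bind_rows(tp(z_i, box_i, exam_i[pair_of]),
                             tp(z_f, box_f, exam_f[pair_of]))
  det_fp <- simulate_false_positives(config, exams$exam_id,
                                     lesions, W, H)
  detections <- dplyr::bind_rows(det_tp, det_fp)

  dataset <- cad_dataset(exams, lesions, detections)
  truth <- structure(list(
    config = config,
    events = tibble::tibble(
      patient_id = patient_id[pair_of], lesion_id = lesion_id,
      shared_draw = shared, detected_initial = z_i, detected_followup = z_f
    )
  ), class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

# Poisson false positives per exam, rejected until essentially clear of
# every ground-truth lesion of that exam (IoU <= 0.1, far below the hit
# criterion, so a false positive can never claim a lesion).
simulate_false_positives <- function(config, exam_ids, lesions, W, H) {
  counts <- rpois(length(exam_ids), config$fp_rate)
  total <- sum(counts)
  if (total == 0L) return(empty_detections())
  exam_of <- rep.int(exam_ids, counts)
  draw <- function(m) {
    fw <- runif(m, config$lesion_size_px[1], config$lesion_size_px[2])
    fh <- runif(m, config$lesion_size_px[1], config$lesion_size_px[2])
    fx <- runif(m, fw / 2, W - fw / 2)
    fy <- runif(m, fh / 2, H - fh / 2)
    cbind(fx - fw / 2, fy - fh / 2, fx + fw / 2, fy + fh / 2)
  }
  boxes <- draw(total)
  les_split <- split(seq_len(nrow(lesions)), lesions$exam_id)
  les_box <- as.matrix(lesions[c("x_min", "y_min", "x_max", "y_max")])
  max_iou_vs_gt <- function(idx) {
    vapply(idx, function(i) {
      li <- les_split[[exam_of[i]]]
      if (!length(li)) return(0)
      max(box_iou(les_box[li, , drop = FALSE],
                  boxes[rep(i, length(li)), , drop = FALSE]))
    }, numeric(1))
  }
  check <- seq_len(total)
  for (iter in 1:100) {
    bad <- check[max_iou_vs_gt(check) > 0.1]
    if (!length(bad)) break
    boxes[bad, ] <- draw(length(bad))
    check <- bad
  }
  tibble::tibble(
    exam_id = exam_of,
    as_box_tibble(boxes),
    confidence = clamp01(config$fp_score(total))
  )
}

# Translate boxes by a uniform fraction (at most `max_frac`) of their side
# lengths, clamped to the image; shape is preserved so the IoU with the
# original box is ((1-a)(1-b)) / (2 - (1-a)(1-b)) > 0.5 whenever
# max_frac <= 0.18.
jitter_boxes <- function(boxes, max_frac, W, H) {
  m <- nrow(boxes)
  if (m == 0L || max_frac == 0) return(boxes)
  w <- boxes[, 3] - boxes[, 1]
  h <- boxes[, 4] - boxes[, 2]
  dx <- runif(m, -max_frac, max_frac) * w
  dy <- runif(m, -max_frac, max_frac) * h
  dx <- pmin(pmax(dx, -boxes[, 1]), W - boxes[, 3])
  dy <- pmin(pmax(dy, -boxes[, 2]), H - boxes[, 4])
  boxes + cbind(dx, dy, dx, dy)
}

as_box_tibble <- function(m) {
  tibble::tibble(x_min = m[, 1], y_min = m[, 2], x_max = m[, 3], y_max = m[, 4])
}

# keep scores strictly inside [0,1] (and away from exact 0 so a permissive
# threshold of 0 retains every detection)
clamp01 <- function(x) pmin(pmax(x, 1e-12), 1)

#' Expected agreement under the simulator's detection mechanism
#'
#' Under the shared-draw mixture with per-exam sensitivity `s` and
#' correlation `rho`, the per-lesion paired outcomes have probabilities
#' `P(a) = rho * s + (1 - rho) * s^2` and `P(b) + P(c) = 2 (1 - rho) s (1 - s)`,
#' so the percent positive agreement converges to
#' `100 * (rho + (1 - rho) * s)` and Chamberlain's variant to its identity
#' transform `100 * p / (200 - p)`.
#'
#' @param s Sensitivity in `(0, 1]`.
#' @param rho Between-exam correlation in `[0, 1]`.
#' @return Expected percentage in `[0, 100]`.
#' @examples
#' expected_ppa(0.8, 0)     # 80
#' expected_cppa(0.8, 0)    # 66.67
#' @export
expected_ppa <- function(s, rho) {
  if (any(s <= 0)) {
    stop_reprocad("undefined_agreement", "expected agreement is undefined at s = 0 (nothing is ever detected)")
  }
  stopifnot(all(s <= 1), all(rho >= 0 & rho <= 1))
  100 * (rho + (1 - rho) * s)
}

#' @rdname expected_ppa
#' @export
expected_cppa <- function(s, rho) {
  cppa_from_ppa(expected_ppa(s, rho))
}
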