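#' Free-response ROC curve across exams
#'
#' Sweeps the confidence threshold over every distinct detection confidence
#' (descending) and records, at each threshold, the fraction of lesions hit
#' (sensitivity) and the mean number of surviving false positives per exam.
#'
#' @param matches List of `exam_match` objects, one per exam
#'   (see [match_dataset()]).
#' @return A `froc_curve`: tibble with columns `tau`, `avg_fp`,
#'   `sensitivity`, ordered by decreasing `tau`; attributes `n_exams` and
#'   `n_lesions`. As `tau` decreases, `avg_fp` and `sensitivity` are both
#'   non-decreasing.
#' @export
froc_curve <- function(matches) {
  stopifnot(length(matches) > 0L)
  hit_conf <- unlist(lapply(matches, function(m) m$hits$confidence), use.names = FALSE)
  fp_conf <- unlist(lapply(matches, function(m) m$false_positives$confidence), use.names = FALSE)
  n_lesions <- sum(vapply(matches, function(m) as.numeric(m$n_lesions), numeric(1)))
  n_exams <- length(matches)
  if (n_lesions == 0L) {
    stop_reprocad("no_lesions", "FROC sensitivity is undefined without ground-truth lesions")
  }
  taus <- sort(unique(c(hit_conf, fp_conf)), decreasing = TRUE)
  curve <- tibble::tibble(
    tau = taus,
    avg_fp = cumsum(tabulate(match(fp_conf, taus), nbins = length(taus))) / n_exams,
    sensitivity = cumsum(tabulate(match(hit_conf, taus), nbins = length(taus))) / n_lesions
  )
  structure(curve, n_exams = n_exams, n_lesions = n_lesions,
            class = c("froc_curve", class(curve)))
}

#' Operating threshold at a false-positive budget
#'
#' Returns the confidence cut-off realizing the highest sensitivity whose
#' average false-positive rate stays within `fp_target`: the smallest `tau`
#' on the curve with `avg_fp <= fp_target`. If even the strictest threshold
#' exceeds the budget, `Inf` is returned (the detector is silenced).
#'
#' @param curve A [froc_curve()].
#' @param fp_target Non-negative target average false positives per image.
#' @return A single confidence threshold.
#' @export
threshold_at_fp <- function(curve, fp_target) {
  stopifnot(inherits(curve, "froc_curve"), nrow(curve) > 0L)
  if (!is.numeric(fp_target) || length(fp_target) != 1L || is.na(fp_target) || fp_target < 0) {
    stop_reprocad("bad_fp_target", "fp_target must be a single non-negative number")
  }
  ok <- curve$avg_fp <= fp_target
  if (!any(ok)) return(Inf)
  min(curve$tau[ok])
}

#' JAFROC figure of merit
#'
#' The figure of merit is the probability-like score that a lesion's rating
#' beats the highest false-positive rating of an image, averaged over all
#' (image, lesion) pairs:
#' \deqn{FOM = \frac{1}{N_I N_L} \sum_{i=1}^{N_I} \sum_{l=1}^{N_L} \psi(F_i, r_l)}
#' where \eqn{r_l} is the confidence of the detection that hit lesion
#' \eqn{l} (undetected lesions rate \eqn{-\infty}), \eqn{F_i} is the highest
#' false-positive confidence in image \eqn{i} (\eqn{-\infty} if none), and
#' \eqn{\psi} scores 1 when \eqn{r_l > F_i}, 1/2 when they are equal
#' (including the doubly-undetected \eqn{-\infty} pair) and 0 otherwise.
#' Because every exam in this setting contains at least one lesion, the
#' variant using the highest false positive of *every* image is used. The
#' result is invariant under any strictly increasing transform of the
#' confidences.
#'
#' @param matches List of `exam_match` objects, one per exam.
#' @return A value in `[0, 1]`; 1 for a perfect detector, 0.5 when no
#'   detection was produced at all.
#' @export
jafroc_fom <- function(matches) {
  r <- lesion_ratings(matches)
  f <- image_fp_ratings(matches)
  if (length(r) == 0L) {
    stop_reprocad("no_lesions", "the figure of merit is undefined without lesions")
  }
  fs <- sort(f)
  lt <- findInterval(r, fs, left.open = TRUE)   # false positives rated strictly below r
  le <- findInterval(r, fs)                     # rated at or below r
  sum(lt + 0.5 * (le - lt)) / (length(r) * length(f))
}

# Per-lesion rating: confidence of the hit detection, -Inf for a miss.
lesion_ratings <- function(matches) {
  unlist(lapply(matches, function(m) {
    c(m$hits$confidence, rep(-Inf, length(m$missed)))
  }), use.names = FALSE)
}

# Per-image highest false-positive rating, -Inf when the image has none.
image_fp_ratings <- function(matches) {
  vapply(matches, function(m) {
    if (nrow(m$false_positives)) max(m$false_positives$confidence) else -Inf
  }, numeric(1), USE.NAMES = FALSE)
}

#' Figure of merit with a resampled 95% confidence interval
#'
#' Point estimate of the JAFROC figure of merit on the full dataset plus a
#' patient-level resampling interval: by default a percentile bootstrap
#' (patients drawn with replacement, both exams of a drawn patient enter the
#' resample), alternatively leave-one-patient-out jackknife pseudovalues
#' with a t-interval.
#'
#' @param dataset A [cad_dataset()].
#' @param n_boot Number of bootstrap resamples (ignored for the jackknife);
#'   at least 100.
#' @param seed Integer seed making the interval reproducible.
#' @param method `"bootstrap"` (percentile, default) or `"jackknife"`.
#' @param iou_threshold,strict Passed to [match_dataset()].
#' @return A `fom_result`: list with `fom`, `ci_low`, `ci_high`, `n_boot`,
#'   `seed`, `method`.
#' @export
fom_ci <- function(dataset, n_boot = 2000L, seed = 1L,
                   method = c("bootstrap", "jackknife"),
                   iou_threshold = 0.5, strict = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "cad_dataset"))
  if (method == "bootstrap" && n_boot < 100L) {
    stop_reprocad("bad_n_boot", "n_boot must be at least 100")
  }
  pairs <- exam_pairs(dataset)
  if (nrow(pairs) < 2L) {
    stop_reprocad("too_few_patients", "resampling needs at least 2 patients")
  }
  matches <- match_dataset(dataset, iou_threshold = iou_threshold, strict = strict)

  # patient-level sufficient statistics: lesion ratings and per-image max FP
  by_patient <- lapply(seq_len(nrow(pairs)), function(k) {
    ms <- matches[c(pairs$initial_exam_id[k], pairs$followup_exam_id[k])]
    list(r = lesion_ratings(ms), f = image_fp_ratings(ms))
  })
  fom_of <- function(idx) {
    r <- unlist(lapply(by_patient[idx], `[[`, "r"), use.names = FALSE)
    f <- unlist(lapply(by_patient[idx], `[[`, "f"), use.names = FALSE)
    if (!length(r)) return(NA_real_)
    fs <- sort(f)
    lt <- findInterval(r, fs, left.open = TRUE)
    le <- findInterval(r, fs)
    sum(lt + 0.5 * (le - lt)) / (length(r) * length(f))
  }
  n <- nrow(pairs)
  fom <- fom_of(seq_len(n))

  if (method == "bootstrap") {
    stat <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          v <- fom_of(sample.int(n, n, replace = TRUE))
          if (!is.na(v)) return(v)   # redraw resamples that carry no lesion
        }
      }, numeric(1))
    })
    ci <- unname(quantile(stat, c(0.025, 0.975), type = 7))
  } else {
    pseudo <- vapply(seq_len(n), function(k) {
      n * fom - (n - 1) * fom_of(setdiff(seq_len(n), k))
    }, numeric(1))
    half <- qt(0.975, df = n - 1) * sd(pseudo) / sqrt(n)
    ci <- mean(pseudo) + c(-half, half)
    ci <- pmin(pmax(ci, 0), 1)
    n_boot <- NA_integer_
  }
  structure(list(fom = fom, ci_low = min(ci[1], fom), ci_high = max(ci[2], fom),
                 n_boot = n_boot, seed = seed, method = method),
            class = "fom_result")
}

#' @export
print.fom_result <- function(x, ...) {
  cat(sprintf("FOM %.2f (95%% CI %.2f-%.2f; %s)\n",
              x$fom, x$ci_low, x$ci_high, x$method))
  invisible(x)
}
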