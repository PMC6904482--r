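#' Percent positive agreement and Chamberlain's variant
#'
#' Given the paired confusion counts — `a` lesions detected in both the
#' initial and the follow-up exam, `b` detected only in the initial exam,
#' `c` only in the follow-up — the two agreement statistics are
#' \deqn{PPA = 100 \cdot \frac{2a}{2a + b + c}, \qquad
#'       CPPA = 100 \cdot \frac{a}{a + b + c}.}
#' The count `d` (detected in neither exam) never enters either statistic.
#' For any single confusion the two are linked by
#' `CPPA = 100 * PPA / (200 - PPA)`; see [cppa_from_ppa()].
#'
#' @param a,b,c Non-negative counts, not all zero. Vectorized.
#' @return Percentage(s) in `[0, 100]`.
#' @examples
#' compute_ppa(104, 6, 5)   # 94.98 at 2 dp
#' compute_cppa(104, 6, 5)  # 90.43 at 2 dp
#' @export
compute_ppa <- function(a, b, c) {
  check_confusion(a, b, c)
  100 * 2 * a / (2 * a + b + c)
}

#' @rdname compute_ppa
#' @export
compute_cppa <- function(a, b, c) {
  check_confusion(a, b, c)
  100 * a / (a + b + c)
}

check_confusion <- function(a, b, c) {
  if (any(c(a, b, c) < 0) || anyNA(c(a, b, c))) {
    stop_reprocad("bad_counts", "confusion counts a, b, c must be non-negative")
  }
  if (any(a + b + c == 0)) {
    stop_reprocad("undefined_agreement",
                  "agreement is undefined when no lesion was detected in either exam (a = b = c = 0)")
  }
  invisible(NULL)
}

#' Convert between PPA and CPPA for a single confusion
#'
#' For one set of counts `(a, b, c)` the two agreement statistics determine
#' each other: `CPPA = 100 * PPA / (200 - PPA)` and inversely
#' `PPA = 200 * CPPA / (100 + CPPA)`. The identity does not survive
#' averaging over several operating points.
#'
#' @param ppa,cppa Percentage in `[0, 100]`.
#' @return The other statistic, as a percentage.
#' @examples
#' cppa_from_ppa(96.55)  # 93.33 at 2 dp
#' ppa_from_cppa(93.33)  # 96.55 at 2 dp
#' @export
cppa_from_ppa <- function(ppa) {
  stopifnot(is.numeric(ppa), all(ppa >= 0 & ppa <= 100))
  100 * ppa / (200 - ppa)
}

#' @rdname cppa_from_ppa
#' @export
ppa_from_cppa <- function(cppa) {
  stopifnot(is.numeric(cppa), all(cppa >= 0 & cppa <= 100))
  200 * cppa / (100 + cppa)
}

#' Paired confusion counts at an operating threshold
#'
#' Tallies, per ground-truth lesion across all exam pairs, whether its hit
#' detection survives the confidence cut-off `tau` in the initial and in the
#' follow-up exam: `a` survives in both, `b` initial only, `c` follow-up
#' only, `d` neither. With `unit = "exam"` the tally is per exam pair
#' instead: an exam counts as positive when at least one of its lesions is
#' detected.
#'
#' @param dataset A [cad_dataset()].
#' @param matches Named list of `exam_match` objects from [match_dataset()].
#' @param tau Finite confidence threshold.
#' @param unit `"lesion"` (default) or `"exam"`.
#' @return A `paired_confusion`: named integer vector `c(a, b, c, d)` with
#'   `a + b + c + d` equal to the number of counting units.
#' @export
paired_confusion <- function(dataset, matches, tau, unit = c("lesion", "exam")) {
  unit <- match.arg(unit)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau)) {
    stop_reprocad("bad_tau", "tau must be a single number (may be -Inf/Inf to keep/drop everything)")
  }
  ht <- lesion_hit_table(dataset, matches)
  det_i <- !is.na(ht$conf_initial) & ht$conf_initial >= tau
  det_f <- !is.na(ht$conf_followup) & ht$conf_followup >= tau
  if (unit == "exam") {
    det_i <- tapply(det_i, ht$patient_id, any)
    det_f <- tapply(det_f, ht$patient_id, any)
  }
  out <- c(a = sum(det_i & det_f), b = sum(det_i & !det_f),
           c = sum(!det_i & det_f), d = sum(!det_i & !det_f))
  structure(as.integer(out), names = names(out), class = "paired_confusion")
}

# One row per (patient, lesion): confidence of the surviving hit in each
# exam of the pair, NA when the lesion was not hit at any threshold.
lesion_hit_table <- function(dataset, matches) {
  stopifnot(inherits(dataset, "cad_dataset"))
  pairs <- exam_pairs(dataset)
  hit_conf <- function(exam_ids) {
    hits <- lapply(matches[exam_ids], function(m) m$hits)
    h <- dplyr::bind_rows(hits, .id = "exam_id")
    stats::setNames(h$confidence, paste(h$exam_id, h$lesion_id, sep = "\r"))
  }
  les <- dplyr::left_join(dataset$lesions,
                          dataset$exams[c("exam_id", "patient_id", "role")],
                          by = "exam_id")
  ini <- les[les$role == "initial", c("patient_id", "lesion_id", "exam_id")]
  ci <- hit_conf(pairs$initial_exam_id)
  cf <- hit_conf(pairs$followup_exam_id)
  fu_exam <- stats::setNames(pairs$followup_exam_id, pairs$patient_id)
  tibble::tibble(
    patient_id = ini$patient_id,
    lesion_id = ini$lesion_id,
    conf_initial = unname(ci[paste(ini$exam_id, ini$lesion_id, sep = "\r")]),
    conf_followup = unname(cf[paste(fu_exam[ini$patient_id], ini$lesion_id, sep = "\r")])
  )
}

#' Agreement across a set of false-positive operating points
#'
#' Runs the full reproducibility analysis: matches every exam, builds the
#' FROC curve (from the initial exams by default), selects the confidence
#' threshold realizing each target average-false-positive rate, computes the
#' paired confusion plus PPA and CPPA at each operating point, and reports
#' the mean and population standard deviation over the operating points.
#'
#' @param dataset A [cad_dataset()].
#' @param fp_targets Increasing positive vector of target average false
#'   positives per image; default `c(0.1, 0.2, 0.3, 0.4, 0.5)`.
#' @param iou_threshold,strict Hit criterion, see [match_exam()].
#' @param froc_source `"initial"` (default) builds the operating-point FROC
#'   from the initial exams only; `"both"` uses all exams.
#' @param unit Counting unit for the confusion, see [paired_confusion()].
#' @return An `agreement_result`: list with tibble `per_threshold`
#'   (`fp_target`, `tau`, `a`, `b`, `c`, `d`, `sensitivity`, `ppa`, `cppa`)
#'   and summaries `ppa_mean`, `ppa_sd`, `cppa_mean`, `cppa_sd` (the sd is
#'   the population form, dividing by the number of operating points).
#' @export
agreement_over_thresholds <- function(dataset,
                                      fp_targets = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                      iou_threshold = 0.5, strict = TRUE,
                                      froc_source = c("initial", "both"),
                                      unit = c("lesion", "exam")) {
  froc_source <- match.arg(froc_source)
  unit <- match.arg(unit)
  if (!length(fp_targets) || any(fp_targets <= 0) || is.unsorted(fp_targets, strictly = TRUE)) {
    stop_reprocad("bad_fp_target", "fp_targets must be a non-empty, strictly increasing, positive vector")
  }
  matches <- match_dataset(dataset, iou_threshold = iou_threshold, strict = strict)
  pairs <- exam_pairs(dataset)
  froc_ids <- if (froc_source == "initial") pairs$initial_exam_id else dataset$exams$exam_id
  curve <- froc_curve(matches[froc_ids])
  ht <- lesion_hit_table(dataset, matches)

  rows <- lapply(fp_targets, function(tgt) {
    tau <- threshold_at_fp(curve, tgt)
    det_i <- !is.na(ht$conf_initial) & ht$conf_initial >= tau
    det_f <- !is.na(ht$conf_followup) & ht$conf_followup >= tau
    if (unit == "exam") {
      det_i <- tapply(det_i, ht$patient_id, any)
      det_f <- tapply(det_f, ht$patient_id, any)
    }
    a <- sum(det_i & det_f); b <- sum(det_i & !det_f)
    cc <- sum(!det_i & det_f); d <- sum(!det_i & !det_f)
    pos <- a + b + cc
    sens <- if (is.finite(tau)) {
      sum(vapply(matches[pairs$initial_exam_id],
                 function(m) sum(m$hits$confidence >= tau), numeric(1))) /
        sum(ht$lesion_id != "")  # lesions per exam role are equal by pairing
    } else 0
    tibble::tibble(
      fp_target = tgt, tau = tau, a = a, b = b, c = cc, d = d,
      sensitivity = sens,
      ppa = if (pos > 0) compute_ppa(a, b, cc) else NA_real_,
      cppa = if (pos > 0) compute_cppa(a, b, cc) else NA_real_
    )
  })
  per_threshold <- dplyr::bind_rows(rows)
  if (anyNA(per_threshold$ppa)) {
    warning("agreement undefined at some operating points (no lesion detected in either exam)",
            call. = FALSE)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(
    per_threshold = per_threshold,
    ppa_mean = mean(per_threshold$ppa), ppa_sd = pop_sd(per_threshold$ppa),
    cppa_mean = mean(per_threshold$cppa), cppa_sd = pop_sd(per_threshold$cppa),
    unit = unit, froc_source = froc_source, iou_threshold = iou_threshold
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement over %d operating points (per-%s counting):\n",
              nrow(x$per_threshold), x$unit))
  df <- x$per_threshold
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  avg FP %.2f  tau %-8s a=%d b=%d c=%d d=%d  PPA %6.2f  CPPA %6.2f\n",
                df$fp_target[i], formatC(df$tau[i], digits = 4, format = "g"),
                df$a[i], df$b[i], df$c[i], df$d[i], df$ppa[i], df$cppa[i]))
  }
  cat(sprintf("  PPA  %.2f +/- %.2f\n  CPPA %.2f +/- %.2f\n",
              x$ppa_mean, x$ppa_sd, x$cppa_mean, x$cppa_sd))
  invisible(x)
}
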