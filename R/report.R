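#' Run the full reproducibility evaluation on a dataset
#'
#' One call producing everything the analysis reports: the JAFROC figure of
#' merit with its resampled 95% confidence interval, the FROC curve, and
#' PPA/CPPA with per-operating-point confusion grids aggregated over the
#' false-positive targets.
#'
#' @param dataset A [cad_dataset()].
#' @param method_name Label for the detector being evaluated.
#' @param fp_targets Target average false positives per image at which
#'   operating thresholds are selected.
#' @param iou_threshold,strict Hit criterion, see [match_exam()].
#' @param n_boot,ci_method Confidence-interval settings, see [fom_ci()].
#' @param seed Seed for the resampling.
#' @param unit,froc_source See [agreement_over_thresholds()].
#' @return A `cad_report`: list with `method`, `fom` ([fom_ci()] result),
#'   `agreement` ([agreement_over_thresholds()] result), `froc`
#'   ([froc_curve()]), and the settings used.
#' @export
evaluate_dataset <- function(dataset, method_name = "detector",
                             fp_targets = c(0.1, 0.2, 0.3, 0.4, 0.5),
                             iou_threshold = 0.5, strict = TRUE,
                             n_boot = 2000L, ci_method = "bootstrap",
                             seed = 1L, unit = "lesion",
                             froc_source = "initial") {
  stopifnot(inherits(dataset, "cad_dataset"))
  agreement <- agreement_over_thresholds(
    dataset, fp_targets = fp_targets, iou_threshold = iou_threshold,
    strict = strict, froc_source = froc_source, unit = unit
  )
  matches <- match_dataset(dataset, iou_threshold = iou_threshold, strict = strict)
  froc <- froc_curve(matches)
  fom <- fom_ci(dataset, n_boot = n_boot, seed = seed, method = ci_method,
                iou_threshold = iou_threshold, strict = strict)
  structure(list(
    method = method_name,
    fom = fom,
    agreement = agreement,
    froc = froc,
    settings = list(fp_targets = fp_targets, iou_threshold = iou_threshold,
                    strict = strict, n_boot = n_boot, ci_method = ci_method,
                    seed = seed, unit = unit, froc_source = froc_source,
                    n_pairs = nrow(exam_pairs(dataset)))
  ), class = "cad_report")
}

#' @export
print.cad_report <- function(x, ...) {
  cat(sprintf("== %s: reproducibility report over %d exam pairs ==\n",
              x$method, x$settings$n_pairs))
  cat(sprintf("FOM  %.2f (95%% CI %.2f-%.2f)\n", x$fom$fom, x$fom$ci_low, x$fom$ci_high))
  cat(sprintf("PPA  %.2f +/- %.2f %%\nCPPA %.2f +/- %.2f %%\n",
              x$agreement$ppa_mean, x$agreement$ppa_sd,
              x$agreement$cppa_mean, x$agreement$cppa_sd))
  print(x$agreement)
  invisible(x)
}

#' Write a report to disk
#'
#' Emits `report.json` (all numbers at full precision), a human-readable
#' `report.txt` (two-decimal formatting), the FROC curve as `froc.csv`, and
#' optionally the FROC figure as a PNG. Output is byte-identical across
#' reruns with identical inputs.
#'
#' @param report A `cad_report` from [evaluate_dataset()].
#' @param dir Output directory, created if needed.
#' @param plot Also write `froc.png`.
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, dir, plot = FALSE) {
  stopifnot(inherits(report, "cad_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(dir, "report.json"),
             txt = file.path(dir, "report.txt"),
             froc = file.path(dir, "froc.csv"))
  jsonlite::write_json(report_as_list(report), paths[["json"]],
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  writeLines(utils::capture.output(print(report)), paths[["txt"]])
  readr::write_csv(tibble::as_tibble(report$froc), paths[["froc"]])
  if (plot) {
    paths <- c(paths, png = file.path(dir, "froc.png"))
    ggplot2::ggsave(paths[["png"]], plot_froc(report$froc),
                    width = 5, height = 4, dpi = 150)
  }
  invisible(paths)
}

# JSON-friendly view of a report, mirroring the usual table layout
# (method, FOM + CI, PPA/CPPA mean +/- sd) plus the per-threshold a/b/c/d grids.
report_as_list <- function(report) {
  ag <- report$agreement
  list(
    method = report$method,
    settings = report$settings,
    fom = list(fom = report$fom$fom, ci_low = report$fom$ci_low,
               ci_high = report$fom$ci_high, method = report$fom$method,
               n_boot = report$fom$n_boot, seed = report$fom$seed),
    ppa = list(mean = ag$ppa_mean, sd = ag$ppa_sd, sd_type = "population"),
    cppa = list(mean = ag$cppa_mean, sd = ag$cppa_sd, sd_type = "population"),
    per_threshold = lapply(seq_len(nrow(ag$per_threshold)), function(i) {
      r <- ag$per_threshold[i, ]
      list(fp_target = r$fp_target, tau = r$tau,
           confusion = list(a = r$a, b = r$b, c = r$c, d = r$d),
           sensitivity = r$sensitivity, ppa = r$ppa, cppa = r$cppa)
    }),
    froc = list(tau = report$froc$tau, avg_fp = report$froc$avg_fp,
                sensitivity = report$froc$sensitivity)
  )
}

#' Plot a FROC curve
#'
#' @param curve A [froc_curve()], or a list of them named by method.
#' @return A ggplot object: sensitivity against average false positives per
#'   image.
#' @export
plot_froc <- function(curve) {
  if (inherits(curve, "froc_curve")) curve <- list(detector = curve)
  df <- dplyr::bind_rows(lapply(curve, tibble::as_tibble), .id = "method")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg_fp, y = .data$sensitivity,
                                   colour = .data$method)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "average false positives per image",
                  y = "lesion sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}
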