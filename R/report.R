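## AuditResult container and reporting: every auditor returns a comparable
## object holding per-round AUCs, the auditor-specific reference
## performance, their delta and a verdict; broom-style tidy()/glance() and
## autoplot() methods, and JSON/TSV serialization for whole reports.

new_audit_result <- function(auditor, per_round_auc, reference_auc,
                             verdict, tolerance, details = list()) {
  stopifnot(length(per_round_auc) >= 1)
  mean_auc <- mean(per_round_auc)
  structure(
    list(
      auditor = auditor,
      per_round_auc = as.numeric(per_round_auc),
      mean_auc = mean_auc,
      reference_auc = reference_auc,
      delta = mean_auc - reference_auc,
      verdict = verdict,
      tolerance = tolerance,
      details = details
    ),
    class = "audit_result"
  )
}

#' @export
print.audit_result <- function(x, ...) {
  cat(sprintf(
    "<audit_result> %s\n  mean AUC %.3f | reference %.3f | delta %+.3f | %s (tol %.2f)\n",
    x$auditor, x$mean_auc, x$reference_auc, x$delta, x$verdict, x$tolerance
  ))
  invisible(x)
}

#' @describeIn tidy-audit Per-round AUCs of one auditor.
#' @export
tidy.audit_result <- function(x, ...) {
  tibble(
    auditor = x$auditor,
    round = seq_along(x$per_round_auc),
    auc = x$per_round_auc
  )
}

#' Tidy and one-row summaries of audit results
#'
#' `tidy()` returns one row per round with its AUC; `glance()` returns a
#' one-row summary (mean AUC, reference, delta, verdict, tolerance).
#'
#' @param x An `audit_result` or `audit_report`.
#' @param ... Unused.
#' @name tidy-audit
#' @return A tibble.
NULL

#' @describeIn tidy-audit One-row summary of one auditor.
#' @export
glance.audit_result <- function(x, ...) {
  tibble(
    auditor = x$auditor,
    n_rounds = length(x$per_round_auc),
    mean_auc = x$mean_auc,
    sd_auc = stats::sd(x$per_round_auc),
    reference_auc = x$reference_auc,
    delta = x$delta,
    verdict = x$verdict,
    tolerance = x$tolerance
  )
}

#' @export
autoplot.audit_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$round, y = .data$auc)) +
    ggplot2::geom_hline(yintercept = object$reference_auc,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = object$auditor,
      subtitle = sprintf("mean AUC %.3f vs reference %.3f (%s)",
                         object$mean_auc, object$reference_auc,
                         object$verdict),
      x = "round", y = "AUC"
    ) +
    ggplot2::theme_minimal()
}

new_audit_report <- function(results, narrative, metadata = list()) {
  stopifnot(all(vapply(results, inherits, logical(1), "audit_result")))
  structure(
    list(results = results, narrative = narrative, metadata = metadata),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>", length(x$results), "auditor(s)\n")
  print(glance(x))
  cat("\n", x$narrative, "\n", sep = "")
  invisible(x)
}

#' @describeIn tidy-audit Per-round AUCs of every auditor in a report.
#' @export
tidy.audit_report <- function(x, ...) {
  dplyr::bind_rows(lapply(x$results, tidy))
}

#' @describeIn tidy-audit One row per auditor in a report.
#' @export
glance.audit_report <- function(x, ...) {
  dplyr::bind_rows(lapply(x$results, glance))
}

#' @export
autoplot.audit_report <- function(object, ...) {
  dat <- tidy(object)
  refs <- glance(object)[c("auditor", "reference_auc")]
  dat$auditor <- factor(dat$auditor, levels = unique(dat$auditor))
  refs$auditor <- factor(refs$auditor, levels = levels(dat$auditor))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$auditor, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::geom_point(data = refs,
                        ggplot2::aes(y = .data$reference_auc),
                        shape = 4, size = 3, colour = "red") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "per-round AUC",
                  caption = "red cross: auditor's reference performance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write an audit report to a run directory
#'
#' Writes `report.json` (metadata plus one record per auditor), a
#' companion `per_round_auc.tsv`, and `verdict.txt` with the narrative.
#'
#' @param report An `audit_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- lapply(report$results, function(r) {
    list(
      auditor = r$auditor,
      per_round_auc = r$per_round_auc,
      mean_auc = r$mean_auc,
      reference_auc = r$reference_auc,
      delta = r$delta,
      verdict = r$verdict,
      tolerance = r$tolerance
    )
  })
  jsonlite::write_json(
    list(metadata = report$metadata, narrative = report$narrative,
         results = records),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  utils::write.table(tidy(report), file.path(dir, "per_round_auc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$narrative, file.path(dir, "verdict.txt"))
  invisible(dir)
}

#' Read an audit report back from a run directory
#'
#' @param dir Directory written by [write_report()], or a path to a
#'   `report.json`.
#' @return An `audit_report`.
#' @export
read_report <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "report.json") else dir
  if (!file.exists(path)) abort(paste0("no report found at ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(raw$results) || length(raw$results) == 0) {
    abort("report contains no auditor results")
  }
  results <- lapply(raw$results, function(r) {
    new_audit_result(r$auditor, unlist(r$per_round_auc), r$reference_auc,
                     r$verdict, r$tolerance)
  })
  new_audit_report(results, raw$narrative %||% "", raw$metadata %||% list())
}
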