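#' Validation configuration
#'
#' @param alpha significance threshold on the expression-change p-value
#'   (default 0.01). Direction is fixed: only negative expression changes
#'   (knock-down) count as true off-targets.
#' @return object of class `"validation_config"`.
#' @export
validation_config <- function(alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(alpha = alpha, direction = "negative"),
            class = "validation_config")
}

#' Construct / check an expression-change table
#'
#' One row per transcript: `accession`, `log_ratio` (signed expression
#' change relative to the mock-transfection control) and `p_value`.
#'
#' @param tab data.frame with those three columns.
#' @param timepoint_label free-text label (e.g. `"24h"`).
#' @return the validated data.frame with a `timepoint_label` attribute.
#' @export
expression_table <- function(tab, timepoint_label = "24h") {
  stopifnot(all(c("accession", "log_ratio", "p_value") %in% names(tab)))
  if (anyDuplicated(tab$accession)) {
    stop("duplicate accession(s) in expression table: ",
         paste(unique(tab$accession[duplicated(tab$accession)]),
               collapse = ", "), call. = FALSE)
  }
  p <- tab$p_value
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p_value must lie in [0, 1]", call. = FALSE)
  }
  attr(tab, "timepoint_label") <- timepoint_label
  tab
}

#' Transcripts regarded as true off-targets
#'
#' A transcript counts as a true off-target when its expression change is
#' negative with p-value below `alpha` relative to the mock control.
#'
#' @param tab an [expression_table()].
#' @param cfg a [validation_config()].
#' @return character vector of accessions.
#' @export
true_offtargets <- function(tab, cfg = validation_config()) {
  tab <- expression_table(tab, attr(tab, "timepoint_label") %||% "24h")
  tab$accession[tab$log_ratio < 0 & tab$p_value < cfg$alpha]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' True/false positive counts for a prediction set
#'
#' @param predicted character vector (set) of predicted off-target
#'   accessions.
#' @param truth character vector (set) of true off-target accessions.
#' @return list with `tp`, `fp` and `tp_rate` (`tp / |predicted|`, 0 for
#'   an empty prediction set). `tp + fp == length(unique(predicted))`
#'   always.
#' @export
tp_fp <- function(predicted, truth) {
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  tp <- sum(predicted %in% truth)
  fp <- length(predicted) - tp
  list(tp = tp, fp = fp,
       tp_rate = if (length(predicted)) tp / length(predicted) else 0)
}

#' Per-siRNA and pooled validation report
#'
#' Scores predicted off-targets against expression-change tables, one
#' table (or one shared table) per siRNA. The pooled rate is computed
#' over predictions pooled across siRNAs — each (siRNA, transcript)
#' prediction counts once — which is the primary summary; the mean of
#' per-siRNA rates and a unique-transcript pooled view are reported
#' alongside since either denominator convention is defensible.
#'
#' @param predictions named list: per siRNA, a character vector of
#'   predicted off-target accessions.
#' @param tables either a single [expression_table()] shared by all
#'   siRNAs, or a named list of tables keyed like `predictions`.
#' @param cfg a [validation_config()].
#' @return list with `per_sirna` (data.frame: sirna_id, n_predicted, tp,
#'   fp, tp_rate, missing_table), `pooled_tp_rate` (pairs pooled),
#'   `mean_tp_rate`, `pooled_transcript_tp_rate`, `pooled_tp`,
#'   `pooled_fp`.
#' @export
validation_report <- function(predictions, tables,
                              cfg = validation_config()) {
  stopifnot(is.list(predictions), !is.null(names(predictions)))
  shared <- is.data.frame(tables)
  rows <- list()
  pooled_tp <- 0L; pooled_fp <- 0L
  all_pred <- character(0); all_truth <- character(0)
  for (id in names(predictions)) {
    pred <- unique(as.character(predictions[[id]]))
    tab <- if (shared) tables else tables[[id]]
    if (is.null(tab)) {
      # predictions with no table are reported as missing, never dropped
      rows[[id]] <- data.frame(sirna_id = id, n_predicted = length(pred),
                               tp = NA_integer_, fp = NA_integer_,
                               tp_rate = NA_real_, missing_table = TRUE,
                               stringsAsFactors = FALSE)
      next
    }
    truth <- true_offtargets(tab, cfg)
    res <- tp_fp(pred, truth)
    rows[[id]] <- data.frame(sirna_id = id, n_predicted = length(pred),
                             tp = res$tp, fp = res$fp, tp_rate = res$tp_rate,
                             missing_table = FALSE, stringsAsFactors = FALSE)
    pooled_tp <- pooled_tp + res$tp
    pooled_fp <- pooled_fp + res$fp
    all_pred <- c(all_pred, pred)
    all_truth <- union(all_truth, truth)
  }
  per_sirna <- do.call(rbind, rows)
  rownames(per_sirna) <- NULL
  n_pooled <- pooled_tp + pooled_fp
  scored <- per_sirna[!per_sirna$missing_table & per_sirna$n_predicted > 0, ]
  transcript_view <- tp_fp(all_pred, all_truth)
  list(
    per_sirna = per_sirna,
    pooled_tp = pooled_tp,
    pooled_fp = pooled_fp,
    pooled_tp_rate = if (n_pooled) pooled_tp / n_pooled else 0,
    mean_tp_rate = if (nrow(scored)) mean(scored$tp_rate) else 0,
    pooled_transcript_tp_rate = transcript_view$tp_rate
  )
}

#' Format a validation report as text
#'
#' @param report a [validation_report()] result.
#' @return character vector of lines.
#' @export
format_validation_report <- function(report) {
  c(sprintf("pooled TP rate (pairs):        %.4f (%d TP / %d FP)",
            report$pooled_tp_rate, report$pooled_tp, report$pooled_fp),
    sprintf("mean per-siRNA TP rate:        %.4f", report$mean_tp_rate),
    sprintf("pooled TP rate (transcripts):  %.4f",
            report$pooled_transcript_tp_rate),
    "",
    utils::capture.output(print(report$per_sirna, row.names = FALSE)))
}
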