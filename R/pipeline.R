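#' Pipeline configuration
#'
#' Bundles the sub-configurations of the end-to-end analysis and selects
#' the complementarity-search variant: `"full_sw"` (whole-transcript
#' local alignment), `"seed_window_sw"` (alignment restricted to ~50-nt
#' windows around seed sites), `"mirna_like"` (seed + 3'-compensatory
#' rules only) or `"all"` (windows + miRNA-like rules; the default). The
#' variant is always a user choice, never auto-selected.
#'
#' Full-transcript alignment over a large transcriptome is the
#' pipeline's slow path; `max_full_sw_targets` (default 200) is a
#' guardrail, not semantics — the run refuses full-SW mode above it
#' unless `allow_large_full_sw` is set.
#'
#' @param mode search variant, see above.
#' @param max_full_sw_targets maximum transcriptome size accepted in
#'   `full_sw` mode.
#' @param allow_large_full_sw override the guardrail.
#' @param use_conservation filter miRNA-like support to conserved sites
#'   (requires a conserved-interval set at run time).
#' @param emit_all write a SeedSeq record for every transcript, not just
#'   those with calls.
#' @param scan a [scan_config()].
#' @param scoring a [scoring_scheme()].
#' @param classifier a [classifier_config()].
#' @param validation a [validation_config()].
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("all", "seed_window_sw", "full_sw",
                                     "mirna_like"),
                            max_full_sw_targets = 200L,
                            allow_large_full_sw = FALSE,
                            use_conservation = FALSE,
                            emit_all = FALSE,
                            scan = scan_config(),
                            scoring = scoring_scheme(),
                            classifier = classifier_config(),
                            validation = validation_config()) {
  mode <- match.arg(mode)
  structure(
    list(mode = mode,
         max_full_sw_targets = as.integer(max_full_sw_targets),
         allow_large_full_sw = isTRUE(allow_large_full_sw),
         use_conservation = isTRUE(use_conservation),
         emit_all = isTRUE(emit_all),
         scan = scan, scoring = scoring, classifier = classifier,
         validation = validation),
    class = "pipeline_config"
  )
}

#' Run the off-target analysis end to end
#'
#' Searches complementarity between every library siRNA and every
#' transcript (excluding each siRNA's own on-target gene), classifies
#' the evidence into off-target categories, optionally filters
#' miRNA-like support to conserved sites, annotates transcripts as
#' SeedSeq records and, when an expression table is supplied, scores the
#' predictions against it. All outputs are deterministic for fixed
#' inputs and configuration.
#'
#' @param config a [pipeline_config()].
#' @param transcriptome list of [transcript()] objects.
#' @param library list of [sirna()] objects.
#' @param conserved optional [conserved_intervals()] set (required when
#'   `config$use_conservation`).
#' @param expression optional [expression_table()] (one shared table) or
#'   named list of tables per siRNA id.
#' @param out_dir optional directory; when given, writes
#'   `offtargets.tsv`, `seedseq.txt` and (if validated)
#'   `validation.txt`.
#' @return list with `records` (off-target records), `table`
#'   ([offtarget_table()] data.frame), `seedseq_records`,
#'   `seedseq_text`, and `validation` (a [validation_report()] or
#'   `NULL`).
#' @export
run_pipeline <- function(config, transcriptome, library, conserved = NULL,
                         expression = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode == "full_sw" &&
      length(transcriptome) > config$max_full_sw_targets &&
      !config$allow_large_full_sw) {
    stop("full_sw mode refused: ", length(transcriptome),
         " transcripts exceed max_full_sw_targets (",
         config$max_full_sw_targets,
         "); restrict the transcriptome or set allow_large_full_sw",
         call. = FALSE)
  }
  if (config$use_conservation && is.null(conserved)) {
    stop("use_conservation requires a conserved-interval set",
         call. = FALSE)
  }

  records <- list()
  for (s in library) {
    recs <- call_offtargets(s, transcriptome, config$scan, config$scoring,
                            config$classifier, config$mode)
    records <- c(records, recs)
  }
  if (config$use_conservation) {
    records <- filter_conserved(records, conserved)
  }
  tab <- offtarget_table(records)

  accs_with_calls <- unique(tab$accession)
  emit <- if (config$emit_all) transcriptome else
    Filter(function(t) t$accession %in% accs_with_calls, transcriptome)
  seedseq_records <- lapply(emit, function(t) {
    annotate_transcript(
      t, Filter(function(r) r$transcript_accession == t$accession, records))
  })
  seedseq_text <- if (length(seedseq_records))
    write_seedseq(seedseq_records) else NULL

  validation <- NULL
  if (!is.null(expression)) {
    ids <- vapply(library, `[[`, character(1), "sirna_id")
    predictions <- stats::setNames(
      lapply(ids, function(id) tab$accession[tab$sirna_id == id]), ids)
    validation <- validation_report(predictions, expression,
                                    config$validation)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab, file.path(out_dir, "offtargets.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(seedseq_text)) {
      writeLines(seedseq_text, file.path(out_dir, "seedseq.txt"))
    }
    if (!is.null(validation)) {
      writeLines(format_validation_report(validation),
                 file.path(out_dir, "validation.txt"))
    }
  }

  list(records = records, table = tab, seedseq_records = seedseq_records,
       seedseq_text = seedseq_text, validation = validation)
}
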