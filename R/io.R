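#' Read a transcriptome from FASTA
#'
#' The accession is the first whitespace-delimited token of each header;
#' a gene symbol is taken from an optional `gene=` key and a 3'UTR offset
#' from an optional `utr3_start=` key (0-based), both anywhere in the
#' header.
#'
#' @param path FASTA file (RNA or DNA alphabet).
#' @return list of [transcript()] objects.
#' @export
read_transcriptome <- function(path) {
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    acc <- strsplit(header, "\\s+")[[1]][1]
    gene <- ""
    m <- regmatches(header, regexpr("gene=[^[:space:]]+", header))
    if (length(m)) gene <- sub("^gene=", "", m)
    utr3 <- NULL
    m <- regmatches(header, regexpr("utr3_start=[0-9]+", header))
    if (length(m)) utr3 <- as.integer(sub("^utr3_start=", "", m))
    transcript(acc, as.character(set[[i]]), gene_symbol = gene,
               utr3_start = utr3)
  })
}

#' Write a transcriptome to FASTA
#'
#' Headers carry the `gene=` and `utr3_start=` keys that
#' [read_transcriptome()] understands.
#'
#' @param transcriptome list of [transcript()] objects.
#' @param path output file.
#' @export
write_transcriptome <- function(transcriptome, path) {
  lines <- unlist(lapply(transcriptome, function(t) {
    header <- paste0(">", t$accession,
                     if (nzchar(t$gene_symbol)) paste0(" gene=", t$gene_symbol),
                     if (!is.null(t$utr3_start))
                       paste0(" utr3_start=", t$utr3_start))
    body <- substring(t$sequence, seq(1L, nchar(t$sequence), 60L),
                      pmin(seq(60L, nchar(t$sequence) + 59L, 60L),
                           nchar(t$sequence)))
    c(header, body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read an siRNA library table
#'
#' Delimited table with columns `sirna_id`, `gene`, `antisense` and an
#' optional `sense` column.
#'
#' @param path TSV/CSV file (delimiter sniffed from the extension:
#'   `.csv` means comma, anything else tab).
#' @param seed_def seed register passed to [sirna()].
#' @return list of [sirna()] objects.
#' @export
read_sirna_library <- function(path, seed_def = c(2L, 8L)) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("sirna_id", "gene", "antisense") %in% names(tab)))
  lapply(seq_len(nrow(tab)), function(i) {
    sirna(tab$sirna_id[i], tab$gene[i], tab$antisense[i],
          sense = if ("sense" %in% names(tab) && nzchar(tab$sense[i]))
            tab$sense[i] else NULL,
          seed_def = seed_def)
  })
}

#' The packaged reference siRNA library
#'
#' Thirteen siRNA/off-target/miRNA associations shipped with the package
#' (siRNAs whose off-target transcripts are validated targets of miRNAs
#' sharing the same seed). Several siRNAs appear in more than one
#' association; `unique_sirnas = TRUE` collapses to one [sirna()] per
#' vendor id.
#'
#' @param unique_sirnas collapse duplicate siRNA ids.
#' @param seed_def seed register passed to [sirna()].
#' @return list of [sirna()] objects; the raw association table is
#'   attached as attribute `"associations"`.
#' @export
mirna_matched_sirnas <- function(unique_sirnas = TRUE, seed_def = c(2L, 8L)) {
  path <- system.file("extdata", "mirna_matched_sirnas.tsv", package = "seedseq",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  rows <- if (unique_sirnas) tab[!duplicated(tab$sirna_id), ] else tab
  out <- lapply(seq_len(nrow(rows)), function(i) {
    sirna(rows$sirna_id[i], rows$gene[i], rows$antisense[i],
          seed_def = seed_def)
  })
  attr(out, "associations") <- tab
  out
}

#' Read a conserved-interval table
#'
#' BED-like 3-column delimited input (`accession`, `start`, `end`),
#' 0-based half-open, with or without a header line.
#'
#' @param path file path.
#' @param min_length,species_set passed to [conserved_intervals()].
#' @return a [conserved_intervals()] set.
#' @export
read_conserved <- function(path, min_length = 8L,
                           species_set = "human,chimp,mouse,rat,dog") {
  first <- readLines(path, n = 1L)
  has_header <- grepl("accession", first, fixed = TRUE)
  tab <- utils::read.delim(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) names(tab)[1:3] <- c("accession", "start", "end")
  conserved_intervals(tab, min_length = min_length,
                      species_set = species_set)
}

#' Read an expression-change table
#'
#' Delimited table with the three required columns `accession`,
#' `log_ratio`, `p_value`. Differently-named source columns can be
#' mapped through `col_map`, so any table carrying the three quantities
#' can be consumed.
#'
#' @param path file path (TSV, or CSV by extension).
#' @param col_map named character vector mapping required names to the
#'   file's column names, e.g.
#'   `c(accession = "RefSeq", log_ratio = "logFC", p_value = "P.Value")`.
#' @param timepoint_label label forwarded to [expression_table()].
#' @return an [expression_table()].
#' @export
read_expression <- function(path, col_map = NULL, timepoint_label = "24h") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (want in names(col_map)) {
      if (!col_map[[want]] %in% names(tab)) {
        stop("column ", col_map[[want]], " not found in ", path,
             call. = FALSE)
      }
      names(tab)[names(tab) == col_map[[want]]] <- want
    }
  }
  expression_table(tab[, c("accession", "log_ratio", "p_value")],
                   timepoint_label)
}
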