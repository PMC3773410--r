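#' Construct a SeedSeq record
#'
#' A SeedSeq record is a GenBank-dialect flat-file record annotating a
#' transcript with the siRNAs predicted to off-target it. Off-target
#' information lives in the FEATURES section under the `target_siRNAs`
#' tag; the fixed qualifier vocabulary is `sirna_id`, `supplier`,
#' `categories`, `seed_occurrences` (dialect version 1, stamped in the
#' file header comment).
#'
#' @param locus_name LOCUS name (usually the accession).
#' @param sequence nucleotide sequence (normalized internally; the
#'   `molecule` field decides the output alphabet).
#' @param molecule `"DNA"` or `"RNA"`.
#' @param definition DEFINITION line content; pipe-joined `key=value`
#'   metadata is preserved verbatim (see [definition_fields()]).
#' @param accession ACCESSION; defaults to the locus name.
#' @param features list of features, each a list with `key` (string),
#'   `location` (1-based inclusive `c(start, end)`, or `NULL` for the
#'   full record) and `qualifiers` (named list; values coerced to
#'   character).
#' @return object of class `"seedseq_record"`.
#' @export
seedseq_record <- function(locus_name, sequence, molecule = c("DNA", "RNA"),
                           definition = "", accession = locus_name,
                           features = list()) {
  molecule <- match.arg(molecule)
  sequence <- rna_norm(sequence)
  len <- nchar(sequence)
  features <- lapply(features, function(f) {
    stopifnot(is.list(f), !is.null(f$key))
    loc <- if (is.null(f$location)) c(1L, len) else as.integer(f$location)
    if (length(loc) != 2L || any(is.na(loc)) || loc[1] < 1L ||
        loc[2] > len || loc[1] > loc[2]) {
      stop("feature location out of record bounds: ",
           paste(loc, collapse = ".."), call. = FALSE)
    }
    quals <- lapply(f$qualifiers, as.character)
    list(key = as.character(f$key), location = loc, qualifiers = quals)
  })
  structure(
    list(locus_name = as.character(locus_name), length = len,
         molecule = molecule, definition = as.character(definition),
         accession = as.character(accession), features = features,
         sequence = sequence),
    class = "seedseq_record"
  )
}

#' @export
print.seedseq_record <- function(x, ...) {
  cat(sprintf("<SeedSeq record %s: %d bp %s, %d feature(s)>\n",
              x$accession, x$length, x$molecule, length(x$features)))
  invisible(x)
}

#' Parsed key=value view of a record DEFINITION
#'
#' SeedSeq DEFINITION lines carry pipe-joined `key=value` metadata
#' (e.g. `sym=TPH2|geneid=121278|...`); unknown keys survive round-trips
#' because the raw string is what is stored.
#'
#' @param r a [seedseq_record()].
#' @return named character vector (empty when the definition is not in
#'   key=value form).
#' @export
definition_fields <- function(r) {
  stopifnot(inherits(r, "seedseq_record"))
  parts <- strsplit(r$definition, "|", fixed = TRUE)[[1]]
  parts <- parts[grepl("=", parts, fixed = TRUE)]
  if (!length(parts)) return(stats::setNames(character(0), character(0)))
  keys <- sub("=.*$", "", parts)
  vals <- sub("^[^=]*=", "", parts)
  stats::setNames(vals, keys)
}

# ---- reader -----------------------------------------------------------

parse_error <- function(line_no, msg) {
  stop(sprintf("SeedSeq parse error at line %d: %s", line_no, msg),
       call. = FALSE)
}

parse_one_record <- function(lines, offset, strict) {
  txt <- sub("[[:space:]]+$", "", lines)
  keep <- !grepl("^#", txt)
  idx <- which(keep & nzchar(txt))
  if (!length(idx)) return(NULL)

  kw_at <- function(pat) {
    hits <- idx[grepl(pat, txt[idx])]
    if (length(hits)) hits[1] else NA_integer_
  }
  locus_i <- kw_at("^LOCUS\\b")
  origin_i <- kw_at("^ORIGIN\\b")
  if (is.na(locus_i)) parse_error(offset + idx[1], "missing LOCUS line")
  if (is.na(origin_i)) parse_error(offset + locus_i, "missing ORIGIN line")

  toks <- strsplit(sub("^LOCUS\\s+", "", txt[locus_i]), "\\s+")[[1]]
  locus_name <- toks[1]
  locus_len <- suppressWarnings(as.integer(toks[2]))
  molecule <- if (any(toupper(toks) == "RNA")) "RNA" else "DNA"

  # DEFINITION with indented continuation lines, joined by one space
  definition <- ""
  def_i <- kw_at("^DEFINITION\\b")
  if (!is.na(def_i)) {
    pieces <- sub("^DEFINITION\\s*", "", txt[def_i])
    j <- def_i + 1L
    while (j < origin_i && grepl("^\\s", txt[j]) && nzchar(trimws(txt[j]))) {
      pieces <- c(pieces, trimws(txt[j]))
      j <- j + 1L
    }
    definition <- paste(pieces, collapse = " ")
  }

  accession <- locus_name
  acc_i <- kw_at("^ACCESSION\\b")
  if (!is.na(acc_i)) {
    # BASE COUNT may share the ACCESSION line in loosely-formatted records
    acc_toks <- strsplit(sub("^ACCESSION\\s+", "", txt[acc_i]), "\\s+")[[1]]
    accession <- acc_toks[1]
  }

  # FEATURES section: feature keys at indent, qualifiers as /key=value
  features <- list()
  feat_i <- kw_at("^FEATURES\\b")
  if (!is.na(feat_i)) {
    j <- feat_i + 1L
    cur <- NULL
    while (j <= length(txt) &&
           !grepl("^(BASE COUNT|ORIGIN|LOCUS|ACCESSION)\\b", txt[j])) {
      ln <- txt[j]
      if (grepl("^\\s+/", ln)) {
        if (is.null(cur)) parse_error(offset + j, "qualifier before feature key")
        q <- sub("^\\s+/", "", ln)
        qkey <- sub("=.*$", "", q)
        qval <- if (grepl("=", q, fixed = TRUE)) sub("^[^=]*=", "", q) else ""
        qval <- gsub('^"|"$', "", qval)
        cur$qualifiers[[qkey]] <- qval
      } else if (grepl("^\\s+\\S", ln)) {
        if (!is.null(cur)) features[[length(features) + 1L]] <- cur
        ft <- strsplit(trimws(ln), "\\s+")[[1]]
        loc <- NULL
        if (length(ft) > 1L && grepl("^<?\\d+\\.\\.>?\\d+$", ft[2])) {
          nums <- as.integer(strsplit(gsub("[<>]", "", ft[2]),
                                      "..", fixed = TRUE)[[1]])
          loc <- nums
        }
        cur <- list(key = ft[1], location = loc, qualifiers = list())
      }
      j <- j + 1L
    }
    if (!is.null(cur)) features[[length(features) + 1L]] <- cur
  }

  # BASE COUNT as printed in the source record (checked against the
  # sequence below)
  stated_counts <- NULL
  bc_i <- kw_at("\\bBASE COUNT\\b")
  if (!is.na(bc_i)) {
    m <- gregexpr("(\\d+)\\s+([acgutACGUT])\\b", txt[bc_i])[[1]]
    if (m[1] != -1L) {
      pieces <- regmatches(txt[bc_i], gregexpr(
        "(\\d+)\\s+([acgutACGUT])\\b", txt[bc_i]))[[1]]
      vals <- as.integer(sub("\\s+[a-zA-Z]$", "", pieces))
      bases <- toupper(sub("^\\d+\\s+", "", pieces))
      stated_counts <- stats::setNames(vals, bases)
    }
  }

  # ORIGIN block: strip position labels, grouping whitespace, stray
  # punctuation; case-insensitive
  seq_lines <- character(0)
  j <- origin_i + 1L
  while (j <= length(txt) && !grepl("^//", txt[j]) &&
         !grepl("^LOCUS\\b", txt[j])) {
    seq_lines <- c(seq_lines, gsub("[^A-Za-z]", "", txt[j]))
    j <- j + 1L
  }
  sequence <- paste(seq_lines, collapse = "")
  if (!nzchar(sequence)) parse_error(offset + origin_i, "empty ORIGIN block")

  rec <- seedseq_record(locus_name, sequence, molecule,
                        definition = definition, accession = accession,
                        features = features)
  if (!is.na(locus_len) && locus_len != rec$length) {
    msg <- sprintf("record %s: LOCUS says %d bp but ORIGIN holds %d",
                   accession, locus_len, rec$length)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (!is.null(stated_counts)) {
    actual <- base_count(rec$sequence,
                         alphabet = if (molecule == "DNA") "DNA" else "RNA")
    common <- intersect(names(stated_counts), names(actual))
    if (!identical(stated_counts[common], actual[common])) {
      msg <- sprintf("record %s: BASE COUNT line disagrees with sequence",
                     accession)
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  rec
}

#' Read SeedSeq records
#'
#' Parses one or more records from a SeedSeq/GenBank-dialect file or
#' string. The reader is tolerant: the terminal `//` and the FEATURES
#' section may be absent, ORIGIN lines may carry position labels, 10-base
#' grouping, arbitrary whitespace and either case, and `#` comment lines
#' are skipped. A BASE COUNT line inconsistent with the sequence is a
#' warning (an error under `strict = TRUE`).
#'
#' @param x path to a file, or a character vector of lines / a single
#'   string with embedded newlines.
#' @param strict escalate consistency warnings to errors.
#' @return list of [seedseq_record()] objects.
#' @export
read_seedseq <- function(x, strict = FALSE) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  # split into record blocks on "//" terminators and fresh LOCUS lines
  breaks <- integer(0)
  in_block <- FALSE
  starts <- integer(0)
  for (i in seq_along(lines)) {
    if (grepl("^LOCUS\\b", lines[i]) && !in_block) {
      starts <- c(starts, i); in_block <- TRUE
    } else if (grepl("^LOCUS\\b", lines[i]) && in_block) {
      breaks <- c(breaks, i - 1L); starts <- c(starts, i)
    } else if (grepl("^//", lines[i]) && in_block) {
      breaks <- c(breaks, i); in_block <- FALSE
    }
  }
  if (in_block) breaks <- c(breaks, length(lines))
  if (!length(starts)) {
    parse_error(1L, "missing LOCUS line")
  }
  records <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    records[[k]] <- parse_one_record(lines[starts[k]:breaks[k]],
                                     starts[k] - 1L, strict)
  }
  records[!vapply(records, is.null, logical(1))]
}

# ---- writer -----------------------------------------------------------

wrap_definition <- function(definition, width = 67L) {
  words <- strsplit(definition, " ", fixed = TRUE)[[1]]
  if (!length(words)) return("DEFINITION  ")
  lines <- character(0)
  cur <- words[1]
  for (w in words[-1]) {
    if (nchar(cur) + 1L + nchar(w) > width) {
      lines <- c(lines, cur); cur <- w
    } else cur <- paste(cur, w)
  }
  lines <- c(lines, cur)
  c(paste0("DEFINITION  ", lines[1]),
    if (length(lines) > 1L) paste0("            ", lines[-1]))
}

format_one_record <- function(r, case) {
  out_seq <- if (r$molecule == "DNA") chartr("U", "T", r$sequence)
             else r$sequence
  if (case == "lower") out_seq <- tolower(out_seq)
  counts <- base_count(r$sequence,
                       alphabet = if (r$molecule == "DNA") "DNA" else "RNA")
  lines <- c(
    sprintf("LOCUS       %-17s %6d bp    %s", r$locus_name, r$length,
            r$molecule),
    wrap_definition(r$definition),
    sprintf("ACCESSION   %s", r$accession)
  )
  if (length(r$features)) {
    lines <- c(lines, "FEATURES             Location/Qualifiers")
    for (f in r$features) {
      lines <- c(lines, sprintf("     %-16s%d..%d", f$key,
                                f$location[1], f$location[2]))
      for (qk in names(f$qualifiers)) {
        v <- f$qualifiers[[qk]]
        if (!grepl("^[0-9]+$", v)) v <- paste0('"', v, '"')
        lines <- c(lines, sprintf("                     /%s=%s", qk, v))
      }
    }
  }
  lines <- c(lines, sprintf("BASE COUNT  %8d %s %8d %s %8d %s %8d %s",
                            counts[1], tolower(names(counts)[1]),
                            counts[2], tolower(names(counts)[2]),
                            counts[3], tolower(names(counts)[3]),
                            counts[4], tolower(names(counts)[4])),
             "ORIGIN")
  for (i in seq(1L, r$length, by = 60L)) {
    chunk <- substr(out_seq, i, min(i + 59L, r$length))
    groups <- paste(substring(chunk, seq(1L, nchar(chunk), 10L),
                              pmin(seq(10L, nchar(chunk) + 9L, 10L),
                                   nchar(chunk))),
                    collapse = " ")
    lines <- c(lines, sprintf("%9d %s", i, groups))
  }
  c(lines, "//")
}

#' Write SeedSeq records
#'
#' Emits the SeedSeq dialect: LOCUS, DEFINITION, ACCESSION, FEATURES
#' (with `target_siRNAs` qualifiers), a BASE COUNT line recomputed from
#' the sequence, and an ORIGIN block with 1-based position labels, 60
#' residues per line in 10-residue groups, each record terminated by
#' `//`. A `#`-prefixed header comment stamps the dialect and qualifier
#' vocabulary version. ORIGIN case is lowercase by default (GenBank
#' convention); comparisons on read are case-insensitive either way.
#'
#' @param records a [seedseq_record()] or list of them.
#' @param path optional output file; when `NULL` the text is returned.
#' @param case `"lower"` or `"upper"` ORIGIN residues.
#' @return invisibly (or visibly when `path` is `NULL`), the formatted
#'   text as a single string.
#' @export
write_seedseq <- function(records, path = NULL, case = c("lower", "upper")) {
  case <- match.arg(case)
  if (inherits(records, "seedseq_record")) records <- list(records)
  header <- paste0("# SeedSeq dialect v1 ",
                   "(target_siRNAs qualifiers: sirna_id, supplier, ",
                   "categories, seed_occurrences)")
  body <- unlist(lapply(records, function(r) {
    stopifnot(inherits(r, "seedseq_record"))
    if (r$length != nchar(r$sequence)) {
      stop("refusing to write record ", r$accession,
           ": length field disagrees with sequence", call. = FALSE)
    }
    format_one_record(r, case)
  }))
  text <- paste(c(header, body), collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Annotate a transcript with its off-targeting siRNAs
#'
#' Builds the SeedSeq record for a transcript: one `target_siRNAs`
#' feature per off-targeting siRNA (deduplicated by `sirna_id`, ordered
#' by it), located at the siRNA's best supporting seed site, or spanning
#' the full record for site-less near-exact/partial evidence.
#'
#' @param t a [transcript()].
#' @param records list of `"offtarget_record"` objects, all referencing
#'   `t`.
#' @param supplier optional supplier label written into each feature.
#' @return a [seedseq_record()] (molecule `"RNA"`).
#' @export
annotate_transcript <- function(t, records, supplier = NULL) {
  stopifnot(inherits(t, "transcript"))
  for (r in records) {
    if (!identical(r$transcript_accession, t$accession)) {
      stop("off-target record for ", r$transcript_accession,
           " does not reference transcript ", t$accession, call. = FALSE)
    }
  }
  ids <- vapply(records, `[[`, character(1), "sirna_id")
  records <- records[!duplicated(ids)]
  records <- records[order(vapply(records, `[[`, character(1), "sirna_id"))]
  len <- nchar(t$sequence)
  features <- lapply(records, function(r) {
    loc <- NULL
    if (!is.null(r$mirna_sites) && nrow(r$mirna_sites)) {
      loc <- c(r$mirna_sites$start[1] + 1L, r$mirna_sites$end[1])
    } else if (!is.null(r$best_alignment) &&
               diff(r$best_alignment$target_interval) > 0) {
      loc <- c(r$best_alignment$target_interval[1] + 1L,
               r$best_alignment$target_interval[2])
    }
    quals <- list(sirna_id = r$sirna_id)
    if (!is.null(supplier)) quals$supplier <- supplier
    quals$categories <- paste(r$categories, collapse = ",")
    quals$seed_occurrences <- as.character(r$seed_occurrences)
    list(key = "target_siRNAs", location = loc, qualifiers = quals)
  })
  defn <- paste0("acc=", t$accession,
                 if (nzchar(t$gene_symbol)) paste0("|sym=", t$gene_symbol),
                 "|len=", len)
  seedseq_record(t$accession, t$sequence, molecule = "RNA",
                 definition = defn, accession = t$accession,
                 features = features)
}
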