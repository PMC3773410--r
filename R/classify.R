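#' Off-target classifier configuration
#'
#' Thresholds and regions of the rule set. The defaults encode the
#' published evidence on sequence-dependent off-targeting: ~90%
#' complementarity (17 of the 19 duplex-core nucleotides) for near-exact
#' off-targets; 11 contiguous or 15 total paired nucleotides for partial
#' ones; a perfect 7-mer seed, or a single seed mismatch rescued by
#' perfect pairing of the siRNA 3' region (positions 13-19), for
#' miRNA-like sites; and pairing across antisense positions 8-10 (the
#' cleavage site) for slicer competence.
#'
#' @param near_exact_min_paired minimum paired positions (of the 19-nt
#'   duplex core) for a near-exact call.
#' @param partial_min_contiguous minimum longest contiguous paired run for
#'   a partial call.
#' @param partial_min_total minimum total paired positions for a partial
#'   call.
#' @param compensatory_region antisense positions whose perfect pairing
#'   rescues a single seed mismatch (3' compensatory rule).
#' @param center_region antisense positions opposite the mRNA cleavage
#'   site.
#' @param require_utr3_for_mirna_like if `TRUE` (default) miRNA-like sites
#'   must lie in the transcript's 3'UTR; whole-transcript mode is
#'   available because seed complementarity anywhere in the transcript has
#'   also been associated with off-targeting.
#' @return object of class `"classifier_config"`.
#' @export
classifier_config <- function(near_exact_min_paired = 17L,
                              partial_min_contiguous = 11L,
                              partial_min_total = 15L,
                              compensatory_region = c(13L, 19L),
                              center_region = c(8L, 10L),
                              require_utr3_for_mirna_like = TRUE) {
  stopifnot(near_exact_min_paired > 0, partial_min_contiguous > 0,
            partial_min_total > 0)
  compensatory_region <- as.integer(compensatory_region)
  center_region <- as.integer(center_region)
  if (any(compensatory_region < 1L) || any(compensatory_region > 19L) ||
      any(center_region < 1L) || any(center_region > 19L)) {
    stop("classifier regions must lie within the 19-nt duplex core",
         call. = FALSE)
  }
  structure(
    list(near_exact_min_paired = as.integer(near_exact_min_paired),
         partial_min_contiguous = as.integer(partial_min_contiguous),
         partial_min_total = as.integer(partial_min_total),
         compensatory_region = compensatory_region,
         center_region = center_region,
         require_utr3_for_mirna_like = isTRUE(require_utr3_for_mirna_like)),
    class = "classifier_config"
  )
}

#' Classify a duplex alignment into off-target categories
#'
#' @param aln a `"duplex_alignment"`.
#' @param cfg a [classifier_config()].
#' @return character vector, a subset of `c("near_exact", "partial")`
#'   (possibly empty; the categories may co-occur).
#' @export
classify_alignment <- function(aln, cfg = classifier_config()) {
  stopifnot(inherits(aln, "duplex_alignment"))
  out <- character(0)
  if (aln$paired_positions >= cfg$near_exact_min_paired) {
    out <- c(out, "near_exact")
  }
  if (aln$longest_contiguous_run >= cfg$partial_min_contiguous ||
      aln$paired_positions >= cfg$partial_min_total) {
    out <- c(out, "partial")
  }
  out
}

#' Is the duplex competent for slicer cleavage?
#'
#' Mismatches opposite the mRNA cleavage site (antisense positions 8-10)
#' abolish cleavage; a G:U wobble there counts as paired when the scheme
#' treats wobble as match.
#'
#' @inheritParams classify_alignment
#' @return logical.
#' @export
cleavage_competent <- function(aln, cfg = classifier_config()) {
  stopifnot(inherits(aln, "duplex_alignment"))
  if (is.null(aln$anti_status)) {
    stop("cleavage competence needs a duplex alignment from align_duplex()",
         call. = FALSE)
  }
  pos <- seq(cfg$center_region[1], cfg$center_region[2])
  pos <- pos[pos <= length(aln$anti_status)]
  if (!length(pos)) return(FALSE)
  all(status_paired(aln$anti_status[pos], aln$scheme))
}

# Position on the mRNA (0-based) paired with antisense position p, for a
# seed site whose interval starts at `start`. The site's first base pairs
# the seed's 3'-most antisense position (seed_len + 1), so
# m = start + (seed_len + 1 - p).
anti_partner_pos <- function(site_start, seed_len, p) {
  as.integer(site_start) + (as.integer(seed_len) + 1L - as.integer(p))
}

# number of unpaired positions across the antisense seed at a given site
seed_mismatch_count <- function(sirna, tseq, site, scheme) {
  seed_len <- as.integer(site$seed_len)
  seed_pos <- seq(2L, seed_len + 1L)
  st <- vapply(seed_pos, function(p) {
    anti_pos_status(sirna, tseq, p,
                    anti_partner_pos(site$start, seed_len, p))
  }, character(1))
  sum(!status_paired(st, scheme))
}

#' miRNA-like off-target call for a seed site
#'
#' A site qualifies when the antisense seed is perfectly paired, or when
#' it carries exactly one seed mismatch rescued by perfect pairing of the
#' 3' compensatory region (antisense positions 13-19 by default). With
#' `require_utr3_for_mirna_like` the site must lie in the 3'UTR.
#'
#' @param sirna an [sirna()].
#' @param t the [transcript()] carrying the site.
#' @param site one row of [find_seed_sites()] / `find_seed_sites_mm1()`.
#' @param cfg a [classifier_config()].
#' @param scheme a [scoring_scheme()] (controls whether wobble counts as
#'   paired).
#' @return logical.
#' @export
classify_mirna_like <- function(sirna, t, site, cfg = classifier_config(),
                                scheme = scoring_scheme()) {
  stopifnot(inherits(sirna, "sirna"), inherits(t, "transcript"))
  if (cfg$require_utr3_for_mirna_like) {
    if (is.null(t$utr3_start)) {
      stop("miRNA-like calls restricted to the 3'UTR, but transcript ",
           t$accession, " has no utr3_start", call. = FALSE)
    }
    if (site$start < t$utr3_start) return(FALSE)
  }
  mm <- seed_mismatch_count(sirna, t$sequence, site, scheme)
  if (mm == 0L) return(TRUE)
  if (mm != 1L) return(FALSE)
  comp_pos <- seq(cfg$compensatory_region[1], cfg$compensatory_region[2])
  st <- vapply(comp_pos, function(p) {
    anti_pos_status(sirna, t$sequence, p,
                    anti_partner_pos(site$start, site$seed_len, p))
  }, character(1))
  all(status_paired(st, scheme))
}

# cleavage competence evaluated positionally at a seed site (used for
# records whose only evidence is miRNA-like)
site_cleavage_competent <- function(sirna, tseq, site, cfg, scheme) {
  pos <- seq(cfg$center_region[1], cfg$center_region[2])
  st <- vapply(pos, function(p) {
    anti_pos_status(sirna, tseq, p,
                    anti_partner_pos(site$start, site$seed_len, p))
  }, character(1))
  all(status_paired(st, scheme))
}

#' Call off-target transcripts for one siRNA
#'
#' Runs the selected complementarity-search variant against every
#' transcript except those of the siRNA's own on-target gene and emits one
#' record per transcript with at least one off-target category.
#'
#' Variants: `"full_sw"` aligns the duplex against the whole transcript;
#' `"seed_window_sw"` (default within `"all"`) aligns only ~50-nt windows
#' cut around exact seed-motif sites; `"mirna_like"` applies the seed /
#' 3'-compensatory rules (admitting one seed mismatch) without alignment
#' thresholds. `"all"` combines windowed alignment with the miRNA-like
#' rules.
#'
#' @param sirna an [sirna()].
#' @param transcriptome list of [transcript()] objects.
#' @param scan_cfg a [scan_config()].
#' @param scheme a [scoring_scheme()].
#' @param cfg a [classifier_config()].
#' @param mode one of `"all"`, `"seed_window_sw"`, `"full_sw"`,
#'   `"mirna_like"`.
#' @return list of `"offtarget_record"` objects, ordered by accession.
#' @export
call_offtargets <- function(sirna, transcriptome,
                            scan_cfg = scan_config(),
                            scheme = scoring_scheme(),
                            cfg = classifier_config(),
                            mode = c("all", "seed_window_sw", "full_sw",
                                     "mirna_like")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sirna, "sirna"))
  records <- list()
  accs <- vapply(transcriptome, function(t) t$accession, character(1))
  for (t in transcriptome[order(accs)]) {
    if (nzchar(sirna$on_target_gene) &&
        identical(t$gene_symbol, sirna$on_target_gene)) next
    rec <- classify_transcript(sirna, t, scan_cfg, scheme, cfg, mode)
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  records
}

# evidence gathering for a single (siRNA, transcript) pair
classify_transcript <- function(sirna, t, scan_cfg, scheme, cfg, mode) {
  categories <- character(0)
  best_aln <- NULL
  sites <- find_seed_sites(t, sirna, scan_cfg)

  if (mode %in% c("all", "seed_window_sw")) {
    for (k in seq_len(nrow(sites))) {
      w <- extract_window(t, sites[k, ], scan_cfg)
      aln <- align_duplex(sirna, w$sequence, scheme)
      # report target coordinates on the transcript, not the window
      aln$target_interval <- aln$target_interval + w$start
      categories <- union(categories, classify_alignment(aln, cfg))
      if (is.null(best_aln) || aln$score > best_aln$score) best_aln <- aln
    }
  } else if (mode == "full_sw") {
    aln <- align_duplex(sirna, t$sequence, scheme)
    categories <- union(categories, classify_alignment(aln, cfg))
    best_aln <- aln
  }

  mirna_sites <- NULL
  if (mode %in% c("all", "mirna_like") &&
      (!cfg$require_utr3_for_mirna_like || !is.null(t$utr3_start))) {
    cand <- find_seed_sites_mm1(t, sirna, scan_cfg, scheme$wobble_as_match)
    if (nrow(cand)) {
      ok <- vapply(seq_len(nrow(cand)), function(k) {
        classify_mirna_like(sirna, t, cand[k, ], cfg, scheme)
      }, logical(1))
      mirna_sites <- cand[ok, , drop = FALSE]
      if (nrow(mirna_sites)) categories <- union(categories, "mirna_like")
    }
  }

  if (!length(categories)) return(NULL)

  cleav <- if (!is.null(best_aln)) {
    cleavage_competent(best_aln, cfg)
  } else {
    any(vapply(seq_len(nrow(mirna_sites)), function(k) {
      site_cleavage_competent(sirna, t$sequence, mirna_sites[k, ], cfg,
                              scheme)
    }, logical(1)))
  }

  structure(
    list(sirna_id = sirna$sirna_id,
         transcript_accession = t$accession,
         gene_symbol = t$gene_symbol,
         categories = sort(categories),
         cleavage_competent = cleav,
         seed_occurrences = nrow(sites),
         seed_gc = seed_gc_fraction(sirna),
         best_alignment = best_aln,
         mirna_sites = mirna_sites,
         conserved_site_count = NA_integer_),
    class = "offtarget_record"
  )
}

#' @export
print.offtarget_record <- function(x, ...) {
  cat(sprintf("<off-target %s -> %s [%s]%s, %d seed site(s)>\n",
              x$sirna_id, x$transcript_accession,
              paste(x$categories, collapse = ","),
              if (x$cleavage_competent) " cleavage-competent" else "",
              x$seed_occurrences))
  invisible(x)
}

#' Flatten off-target records to a table
#'
#' @param records list of `"offtarget_record"` objects (possibly from
#'   several siRNAs).
#' @return data.frame with one row per record: `sirna_id`, `accession`,
#'   `gene`, `categories` (comma-joined), `seed_occurrences`,
#'   `paired_positions`, `contiguous_run`, `cleavage_competent`,
#'   `seed_gc`, `conserved_site_count`.
#' @export
offtarget_table <- function(records) {
  if (!length(records)) {
    return(data.frame(
      sirna_id = character(0), accession = character(0),
      gene = character(0), categories = character(0),
      seed_occurrences = integer(0), paired_positions = integer(0),
      contiguous_run = integer(0), cleavage_competent = logical(0),
      seed_gc = numeric(0), conserved_site_count = integer(0),
      stringsAsFactors = FALSE
    ))
  }
  data.frame(
    sirna_id = vapply(records, `[[`, character(1), "sirna_id"),
    accession = vapply(records, `[[`, character(1), "transcript_accession"),
    gene = vapply(records, `[[`, character(1), "gene_symbol"),
    categories = vapply(records, function(r)
      paste(r$categories, collapse = ","), character(1)),
    seed_occurrences = vapply(records, `[[`, integer(1), "seed_occurrences"),
    paired_positions = vapply(records, function(r)
      if (is.null(r$best_alignment)) NA_integer_
      else as.integer(r$best_alignment$paired_positions), integer(1)),
    contiguous_run = vapply(records, function(r)
      if (is.null(r$best_alignment)) NA_integer_
      else as.integer(r$best_alignment$longest_contiguous_run), integer(1)),
    cleavage_competent = vapply(records, `[[`, logical(1),
                                "cleavage_competent"),
    seed_gc = vapply(records, `[[`, numeric(1), "seed_gc"),
    conserved_site_count = vapply(records, `[[`, integer(1),
                                  "conserved_site_count"),
    stringsAsFactors = FALSE
  )
}
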