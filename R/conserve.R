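#' Build a conserved-interval set
#'
#' Consumes pre-computed conserved regions in *transcript* coordinates as
#' a BED-like 3-column table: `accession`, `start`, `end`, 0-based
#' half-open (stated explicitly since BED dialects vary). Overlapping or
#' adjacent intervals are merged, then intervals shorter than
#' `min_length` are dropped (conserved regions of length 8 bases or more
#' are the ones considered). Extraction of the intervals themselves (e.g.
#' from a multiz 46-way alignment restricted to a species subset) happens
#' upstream under the caller's definition of "conserved".
#'
#' @param tab data.frame with columns `accession`, `start`, `end`.
#' @param min_length minimum retained interval length, default 8.
#' @param species_set free-text label recording the species the intervals
#'   were derived from; default `"human,chimp,mouse,rat,dog"`.
#' @return object of class `"conserved_intervals"`.
#' @export
conserved_intervals <- function(tab, min_length = 8L,
                                species_set = "human,chimp,mouse,rat,dog") {
  if (!nrow(tab)) {
    out <- data.frame(accession = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
    return(structure(list(intervals = out,
                          min_length = as.integer(min_length),
                          species_set = species_set),
                     class = "conserved_intervals"))
  }
  stopifnot(all(c("accession", "start", "end") %in% names(tab)))
  start <- as.integer(tab$start); end <- as.integer(tab$end)
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    stop("malformed conserved interval row(s) ",
         paste(bad, collapse = ", "), ": need 0 <= start < end",
         call. = FALSE)
  }
  merged <- lapply(split(seq_len(nrow(tab)), tab$accession), function(idx) {
    # 0-based half-open -> IRanges 1-based closed; merge overlapping or
    # adjacent runs, then back
    ir <- IRanges::reduce(IRanges::IRanges(start = start[idx] + 1L,
                                           end = end[idx]),
                          min.gapwidth = 1L)
    data.frame(accession = tab$accession[idx[1]],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[(out$end - out$start) >= min_length, , drop = FALSE]
  out <- out[order(out$accession, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(intervals = out, min_length = as.integer(min_length),
                 species_set = species_set),
            class = "conserved_intervals")
}

#' @export
print.conserved_intervals <- function(x, ...) {
  cat(sprintf("<conserved intervals: %d interval(s) on %d transcript(s), min length %d (%s)>\n",
              nrow(x$intervals), length(unique(x$intervals$accession)),
              x$min_length, x$species_set))
  invisible(x)
}

#' Is a seed site conserved?
#'
#' A site counts as conserved only when its interval is fully contained
#' in a retained conserved interval of the same transcript (containment,
#' not mere overlap: the strictest deterministic reading of restricting
#' sites to orthologously conserved locations). Unknown accessions are
#' not conserved.
#'
#' @param site list/row with `accession`, `start`, `end` (0-based
#'   half-open).
#' @param cset a [conserved_intervals()] set.
#' @return logical.
#' @export
is_conserved <- function(site, cset) {
  stopifnot(inherits(cset, "conserved_intervals"))
  iv <- cset$intervals
  iv <- iv[iv$accession == site$accession, , drop = FALSE]
  if (!nrow(iv)) return(FALSE)
  any(iv$start <= site$start & site$end <= iv$end)
}

#' Restrict miRNA-like support to conserved sites
#'
#' Each record's miRNA-like supporting sites are filtered to the
#' conserved ones; records whose *only* support was non-conserved
#' miRNA-like sites are dropped. Near-exact and partial calls are left
#' untouched (conservation is a seed-site notion). The output is always a
#' subset of the input.
#'
#' @param records list of `"offtarget_record"` objects.
#' @param cset a [conserved_intervals()] set.
#' @return filtered record list with `conserved_site_count` filled in.
#' @export
filter_conserved <- function(records, cset) {
  stopifnot(inherits(cset, "conserved_intervals"))
  out <- list()
  for (rec in records) {
    if (!is.null(rec$mirna_sites) && nrow(rec$mirna_sites)) {
      keep <- vapply(seq_len(nrow(rec$mirna_sites)), function(k) {
        is_conserved(rec$mirna_sites[k, ], cset)
      }, logical(1))
      rec$conserved_site_count <- sum(keep)
      rec$mirna_sites <- rec$mirna_sites[keep, , drop = FALSE]
      if (!nrow(rec$mirna_sites)) {
        rec$categories <- setdiff(rec$categories, "mirna_like")
      }
    } else if ("mirna_like" %in% rec$categories) {
      rec$conserved_site_count <- 0L
      rec$categories <- setdiff(rec$categories, "mirna_like")
    } else {
      rec$conserved_site_count <- 0L
    }
    if (length(rec$categories)) out[[length(out) + 1L]] <- rec
  }
  out
}
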