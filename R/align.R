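#' Alignment scoring scheme
#'
#' Linear-gap local alignment scores. Defaults (+2 match, -1 mismatch, -2
#' per gapped position) are chosen so a 7-nt exact seed outscores scattered
#' matches; all values are configuration, not constants of the method.
#'
#' @param match score for a paired position (> 0).
#' @param mismatch score for a mismatched position (<= 0).
#' @param gap score per gapped position, linear (<= 0).
#' @param wobble_as_match if `TRUE` (default) a G:U wobble pair scores, and
#'   counts, as a paired position: RISC recognizes G:U like an authentic
#'   Watson-Crick pair in the guide-mRNA duplex.
#' @return object of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap = -2,
                           wobble_as_match = TRUE) {
  if (match <= 0) stop("match score must be positive", call. = FALSE)
  if (mismatch > 0) stop("mismatch score must be <= 0", call. = FALSE)
  if (gap > 0) stop("gap score must be <= 0", call. = FALSE)
  structure(
    list(match = match, mismatch = mismatch, gap = gap,
         wobble_as_match = isTRUE(wobble_as_match)),
    class = "scoring_scheme"
  )
}

#' Classify a guide/mRNA base pair
#'
#' @param antisense_base,mrna_base single canonical residues (A/C/G/U).
#' @param s a [scoring_scheme()] (only used for documentation symmetry;
#'   the classification itself is scheme-independent).
#' @return `"match"` for a Watson-Crick pair (A:U, U:A, G:C, C:G),
#'   `"wobble"` for G:U / U:G, `"mismatch"` otherwise. Whether wobble
#'   scores as a match is decided by `s$wobble_as_match` downstream.
#' @export
#' @examples
#' pair_bases("G", "U")  # "wobble"
pair_bases <- function(antisense_base, mrna_base, s = scoring_scheme()) {
  a <- rna_norm(antisense_base); b <- rna_norm(mrna_base)
  stopifnot(nchar(a) == 1L, nchar(b) == 1L)
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  if (wc[[a]] == b) return("match")
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return("wobble")
  "mismatch"
}

# Vectorized pair status in *target-site space*: tb is the expected
# target-site base (the complement of the antisense base) and mb the
# observed mRNA base. tb == mb is a Watson-Crick pair of the underlying
# duplex; site C against mRNA U (antisense G : mRNA U) and site A against
# mRNA G (antisense U : mRNA G) are the two wobbles.
site_pair_status <- function(tb, mb) {
  status <- rep("mismatch", length(mb))
  status[tb == mb] <- "match"
  status[(tb == "C" & mb == "U") | (tb == "A" & mb == "G")] <- "wobble"
  status
}

status_score <- function(status, s) {
  sc <- ifelse(status == "match", s$match, s$mismatch)
  if (s$wobble_as_match) sc[status == "wobble"] <- s$match
  sc
}

status_paired <- function(status, s) {
  status == "match" | (s$wobble_as_match & status == "wobble")
}

longest_run <- function(flags) {
  if (!length(flags) || !any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under a linear gap model. By default "match"
#' means sequence identity (used when aligning an expected target-site
#' sequence against an mRNA window); with
#' `substitution = "target_site"` the wobble-equivalent substitutions of
#' the guide-mRNA duplex are honored (see [align_duplex()]).
#'
#' Ties are resolved deterministically: the best cell is the first maximum
#' in column-major order and the traceback prefers diagonal over
#' query-gap over target-gap moves.
#'
#' @param a,b nonempty sequences (query and target).
#' @param s a [scoring_scheme()].
#' @param substitution `"identity"` or `"target_site"`.
#' @return object of class `"duplex_alignment"`: `score`,
#'   `query_interval` / `target_interval` (0-based half-open),
#'   `paired_positions`, `longest_contiguous_run`, `pairing_string`
#'   (`|` match, `:` wobble, `.` mismatch, `-` gap) and the per-column
#'   table `columns`.
#' @export
#' @examples
#' smith_waterman("ACGUACGU", "ACGUACGU")$score  # 16
smith_waterman <- function(a, b, s = scoring_scheme(),
                           substitution = c("identity", "target_site")) {
  substitution <- match.arg(substitution)
  a <- rna_norm(a); b <- rna_norm(b)
  if (!nzchar(a) || !nzchar(b)) {
    stop("smith_waterman requires nonempty sequences", call. = FALSE)
  }
  A <- seq_chars(a); B <- seq_chars(b)
  n <- length(A); m <- length(B)

  stat_fun <- if (substitution == "identity") {
    function(ai) ifelse(B == ai, "match", "mismatch")
  } else {
    function(ai) site_pair_status(rep(ai, m), B)
  }

  H <- matrix(0, n + 1L, m + 1L)
  drift <- s$gap * seq_len(m)
  for (i in seq_len(n)) {
    sub <- status_score(stat_fun(A[i]), s)
    v <- pmax(0, H[i, 1:m] + sub, H[i, 2:(m + 1L)] + s$gap)
    # close over left-gap chains: H[i+1, j+1] = max_k<=j v_k + gap*(j-k)
    H[i + 1L, 2:(m + 1L)] <- cummax(v - drift) + drift
  }

  best <- which.max(H)  # first maximum, column-major: deterministic
  score <- H[best]
  ij <- arrayInd(best, dim(H))
  i <- ij[1]; j <- ij[2]

  cols <- list()
  while (i > 1L || j > 1L) {
    if (H[i, j] <= 0) break
    diag_ok <- i > 1L && j > 1L
    if (diag_ok) {
      st <- stat_fun(A[i - 1L])[j - 1L]
      diag_ok <- H[i, j] == H[i - 1L, j - 1L] + status_score(st, s)
    }
    if (diag_ok) {
      cols[[length(cols) + 1L]] <-
        list(a_pos = i - 1L, b_pos = j - 1L, status = st)
      i <- i - 1L; j <- j - 1L
    } else if (i > 1L && H[i, j] == H[i - 1L, j] + s$gap) {
      cols[[length(cols) + 1L]] <-
        list(a_pos = i - 1L, b_pos = NA_integer_, status = "gap")
      i <- i - 1L
    } else if (j > 1L && H[i, j] == H[i, j - 1L] + s$gap) {
      cols[[length(cols) + 1L]] <-
        list(a_pos = NA_integer_, b_pos = j - 1L, status = "gap")
      j <- j - 1L
    } else break
  }
  cols <- rev(cols)
  columns <- data.frame(
    a_pos = vapply(cols, `[[`, integer(1), "a_pos"),
    b_pos = vapply(cols, `[[`, integer(1), "b_pos"),
    status = vapply(cols, `[[`, character(1), "status"),
    stringsAsFactors = FALSE
  )

  paired_flags <- status_paired(columns$status, s) & columns$status != "gap"
  a_used <- columns$a_pos[!is.na(columns$a_pos)]
  b_used <- columns$b_pos[!is.na(columns$b_pos)]
  sym <- c(match = "|", wobble = ":", mismatch = ".", gap = "-")

  structure(
    list(
      score = score,
      query_interval = if (length(a_used))
        c(min(a_used) - 1L, max(a_used)) else c(0L, 0L),
      target_interval = if (length(b_used))
        c(min(b_used) - 1L, max(b_used)) else c(0L, 0L),
      paired_positions = sum(paired_flags),
      longest_contiguous_run = longest_run(paired_flags),
      pairing_string = paste(sym[columns$status], collapse = ""),
      columns = columns,
      scheme = s,
      substitution = substitution,
      anti_status = NULL,
      core_len = NA_integer_
    ),
    class = "duplex_alignment"
  )
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf(
    "<duplex alignment: score %g, %d paired, run %d, query [%d,%d), target [%d,%d)>\n",
    x$score, x$paired_positions, x$longest_contiguous_run,
    x$query_interval[1], x$query_interval[2],
    x$target_interval[1], x$target_interval[2]))
  if (nzchar(x$pairing_string)) cat(" pairing: ", x$pairing_string, "\n")
  invisible(x)
}

#' Align an siRNA duplex against an mRNA window
#'
#' Runs Smith-Waterman between the siRNA's expected target site (the
#' reverse complement of the antisense duplex core, positions 1-19) and
#' the mRNA window, honoring G:U wobble equivalence. Pairing statistics
#' (`paired_positions`, `longest_contiguous_run`) are reported over the
#' duplex core, so the "17 of 19" near-exact denominator is well defined
#' even for 21-nt strands; all numbering is fixed on the antisense strand
#' 5'->3'.
#'
#' @param sirna an [sirna()].
#' @param window mRNA window sequence (from [extract_window()]) or a whole
#'   transcript sequence in full-alignment mode.
#' @param s a [scoring_scheme()].
#' @return a `"duplex_alignment"` whose `anti_status` element gives the
#'   per-antisense-position pairing status over the core
#'   (`match`/`wobble`/`mismatch`/`gap`/`unaligned`).
#' @export
align_duplex <- function(sirna, window, s = scoring_scheme()) {
  stopifnot(inherits(sirna, "sirna"))
  core_len <- min(19L, nchar(sirna$antisense))
  core <- substr(sirna$antisense, 1L, core_len)
  site <- reverse_complement(core)
  aln <- smith_waterman(site, window, s, substitution = "target_site")

  anti_status <- rep("unaligned", core_len)
  cc <- aln$columns
  for (k in seq_len(nrow(cc))) {
    ap <- cc$a_pos[k]
    if (!is.na(ap)) anti_status[core_len + 1L - ap] <- cc$status[k]
  }
  aln$anti_status <- anti_status
  aln$core_len <- core_len
  aln
}

# pairing status of a fixed antisense position against a fixed mRNA
# position (no alignment; used by the positional miRNA-like rules).
# Returns "match"/"wobble"/"mismatch"; positions off the transcript end
# are "mismatch".
anti_pos_status <- function(sirna, tseq, anti_pos, mrna_pos0) {
  if (mrna_pos0 < 0L || mrna_pos0 >= nchar(tseq)) return("mismatch")
  ab <- substr(sirna$antisense, anti_pos, anti_pos)
  mb <- substr(tseq, mrna_pos0 + 1L, mrna_pos0 + 1L)
  pair_bases(ab, mb)
}
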