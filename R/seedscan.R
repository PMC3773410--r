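#' Seed-scan configuration
#'
#' @param seed_len 6 or 7. With 7 the full 2-8 antisense seed is used
#'   (7mer-m8 sites); with 6 the seed is trimmed to antisense positions
#'   2-7, i.e. the 3'-most 6 residues of the mRNA-side motif.
#' @param window_width total width, in nt, of the mRNA window cut around
#'   each seed site and handed to the alignment stage; default 50.
#' @param region `"whole_transcript"` (default) or `"utr3_only"`
#'   (miRNA-like mode; requires `utr3_start` on the transcript).
#' @param allow_wobble_in_seed if `TRUE`, G:U wobble is tolerated inside
#'   the seed match itself (off by default: wobble is an alignment-stage
#'   notion; seed matching is exact).
#' @return object of class `"scan_config"`.
#' @export
scan_config <- function(seed_len = 7L, window_width = 50L,
                        region = c("whole_transcript", "utr3_only"),
                        allow_wobble_in_seed = FALSE) {
  seed_len <- as.integer(seed_len)
  window_width <- as.integer(window_width)
  region <- match.arg(region)
  if (!seed_len %in% c(6L, 7L)) stop("seed_len must be 6 or 7", call. = FALSE)
  if (window_width < seed_len) {
    stop("window_width must be >= seed_len", call. = FALSE)
  }
  structure(
    list(seed_len = seed_len, window_width = window_width, region = region,
         allow_wobble_in_seed = isTRUE(allow_wobble_in_seed)),
    class = "scan_config"
  )
}

# the mRNA-side motif at the configured seed length: the full 7-mer, or its
# 3'-most 6 residues (antisense positions 2-7) when seed_len = 6
scan_motif <- function(sirna, cfg) {
  motif <- seed_site_motif(sirna)
  if (cfg$seed_len == 6L && nchar(motif) == 7L) {
    motif <- substr(motif, 2L, 7L)
  }
  motif
}

# all (possibly overlapping) 0-based start positions of motif in s.
# wobble = TRUE additionally accepts, per position, the mRNA base that
# wobble-pairs with the same antisense base (site C ~ mRNA U, site A ~ mRNA G).
motif_starts <- function(s, motif, wobble = FALSE) {
  if (nchar(s) < nchar(motif)) return(integer(0))
  if (!wobble) {
    # lookahead so overlapping occurrences are all reported
    hits <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
  } else {
    cls <- vapply(seq_chars(motif), function(b) {
      switch(b, A = "[AG]", C = "[CU]", b)
    }, character(1))
    hits <- gregexpr(paste0("(?=", paste(cls, collapse = ""), ")"),
                     s, perl = TRUE)[[1]]
  }
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Locate seed-match sites in a transcript
#'
#' Finds every interval where the transcript exactly matches the siRNA's
#' mRNA-side seed motif (overlapping occurrences are all reported). In
#' `utr3_only` mode, only sites starting at or after `utr3_start` are kept.
#'
#' @param t a [transcript()].
#' @param sirna an [sirna()].
#' @param cfg a [scan_config()].
#' @return data.frame with columns `accession`, `start`, `end` (0-based
#'   half-open), `seed_len`, `in_utr3`, sorted by `start`.
#' @export
#' @examples
#' t <- transcript("NM_TEST", "GGCAGUAUUGG")
#' s <- sirna("s35278", "WNK3", "AAAUACUGACAAACGUGAGGC")
#' find_seed_sites(t, s, scan_config())
find_seed_sites <- function(t, sirna, cfg = scan_config()) {
  stopifnot(inherits(t, "transcript"), inherits(sirna, "sirna"),
            inherits(cfg, "scan_config"))
  if (cfg$region == "utr3_only" && is.null(t$utr3_start)) {
    stop("utr3_only scanning requested but transcript ", t$accession,
         " has no utr3_start", call. = FALSE)
  }
  motif <- scan_motif(sirna, cfg)
  starts <- motif_starts(t$sequence, motif, cfg$allow_wobble_in_seed)
  if (cfg$region == "utr3_only") {
    starts <- starts[starts >= t$utr3_start]
  }
  in_utr3 <- if (is.null(t$utr3_start)) rep(FALSE, length(starts)) else
    starts >= t$utr3_start
  data.frame(
    accession = rep(t$accession, length(starts)),
    start = starts,
    end = starts + cfg$seed_len,
    seed_len = rep(cfg$seed_len, length(starts)),
    in_utr3 = in_utr3,
    stringsAsFactors = FALSE
  )
}

# seed sites with at most one mismatch (exact sites included); used by the
# miRNA-like 3' compensatory rule, which admits a single seed mismatch.
# Wobble counts as a match when wobble_as_match is set on the scheme.
find_seed_sites_mm1 <- function(t, sirna, cfg = scan_config(),
                                wobble_as_match = TRUE) {
  stopifnot(inherits(t, "transcript"), inherits(sirna, "sirna"))
  if (cfg$region == "utr3_only" && is.null(t$utr3_start)) {
    stop("utr3_only scanning requested but transcript ", t$accession,
         " has no utr3_start", call. = FALSE)
  }
  motif <- seq_chars(scan_motif(sirna, cfg))
  k <- length(motif)
  tc <- seq_chars(t$sequence)
  n <- length(tc)
  if (n < k) starts <- integer(0) else {
    npos <- n - k + 1L
    mism <- integer(npos)
    for (j in seq_len(k)) {
      obs <- tc[j:(j + npos - 1L)]
      ok <- obs == motif[j]
      if (wobble_as_match) {
        ok <- ok | (motif[j] == "C" & obs == "U") |
          (motif[j] == "A" & obs == "G")
      }
      mism <- mism + !ok
    }
    starts <- which(mism <= 1L) - 1L
    mm <- mism[starts + 1L]
  }
  if (cfg$region == "utr3_only") {
    keep <- starts >= t$utr3_start
    starts <- starts[keep]; if (length(mm)) mm <- mm[keep]
  }
  in_utr3 <- if (is.null(t$utr3_start)) rep(FALSE, length(starts)) else
    starts >= t$utr3_start
  data.frame(
    accession = rep(t$accession, length(starts)),
    start = starts, end = starts + k,
    seed_len = rep(cfg$seed_len, length(starts)),
    in_utr3 = in_utr3,
    seed_mismatches = if (length(starts)) mm else integer(0),
    stringsAsFactors = FALSE
  )
}

#' Count seed-motif occurrences in a transcript
#'
#' @inheritParams find_seed_sites
#' @return non-negative integer.
#' @export
count_seed_occurrences <- function(t, sirna, cfg = scan_config()) {
  nrow(find_seed_sites(t, sirna, cfg))
}

#' Cut the mRNA window around a seed site
#'
#' The window has total width `cfg$window_width` centred on the site: the
#' left flank gets `floor((width - seed_len) / 2)` nt and the remainder
#' goes right. Windows are clipped at transcript boundaries (and may then
#' be shorter); clipping only ever removes flank, never seed residues.
#'
#' @param t a [transcript()].
#' @param site one row of a [find_seed_sites()] result (or any list with
#'   `start`, `end`).
#' @param cfg a [scan_config()].
#' @return list with `start`, `end` (0-based half-open window interval) and
#'   `sequence` (the slice).
#' @export
extract_window <- function(t, site, cfg = scan_config()) {
  stopifnot(inherits(t, "transcript"))
  len <- nchar(t$sequence)
  s <- as.integer(site$start); e <- as.integer(site$end)
  if (is.na(s) || is.na(e) || s < 0L || e > len || s >= e) {
    stop("seed site [", s, ",", e, ") outside transcript ", t$accession,
         " (length ", len, ")", call. = FALSE)
  }
  seed_len <- e - s
  left <- (cfg$window_width - seed_len) %/% 2L
  right <- cfg$window_width - seed_len - left
  ws <- max(0L, s - left)
  we <- min(len, e + right)
  list(start = ws, end = we,
       sequence = substr(t$sequence, ws + 1L, we))
}
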