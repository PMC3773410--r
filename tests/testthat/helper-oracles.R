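# independent oracles and small generators shared across tests

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# local-alignment score by plain recursive enumeration (no memoisation, no
# DP table): max over all start pairs of the best suffix extension, with
# the option to stop at any point. Tractable only for very short inputs.
sw_oracle_recursive <- function(a, b, s = scoring_scheme()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  ext <- function(i, j) {
    best <- 0
    if (i <= n && j <= m) {
      sc <- if (A[i] == B[j]) s$match else s$mismatch
      best <- max(best, sc + ext(i + 1L, j + 1L))
    }
    if (i <= n) best <- max(best, s$gap + ext(i + 1L, j))
    if (j <= m) best <- max(best, s$gap + ext(i, j + 1L))
    best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) best <- max(best, ext(i, j))
  best
}

# same enumeration formulated top-down with memoised suffix values; usable
# to length ~10
sw_oracle_memo <- function(a, b, s = scoring_scheme()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  memo <- matrix(NA_real_, n + 1L, m + 1L)
  ext <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- 0
    if (i <= n && j <= m) {
      sc <- if (A[i] == B[j]) s$match else s$mismatch
      best <- max(best, sc + ext(i + 1L, j + 1L))
    }
    if (i <= n) best <- max(best, s$gap + ext(i + 1L, j))
    if (j <= m) best <- max(best, s$gap + ext(i, j + 1L))
    memo[i, j] <<- best
    best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) best <- max(best, ext(i, j))
  best
}

# third, fully independent route: Biostrings local alignment with the same
# linear gap model (gapOpening = 0)
sw_oracle_biostrings <- function(a, b, s = scoring_scheme()) {
  mat <- matrix(s$mismatch, 4, 4,
                dimnames = list(c("A", "C", "G", "U"),
                                c("A", "C", "G", "U")))
  diag(mat) <- s$match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(a), Biostrings::RNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = abs(s$gap))
  max(0, Biostrings::score(pa))
}

# position-by-position substring comparison (the naive seed-scan oracle)
naive_motif_starts <- function(seqstr, motif) {
  k <- nchar(motif); n <- nchar(seqstr)
  if (n < k) return(integer(0))
  pos0 <- 0:(n - k)
  pos0[vapply(pos0, function(i) {
    substr(seqstr, i + 1L, i + k) == motif
  }, logical(1))]
}

# all RNA sequences of a given length
all_rna_seqs <- function(len) {
  if (len == 0L) return(character(0))
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "U")), len))
  apply(grid, 1, paste, collapse = "")
}

# a bare duplex_alignment carrying given pairing statistics (unit tests of
# the threshold rules)
stub_alignment <- function(paired, run, anti_status = NULL,
                           scheme = scoring_scheme()) {
  structure(
    list(score = paired * scheme$match,
         query_interval = c(0L, paired), target_interval = c(0L, paired),
         paired_positions = as.integer(paired),
         longest_contiguous_run = as.integer(run),
         pairing_string = strrep("|", paired),
         columns = NULL, scheme = scheme, substitution = "target_site",
         anti_status = anti_status, core_len = 19L),
    class = "duplex_alignment"
  )
}

# mRNA base that pairs (Watson-Crick) a given antisense base
wc_partner <- function(b) chartr("ACGU", "UGCA", b)

# mutate the partner of a given antisense position inside a perfect
# target site (site = reverse complement of the 19-nt core); returns the
# modified site string
mutate_partner <- function(sirna, anti_pos, to = NULL) {
  core <- substr(sirna$antisense, 1L, 19L)
  site <- strsplit(reverse_complement(core), "")[[1]]
  i <- 20L - anti_pos
  ab <- substr(core, anti_pos, anti_pos)
  if (is.null(to)) {
    forbidden <- c(wc_partner(ab), switch(ab, G = "U", U = "G", character(0)))
    to <- setdiff(c("A", "C", "G", "U"), forbidden)[1]
  }
  site[i] <- to
  paste(site, collapse = "")
}
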