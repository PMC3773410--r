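#' Normalize a nucleotide sequence to the internal RNA alphabet
#'
#' All sequences in the package are carried internally as uppercase RNA
#' strings over \{A, C, G, U\}. DNA input is accepted: `T` is mapped to `U`.
#' Whitespace is stripped so sequences pasted from flat-file records work
#' directly.
#'
#' @param x character scalar; nucleotide sequence (RNA or DNA alphabet,
#'   any case).
#' @return uppercase RNA character scalar.
#' @export
#' @examples
#' rna_norm("acgt")   # "ACGU"
rna_norm <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  s <- chartr("tT", "uU", gsub("[[:space:]]", "", x))
  s <- toupper(s)
  bad <- gsub("[ACGU]", "", s)
  if (nzchar(bad)) {
    stop("non-canonical residue(s) after normalization: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  }
  s
}

# split a normalized sequence into a character vector of residues
seq_chars <- function(s) {
  if (!nzchar(s)) return(character(0))
  strsplit(s, "", fixed = TRUE)[[1]]
}

#' Reverse complement of an RNA sequence
#'
#' Complements A<->U and C<->G and reverses the sequence. Used to turn an
#' antisense seed into the mRNA-side site motif it base-pairs with.
#'
#' @param s sequence (normalized internally).
#' @return the reverse complement, RNA alphabet.
#' @export
#' @examples
#' reverse_complement("AAUACUG")  # "CAGUAUU"
reverse_complement <- function(s) {
  s <- rna_norm(s)
  comp <- chartr("ACGU", "UGCA", s)
  paste(rev(seq_chars(comp)), collapse = "")
}

#' Count residues of a sequence
#'
#' @param s sequence (normalized internally).
#' @param alphabet `"RNA"` (counts named A, C, G, U) or `"DNA"` (the U count
#'   is reported under T, matching the source alphabet of a record on
#'   output).
#' @return named integer vector; counts always sum to `nchar(s)`.
#' @export
#' @examples
#' base_count("ACGUACGU")
base_count <- function(s, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  s <- rna_norm(s)
  ch <- seq_chars(s)
  n <- vapply(c("A", "C", "G", "U"), function(b) sum(ch == b), integer(1))
  if (alphabet == "DNA") names(n) <- c("A", "C", "G", "T")
  n
}

#' Construct a transcript
#'
#' @param accession transcript accession (e.g. `NM_`/`NR_`/`XM_`/`XR_`
#'   prefixed); must be nonempty.
#' @param sequence nucleotide sequence (normalized internally).
#' @param gene_symbol gene symbol, used for on-target exclusion.
#' @param utr3_start optional 0-based offset of the first 3'UTR base;
#'   must be smaller than the sequence length.
#' @return object of class `"transcript"`.
#' @export
transcript <- function(accession, sequence, gene_symbol = "",
                       utr3_start = NULL) {
  if (!is.character(accession) || length(accession) != 1L ||
      !nzchar(accession)) {
    stop("accession must be a nonempty string", call. = FALSE)
  }
  sequence <- rna_norm(sequence)
  if (!is.null(utr3_start)) {
    utr3_start <- as.integer(utr3_start)
    if (is.na(utr3_start) || utr3_start < 0L ||
        utr3_start >= nchar(sequence)) {
      stop("utr3_start must lie within the sequence (0 <= utr3_start < ",
           nchar(sequence), ")", call. = FALSE)
    }
  }
  structure(
    list(accession = accession, gene_symbol = gene_symbol,
         sequence = sequence, utr3_start = utr3_start),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s), %d nt%s>\n", x$accession,
              if (nzchar(x$gene_symbol)) x$gene_symbol else "?",
              nchar(x$sequence),
              if (is.null(x$utr3_start)) ""
              else sprintf(", 3'UTR from %d", x$utr3_start)))
  invisible(x)
}

#' Construct an siRNA
#'
#' The antisense (guide) strand is given 5'->3'. The seed region defaults
#' to antisense positions 2-8 (1-based, inclusive; the 7mer-m8 register).
#' A 1-7 register can be requested through `seed_def` for libraries
#' designed around position-1 anchoring. When the sense strand is absent it
#' is derived as the reverse complement of antisense positions 1-19 (the
#' duplex core); the 2-nt 3' overhangs never participate in scoring.
#'
#' @param sirna_id vendor identifier.
#' @param gene on-target gene symbol.
#' @param antisense antisense strand, 5'->3', 19-23 nt.
#' @param sense optional sense strand; derived from the antisense core when
#'   missing.
#' @param seed_def integer pair `(start, end)`, 1-based inclusive positions
#'   of the seed on the antisense strand; default `c(2, 8)`.
#' @return object of class `"sirna"`.
#' @export
#' @examples
#' s <- sirna("s35278", "WNK3", "AAAUACUGACAAACGUGAGGC")
#' extract_seed(s)
sirna <- function(sirna_id, gene, antisense, sense = NULL,
                  seed_def = c(2L, 8L)) {
  antisense <- rna_norm(antisense)
  n <- nchar(antisense)
  if (n < 19L || n > 23L) {
    stop("antisense strand must be 19-23 nt (got ", n, ")", call. = FALSE)
  }
  seed_def <- as.integer(seed_def)
  if (length(seed_def) != 2L || any(is.na(seed_def)) ||
      seed_def[1] < 1L || seed_def[2] > n || seed_def[1] > seed_def[2]) {
    stop("seed_def must lie within the antisense strand", call. = FALSE)
  }
  if (is.null(sense)) {
    sense <- reverse_complement(substr(antisense, 1L, min(19L, n)))
  } else {
    sense <- rna_norm(sense)
  }
  structure(
    list(sirna_id = as.character(sirna_id), on_target_gene = as.character(gene),
         antisense = antisense, sense = sense,
         seed_def = seed_def, center_def = c(8L, 10L)),
    class = "sirna"
  )
}

#' @export
print.sirna <- function(x, ...) {
  cat(sprintf("<siRNA %s -> %s, antisense 5'-%s-3', seed %d-%d>\n",
              x$sirna_id, x$on_target_gene, x$antisense,
              x$seed_def[1], x$seed_def[2]))
  invisible(x)
}

#' Extract the seed region of an siRNA
#'
#' Returns the antisense residues of the seed region (default positions
#' 2-8, a 7-mer).
#'
#' @param sirna an [sirna()] object.
#' @return RNA string of `seed_def[2] - seed_def[1] + 1` residues.
#' @export
extract_seed <- function(sirna) {
  stopifnot(inherits(sirna, "sirna"))
  if (nchar(sirna$antisense) < sirna$seed_def[2]) {
    stop("antisense strand shorter than the seed region", call. = FALSE)
  }
  substr(sirna$antisense, sirna$seed_def[1], sirna$seed_def[2])
}

#' mRNA-side seed site motif
#'
#' The motif a transcript must carry to seed-pair with the siRNA: the
#' reverse complement of the antisense seed region.
#'
#' @inheritParams extract_seed
#' @return RNA string (7 nt under the default seed definition).
#' @export
seed_site_motif <- function(sirna) {
  reverse_complement(extract_seed(sirna))
}

#' G+C fraction of the seed region
#'
#' High seed G/C content is a reported correlate of off-target propensity;
#' the value is reported alongside calls but never used as a filter (no
#' accepted threshold exists).
#'
#' @inheritParams extract_seed
#' @return fraction in `[0, 1]`.
#' @export
seed_gc_fraction <- function(sirna) {
  seed <- extract_seed(sirna)
  ch <- seq_chars(seed)
  sum(ch %in% c("G", "C")) / length(ch)
}
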