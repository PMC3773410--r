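gxp_path <- system.file("extdata", "GXP_170357.seedseq",
                        package = "seedseq", mustWork = TRUE)

test_that("the packaged promoter record parses with exact statistics", {
  r <- read_seedseq(gxp_path)[[1]]
  expect_equal(r$accession, "GXP_170357")
  expect_equal(r$locus_name, "GXP_170357")
  expect_equal(r$length, 743L)
  expect_equal(r$molecule, "DNA")
  bc <- base_count(r$sequence, alphabet = "DNA")
  expect_equal(unname(bc), c(216L, 180L, 147L, 200L))
  df <- definition_fields(r)
  expect_equal(unname(df["sym"]), "TPH2")
  expect_equal(unname(df["geneid"]), "121278")
  expect_equal(unname(df["spec"]), "Homo sapiens")
  expect_equal(unname(df["len"]), "743")
})

test_that("re-parsing the rewritten record is idempotent", {
  r1 <- read_seedseq(gxp_path)[[1]]
  r2 <- read_seedseq(write_seedseq(r1))[[1]]
  expect_identical(r1, r2)
  r3 <- read_seedseq(write_seedseq(r2))[[1]]
  expect_identical(r2, r3)
})

test_that("a 743-nt ORIGIN block spans 13 lines ending with 23 residues", {
  r <- read_seedseq(gxp_path)[[1]]
  lines <- strsplit(write_seedseq(r), "\n")[[1]]
  origin <- which(lines == "ORIGIN")
  seq_lines <- lines[(origin + 1L):(length(lines) - 1L)]
  expect_length(seq_lines, 13L)
  last <- gsub("[^a-zA-Z]", "", seq_lines[13])
  expect_equal(nchar(last), 23L)
  expect_equal(toupper(last), "AGCATCAGCTACTTGGCAGCTCA")
  # position labels are 1-based line starts
  expect_match(seq_lines[13], "^\\s+721 ")
})

test_that("generated records round-trip through write and read", {
  set.seed(61)
  for (k in 1:20) {
    n_feat <- sample(0:3, 1)
    len <- sample(60:400, 1)
    feats <- lapply(seq_len(n_feat), function(i) {
      st <- sample(seq_len(len - 8L), 1)
      list(key = "target_siRNAs", location = c(st, st + 6L),
           qualifiers = list(sirna_id = sprintf("s%05d", sample(1e4, 1)),
                             categories = "mirna_like",
                             seed_occurrences = as.character(sample(5, 1))))
    })
    rec <- seedseq_record(sprintf("NM_%06d", k), rand_rna(len),
                          molecule = sample(c("DNA", "RNA"), 1),
                          definition = sprintf("acc=NM_%06d|len=%d", k, len),
                          features = feats)
    back <- read_seedseq(write_seedseq(rec))[[1]]
    expect_identical(back, rec)
  }
})

test_that("multi-record files split on // and both round-trip", {
  set.seed(62)
  r1 <- seedseq_record("NM_A1", rand_rna(80), molecule = "RNA")
  r2 <- seedseq_record("NM_A2", rand_rna(95), molecule = "RNA")
  back <- read_seedseq(write_seedseq(list(r1, r2)))
  expect_length(back, 2L)
  expect_identical(back[[1]], r1)
  expect_identical(back[[2]], r2)
})

test_that("parse errors carry line numbers; BASE COUNT checks escalate", {
  expect_error(read_seedseq("FOO bar\nbaz"), "line 1.*LOCUS")
  expect_error(read_seedseq("LOCUS NM_X 4 bp RNA\nACCESSION NM_X"),
               "ORIGIN")
  bad_bc <- paste(c("LOCUS NM_X 8 bp RNA",
                    "BASE COUNT 5 a 1 c 1 g 1 u",
                    "ORIGIN", "1 ACGUACGU"), collapse = "\n")
  expect_warning(read_seedseq(bad_bc), "BASE COUNT")
  expect_error(read_seedseq(bad_bc, strict = TRUE), "BASE COUNT")
})

test_that("a record with two target_siRNAs features writes two blocks", {
  rec <- seedseq_record("NM_F", strrep("ACGU", 30), molecule = "RNA",
    features = list(
      list(key = "target_siRNAs", location = c(5, 11),
           qualifiers = list(sirna_id = "s1")),
      list(key = "target_siRNAs", location = c(40, 46),
           qualifiers = list(sirna_id = "s2"))))
  lines <- strsplit(write_seedseq(rec), "\n")[[1]]
  expect_length(grep("^\\s+target_siRNAs\\s", lines), 2L)
  expect_error(seedseq_record("NM_F", "ACGU",
    features = list(list(key = "x", location = c(1, 9)))), "bounds")
})

test_that("the BASE COUNT line always matches the written sequence", {
  set.seed(63)
  for (k in 1:5) {
    rec <- seedseq_record("NM_B", rand_rna(sample(50:200, 1)),
                          molecule = "DNA")
    txt <- write_seedseq(rec)
    bc_line <- grep("^BASE COUNT", strsplit(txt, "\n")[[1]], value = TRUE)
    nums <- as.integer(regmatches(bc_line, gregexpr("\\d+", bc_line))[[1]])
    expect_equal(nums, unname(base_count(rec$sequence, "DNA")))
  }
})

test_that("transcripts are annotated with one feature per siRNA", {
  motif_t <- transcript("NM_T", paste0(strrep("G", 30), "CAGUAUU",
                                       strrep("G", 30)),
                        gene_symbol = "ZEB1", utr3_start = 20L)
  s <- sirna("s35278", "WNK3", "AAAUACUGACAAACGUGAGGC")
  recs <- call_offtargets(s, list(motif_t))
  ann <- annotate_transcript(motif_t, recs)
  expect_length(ann$features, 1L)
  f <- ann$features[[1]]
  expect_equal(f$key, "target_siRNAs")
  expect_equal(f$qualifiers$sirna_id, "s35278")
  expect_equal(f$location, c(31L, 37L))

  # no off-targets -> no features; duplicates deduplicate
  expect_length(annotate_transcript(motif_t, list())$features, 0L)
  expect_length(annotate_transcript(motif_t, c(recs, recs))$features, 1L)
  # mismatched accession is refused
  other <- transcript("NM_OTHER", "ACGUACGU")
  expect_error(annotate_transcript(other, recs), "does not reference")
})

test_that("seven off-targeting siRNAs produce seven features", {
  set.seed(64)
  sirnas <- lapply(1:7, function(i)
    sirna(sprintf("s%02d", i), sprintf("G%02d", i), rand_rna(21)))
  motifs <- vapply(sirnas, seed_site_motif, character(1))
  seqstr <- paste0(rand_rna(20),
                   paste(vapply(motifs, function(m)
                     paste0(m, rand_rna(5)), character(1)), collapse = ""),
                   rand_rna(10))
  t <- transcript("NM_7", seqstr, gene_symbol = "TARGET7", utr3_start = 10L)
  recs <- unlist(lapply(sirnas, function(s) call_offtargets(s, list(t))),
                 recursive = FALSE)
  ann <- annotate_transcript(t, recs)
  expect_length(ann$features, 7L)
  ids <- vapply(ann$features, function(f) f$qualifiers$sirna_id, "")
  expect_equal(ids, sort(ids))  # deterministic order
})
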