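# a small spec used throughout (fewer transcripts than the default keeps
# the suite fast while still planting every class)
small_spec <- function(seed = 7L) {
  fixture_spec(rng_seed = seed,
               n_transcripts = 8L,
               planted = c(near_exact = 1L, partial_contiguous11 = 1L,
                           partial_total15 = 1L, m8_seed = 2L,
                           compensatory = 1L, decoy_nonconserved = 1L),
               library_size = 2L)
}

test_that("generation is fully deterministic given the seed", {
  fs <- small_spec()
  lib1 <- generate_library(fs); lib2 <- generate_library(fs)
  expect_identical(lib1, lib2)
  tr1 <- generate_transcriptome(fs, lib1)
  tr2 <- generate_transcriptome(fs, lib2)
  expect_identical(tr1, tr2)
  cs1 <- generate_conserved(fs, tr1); cs2 <- generate_conserved(fs, tr2)
  expect_identical(cs1, cs2)
  e1 <- generate_expression(fs, c("NM_1", "NM_2"))
  e2 <- generate_expression(fs, c("NM_1", "NM_2"))
  expect_identical(e1, e2)
})

test_that("generated strands are 21 nt with valid seeds", {
  lib <- generate_library(fixture_spec(rng_seed = 3, library_size = 6))
  expect_length(lib, 6L)
  for (s in lib) {
    expect_equal(nchar(s$antisense), 21L)
    expect_equal(nchar(extract_seed(s)), 7L)
  }
  # no two share a seed motif (collision-free construction)
  motifs <- vapply(lib, seed_site_motif, character(1))
  expect_equal(anyDuplicated(motifs), 0L)
})

test_that("the packaged reference library is shipped verbatim", {
  lib <- mirna_matched_sirnas()
  byid <- setNames(lib, vapply(lib, `[[`, "", "sirna_id"))
  expect_equal(byid$s35278$antisense, "AAAUACUGACAAACGUGAGGC")
  expect_equal(byid$s30875$antisense, "AAAUACUGAUAUCCAAUGGGC")
  expect_equal(byid$s35278$on_target_gene, "WNK3")
  assoc <- attr(mirna_matched_sirnas(unique_sirnas = FALSE), "associations")
  expect_equal(nrow(assoc), 13L)
  expect_length(mirna_matched_sirnas(unique_sirnas = FALSE), 13L)
})

test_that("every planted seed site is recovered and nothing else", {
  fs <- small_spec()
  lib <- generate_library(fs)
  tr <- generate_transcriptome(fs, lib)
  man <- tr$manifest
  byid <- setNames(lib, vapply(lib, `[[`, "", "sirna_id"))
  exact_classes <- c("near_exact", "m8_seed", "decoy_nonconserved")
  for (t in tr$transcriptome) {
    for (s in lib) {
      exp_starts <- sort(man$site_start[
        man$accession == t$accession & man$sirna_id == s$sirna_id &
          man$class %in% exact_classes])
      got <- sort(find_seed_sites(t, s)$start)
      expect_identical(got, as.integer(exp_starts))
    }
  }
  # recall of planted m8 sites specifically is 1.0
  m8 <- man[man$class == "m8_seed", ]
  expect_gt(nrow(m8), 0L)
  for (i in seq_len(nrow(m8))) {
    t <- Filter(function(x) x$accession == m8$accession[i],
                tr$transcriptome)[[1]]
    st <- find_seed_sites(t, byid[[m8$sirna_id[i]]])
    expect_true(m8$site_start[i] %in% st$start)
  }
})

test_that("planted near-exact regions align with at least 17 paired", {
  fs <- small_spec()
  lib <- generate_library(fs)
  tr <- generate_transcriptome(fs, lib)
  man <- tr$manifest
  byid <- setNames(lib, vapply(lib, `[[`, "", "sirna_id"))
  ne <- man[man$class == "near_exact", ]
  expect_gt(nrow(ne), 0L)
  for (i in seq_len(nrow(ne))) {
    t <- Filter(function(x) x$accession == ne$accession[i],
                tr$transcriptome)[[1]]
    w <- substr(t$sequence, ne$start[i] - 9L, ne$end[i] + 10L)
    aln <- align_duplex(byid[[ne$sirna_id[i]]], w)
    expect_gte(aln$paired_positions, 17L)
  }
})

test_that("planted partial classes carry the promised pairing statistics", {
  fs <- small_spec()
  lib <- generate_library(fs)
  tr <- generate_transcriptome(fs, lib)
  man <- tr$manifest
  byid <- setNames(lib, vapply(lib, `[[`, "", "sirna_id"))
  for (cls in c("partial_contiguous11", "partial_total15")) {
    rows <- man[man$class == cls, ]
    expect_gt(nrow(rows), 0L)
    for (i in seq_len(nrow(rows))) {
      t <- Filter(function(x) x$accession == rows$accession[i],
                  tr$transcriptome)[[1]]
      aln <- align_duplex(byid[[rows$sirna_id[i]]], t$sequence)
      if (cls == "partial_contiguous11") {
        expect_gte(aln$longest_contiguous_run, 11L)
      } else {
        expect_gte(aln$paired_positions, 15L)
        expect_lt(aln$paired_positions, 17L)
      }
    }
  }
})

test_that("the conservation track covers planted sites but never decoys", {
  fs <- small_spec()
  lib <- generate_library(fs)
  tr <- generate_transcriptome(fs, lib)
  cset <- generate_conserved(fs, tr)
  man <- tr$manifest
  cons <- man[!is.na(man$conserved) & man$conserved &
                !is.na(man$site_start), ]
  for (i in seq_len(nrow(cons))) {
    expect_true(is_conserved(list(accession = cons$accession[i],
                                  start = cons$site_start[i],
                                  end = cons$site_end[i]), cset))
  }
  dec <- man[!is.na(man$conserved) & !man$conserved, ]
  expect_gt(nrow(dec), 0L)
  for (i in seq_len(nrow(dec))) {
    expect_false(is_conserved(list(accession = dec$accession[i],
                                   start = dec$site_start[i],
                                   end = dec$site_end[i]), cset))
  }
})

test_that("fixture files round-trip through the pipeline readers", {
  fs <- small_spec()
  dir <- withr::local_tempdir()
  paths <- write_fixture_set(fs, dir)
  expect_true(all(file.exists(paths)))
  tr_back <- read_transcriptome(paths["transcriptome"])
  tr <- generate_transcriptome(fs, generate_library(fs))
  expect_equal(length(tr_back), length(tr$transcriptome))
  expect_identical(tr_back[[1]], tr$transcriptome[[1]])
  lib_back <- read_sirna_library(paths["library"])
  expect_identical(lib_back, generate_library(fs))
  cs_back <- read_conserved(paths["conserved"])
  expect_identical(cs_back$intervals,
                   generate_conserved(fs, tr)$intervals)
  expr_back <- read_expression(paths["expression"])
  expect_equal(nrow(expr_back) > 0, TRUE)
})

test_that("infeasible fixture specs are rejected", {
  expect_error(fixture_spec(planted = c(bogus_class = 1L)), "unknown")
  expect_error(fixture_spec(length_range = c(50L, 60L)), "length_range")
})
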