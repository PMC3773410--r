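test_that("intervals merge when overlapping or adjacent, then length-filter", {
  cs <- conserved_intervals(data.frame(
    accession = c("NM_X", "NM_X"), start = c(0L, 4L), end = c(6L, 12L)))
  expect_equal(cs$intervals$start, 0L)
  expect_equal(cs$intervals$end, 12L)

  # a 7-long interval is dropped under the 8-nt minimum
  short <- conserved_intervals(data.frame(
    accession = "NM_X", start = 5L, end = 12L))
  expect_equal(nrow(short$intervals), 0L)
  kept <- conserved_intervals(data.frame(
    accession = "NM_X", start = 5L, end = 13L))
  expect_equal(nrow(kept$intervals), 1L)

  # adjacent short pieces can merge into a retained interval
  adj <- conserved_intervals(data.frame(
    accession = "NM_X", start = c(0L, 4L), end = c(4L, 9L)))
  expect_equal(adj$intervals$end - adj$intervals$start, 9L)

  empty <- conserved_intervals(data.frame(
    accession = character(0), start = integer(0), end = integer(0)))
  expect_equal(nrow(empty$intervals), 0L)
})

test_that("malformed rows are rejected with their row number", {
  expect_error(conserved_intervals(data.frame(
    accession = c("NM_X", "NM_Y"), start = c(0L, 9L), end = c(8L, 9L))),
    "row\\(s\\) 2")
})

test_that("conservation requires full containment, not overlap", {
  cs <- conserved_intervals(data.frame(
    accession = "NM_X", start = 5L, end = 20L))
  expect_true(is_conserved(list(accession = "NM_X", start = 10L, end = 17L),
                           cs))
  cs2 <- conserved_intervals(data.frame(
    accession = "NM_X", start = 12L, end = 30L))
  expect_false(is_conserved(list(accession = "NM_X", start = 10L, end = 17L),
                            cs2))
  expect_false(is_conserved(list(accession = "NM_Z", start = 10L, end = 17L),
                            cs))
})

# a record whose miRNA-like support sits at known positions
planted_record <- function() {
  s <- sirna("s35278", "WNK3", "AAAUACUGACAAACGUGAGGC")
  motif <- seed_site_motif(s)
  set.seed(51)
  seqstr <- paste0(rand_rna(30), motif, rand_rna(80), motif, rand_rna(20))
  t <- transcript("NM_P", seqstr, gene_symbol = "OTHER", utr3_start = 25L)
  # the miRNA-like search variant: the record's only support is its sites
  recs <- call_offtargets(s, list(t), mode = "mirna_like")
  stopifnot(length(recs) == 1L, nrow(recs[[1]]$mirna_sites) == 2L,
            identical(recs[[1]]$categories, "mirna_like"))
  list(rec = recs[[1]], t = t)
}

test_that("filtering keeps records with at least one conserved site", {
  pr <- planted_record()
  sites <- pr$rec$mirna_sites
  # cover only the first site
  cs <- conserved_intervals(data.frame(
    accession = "NM_P", start = sites$start[1] - 1L,
    end = sites$end[1] + 1L))
  out <- filter_conserved(list(pr$rec), cs)
  expect_length(out, 1L)
  expect_equal(out[[1]]$conserved_site_count, 1L)
  expect_equal(nrow(out[[1]]$mirna_sites), 1L)

  # cover nothing -> record dropped entirely (only miRNA-like support)
  none <- conserved_intervals(data.frame(
    accession = "NM_P", start = 0L, end = 9L))
  expect_length(filter_conserved(list(pr$rec), none), 0L)

  expect_length(filter_conserved(list(), cs), 0L)
})

test_that("filtering never adds records and full coverage is the identity", {
  pr <- planted_record()
  full <- conserved_intervals(data.frame(
    accession = "NM_P", start = 0L, end = nchar(pr$t$sequence)))
  out <- filter_conserved(list(pr$rec), full)
  expect_length(out, 1L)
  expect_equal(out[[1]]$categories, pr$rec$categories)
  expect_equal(out[[1]]$mirna_sites, pr$rec$mirna_sites)

  # subset property under an arbitrary partial track
  set.seed(52)
  part <- conserved_intervals(data.frame(
    accession = "NM_P", start = c(0L, 40L), end = c(20L, 60L)))
  sub <- filter_conserved(list(pr$rec), part)
  expect_lte(length(sub), 1L)
  if (length(sub)) {
    expect_true(all(sub[[1]]$categories %in% pr$rec$categories))
  }
})

test_that("near-exact and partial calls survive conservation filtering", {
  s <- sirna("s35278", "WNK3", "AAAUACUGACAAACGUGAGGC")
  site <- reverse_complement(substr(s$antisense, 1, 19))
  set.seed(53)
  t <- transcript("NM_Q", paste0(rand_rna(40), site, rand_rna(40)),
                  gene_symbol = "OTHER", utr3_start = 95L)
  recs <- call_offtargets(s, list(t), mode = "seed_window_sw")
  none <- conserved_intervals(data.frame(
    accession = "NM_Q", start = 0L, end = 8L))
  out <- filter_conserved(recs, none)
  expect_length(out, 1L)
  expect_setequal(out[[1]]$categories, c("near_exact", "partial"))
})
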