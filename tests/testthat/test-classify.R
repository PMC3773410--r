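s35278 <- sirna("s35278", "WNK3", "AAAUACUGACAAACGUGAGGC")

test_that("alignment categories respect their thresholds at the boundary", {
  cfg <- classifier_config()
  expect_setequal(classify_alignment(stub_alignment(17, 9), cfg),
                  c("near_exact", "partial"))
  expect_setequal(classify_alignment(stub_alignment(16, 9), cfg), "partial")
  expect_setequal(classify_alignment(stub_alignment(14, 11), cfg), "partial")
  expect_equal(classify_alignment(stub_alignment(14, 10), cfg), character(0))
  expect_setequal(classify_alignment(stub_alignment(15, 8), cfg), "partial")
  expect_equal(classify_alignment(stub_alignment(14, 8), cfg), character(0))
  expect_equal(classify_alignment(stub_alignment(10, 8), cfg), character(0))
})

test_that("near-exact implies partial under default thresholds", {
  cfg <- classifier_config()
  set.seed(41)
  for (k in 1:50) {
    paired <- sample(0:19, 1)
    run <- sample(0:paired, 1)
    cats <- classify_alignment(stub_alignment(paired, run), cfg)
    if ("near_exact" %in% cats) expect_true("partial" %in% cats)
  }
})

test_that("raising any threshold never adds categories", {
  set.seed(42)
  for (k in 1:40) {
    paired <- sample(0:19, 1); run <- sample(0:paired, 1)
    aln <- stub_alignment(paired, run)
    base <- classify_alignment(aln, classifier_config())
    for (cfg in list(classifier_config(near_exact_min_paired = 18),
                     classifier_config(partial_min_contiguous = 12),
                     classifier_config(partial_min_total = 16))) {
      expect_true(all(classify_alignment(aln, cfg) %in% base))
    }
  }
})

test_that("cleavage competence requires pairing across positions 8-10", {
  expect_true(cleavage_competent(align_duplex(
    s35278, reverse_complement(substr(s35278$antisense, 1, 19)))))
  expect_false(cleavage_competent(align_duplex(
    s35278, mutate_partner(s35278, 9L))))
  # wobble at position 9: antisense base at 9 is C -> mRNA G; use a
  # position with G or U instead so a wobble exists
  core <- substr(s35278$antisense, 1, 19)
  b9 <- substr(core, 9, 9)
  wob <- switch(b9, G = "U", U = "G", NA)
  if (!is.na(wob)) {
    site_w <- mutate_partner(s35278, 9L, to = wob)
    expect_true(cleavage_competent(align_duplex(s35278, site_w)))
    expect_false(cleavage_competent(align_duplex(
      s35278, site_w, scoring_scheme(wobble_as_match = FALSE))))
  }
  expect_error(cleavage_competent(smith_waterman("ACGU", "ACGU")),
               "align_duplex")
})

test_that("wobble at the cleavage site toggles with the scheme", {
  # construct an siRNA with U at antisense position 9 so U:G wobble exists
  anti <- paste0("AACGUACG", "U", "ACGUACGUACGU")  # 21 nt
  s <- sirna("wob9", "G", anti)
  site_w <- mutate_partner(s, 9L, to = "G")
  expect_true(cleavage_competent(align_duplex(s, site_w)))
  expect_false(cleavage_competent(
    align_duplex(s, site_w, scoring_scheme(wobble_as_match = FALSE))))
})

make_utr_transcript <- function(site_seq, utr3_start = 20L, flank = 30L) {
  set.seed(43)
  transcript("NM_UTR",
             paste0(rand_rna(utr3_start + 5L), site_seq, rand_rna(flank)),
             utr3_start = utr3_start)
}

test_that("miRNA-like rule 1: perfect m8 seed site in the 3'UTR", {
  t <- make_utr_transcript(seed_site_motif(s35278))
  st <- find_seed_sites(t, s35278)
  expect_equal(nrow(st), 1L)
  expect_true(classify_mirna_like(s35278, t, st[1, ]))
})

test_that("miRNA-like rule 1 fails outside the 3'UTR by default", {
  seqstr <- paste0("GG", seed_site_motif(s35278), rand_rna(30))
  t <- transcript("NM_CDS", seqstr, utr3_start = 30L)
  st <- find_seed_sites(t, s35278)
  expect_false(classify_mirna_like(s35278, t, st[1, ]))
  # whole-transcript mode admits it
  cfg <- classifier_config(require_utr3_for_mirna_like = FALSE)
  expect_true(classify_mirna_like(s35278, t, st[1, ], cfg))
})

test_that("miRNA-like requires a 3'UTR annotation when restricted", {
  t <- transcript("NM_NOUTR", paste0("GG", seed_site_motif(s35278), "GG"))
  st <- find_seed_sites(t, s35278)
  expect_error(classify_mirna_like(s35278, t, st[1, ]), "utr3_start")
})

test_that("miRNA-like rule 2: one seed mismatch rescued by 13-19 pairing", {
  # full 19-nt planted site with the partner of antisense position 5
  # mutated: one seed mismatch, compensatory region perfectly paired
  site <- mutate_partner(s35278, 5L)
  t <- make_utr_transcript(site)
  mm1 <- seedseq:::find_seed_sites_mm1(t, s35278)
  mm1 <- mm1[mm1$seed_mismatches == 1L, ]
  expect_equal(nrow(mm1), 1L)
  expect_true(classify_mirna_like(s35278, t, mm1[1, ]))

  # additionally break the compensatory region -> both clauses fail
  site2 <- strsplit(site, "")[[1]]
  site2[20L - 15L] <- setdiff(c("A", "C", "G", "U"),
                              c(site2[20L - 15L],
                                wc_partner(substr(s35278$antisense, 15, 15)),
                                switch(substr(s35278$antisense, 15, 15),
                                       G = "U", U = "G", character(0))))[1]
  t2 <- make_utr_transcript(paste(site2, collapse = ""))
  mm2 <- seedseq:::find_seed_sites_mm1(t2, s35278)
  mm2 <- mm2[mm2$seed_mismatches == 1L, ]
  expect_equal(nrow(mm2), 1L)
  expect_false(classify_mirna_like(s35278, t2, mm2[1, ]))
})

test_that("off-target calling excludes the on-target gene", {
  site <- reverse_complement(substr(s35278$antisense, 1, 19))
  on_t <- transcript("NM_ON", paste0(rand_rna(10), site, rand_rna(10)),
                     gene_symbol = "WNK3", utr3_start = 5L)
  recs <- call_offtargets(s35278, list(on_t))
  expect_length(recs, 0L)
  expect_length(call_offtargets(s35278, list()), 0L)
})

test_that("a planted perfect-m8 3'UTR site yields one miRNA-like record", {
  t <- make_utr_transcript(seed_site_motif(s35278))
  t$gene_symbol <- "OTHER"
  recs <- call_offtargets(s35278, list(t))
  expect_length(recs, 1L)
  expect_true("mirna_like" %in% recs[[1]]$categories)
  expect_equal(recs[[1]]$seed_occurrences, 1L)
})

test_that("a planted 19/19 region yields near-exact + partial, cleavable", {
  site <- reverse_complement(substr(s35278$antisense, 1, 19))
  set.seed(44)
  t <- transcript("NM_NE", paste0(rand_rna(40), site, rand_rna(40)),
                  gene_symbol = "OTHER", utr3_start = 70L)
  recs <- call_offtargets(s35278, list(t), mode = "seed_window_sw")
  expect_length(recs, 1L)
  expect_setequal(recs[[1]]$categories, c("near_exact", "partial"))
  expect_true(recs[[1]]$cleavage_competent)
  expect_equal(recs[[1]]$best_alignment$paired_positions, 19L)
})

test_that("records flatten to a well-formed table", {
  t <- make_utr_transcript(seed_site_motif(s35278))
  t$gene_symbol <- "OTHER"
  recs <- call_offtargets(s35278, list(t))
  tab <- offtarget_table(recs)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$sirna_id, "s35278")
  expect_equal(tab$categories, "mirna_like")
  expect_equal(tab$seed_gc, 2 / 7)
  empty <- offtarget_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("sirna_id", "accession", "categories") %in% names(empty)))
})
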