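#' Fixture generator specification
#'
#' Describes a fully deterministic synthetic data set: a random siRNA
#' library, a transcriptome with planted off-target sites of known
#' classes (plus an exhaustive ground-truth manifest), a conservation
#' track and an expression-change table. Each generator reseeds its own
#' documented RNG stream (`rng_seed` + a fixed offset), so adding one
#' generator never shifts another's output.
#'
#' Planted classes: `near_exact` (perfect 19-nt duplex core partner),
#' `partial_contiguous11` (partners of antisense 9-19: an 11-nt
#' contiguous run, no seed), `partial_total15` (15 paired positions, max
#' run 8, one seed mismatch), `m8_seed` (exact 7mer-m8 site in the
#' 3'UTR), `compensatory` (one seed mismatch rescued by perfect
#' antisense 13-19 pairing, 3'UTR), `decoy_nonconserved` (an m8 site the
#' conservation track deliberately does not cover).
#'
#' @param rng_seed integer master seed.
#' @param n_transcripts number of background transcripts.
#' @param length_range transcript length range in nt.
#' @param utr3_fraction fraction of each transcript that is 3'UTR.
#' @param planted named integer vector of planted-site counts per class.
#' @param library_size number of random siRNAs.
#' @param tp_rate probability a predicted off-target is a true one in the
#'   generated expression table.
#' @param conservation_coverage approximate background fraction of each
#'   transcript covered by conserved intervals (planted conserved sites
#'   are always covered; decoys never).
#' @return object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(rng_seed = 1L,
                         n_transcripts = 14L,
                         length_range = c(400L, 600L),
                         utr3_fraction = 0.4,
                         planted = c(near_exact = 2L,
                                     partial_contiguous11 = 2L,
                                     partial_total15 = 2L,
                                     m8_seed = 4L,
                                     compensatory = 2L,
                                     decoy_nonconserved = 2L),
                         library_size = 3L,
                         tp_rate = 0.65,
                         conservation_coverage = 0.3) {
  stopifnot(all(planted >= 0), utr3_fraction >= 0, utr3_fraction <= 1,
            tp_rate >= 0, tp_rate <= 1,
            conservation_coverage >= 0, conservation_coverage <= 1,
            length_range[1] >= 150L)
  known <- c("near_exact", "partial_contiguous11", "partial_total15",
             "m8_seed", "compensatory", "decoy_nonconserved")
  if (!all(names(planted) %in% known)) {
    stop("unknown planted class(es): ",
         paste(setdiff(names(planted), known), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(rng_seed = as.integer(rng_seed),
         n_transcripts = as.integer(n_transcripts),
         length_range = as.integer(length_range),
         utr3_fraction = utr3_fraction,
         planted = planted,
         library_size = as.integer(library_size),
         tp_rate = tp_rate,
         conservation_coverage = conservation_coverage),
    class = "fixture_spec"
  )
}

# documented RNG stream offsets, one per generator
.fixture_streams <- c(library = 1000L, transcriptome = 2000L,
                      conserved = 3000L, expression = 4000L)

seed_stream <- function(fspec, stream) {
  set.seed((fspec$rng_seed + .fixture_streams[[stream]]) %%
             .Machine$integer.max)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# an mRNA base that neither Watson-Crick- nor wobble-pairs the given
# antisense base
nonpairing_base <- function(anti_base) {
  forbidden <- switch(anti_base,
                      A = "U", C = "G",
                      G = c("C", "U"), U = c("A", "G"))
  choices <- setdiff(c("A", "C", "G", "U"), forbidden)
  if (length(choices) == 1L) choices else sample(choices, 1L)
}

#' Generate a random siRNA library
#'
#' Random 21-nt antisense strands with valid seeds. Strands are
#' rejection-sampled so that no two siRNAs share a 7-mer seed motif and
#' no siRNA's motif occurs inside another's expected target site
#' (keeping planted sites attributable to a single siRNA).
#'
#' @param fspec a [fixture_spec()].
#' @return list of [sirna()] objects.
#' @export
generate_library <- function(fspec) {
  stopifnot(inherits(fspec, "fixture_spec"))
  seed_stream(fspec, "library")
  lib <- list()
  motifs <- character(0)
  sites <- character(0)
  k <- 0L
  while (length(lib) < fspec$library_size) {
    k <- k + 1L
    if (k > 1000L) stop("could not draw a collision-free library")
    cand <- sirna(sprintf("sim_siRNA_%02d", length(lib) + 1L),
                  sprintf("TGT%02d", length(lib) + 1L),
                  rand_seq(21L))
    motif <- seed_site_motif(cand)
    site <- reverse_complement(substr(cand$antisense, 1L, 19L))
    clash <- motif %in% motifs ||
      any(vapply(sites, function(s) grepl(motif, s, fixed = TRUE),
                 logical(1))) ||
      any(vapply(motifs, function(m) grepl(m, site, fixed = TRUE),
                 logical(1)))
    if (!clash) {
      lib[[length(lib) + 1L]] <- cand
      motifs <- c(motifs, motif)
      sites <- c(sites, site)
    }
  }
  lib
}

# --- planted segment constructors -------------------------------------
# rc_core[i] is the partner of antisense position (core_len + 1 - i);
# mutations are expressed in antisense coordinates.

plant_segment <- function(sirna, class) {
  core <- substr(sirna$antisense, 1L, 19L)
  s <- seq_chars(reverse_complement(core))
  a <- seq_chars(core)
  mutate_at <- function(anti_pos) {
    for (p in anti_pos) s[20L - p] <<- nonpairing_base(a[p])
  }
  switch(class,
    near_exact = {},
    partial_contiguous11 = {
      s <- seq_chars(reverse_complement(substr(core, 9L, 19L)))
    },
    partial_total15 = mutate_at(c(8L, 17L, 18L, 19L)),
    compensatory = mutate_at(c(5L, 9L, 10L, 11L, 12L)),
    m8_seed = ,
    decoy_nonconserved = {
      s <- seq_chars(seed_site_motif(sirna))
    },
    stop("unknown planted class: ", class)
  )
  paste(s, collapse = "")
}

# 0-based start of the embedded seed site within a planted segment
# (NA when the segment carries no exact or near-miss seed site)
plant_site_offset <- function(class) {
  switch(class,
         near_exact = 11L, partial_total15 = 11L, compensatory = 11L,
         m8_seed = 0L, decoy_nonconserved = 0L,
         partial_contiguous11 = NA_integer_)
}

# class -> off-target categories the default classifier (mode "all")
# must produce for the planted transcript
plant_categories <- function(class) {
  switch(class,
         near_exact = c("near_exact", "partial"),
         m8_seed = , compensatory = , decoy_nonconserved = "mirna_like",
         partial_contiguous11 = , partial_total15 = character(0))
}

#' Expected off-target calls implied by a fixture manifest
#'
#' Folds a ground-truth manifest into the per-(siRNA, transcript) calls
#' the default classifier (mode `"all"`) must emit.
#'
#' @param manifest manifest data.frame from [generate_transcriptome()].
#' @return data.frame `sirna_id`, `accession`, `categories`
#'   (comma-joined, sorted), one row per pair with nonempty categories,
#'   ordered by sirna_id then accession.
#' @export
expected_offtarget_calls <- function(manifest) {
  keys <- unique(manifest[, c("sirna_id", "accession")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    cls <- manifest$class[manifest$sirna_id == keys$sirna_id[i] &
                            manifest$accession == keys$accession[i]]
    cats <- sort(unique(unlist(lapply(cls, plant_categories))))
    if (!length(cats)) return(NULL)
    data.frame(sirna_id = keys$sirna_id[i], accession = keys$accession[i],
               categories = paste(cats, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(sirna_id = character(0), accession = character(0),
                      categories = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$sirna_id, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# does this transcript, classified with all-default configurations,
# produce exactly the calls and sites its manifest rows promise?
audit_transcript <- function(t, lib, rows) {
  scan_cfg <- scan_config(); scheme <- scoring_scheme()
  cls_cfg <- classifier_config()
  for (s in lib) {
    mine <- rows[rows$sirna_id == s$sirna_id, , drop = FALSE]
    exp_exact <- sort(mine$site_start[
      mine$class %in% c("near_exact", "m8_seed", "decoy_nonconserved")])
    got_exact <- sort(find_seed_sites(t, s, scan_cfg)$start)
    if (!identical(as.integer(got_exact), as.integer(exp_exact))) {
      return(FALSE)
    }
    rec <- classify_transcript(s, t, scan_cfg, scheme, cls_cfg, "all")
    exp_cats <- sort(unique(unlist(lapply(mine$class, plant_categories))))
    if (is.null(rec)) {
      if (length(exp_cats)) return(FALSE)
      next
    }
    if (!identical(rec$categories, exp_cats)) return(FALSE)
    exp_mirna <- sort(mine$site_start[
      mine$class %in% c("m8_seed", "decoy_nonconserved", "compensatory")])
    got_mirna <- if (is.null(rec$mirna_sites)) integer(0) else
      sort(rec$mirna_sites$start)
    if (!identical(as.integer(got_mirna), as.integer(exp_mirna))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Generate a transcriptome with planted off-target sites
#'
#' Backgrounds are rejection-sampled until, for every library siRNA, the
#' exact seed-motif occurrences and the default classifier's calls match
#' the planted ground truth exactly — so the returned manifest is
#' exhaustive: every planted site is detectable by the stage it targets
#' and no stage detects anything absent from the manifest.
#'
#' @param fspec a [fixture_spec()].
#' @param lib siRNA library, default [generate_library()] under the same
#'   spec.
#' @return list with `transcriptome` (list of [transcript()]) and
#'   `manifest` (data.frame: `accession`, `sirna_id`, `class`, `start`,
#'   `end` — the planted segment, 0-based half-open — `site_start`,
#'   `site_end` — the embedded seed site, NA for seedless classes — and
#'   `conserved`).
#' @export
generate_transcriptome <- function(fspec, lib = generate_library(fspec)) {
  stopifnot(inherits(fspec, "fixture_spec"))
  force(lib)  # evaluate before seeding: lib may itself draw from the RNG
  seed_stream(fspec, "transcriptome")

  classes <- rep(names(fspec$planted), fspec$planted)
  n_tr <- fspec$n_transcripts
  if (length(classes) && n_tr == 0L) {
    stop("cannot plant sites without transcripts", call. = FALSE)
  }
  # round-robin assignment of plants to transcripts and siRNAs
  assign_tr <- if (length(classes))
    ((seq_along(classes) - 1L) %% n_tr) + 1L else integer(0)
  assign_si <- if (length(classes))
    ((seq_along(classes) - 1L) %% length(lib)) + 1L else integer(0)

  lens <- sample(seq(fspec$length_range[1], fspec$length_range[2]),
                 n_tr, replace = TRUE)
  transcriptome <- vector("list", n_tr)
  manifest <- list()

  for (i in seq_len(n_tr)) {
    L <- lens[i]
    utr3 <- as.integer(floor(L * (1 - fspec$utr3_fraction)))
    acc <- sprintf("NM_SIM%04d", i)
    gene <- sprintf("GEN%03d", i)
    my_plants <- which(assign_tr == i)
    longest <- if (length(my_plants)) 19L else 0L
    if (utr3 < longest + 40L || L - utr3 < longest + 40L) {
      stop("transcripts too short for the requested plants", call. = FALSE)
    }
    ok <- FALSE
    for (try in seq_len(200L)) {
      chars <- seq_chars(rand_seq(L))
      rows <- list()
      occupied <- matrix(numeric(0), ncol = 2)
      feasible <- TRUE
      for (k in my_plants) {
        cls <- classes[k]
        s <- lib[[assign_si[k]]]
        seg <- seq_chars(plant_segment(s, cls))
        sl <- length(seg)
        off <- plant_site_offset(cls)
        in_utr <- cls %in% c("m8_seed", "compensatory",
                             "decoy_nonconserved")
        # the seed *site* (not necessarily the whole segment) must sit in
        # the requested region
        site_off <- if (is.na(off)) 0L else off
        lo <- if (in_utr) utr3 - site_off + 1L else 10L
        hi <- if (in_utr) L - sl - 5L else utr3 - sl - 10L
        lo <- max(lo, 0L)
        pos <- NA_integer_
        for (draw in seq_len(50L)) {
          cand <- sample(seq(lo, hi), 1L)
          if (!nrow(occupied) ||
              all(cand + sl + 8L <= occupied[, 1] |
                    cand >= occupied[, 2] + 8L)) {
            pos <- cand; break
          }
        }
        if (is.na(pos)) { feasible <- FALSE; break }
        occupied <- rbind(occupied, c(pos, pos + sl))
        chars[(pos + 1L):(pos + sl)] <- seg
        rows[[length(rows) + 1L]] <- data.frame(
          accession = acc, sirna_id = s$sirna_id, class = cls,
          start = pos, end = pos + sl,
          site_start = if (is.na(off)) NA_integer_ else pos + off,
          site_end = if (is.na(off)) NA_integer_ else pos + off + 7L,
          conserved = switch(cls,
                             decoy_nonconserved = FALSE,
                             partial_contiguous11 = NA,
                             partial_total15 = NA,
                             TRUE),
          stringsAsFactors = FALSE)
      }
      if (!feasible) next
      t <- transcript(acc, paste(chars, collapse = ""),
                      gene_symbol = gene, utr3_start = utr3)
      rows_df <- if (length(rows)) do.call(rbind, rows) else NULL
      audit_rows <- if (is.null(rows_df)) {
        data.frame(accession = character(0), sirna_id = character(0),
                   class = character(0), start = integer(0),
                   end = integer(0), site_start = integer(0),
                   site_end = integer(0), conserved = logical(0),
                   stringsAsFactors = FALSE)
      } else rows_df
      if (audit_transcript(t, lib, audit_rows)) {
        transcriptome[[i]] <- t
        if (!is.null(rows_df)) manifest[[length(manifest) + 1L]] <- rows_df
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not generate a clean background for transcript ", acc,
           " after 200 attempts; try another rng_seed", call. = FALSE)
    }
  }

  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(accession = character(0), sirna_id = character(0),
               class = character(0), start = integer(0), end = integer(0),
               site_start = integer(0), site_end = integer(0),
               conserved = logical(0), stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  list(transcriptome = transcriptome, manifest = manifest)
}

#' Generate a conservation track for a fixture transcriptome
#'
#' Covers every planted conserved seed site (with 2-nt margins, so each
#' interval passes the minimum-length filter), never covers a decoy
#' site, and adds random background intervals up to roughly the
#' requested coverage fraction.
#'
#' @param fspec a [fixture_spec()].
#' @param tr result of [generate_transcriptome()].
#' @return a [conserved_intervals()] set.
#' @export
generate_conserved <- function(fspec, tr) {
  stopifnot(inherits(fspec, "fixture_spec"))
  force(tr)
  seed_stream(fspec, "conserved")
  man <- tr$manifest
  rows <- list()
  for (t in tr$transcriptome) {
    L <- nchar(t$sequence)
    mine <- man[man$accession == t$accession, , drop = FALSE]
    dec <- mine[!is.na(mine$conserved) & !mine$conserved, , drop = FALSE]
    cons <- mine[!is.na(mine$conserved) & mine$conserved &
                   !is.na(mine$site_start), , drop = FALSE]
    for (k in seq_len(nrow(cons))) {
      rows[[length(rows) + 1L]] <- data.frame(
        accession = t$accession,
        start = max(0L, cons$site_start[k] - 2L),
        end = min(L, cons$site_end[k] + 2L), stringsAsFactors = FALSE)
    }
    target_cov <- fspec$conservation_coverage * L
    covered <- sum(vapply(rows, function(r)
      if (r$accession == t$accession) r$end - r$start else 0L, numeric(1)))
    guard <- 0L
    while (covered < target_cov && guard < 100L) {
      guard <- guard + 1L
      w <- sample(20:40, 1L)
      st <- sample(0:(L - w), 1L)
      # background intervals must not make a decoy site conserved
      hits_decoy <- nrow(dec) && any(st <= dec$site_start &
                                       dec$site_end <= st + w)
      if (!hits_decoy) {
        rows[[length(rows) + 1L]] <- data.frame(
          accession = t$accession, start = st, end = st + w,
          stringsAsFactors = FALSE)
        covered <- covered + w
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  cset <- conserved_intervals(tab)
  # merging could in principle bridge background into a decoy; drop any
  # interval that swallowed one
  dec_all <- man[!is.na(man$conserved) & !man$conserved, , drop = FALSE]
  if (nrow(dec_all)) {
    iv <- cset$intervals
    bad <- vapply(seq_len(nrow(iv)), function(k) {
      any(dec_all$accession == iv$accession[k] &
            iv$start[k] <= dec_all$site_start &
            dec_all$site_end <= iv$end[k])
    }, logical(1))
    cset$intervals <- iv[!bad, , drop = FALSE]
  }
  cset
}

#' Generate an expression-change table for a set of predictions
#'
#' Emulates a transfection-experiment table: each predicted accession is
#' made a true off-target (negative log-ratio, p below `alpha`) with
#' probability `fspec$tp_rate`; all other rows are drawn from a null
#' (symmetric log-ratio, uniform p).
#'
#' @param fspec a [fixture_spec()].
#' @param predictions character vector (or named list, flattened) of
#'   predicted off-target accessions.
#' @param universe optional additional accessions given null rows.
#' @param alpha significance threshold the truth rows must beat.
#' @return an [expression_table()].
#' @export
generate_expression <- function(fspec, predictions,
                                universe = character(0), alpha = 0.01) {
  stopifnot(inherits(fspec, "fixture_spec"))
  force(predictions); force(universe)
  seed_stream(fspec, "expression")
  pred <- unique(unlist(predictions, use.names = FALSE))
  extra <- setdiff(unique(universe), pred)
  null_row <- function(acc) data.frame(
    accession = acc, log_ratio = stats::rnorm(1L, 0, 1),
    p_value = stats::runif(1L), stringsAsFactors = FALSE)
  # predicted rows that lose the truth coin are rejection-sampled off the
  # truth criterion, so the planted per-prediction truth probability is
  # exact (not merely approximate) ground truth
  false_row <- function(acc) {
    repeat {
      r <- null_row(acc)
      if (!(r$log_ratio < 0 && r$p_value < alpha)) return(r)
    }
  }
  rows <- lapply(pred, function(acc) {
    if (stats::runif(1L) < fspec$tp_rate) {
      data.frame(accession = acc,
                 log_ratio = -abs(stats::rnorm(1L, 1, 0.4)),
                 p_value = stats::runif(1L, 0, alpha * 0.999),
                 stringsAsFactors = FALSE)
    } else false_row(acc)
  })
  rows <- c(rows, lapply(extra, null_row))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), log_ratio = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  expression_table(tab, timepoint_label = "synthetic")
}

#' Write a complete fixture set to disk
#'
#' Emits the same plain-text formats the pipeline reads: a FASTA
#' transcriptome, a TSV siRNA library, a BED-like conservation table,
#' an expression table and the ground-truth manifest.
#'
#' @param fspec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_fixture_set <- function(fspec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib <- generate_library(fspec)
  tr <- generate_transcriptome(fspec, lib)
  cset <- generate_conserved(fspec, tr)
  calls <- expected_offtarget_calls(tr$manifest)
  expr <- generate_expression(fspec, calls$accession,
                              universe = vapply(tr$transcriptome,
                                                `[[`, character(1),
                                                "accession"))
  paths <- c(transcriptome = file.path(dir, "transcriptome.fa"),
             library = file.path(dir, "library.tsv"),
             conserved = file.path(dir, "conserved.bed"),
             expression = file.path(dir, "expression.tsv"),
             manifest = file.path(dir, "manifest.tsv"))
  write_transcriptome(tr$transcriptome, paths["transcriptome"])
  lib_tab <- data.frame(
    sirna_id = vapply(lib, `[[`, character(1), "sirna_id"),
    gene = vapply(lib, `[[`, character(1), "on_target_gene"),
    antisense = vapply(lib, `[[`, character(1), "antisense"),
    stringsAsFactors = FALSE)
  utils::write.table(lib_tab, paths["library"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cset$intervals, paths["conserved"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(expr, paths["expression"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(tr$manifest, paths["manifest"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
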