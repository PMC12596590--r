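# Hand-built single-exon gene: ATG GCA CGA TAC GCA GCA GCA GCA GCA TAA
REF1 <- "ATGGCACGATACGCAGCAGCAGCAGCATAA"
REF2 <- sub("^(.{11}).", "\\1T", REF1)   # codon 4 TAC -> TAT (both Tyr)
TOY_GM <- gene_model("toy", "e1", 30L)

toy_view <- function(target_seq, two_refs = FALSE) {
  seqs <- if (two_refs)
    c(r1 = REF1, r2 = REF2, t = target_seq)
  else c(r1 = REF1, t = target_seq)
  roles <- if (two_refs) mk_roles(c("r1", "r2"), "t") else mk_roles("r1", "t")
  concatenate_gene(mk_alns(list(e1 = seqs), roles), TOY_GM)
}

test_that("nonsense substitutions are detected with stop triplet and span", {
  # C->T at 7 turns CGA into TGA (7-9)
  tgt <- sub("^(.{6}).", "\\1T", REF1)
  rec <- detect_nonsense_substitutions(toy_view(tgt), "t")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$klass, "nonsense_substitution")
  expect_equal(rec$location, "7")
  expect_equal(rec$stop_triplet, "TGA")
  expect_equal(c(rec$stop_from, rec$stop_to), c(7L, 9L))
  expect_equal(rec$zygosity, "homozygous")

  # heterozygous: Y (C/T) at the same site
  tgt_y <- sub("^(.{6}).", "\\1Y", REF1)
  rec <- detect_nonsense_substitutions(toy_view(tgt_y), "t")
  expect_equal(rec$zygosity, "heterozygous")
  expect_equal(rec$stop_triplet, "TGA")

  # polymorphic references C/T at 12; target G -> TAG (10-12)
  tgt_g <- sub("^(.{11}).", "\\1G", REF1)
  rec <- detect_nonsense_substitutions(toy_view(tgt_g, two_refs = TRUE), "t")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$location, "12")
  expect_equal(rec$stop_triplet, "TAG")
  expect_equal(c(rec$stop_from, rec$stop_to), c(10L, 12L))
  expect_equal(rec$ref_alleles, "C,T")

  # an allele present in ANY reference row is not a mutation
  tgt_t <- sub("^(.{11}).", "\\1T", REF1)
  expect_equal(nrow(detect_nonsense_substitutions(
    toy_view(tgt_t, two_refs = TRUE), "t")), 0L)

  # uninformative N gives no call
  tgt_n <- sub("^(.{6}).", "\\1N", REF1)
  expect_equal(nrow(detect_nonsense_substitutions(toy_view(tgt_n), "t")), 0L)

  # identical target: empty; unknown taxon errors
  expect_equal(nrow(detect_nonsense_substitutions(toy_view(REF1), "t")), 0L)
  expect_error(detect_nonsense_substitutions(toy_view(REF1), "zz"),
               class = "ps_label_error")
})

test_that("random planted stop substitutions agree with the translation oracle", {
  set.seed(101)
  n_hits <- 0L
  for (i in 1:40) {
    ref <- generate_functional_cds(200, gene = "g")
    if (i %% 2 == 0) {
      # random substitution anywhere upstream of the native stop
      pos <- sample(3L * 199L, 1L)
      cur <- substr(ref$cds, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    } else {
      # targeted: pick a (site, allele) whose substitution creates a stop
      cands <- list()
      cods <- codons_of(ref$cds)
      for (ci in sample(199L, 50L)) {
        cod <- strsplit(cods[ci], "")[[1]]
        for (k in 1:3) for (b in setdiff(c("A", "C", "G", "T"), cod[k])) {
          mut <- cod; mut[k] <- b
          if (paste(mut, collapse = "") %in% STOPS)
            cands[[length(cands) + 1L]] <- c(3L * ci - 3L + k, b)
        }
      }
      pick <- cands[[sample(length(cands), 1L)]]
      pos <- as.integer(pick[1]); alt <- pick[2]
    }
    tgt <- paste0(substr(ref$cds, 1, pos - 1), alt,
                  substr(ref$cds, pos + 1, nchar(ref$cds)))
    view <- concatenate_gene(
      mk_alns(list(exon1 = c(r = ref$cds, t = tgt)), mk_roles("r", "t")),
      ref$model)
    rec <- detect_nonsense_substitutions(view, "t")
    starts <- oracle_nonsense_codons(ref$cds, tgt)
    expect_equal(nrow(rec), length(starts))
    if (length(starts)) {
      n_hits <- n_hits + 1L
      expect_equal(rec$stop_from, starts)   # single exon: local == global
      expect_equal(rec$stop_to, starts + 2L)
    }
  }
  expect_gt(n_hits, 0L)   # the 40 draws must exercise the stop case
})

test_that("indels are classified by stop content and frame", {
  roles <- mk_roles("r1", "t")
  mkv <- function(r, t) concatenate_gene(
    mk_alns(list(e1 = c(r1 = r, t = t)), roles), TOY_GM)
  ins_at <- function(s, p, ins) paste0(substr(s, 1, p), ins,
                                       substr(s, p + 1, nchar(s)))
  gap_at <- function(s, p, n) paste0(substr(s, 1, p - 1), strrep("-", n),
                                     substr(s, p + n, nchar(s)))

  # 3-bp insertion carrying an in-frame TAA at a codon boundary: stop_insertion
  v <- mkv(ins_at(REF1, 6, "---"), ins_at(REF1, 6, "TAA"))
  rec <- detect_indels(v, "t")
  expect_equal(rec$klass, "stop_insertion")
  expect_equal(rec$location, "between 6 and 7")
  expect_equal(rec$stop_triplet, "TAA")
  expect_true(rec$inactivating)

  # 1-bp insertion: frameshift_insertion
  v <- mkv(ins_at(REF1, 7, "-"), ins_at(REF1, 7, "A"))
  rec <- detect_indels(v, "t")
  expect_equal(rec$klass, "frameshift_insertion")
  expect_equal(rec$indel_length, 1L)
  expect_equal(rec$location, "between 7 and 8")

  # 3-bp stop-free insertion: inframe_indel, non-inactivating
  v <- mkv(ins_at(REF1, 6, "---"), ins_at(REF1, 6, "GCA"))
  rec <- detect_indels(v, "t")
  expect_equal(rec$klass, "inframe_indel")
  expect_false(rec$inactivating)

  # 2-bp deletion: frameshift_deletion with an interval location
  v <- mkv(REF1, gap_at(REF1, 10, 2))
  rec <- detect_indels(v, "t")
  expect_equal(rec$klass, "frameshift_deletion")
  expect_equal(rec$location, "10-11")
  expect_equal(rec$indel_length, 2L)

  # 3-bp deletion: inframe
  v <- mkv(REF1, gap_at(REF1, 10, 3))
  expect_equal(detect_indels(v, "t")$klass, "inframe_indel")

  # two 1-bp deletions separated by a matched column: two records
  t2 <- gap_at(gap_at(REF1, 10, 1), 12, 1)
  rec <- detect_indels(mkv(REF1, t2), "t")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$location, c("10", "12"))
})

test_that("downstream premature stops match the brute-force oracle", {
  set.seed(202)
  exon_lengths <- c(120L, 123L)
  checked <- 0L
  for (i in 1:50) {
    ref <- generate_functional_cds(80, exon_lengths = exon_lengths)
    g <- sample(220L, 1L)
    len <- sample(c(1L, 2L, 4L), 1L)
    ins <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    loc <- global_to_local(g, exon_lengths)
    fx <- plant_fixture_mutations(
      ref$cds, ref$model,
      list(list(type = "insertion", exon = paste0("exon", loc$exon_index),
                after = loc$pos, seq = ins, taxa = "t")),
      reference_taxa = "r", target_taxa = "t")
    view <- concatenate_gene(fx$alignments, ref$model)
    rec <- detect_indels(view, "t")
    expect_equal(nrow(rec), 1L)
    if (!rec$klass %in% c("frameshift_insertion")) next  # stop inside insert
    got <- locate_downstream_premature_stop(view, "t", rec)
    want <- oracle_downstream_stop(ref$cds, g, ins, exon_lengths)
    if (is.null(want)) {
      expect_null(got)
    } else {
      checked <- checked + 1L
      expect_equal(got$triplet, want$triplet)
      expect_equal(got$from, want$from)
      expect_equal(got$to, want$to)
      if (!is.na(want$from))
        expect_equal(got$exon, paste0("exon", want$exon_index))
    }
  }
  expect_gt(checked, 20L)
  # classification guard: the scan refuses non-frameshift records
  v <- toy_view(sub("^(.{6}).", "\\1T", REF1))
  nonfs <- detect_nonsense_substitutions(v, "t")
  expect_error(locate_downstream_premature_stop(v, "t", nonfs),
               class = "ps_format_error")
})

test_that("zygosity calls follow the ambiguity-code rules", {
  expect_equal(call_zygosity("T", "C", "T"), "homozygous")
  expect_equal(call_zygosity("Y", "C", "T"), "heterozygous")
  expect_equal(call_zygosity("y", "C", "T"), "heterozygous")
  expect_true(is.na(call_zygosity("N", "C", "T")))
  expect_true(is.na(call_zygosity("R", "C", "T")))   # mutant absent
  expect_true(is.na(call_zygosity("B", "C", "T")))   # 3-fold: uninformative
})

test_that("scan_gene orders, tallies and survives row permutation", {
  fx <- tas1r_fixture()
  view <- concatenate_gene(fx$TAS1R1$alignments, fx$TAS1R1$model)
  rep1 <- scan_gene(view, fx$TAS1R1$model, "Lyncodon_patagonicus")
  expect_equal(unname(rep1$tally["nonsense_type"]), 2L)
  expect_equal(unname(rep1$tally["frameshift"]), 2L)
  expect_true(!is.unsorted(rep1$records$exon_index))

  # permuting the alignment rows changes nothing
  perm <- lapply(fx$TAS1R1$alignments, function(a) {
    ord <- rev(a$taxa)
    exon_alignment(a$exon_id,
                   setNames(apply(a$mat[ord, , drop = FALSE], 1,
                                  paste, collapse = ""), ord),
                   a$roles)
  })
  rep2 <- scan_gene(perm, fx$TAS1R1$model, "Lyncodon_patagonicus")
  expect_equal(rep2$tally, rep1$tally)
  expect_equal(rep2$records$location, rep1$records$location)
})

test_that("lesion coordinates are invariant to upstream target insertions", {
  ref <- pseudoscan:::tas1r1_reference()
  m <- ref$model
  cds <- ref$cds
  # same exon-3/exon-6 lesions, plus an extra in-frame insertion far upstream
  fx2 <- plant_fixture_mutations(
    cds, m,
    lesions = list(
      list(type = "insertion", exon = "exon1", after = 30L, seq = "GGG",
           taxa = "Lyncodon_patagonicus"),
      list(type = "substitution", exon = "exon3", pos = 295L, alt = "T",
           taxa = "Lyncodon_patagonicus"),
      list(type = "insertion", exon = "exon6", after = 693L, seq = "A",
           taxa = "Lyncodon_patagonicus")),
    reference_taxa = "Canis_familiaris",
    target_taxa = "Lyncodon_patagonicus")
  shifted <- scan_gene(fx2$alignments, m, "Lyncodon_patagonicus")
  sub_rec <- shifted$records[shifted$records$klass == "nonsense_substitution", ]
  expect_equal(sub_rec$location, "295")
  fs_rec <- shifted$records[shifted$records$klass == "frameshift_insertion", ]
  expect_equal(fs_rec$location, "between 693 and 694")
  expect_equal(c(fs_rec$stop_from, fs_rec$stop_to), c(746L, 748L))
})

test_that("TSV and JSON report serialization round-trips", {
  reps <- tas1r_fixture_reports()
  tsv <- tempfile(fileext = ".tsv")
  write_lesion_tsv(reps, tsv)
  tab <- read.delim(tsv, na.strings = ".")
  expect_equal(nrow(tab), sum(vapply(reps, function(r) nrow(r$records), 1L)))
  expect_equal(names(tab)[1:5],
               c("taxon", "gene", "exon", "class", "location"))

  js <- tempfile(fileext = ".json")
  write_lesion_json(reps, js)
  back <- read_lesion_json(js)
  expect_equal(length(back), length(reps))
  for (i in seq_along(reps)) {
    expect_equal(back[[i]]$tally, reps[[i]]$tally)
    expect_equal(back[[i]]$records$location, reps[[i]]$records$location)
    expect_equal(sort(back[[i]]$references), sort(reps[[i]]$references))
  }
})
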