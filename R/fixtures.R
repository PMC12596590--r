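# Deterministic fixture set reproducing the documented TAS1R1/TAS1R3
# inactivating mutations of Lyncodon patagonicus and Galictis cuja, numbered
# against Canis familiaris and the two non-Lyncodontini ictonychines
# (Ictonyx striatus, Vormela peregusna) in per-exon reference coordinates.
#
# Only the lesion coordinates, alleles and stop spans are documented for
# these genes; the exon structures here are synthetic, chosen so that every
# documented coordinate is arithmetically consistent:
#  - TAS1R1 exons 219/156/300/300/250/932 bp. Exons 3 and 4 start in frame
#    offset 0 (codons 295-297 and 10-12 are in-frame); exon 6 starts in
#    frame offset 1, which places the first shifted-frame stop after the
#    693/694 1-bp insertion exactly at 746-748.
#  - TAS1R3 exons 120/120/693/150/150/213 bp; exon 3 starts in frame
#    offset 0 (codon 688-690 in frame).
# The ">210-bp" exon-4 insertion is fixed at 213 bp: longer than 210 and a
# multiple of 3, so it introduces its stop without compounding a frameshift.

TAS1R_REFERENCE_TAXA <- c("Canis_familiaris", "Ictonyx_striatus",
                          "Vormela_peregusna")
TAS1R_TARGET_TAXA <- c("Lyncodon_patagonicus", "Galictis_cuja")

# Reference CDS for the fixtures: a neutral GCA-codon background with the
# documented codon contexts patched in. Patches are codon-aligned and
# stop-free in the native frame.
tas1r1_reference <- function() {
  model <- gene_model("TAS1R1", paste0("exon", 1:6),
                      c(219L, 156L, 300L, 300L, 250L, 932L))
  b <- rep(c("G", "C", "A"), model$cds_length / 3L)
  b[670:672] <- c("C", "G", "A")   # exon 3, 295-297: CGA (Arg)
  b[685:687] <- c("C", "A", "G")   # exon 4, 10-12: CAG (Gln)
  b[1919:2157] <- "C"              # exon 6 tail, 694-932
  b[1971:1973] <- c("T", "A", "G") # exon 6, 746-748 (in-frame reads C.TAG.C)
  b[2155:2157] <- c("T", "A", "A") # native stop, exon 6, 930-932
  list(cds = paste(b, collapse = ""), model = model)
}

tas1r3_reference <- function() {
  model <- gene_model("TAS1R3", paste0("exon", 1:6),
                      c(120L, 120L, 693L, 150L, 150L, 213L))
  b <- rep(c("G", "C", "A"), model$cds_length / 3L)
  b[928:930] <- c("T", "A", "C")   # exon 3, 688-690: TAC (Tyr)
  b[1444:1446] <- c("T", "A", "A") # native stop, exon 6, 211-213
  list(cds = paste(b, collapse = ""), model = model)
}

#' Build the documented TAS1R1/TAS1R3 lesion fixtures
#'
#' Constructs, fully deterministically, exon-wise alignments of synthetic
#' TAS1R1 and TAS1R3 coding sequences for three reference taxa
#' (C. familiaris, I. striatus, V. peregusna) and two targets
#' (L. patagonicus, G. cuja) carrying the six documented lesions:
#' \itemize{
#'   \item TAS1R1 exon 3: C-to-T at 295 (L. patagonicus), stop TGA 295-297;
#'   \item TAS1R1 exon 4: C-to-T at 10 (G. cuja), stop TAG 10-12;
#'   \item TAS1R1 exon 4: 213-bp insertion between 57 and 58
#'     (L. patagonicus) containing an in-frame TAA;
#'   \item TAS1R1 exon 6: shared 1-bp insertion between 693 and 694 (both
#'     targets), shifted-frame stop TAG at 746-748;
#'   \item TAS1R1 exon 6: shared 1-bp insertion between 823 and 824 (both
#'     targets), no downstream stop;
#'   \item TAS1R3 exon 3: C/T-polymorphic reference site at 690, target G
#'     (L. patagonicus), stop TAG 688-690.
#' }
#' G. cuja's TAS1R3 carries no lesion (intact by construction).
#'
#' @return A named list with elements `TAS1R1` and `TAS1R3`, each a list
#'   `(alignments, roles, model)` as returned by
#'   [plant_fixture_mutations()], plus `reference_taxa` and `target_taxa`.
#' @export
tas1r_fixture <- function() {
  lp <- "Lyncodon_patagonicus"; gc <- "Galictis_cuja"
  r1 <- tas1r1_reference()
  long_ins <- paste0("GCTTAA", strrep("GCA", 69L))  # 213 bp, TAA in frame
  fx1 <- plant_fixture_mutations(
    r1$cds, r1$model,
    lesions = list(
      list(type = "substitution", exon = "exon3", pos = 295L, alt = "T",
           taxa = lp),
      list(type = "substitution", exon = "exon4", pos = 10L, alt = "T",
           taxa = gc),
      list(type = "insertion", exon = "exon4", after = 57L, seq = long_ins,
           taxa = lp),
      list(type = "insertion", exon = "exon6", after = 693L, seq = "A",
           taxa = c(lp, gc)),
      list(type = "insertion", exon = "exon6", after = 823L, seq = "A",
           taxa = c(lp, gc))
    ),
    reference_taxa = TAS1R_REFERENCE_TAXA, target_taxa = TAS1R_TARGET_TAXA)
  r3 <- tas1r3_reference()
  fx3 <- plant_fixture_mutations(
    r3$cds, r3$model,
    lesions = list(
      list(type = "reference_variant", exon = "exon3", pos = 690L,
           alt = "T", taxon = "Vormela_peregusna"),
      list(type = "substitution", exon = "exon3", pos = 690L, alt = "G",
           taxa = lp)
    ),
    reference_taxa = TAS1R_REFERENCE_TAXA, target_taxa = TAS1R_TARGET_TAXA)
  list(TAS1R1 = fx1, TAS1R3 = fx3,
       reference_taxa = TAS1R_REFERENCE_TAXA,
       target_taxa = TAS1R_TARGET_TAXA)
}

#' Scan all fixture gene/taxon combinations
#'
#' Convenience wrapper: runs [scan_gene()] on every target taxon of both
#' fixture genes from [tas1r_fixture()].
#'
#' @param fixture Result of [tas1r_fixture()] (built if missing).
#' @return A list of `lesion_report`s (both targets x both genes).
#' @export
tas1r_fixture_reports <- function(fixture = tas1r_fixture()) {
  out <- list()
  for (gene in c("TAS1R1", "TAS1R3")) {
    fx <- fixture[[gene]]
    view <- concatenate_gene(fx$alignments, fx$model)
    for (tx in fixture$target_taxa)
      out[[paste(tx, gene, sep = ".")]] <- scan_gene(view, fx$model, tx)
  }
  out
}

#' Time-calibrated Ictonychinae fixture tree
#'
#' A dated phylogeny of Ictonychinae with the two constrained node ages:
#' crown Lyncodontini at 3.0 Mya and its parent node (the split from the
#' Ictonyx + Vormela clade, i.e. the old end of the Lyncodontini stem
#' branch) at 9.5 Mya. G. vittata is present as an unsampled tip inside
#' Lyncodontini; the remaining node ages are placeholders.
#'
#' @return A [read_time_tree()] `time_tree`.
#' @export
ictonychinae_tree <- function() {
  read_time_tree(paste0(
    "((Lyncodon_patagonicus:3.0,(Galictis_cuja:1.5,Galictis_vittata:1.5)",
    "galictis:1.5)lyncodontini:6.5,",
    "(Ictonyx_striatus:5.0,Vormela_peregusna:5.0)polecats:4.5)ictonychinae;"))
}

#' Heterodimeric TAS1R receptor definitions
#'
#' The umami receptor is the TAS1R1+TAS1R3 heterodimer and the sweet
#' receptor the TAS1R2+TAS1R3 heterodimer; loss of integrity of either
#' component inactivates the pair.
#'
#' @return Named list of component-gene vectors.
#' @export
tas1r_receptors <- function() {
  list("TAS1R1-TAS1R3" = c("TAS1R1", "TAS1R3"),
       "TAS1R2-TAS1R3" = c("TAS1R2", "TAS1R3"))
}
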