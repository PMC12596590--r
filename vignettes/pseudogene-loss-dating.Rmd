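---
title: "Detecting, classifying and dating gene-inactivating mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, classifying and dating gene-inactivating mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoscan)
```

## The inference chain

pseudoscan implements a small, fully specified inference chain for gene-loss
studies on coding sequences:

1. represent exon-wise multiple alignments with a reference-anchored
   coordinate system and a gene model that tracks reading frame across
   exons;
2. detect and classify inactivating mutations in target taxa;
3. call pseudogene status per gene and functional status per heterodimeric
   receptor;
4. group identical lesions across taxa, assign each group an origin branch
   on a time-calibrated tree by Dollo parsimony, and bracket gene-loss
   events in time.

A synthetic-data module generates functional coding sequences and simulates
their decay after a planted loss event, so every step of the chain can be
validated against a known truth.

## Coordinates and the alignment model

All lesion coordinates are reported against the *reference* rows of the
alignment: 1-based, counted from the 5' end of each exon, left to right.
An alignment column counts as a reference position if **any** reference row
is ungapped there; columns gapped in every reference row are insertion
slots reported as "between p and p+1", with ordinal offsets within a run.
The permissive any-reference rule is a deliberate choice: when several
jointly aligned reference species disagree in gap pattern, numbering
against their union keeps coordinates stable and monotone; the alternative
(all references ungapped) would silently drop positions wherever one
reference carries a private deletion.

The gene model lists exon lengths; the frame offset entering each exon
(`phase_in`) is the cumulative upstream length mod 3, so codons may span
exon junctions and translation is continuous across them. The final codon
of the concatenated reference CDS is the native stop; a stop there is the
gene's terminator, never a lesion. The gap character is fixed to `-` and
`.` is rejected at load time — one dialect, with an explicit error
otherwise. Input case is normalised to upper.

## Lesion detection

**Nonsense substitutions.** Every in-frame reference codon upstream of the
native stop is examined. A record is emitted when the target codon is a
stop (TAA/TAG/TGA; selenocysteine recoding is ignored), no reference row's
codon at that triplet can read as a stop, and at least one codon position
carries a target allele absent from *every* reference row — so at a
reference-polymorphic site (say C in some references, T in others) only a
third allele is a mutation. One record is emitted per stop codon, located
at the first mutated site, carrying the stop triplet and its
reference-coordinate span.

**Zygosity.** Direct sequencing of diploids shows heterozygous sites as
IUPAC ambiguity codes. A plain mutant base is homozygous; a two-allele
code containing the mutant allele is heterozygous; codes expanding to
three or more bases (N, B, D, H, V) are uninformative and give no call.
One edge the convention leaves open: a two-allele code both of whose
alleles are non-reference. We call it heterozygous (two distinct alleles
are present); this cannot arise in the bundled fixtures and is vanishingly
rare in practice.

**Indels.** Maximal runs of target-only ungapped insertion-slot columns
are single insertion records; maximal runs of reference positions gapped
in the target are single deletion records. Slot columns gapped in both the
target and the references belong to other taxa's insertions and are
invisible to both run types; runs separated by at least one matched column
stay distinct. Classification: an insertion whose bases, read in the
target's frame entering the insertion, contain a stop triplet is a
`stop_insertion` — inactivating and tallied with the nonsense class
regardless of its length mod 3, because a stop-carrying insertion
truncates the protein exactly as a nonsense substitution does. Otherwise
length mod 3 ≠ 0 gives a frameshift, and a frame-preserving stop-free
indel is a non-inactivating `inframe_indel`.

**Downstream premature stops.** A frameshift's consequence is located by
translating the target's gap-stripped CDS from the codon containing the
frameshifted position onward, in the target's *own* running frame — which
incorporates every upstream and intervening target indel and continues
across exon junctions — until the first stop or the CDS end. The stop's
span is mapped back to reference coordinates of the exon containing it;
inserted bases consume no reference positions. If the frame happens to
realign onto the native stop, that is the gene's own terminator and no
premature stop is reported. This scan deliberately includes all target
bases between the frameshift and the stop (e.g. a second downstream
insertion): the shifted frame is whatever the target actually encodes.

## Status calls

A gene is a pseudogene iff its scan found at least one inactivating
record. Heterodimeric receptors (umami = TAS1R1+TAS1R3, sweet =
TAS1R2+TAS1R3) are nonfunctional if any component is a pseudogene and
functional only if every component is intact; "severe reduction" of
function is collapsed into the binary nonfunctional call, and an unknown
component propagates to an unknown receptor — a conservative rule that
never upgrades missing evidence to "functional".

## Dollo mapping and loss dating

Identical lesions — same gene, exon, location, class, allele and length —
are merged across taxa into groups with carrier sets. Under the Dollo
assumption (an inactivating lesion, once fixed, is never reverted;
standard for pseudogene lesions), each group is assigned the minimal set
of origins: the maximal clades whose *sampled* descendants all carry the
lesion. Tips without a lesion report are unsampled and never contradict an
assignment; reference taxa count as sampled lesion-free evidence. A
carrier set that is not a sampled clade yields several origins and a
homoplasy flag, so the "independent losses" alternative is always
representable and reported rather than silently discarded.

The loss branch for a gene is the assigned branch closest to the root
whose sampled descendants are all pseudogenes; its time bracket is
`[age(child), age(parent)]` in Mya, and every tip below it — sampled or
not — is predicted nonfunctional. When nested branches qualify, the
rootward one is chosen; if that extension is supported only by unsampled
tips a warning is logged, since data cannot distinguish the nested from
the rootward placement.

Trees are read from Newick with branch lengths in My; they must be rooted,
have positive branch lengths, and be ultrametric within a relative
root-to-tip deviation of 1e-6 (numerical tolerance for hand-edited branch
lengths; tips are then snapped to age 0).

## The bundled TAS1R fixtures

The package's worked example rebuilds the documented lesion catalogue of
the Lyncodontini taste receptor genes. Published alignment figures give
lesion coordinates but not full exon structures, so the fixture gene
models are synthetic, chosen once so that every documented coordinate is
arithmetically consistent: TAS1R1 exons of 219/156/300/300/250/932 bp
(exon 6 must start in frame offset 1 for the shifted-frame stop after the
693/694 insertion to start exactly at 746) and TAS1R3 exons of
120/120/693/150/150/213 bp. The long exon-4 insertion, documented only as
">210 bp", is fixed at 213 bp — longer than 210 and a multiple of 3, so it
introduces its stop codon without compounding a frameshift. The reference
background is a neutral repeated sense codon with the documented codon
contexts patched in; *G. cuja*'s TAS1R3 is built intact (its sequence
carries no documented lesion in this dataset). These choices are made in
code, once, and the acceptance script recomputes all headline numbers from
them at run time.

## The decay simulator

The simulator emulates the stochastic-decay model of pseudogene evolution:
function is lost at a single planted branch, after which the gene drifts
neutrally.

* **Substitutions** follow a Poisson process at rate μ per site per My
  with equal exchange among the three alternative bases (a Jukes–Cantor
  style process — the simplest one-parameter choice adequate for
  exercising the pipeline; no claim of realism about base composition).
* **Purifying constraint** on functional lineages is implemented by
  rejection sampling: a proposed substitution creating an internal stop
  (or destroying the native stop) is discarded, and indels are rejected
  outright — which guarantees, by construction, that functional lineages
  can never yield an inactivating record (the zero-false-positive
  contract). An option admits rare frame-preserving, stop-free indels on
  functional lineages for users who want them; the default is off, since
  intact fixtures in this domain show none.
* **Post-loss decay** accepts every substitution and adds indels at rate ι
  per site per My, insertion or deletion with equal probability, lengths
  geometric with mean 2 bp (short indels dominate real indel spectra).
* **Determinism**: one seeded generator, fixed preorder branch traversal;
  identical config and seed give byte-identical alignments and truth logs.

The truth log records every applied event with its branch, so recovery
experiments can compare inferred loss branches against the planted one.
The simulator emulates sequence-level decay only: it does not model
alignment error (alignments are emitted with their true insertion
columns), base-composition bias, rate variation among sites, or
heterozygosity. Passing tests therefore demonstrate the correctness of
the inference chain on correctly aligned input, not robustness to
alignment artefacts.

## Validation design and problem sizes

The test suite checks each stage against an independent oracle computed by
a different route:

* premature-stop localization against a brute-force apply-indel,
  translate-linearly, map-back oracle on plain strings (100 random planted
  fixtures, plus randomized unit cases);
* Dollo origin counts against an exhaustive minimum-cover search over node
  subsets, on **all** rooted topologies with 3–6 tips and all carrier
  subsets;
* zero false positives over 200 simulated intact clades with μ up to
  0.02 substitutions/site/My;
* loss-branch recovery over 200 seeded replicates on a four-tip tree
  (two reference tips, two target tips; 150-codon gene, μ = 0.005,
  ι = 0.004, loss on the internal branch ancestral to both targets —
  rates at which each descendant expects well over two post-loss
  inactivating events), requiring at least 95% recovery of the planted
  branch.

Problem sizes (100–200 codon genes, four- to six-tip trees, 200
replicates) are the package's chosen desk scale: large enough that every
code path and the recovery statistics are exercised, small enough that the
whole suite runs in a couple of minutes.

## Limitations

Splice-site, promoter, start-codon and whole-exon-deletion lesions are out
of scope, as are probabilistic pseudogene scoring, dN/dS-based relaxation
tests, alignment construction (alignments are inputs) and divergence-time
estimation (the tree is an input). The dating bracket is purely
topological: it is the age interval of the origin branch, with no attempt
to refine placement within the branch.
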