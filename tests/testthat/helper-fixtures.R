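# Shared test helpers: tiny builders and independent oracles. The oracles
# work on plain strings / bitmasks and never call the code paths they check.

STOPS <- c("TAA", "TAG", "TGA")

mk_roles <- function(refs, tgts) {
  setNames(c(rep("reference", length(refs)), rep("target", length(tgts))),
           c(refs, tgts))
}

# Build exon_alignment list from a named list exon_id -> named sequence vector
mk_alns <- function(seq_list, roles) {
  lapply(names(seq_list), function(id)
    exon_alignment(id, seq_list[[id]], roles))
}

codons_of <- function(s) {
  n <- (nchar(s) %/% 3) * 3
  if (n < 3) return(character(0))
  substring(s, seq(1, n - 2, 3), seq(3, n, 3))
}

# Map a global reference position to (exon index, local position)
global_to_local <- function(g, exon_lengths) {
  cb <- cumsum(exon_lengths)
  ei <- which(g <= cb)[1]
  before <- c(0, cb)[ei]
  list(exon_index = ei, pos = g - before)
}

# Independent downstream-stop oracle: plant a single insertion of `ins`
# between global reference positions g and g+1 of `cds`, translate the
# mutant linearly from the codon containing the first inserted base, and
# map the first stop back through simple index arithmetic.
oracle_downstream_stop <- function(cds, g, ins, exon_lengths) {
  tgt <- paste0(substr(cds, 1, g), ins, substr(cds, g + 1, nchar(cds)))
  len <- nchar(ins)
  L <- nchar(cds)
  cods <- codons_of(tgt)
  k0 <- g %/% 3 + 1            # 1-based codon containing target index g+1
  for (k in k0:length(cods)) {
    if (!cods[k] %in% STOPS) next
    idx <- (3 * k - 2):(3 * k)
    refidx <- ifelse(idx <= g, idx, ifelse(idx <= g + len, NA, idx - len))
    mapped <- refidx[!is.na(refidx)]
    if (length(mapped) == 3 && all(mapped == (L - 2):L)) return(NULL)
    if (!length(mapped))
      return(list(triplet = cods[k], from = NA_integer_, to = NA_integer_))
    from <- global_to_local(mapped[1], exon_lengths)
    to <- global_to_local(mapped[length(mapped)], exon_lengths)
    return(list(triplet = cods[k], from = from$pos, to = to$pos,
                exon_index = from$exon_index))
  }
  NULL
}

# Independent nonsense oracle: translate target and reference CDS strings
# codon by codon; report 1-based global codon starts where the target reads
# a stop, the reference does not, and the triplet is not the terminal one.
oracle_nonsense_codons <- function(ref_cds, tgt_cds) {
  rc <- codons_of(ref_cds); tc <- codons_of(tgt_cds)
  hits <- which(tc %in% STOPS & !rc %in% STOPS)
  hits <- setdiff(hits, length(rc))
  3L * hits - 2L
}

# Give an arbitrary topology unit-depth ultrametric branch lengths.
ultrametricize <- function(phy) {
  n <- length(phy$tip.label)
  ages <- numeric(n + phy$Nnode)
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    ages[eo[k, 1]] <- max(ages[eo[k, 1]], ages[eo[k, 2]] + 1)
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  read_time_tree(ape::write.tree(phy))
}

# Hand-made lesion_groups object (one row per carrier set), for driving
# assign_origin_branches without building alignments.
fake_groups <- function(carrier_sets, gene = "g", sampled = NULL) {
  n <- length(carrier_sets)
  out <- data.frame(
    key = paste0("grp", seq_len(n)), gene = gene, exon = "e1",
    exon_index = 1L, location = as.character(seq_len(n)),
    klass = "nonsense_substitution", alt = "T", indel_length = 0L,
    pos_key = as.numeric(seq_len(n)), inactivating = TRUE,
    n_carriers = lengths(carrier_sets), stringsAsFactors = FALSE)
  out$carriers <- carrier_sets
  attr(out, "sampled_by_gene") <- setNames(
    list(sampled %||% sort(unique(unlist(carrier_sets)))), gene)
  class(out) <- c("lesion_groups", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive Dollo oracle: minimum number of origin nodes (each a node whose
# full tip set is inside the carrier set) covering the carriers, found by
# brute-force search over node subsets of increasing size using bitmasks.
oracle_min_origins <- function(phy, carriers) {
  tips <- phy$tip.label
  n <- length(tips)
  nn <- n + phy$Nnode
  desc <- phangorn::Descendants(phy, seq_len(nn), "tips")
  masks <- vapply(desc, function(d) sum(2^(d - 1)), numeric(1))
  cmask <- sum(2^(match(carriers, tips) - 1))
  cand <- masks[bitwAnd(as.integer(masks), bitwNot(as.integer(cmask))) == 0 &
                  masks > 0]
  cand <- as.integer(unique(cand))
  for (k in seq_len(length(carriers))) {
    if (k > length(cand)) break
    combos <- combn(cand, k)
    for (j in seq_len(ncol(combos)))
      if (Reduce(bitwOr, combos[, j]) == as.integer(cmask)) return(k)
  }
  stop("oracle failed to cover carriers")
}
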