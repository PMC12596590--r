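# A sequence state tracks a taxon's CDS against the reference coordinate
# system: `base` holds the residue at each reference position ("-" once
# deleted), `ins` the bases inserted immediately after each position. This
# keeps reference coordinates stable under arbitrary indel histories and
# makes alignment construction exact.
seq_state <- function(cds) {
  base <- strsplit(cds, "", fixed = TRUE)[[1]]
  list(base = base, ins = rep("", length(base)))
}

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Generate a functional reference CDS and its gene model
#'
#' Draws `n_codons` uniform-random sense codons, appends a native stop, and
#' partitions the sequence into exons. The construction guarantees zero
#' internal stop codons. Deterministic under `seed`.
#'
#' @param n_codons Number of sense codons (CDS length is `3 * n_codons + 3`).
#' @param exon_lengths Integer vector of exon lengths in bp summing to
#'   `3 * n_codons + 3`; default one single exon.
#' @param gene Gene name for the model.
#' @param seed Optional integer seed.
#' @return A list with `cds` (character scalar) and `model`
#'   ([gene_model()]).
#' @export
generate_functional_cds <- function(n_codons, exon_lengths = NULL,
                                    gene = "gene1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- 3L * n_codons + 3L
  if (is.null(exon_lengths)) exon_lengths <- total
  if (sum(exon_lengths) != total)
    stop_config("exon lengths sum to %d, expected %d (3*%d + 3)",
                sum(exon_lengths), total, n_codons)
  codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  stop_codon <- sample(STOP_CODONS, 1L)
  cds <- paste(c(codons, stop_codon), collapse = "")
  model <- gene_model(gene, paste0("exon", seq_along(exon_lengths)),
                      exon_lengths)
  list(cds = cds, model = model)
}

# Evolve a sequence state along one branch. Functional lineages evolve under
# purifying constraint implemented as rejection sampling: any substitution
# creating an internal stop (or destroying the native stop) is discarded,
# and indels are rejected outright unless `functional_indels` admits
# frame-preserving, stop-free ones. Lost lineages accept everything and
# additionally draw indels at rate iota with geometric lengths.
evolve_branch <- function(state, t, functional, model, cfg) {
  bases4 <- c("A", "C", "G", "T")
  L <- length(state$base)
  n_codon <- model$cds_length %/% 3L
  events <- list()
  log_event <- function(type, position, length, detail, inactivating) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, position = position, length = length, detail = detail,
      inactivating = inactivating, stringsAsFactors = FALSE)
  }
  codon_after_sub <- function(site, new) {
    ci <- (site - 1L) %/% 3L
    pos <- (3L * ci + 1L):(3L * ci + 3L)
    b <- state$base[pos]
    b[pos == site] <- new
    if (any(b == "-")) NA_character_ else paste(b, collapse = "")
  }
  present <- function() which(state$base != "-")

  # substitutions: Poisson process, Jukes-Cantor-style equal exchange
  pr <- present()
  nsub <- rpois(1L, cfg$mu * t * length(pr))
  if (nsub > 0L) {
    sites <- sample(pr, nsub, replace = TRUE)
    for (site in sites) {
      cur <- state$base[site]
      if (cur == "-") next
      new <- sample(setdiff(bases4, cur), 1L)
      ci <- (site - 1L) %/% 3L
      codon <- codon_after_sub(site, new)
      is_native <- ci == n_codon - 1L
      makes_stop <- !is.na(codon) && codon %in% STOP_CODONS && !is_native
      breaks_native <- is_native && !is.na(codon) && !codon %in% STOP_CODONS
      if (functional && (makes_stop || breaks_native)) next  # rejected
      state$base[site] <- new
      log_event("substitution", site, 0L, paste0(cur, ">", new),
                makes_stop || breaks_native)
    }
  }

  # indels
  pr <- present()
  if (length(pr)) {
    nind <- rpois(1L, cfg$iota * t * length(pr))
    if (functional && !isTRUE(cfg$functional_indels)) nind <- 0L
    for (i in seq_len(nind)) {
      len <- rgeom(1L, 1 / cfg$indel_mean) + 1L
      if (runif(1L) < 0.5) {                       # insertion
        pos <- sample(pr, 1L)
        ins_seq <- paste(sample(bases4, len, replace = TRUE), collapse = "")
        if (functional) {
          # admit only frame-preserving, stop-free, codon-boundary insertions
          if (len %% 3L != 0L || pos %% 3L != 0L) next
          cods <- substring(ins_seq, seq(1L, len, 3L), seq(3L, len, 3L))
          if (any(cods %in% STOP_CODONS)) next
        }
        state$ins[pos] <- paste0(state$ins[pos], ins_seq)
        cods <- if (len >= 3L)
          substring(ins_seq, seq(1L, len - 2L, 3L), seq(3L, len, 3L))
          else character(0)
        log_event("insertion", pos, len, ins_seq,
                  len %% 3L != 0L || any(cods %in% STOP_CODONS))
      } else {                                     # deletion
        start <- sample(pr, 1L)
        if (functional && (len %% 3L != 0L || start %% 3L != 1L ||
                           start + len - 1L >= model$cds_length - 2L)) next
        removed <- 0L
        p <- start
        while (removed < len && p <= L) {
          if (state$base[p] != "-" && p >= start) {
            state$base[p] <- "-"
            removed <- removed + 1L
          }
          if (removed < len && nzchar(state$ins[p])) {
            take <- min(len - removed, nchar(state$ins[p]))
            state$ins[p] <- substring(state$ins[p], take + 1L)
            removed <- removed + take
          }
          p <- p + 1L
        }
        if (removed > 0L)
          log_event("deletion", start, removed, "",
                    removed %% 3L != 0L)
      }
    }
  }

  list(state = state,
       events = if (length(events)) do.call(rbind, events) else NULL)
}

#' Simulate coding-sequence evolution on a dated tree with a planted loss
#'
#' Evolves a reference CDS along every branch of a time tree. Lineages
#' before/outside the planted loss branch evolve under purifying constraint
#' (substitutions creating an internal stop are rejected; indels are
#' rejected, or restricted to frame-preserving stop-free ones when
#' `functional_indels` is set). On the loss branch and all its descendants
#' every substitution is accepted and indels occur at rate `iota` with
#' geometric lengths — neutral pseudogene decay. Every applied event is
#' recorded in the truth log.
#'
#' @param cds Reference CDS (character scalar, from
#'   [generate_functional_cds()]).
#' @param model The matching [gene_model()].
#' @param tree A [read_time_tree()] result (branch lengths in My).
#' @param config List: `mu` (substitutions/site/My), `iota` (indel
#'   events/site/My on lost lineages), `indel_mean` (geometric mean indel
#'   length, default 2), `loss_branch` (label of the loss branch's child
#'   node, or `NULL` for no loss), `functional_indels` (default `FALSE`),
#'   `seed`.
#' @param roles Optional named role vector for the tips. By default the
#'   ancestral reference sequence is included as taxon `"reference"` with
#'   the reference role and every tip is a target, so the output feeds
#'   straight into [scan_gene()].
#' @return A list: `alignments` (per-exon [exon_alignment()]s), `roles`,
#'   `model`, and `truth` (class `sim_truth`: `loss_branch`, `events` data
#'   frame with a `branch_child` column, `seed`, `config`).
#' @export
simulate_clade <- function(cds, model, tree, config, roles = NULL) {
  stopifnot(inherits(tree, "time_tree"), inherits(model, "gene_model"))
  cfg <- utils::modifyList(
    list(mu = 0, iota = 0, indel_mean = 2, loss_branch = NULL,
         functional_indels = FALSE, seed = NULL), config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (nchar(cds) != model$cds_length)
    stop_config("CDS length %d does not match model (%d)", nchar(cds),
                model$cds_length)
  phy <- tree$phy
  loss_node <- NULL
  if (!is.null(cfg$loss_branch)) {
    loss_node <- match(cfg$loss_branch, tree$labels)
    if (is.na(loss_node))
      stop_config("loss branch child '%s' not in tree", cfg$loss_branch)
  }
  n_tip <- length(phy$tip.label)
  states <- vector("list", n_tip + phy$Nnode)
  lost <- logical(n_tip + phy$Nnode)
  states[[tree$root]] <- seq_state(cds)
  lost[tree$root] <- !is.null(loss_node) && loss_node == tree$root
  edges <- ape::reorder.phylo(phy, "cladewise")$edge   # parents first
  lens <- ape::reorder.phylo(phy, "cladewise")$edge.length
  truth_events <- list()
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1L]; ch <- edges[k, 2L]
    lost[ch] <- lost[p] || (!is.null(loss_node) && ch == loss_node)
    res <- evolve_branch(states[[p]], lens[k], functional = !lost[ch],
                         model = model, cfg = cfg)
    states[[ch]] <- res$state
    if (!is.null(res$events)) {
      res$events$branch_child <- tree$labels[ch]
      truth_events[[length(truth_events) + 1L]] <- res$events
    }
  }
  events <- if (length(truth_events)) do.call(rbind, truth_events) else
    data.frame(type = character(0), position = integer(0),
               length = integer(0), detail = character(0),
               inactivating = logical(0), branch_child = character(0))
  tip_states <- setNames(states[seq_len(n_tip)], phy$tip.label)
  if (is.null(roles)) {
    tip_states <- c(list(reference = seq_state(cds)), tip_states)
    roles <- setNames(c("reference", rep("target", n_tip)),
                      c("reference", phy$tip.label))
  }
  alignments <- build_alignments(tip_states, model, roles)
  truth <- structure(
    list(loss_branch = cfg$loss_branch, events = events, seed = cfg$seed,
         config = cfg),
    class = "sim_truth")
  list(alignments = alignments, roles = roles, model = model, truth = truth)
}

# Assemble per-exon alignments from sequence states. Insertion columns after
# reference position p are sized to the longest insertion there across taxa
# and right-padded with gaps.
build_alignments <- function(states, model, roles) {
  taxa <- names(states)
  lapply(seq_along(model$exon_id), function(ei) {
    span <- (model$cum_before[ei] + 1L):(model$cum_before[ei] + model$length[ei])
    widths <- vapply(span, function(p)
      max(vapply(states, function(s) nchar(s$ins[p]), integer(1))), integer(1))
    seqs <- vapply(states, function(s) {
      parts <- character(length(span))
      for (j in seq_along(span)) {
        p <- span[j]
        ins <- s$ins[p]
        pad <- strrep("-", widths[j] - nchar(ins))
        parts[j] <- paste0(s$base[p], ins, pad)
      }
      paste(parts, collapse = "")
    }, character(1))
    exon_alignment(model$exon_id[ei], setNames(seqs, taxa), roles)
  })
}

#' Plant a described set of lesions into fixture alignments
#'
#' Deterministically applies lesion descriptors to designated target taxa on
#' top of a shared reference CDS and returns per-exon alignments with
#' reference and target rows. Descriptor types:
#' \describe{
#'   \item{substitution}{`exon`, `pos`, `alt`, `taxa`}
#'   \item{insertion}{`exon`, `after` (inserted between `after` and
#'     `after+1`), `seq`, `taxa`}
#'   \item{deletion}{`exon`, `pos`, `length`, `taxa`}
#'   \item{reference_variant}{`exon`, `pos`, `alt`, `taxon` — a polymorphic
#'     site among the reference rows}
#' }
#'
#' @param cds Reference CDS.
#' @param model The matching [gene_model()].
#' @param lesions List of descriptors (may be empty).
#' @param reference_taxa Character vector of reference taxon names.
#' @param target_taxa Character vector of target taxon names.
#' @return A list: `alignments` (per-exon [exon_alignment()]s), `roles`,
#'   `model`.
#' @export
plant_fixture_mutations <- function(cds, model, lesions,
                                    reference_taxa = "reference",
                                    target_taxa = "target") {
  stopifnot(inherits(model, "gene_model"))
  if (nchar(cds) != model$cds_length)
    stop_config("CDS length %d does not match model (%d)", nchar(cds),
                model$cds_length)
  taxa <- c(reference_taxa, target_taxa)
  states <- setNames(lapply(taxa, function(x) seq_state(cds)), taxa)
  gpos <- function(exon, pos, allow0 = FALSE) {
    ei <- match(exon, model$exon_id)
    if (is.na(ei)) stop_config("unknown exon '%s'", exon)
    lo <- if (allow0) 0L else 1L
    if (pos < lo || pos > model$length[ei])
      stop_config("position %d outside exon %s (1..%d)", pos, exon,
                  model$length[ei])
    model$cum_before[ei] + pos
  }
  for (les in lesions) {
    type <- les$type %||% stop_config("lesion descriptor without type")
    if (type == "substitution") {
      g <- gpos(les$exon, les$pos)
      for (tx in les$taxa) {
        if (!tx %in% target_taxa) stop_config("'%s' is not a target taxon", tx)
        states[[tx]]$base[g] <- toupper(les$alt)
      }
    } else if (type == "insertion") {
      if (is.null(les$after) || les$after < 1L)
        stop_config("insertion 'after' must be a positive reference position")
      g <- gpos(les$exon, les$after)
      for (tx in les$taxa) {
        if (!tx %in% target_taxa) stop_config("'%s' is not a target taxon", tx)
        states[[tx]]$ins[g] <- paste0(states[[tx]]$ins[g], toupper(les$seq))
      }
    } else if (type == "deletion") {
      g <- gpos(les$exon, les$pos)
      if (is.null(les$length) || les$length < 1L)
        stop_config("deletion needs a positive length")
      if (les$pos + les$length - 1L >
          model$length[match(les$exon, model$exon_id)])
        stop_config("deletion runs past exon %s", les$exon)
      for (tx in les$taxa) {
        if (!tx %in% target_taxa) stop_config("'%s' is not a target taxon", tx)
        states[[tx]]$base[g:(g + les$length - 1L)] <- "-"
      }
    } else if (type == "reference_variant") {
      g <- gpos(les$exon, les$pos)
      if (!les$taxon %in% reference_taxa)
        stop_config("'%s' is not a reference taxon", les$taxon)
      states[[les$taxon]]$base[g] <- toupper(les$alt)
    } else {
      stop_config("unknown lesion type '%s'", type)
    }
  }
  roles <- setNames(c(rep("reference", length(reference_taxa)),
                      rep("target", length(target_taxa))), taxa)
  list(alignments = build_alignments(states, model, roles),
       roles = roles, model = model)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth: loss on %s, %d logged events (%d inactivating)>\n",
              x$loss_branch %||% "none", nrow(x$events),
              sum(x$events$inactivating)))
  invisible(x)
}

#' Serialize a simulation truth log as JSON
#' @param truth A `sim_truth` from [simulate_clade()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(loss_branch = truth$loss_branch, seed = truth$seed,
         config = truth$config[c("mu", "iota", "indel_mean",
                                 "functional_indels")],
         events = truth$events),
    path, auto_unbox = TRUE, pretty = TRUE, na = "null", digits = NA)
  invisible(path)
}
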