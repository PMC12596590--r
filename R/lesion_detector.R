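# Columns of a mutation-record data frame. col_start/col_end are internal
# alignment-column bookkeeping (used to anchor the downstream-stop scan) and
# are dropped from the TSV surface.
RECORD_COLS <- c("taxon", "gene", "exon", "exon_index", "klass", "location",
                 "pos_key", "ref_alleles", "alt", "indel_length", "zygosity",
                 "stop_triplet", "stop_from", "stop_to", "stop_exon",
                 "inactivating", "col_start", "col_end")

empty_records <- function() {
  data.frame(taxon = character(0), gene = character(0), exon = character(0),
             exon_index = integer(0), klass = character(0),
             location = character(0), pos_key = numeric(0),
             ref_alleles = character(0), alt = character(0),
             indel_length = integer(0), zygosity = character(0),
             stop_triplet = character(0), stop_from = integer(0),
             stop_to = integer(0), stop_exon = character(0),
             inactivating = logical(0), col_start = integer(0),
             col_end = integer(0), stringsAsFactors = FALSE)
}

new_record <- function(...) {
  r <- list(...)
  tmpl <- list(taxon = NA_character_, gene = NA_character_,
               exon = NA_character_, exon_index = NA_integer_,
               klass = NA_character_, location = NA_character_,
               pos_key = NA_real_, ref_alleles = NA_character_,
               alt = NA_character_, indel_length = 0L,
               zygosity = NA_character_, stop_triplet = NA_character_,
               stop_from = NA_integer_, stop_to = NA_integer_,
               stop_exon = NA_character_, inactivating = NA,
               col_start = NA_integer_, col_end = NA_integer_)
  tmpl[names(r)] <- r
  as.data.frame(tmpl, stringsAsFactors = FALSE)
}

#' Call the zygosity of a target residue at a mutated site
#'
#' Direct (e.g. Sanger) sequencing of a diploid shows heterozygous sites as
#' IUPAC ambiguity codes. A plain base carrying the mutant allele is called
#' homozygous; a two-allele ambiguity whose expansion contains the mutant
#' allele is heterozygous; an ambiguity not containing the mutant allele, or
#' an uninformative code expanding to three or more bases (N, B, D, H, V),
#' yields no call (`NA`).
#'
#' @param residue Target residue (single character).
#' @param ref_alleles Character vector of reference alleles at the site.
#' @param mutant The mutant allele being called.
#' @return `"homozygous"`, `"heterozygous"` or `NA_character_`.
#' @export
call_zygosity <- function(residue, ref_alleles, mutant) {
  e <- expand_residue(toupper(residue))
  if (length(e) == 0 || length(e) > 2) return(NA_character_)
  if (!mutant %in% e) return(NA_character_)
  if (length(e) == 1) "homozygous" else "heterozygous"
}

# Does a reference row's codon (three residues, possibly ambiguous) admit a
# stop under some expansion? Used to suppress calls where a reference itself
# could read as a stop.
ref_codon_has_stop <- function(r1, r2, r3) {
  e1 <- expand_residue(r1); e2 <- expand_residue(r2); e3 <- expand_residue(r3)
  if (!length(e1) || !length(e2) || !length(e3)) return(FALSE)
  any(outer(outer(e1, e2, paste0), e3, paste0) %in% STOP_CODONS)
}

#' Detect nonsense substitutions in a target taxon
#'
#' Scans every in-frame reference codon upstream of the native stop. A record
#' is emitted when the target's codon (resolving two-allele ambiguities over
#' all expansions) is a stop, no reference row's codon at that triplet can
#' read as a stop, and at least one codon position carries a target allele
#' absent from every reference row there. The record is located at the first
#' such mutated site and carries the stop triplet and its reference-coordinate
#' span.
#'
#' @param view A gene view from [concatenate_gene()].
#' @param target Target taxon name.
#' @return A mutation-record data frame (zero rows if none).
#' @export
detect_nonsense_substitutions <- function(view, target) {
  if (!target %in% view$taxa) stop_label("taxon not in alignment: %s", target)
  model <- view$model
  ref_taxa <- view$taxa[view$roles == "reference"]
  out <- list()
  n_codon <- model$cds_length %/% 3L
  for (ci in seq_len(n_codon - 1L)) {       # native stop codon excluded
    g <- (3L * ci - 2L):(3L * ci)
    cols <- view$ref_col[g]
    tres <- view$mat[target, cols]
    if (any(tres == "-")) next
    texp <- lapply(tres, expand_residue)
    if (any(lengths(texp) == 0L) || any(lengths(texp) > 2L)) next
    # reference allele sets per codon position
    refmat <- view$mat[ref_taxa, cols, drop = FALSE]
    refset <- lapply(1:3, function(k) {
      unique(unlist(lapply(refmat[, k], expand_residue)))
    })
    if (any(lengths(refset) == 0L)) next
    # quick escape: target identical to a reference row everywhere
    if (!any(vapply(1:3, function(k) any(!texp[[k]] %in% refset[[k]]),
                    logical(1)))) next
    if (any(apply(refmat, 1L, function(r) ref_codon_has_stop(r[1], r[2], r[3]))))
      next
    combos <- expand.grid(texp[[1]], texp[[2]], texp[[3]],
                          stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      codon <- paste0(combos[r, 1], combos[r, 2], combos[r, 3])
      if (!codon %in% STOP_CODONS) next
      mutated <- vapply(1:3, function(k) !combos[r, k] %in% refset[[k]],
                        logical(1))
      if (!any(mutated)) next
      k <- which(mutated)[1]
      loc <- global_to_exon(model, g[k])
      span_from <- global_to_exon(model, g[1])
      span_to <- global_to_exon(model, g[3])
      refres <- sort(unique(refmat[, k][refmat[, k] != "-"]))
      out[[length(out) + 1L]] <- new_record(
        taxon = target, gene = model$gene,
        exon = loc$exon, exon_index = loc$exon_index,
        klass = "nonsense_substitution",
        location = as.character(loc$pos), pos_key = loc$pos,
        ref_alleles = paste(refres, collapse = ","),
        alt = combos[r, k][[1]], indel_length = 0L,
        zygosity = call_zygosity(tres[k], refset[[k]], combos[r, k][[1]]),
        stop_triplet = codon, stop_from = span_from$pos, stop_to = span_to$pos,
        stop_exon = span_from$exon, inactivating = TRUE,
        col_start = cols[k], col_end = cols[k])
      break   # one record per stop codon
    }
  }
  if (length(out)) do.call(rbind, out) else empty_records()
}

#' Detect insertions and deletions in a target taxon
#'
#' Maximal runs of target-only ungapped insertion-slot columns become one
#' insertion record each; maximal runs of reference positions gapped in the
#' target become one deletion record each (slot columns gapped in both target
#' and references are invisible to both run types). An insertion whose bases,
#' read in the target's frame entering the insertion, contain a stop triplet
#' is classed `stop_insertion` (inactivating, tallied with the nonsense
#' class); otherwise a length not divisible by 3 gives
#' `frameshift_insertion`/`frameshift_deletion`, and a frame-preserving,
#' stop-free indel is a non-inactivating `inframe_indel`.
#'
#' @inheritParams detect_nonsense_substitutions
#' @return A mutation-record data frame.
#' @export
detect_indels <- function(view, target) {
  if (!target %in% view$taxa) stop_label("taxon not in alignment: %s", target)
  model <- view$model
  t <- view$mat[target, ]
  is_slot <- is.na(view$col$global_ref)
  t_gap <- t == "-"
  n_before <- cumsum(!t_gap)     # target bases in columns 1..j
  out <- list()

  for (ei in seq_along(model$exon_id)) {
    idx <- which(view$col$exon_index == ei)
    ins_run <- integer(0); del_run <- integer(0)
    flush_ins <- function(run) {
      if (!length(run)) return()
      anchor <- view$col$anchor[run[1]]
      seq_ins <- t[run]
      len <- length(run)
      start_before <- if (run[1] > 1L) n_before[run[1] - 1L] else 0L
      r <- start_before %% 3L
      carry <- character(0)
      if (r > 0L) {
        prior <- which(!t_gap[seq_len(run[1] - 1L)])
        carry <- t[tail(prior, r)]
      }
      bases <- c(carry, seq_ins)
      n_cod <- length(bases) %/% 3L
      stop_trip <- NA_character_
      if (n_cod > 0L) {
        cods <- vapply(seq_len(n_cod), function(k)
          paste(bases[(3L * k - 2L):(3L * k)], collapse = ""), character(1))
        hit <- which(cods %in% STOP_CODONS)
        if (length(hit)) stop_trip <- cods[hit[1]]
      }
      klass <- if (!is.na(stop_trip)) "stop_insertion"
        else if (len %% 3L != 0L) "frameshift_insertion" else "inframe_indel"
      out[[length(out) + 1L]] <<- new_record(
        taxon = target, gene = model$gene,
        exon = model$exon_id[ei], exon_index = ei,
        klass = klass,
        location = sprintf("between %d and %d", anchor, anchor + 1L),
        pos_key = anchor + 0.5,
        ref_alleles = "-", alt = paste(seq_ins, collapse = ""),
        indel_length = len, zygosity = "homozygous",
        stop_triplet = stop_trip,
        inactivating = klass != "inframe_indel",
        col_start = run[1], col_end = run[length(run)])
    }
    flush_del <- function(run) {
      if (!length(run)) return()
      p1 <- view$col$ref_pos[run[1]]
      p2 <- view$col$ref_pos[run[length(run)]]
      len <- length(run)
      klass <- if (len %% 3L != 0L) "frameshift_deletion" else "inframe_indel"
      out[[length(out) + 1L]] <<- new_record(
        taxon = target, gene = model$gene,
        exon = model$exon_id[ei], exon_index = ei,
        klass = klass,
        location = if (len == 1L) as.character(p1) else sprintf("%d-%d", p1, p2),
        pos_key = as.numeric(p1),
        ref_alleles = "-", alt = "-",
        indel_length = len, zygosity = "homozygous",
        inactivating = klass != "inframe_indel",
        col_start = run[1], col_end = run[length(run)])
    }
    for (j in idx) {
      if (is_slot[j]) {
        if (!t_gap[j]) {                      # insertion column
          flush_del(del_run); del_run <- integer(0)
          ins_run <- c(ins_run, j)
        } else {                              # neutral: other taxon's slot
          flush_ins(ins_run); ins_run <- integer(0)
        }
      } else {
        if (t_gap[j]) {                       # deletion column
          flush_ins(ins_run); ins_run <- integer(0)
          del_run <- c(del_run, j)
        } else {                              # matched column
          flush_ins(ins_run); ins_run <- integer(0)
          flush_del(del_run); del_run <- integer(0)
        }
      }
    }
    flush_ins(ins_run); flush_del(del_run)
  }
  if (length(out)) do.call(rbind, out) else empty_records()
}

#' Locate the premature stop downstream of a frameshift
#'
#' Translates the target's gap-stripped CDS from the codon containing the
#' frameshifted position onward, in the target's own running frame (which
#' incorporates every upstream and intervening target indel and continues
#' across exon junctions), until the first stop triplet or the end of the
#' CDS. The stop's span is reported in reference coordinates of the exon
#' containing it; inserted target bases do not consume reference positions.
#' A codon that lands exactly on the native stop in the native frame is the
#' gene's own terminator, not a premature stop.
#'
#' @inheritParams detect_nonsense_substitutions
#' @param record A one-row frameshift mutation record (from
#'   [detect_indels()]).
#' @return A list `(triplet, from, to, exon)`, or `NULL` if no stop occurs
#'   before the CDS end.
#' @export
locate_downstream_premature_stop <- function(view, target, record) {
  if (!record$klass %in% c("frameshift_insertion", "frameshift_deletion"))
    stop_format("record is not a frameshift (%s)", record$klass)
  model <- view$model
  cds <- taxon_cds(view, target)
  if (record$klass == "frameshift_insertion") {
    tpos <- match(record$col_start, cds$column)
  } else {
    after <- which(cds$column > record$col_end)
    if (!length(after)) return(NULL)
    tpos <- after[1]
  }
  if (is.na(tpos)) return(NULL)
  n <- length(cds$seq)
  k <- (tpos - 1L) %/% 3L
  while (3L * k + 3L <= n) {
    idx <- (3L * k + 1L):(3L * k + 3L)
    codon <- paste(cds$seq[idx], collapse = "")
    if (codon %in% STOP_CODONS) {
      gl <- cds$global_ref[idx]
      if (all(!is.na(gl)) && identical(as.integer(gl), model$native_stop))
        return(NULL)                 # frame realigned onto the native stop
      mapped <- which(!is.na(gl))
      if (length(mapped)) {
        from <- global_to_exon(model, gl[mapped[1]])
        to <- global_to_exon(model, gl[mapped[length(mapped)]])
        return(list(triplet = codon, from = from$pos, to = to$pos,
                    exon = from$exon))
      }
      # stop entirely within inserted bases: no reference span
      colinfo <- view$col[cds$column[idx[1]], ]
      return(list(triplet = codon, from = NA_integer_, to = NA_integer_,
                  exon = colinfo$exon))
    }
    k <- k + 1L
  }
  NULL
}

#' Scan a gene for inactivating mutations in one target taxon
#'
#' Runs the nonsense and indel detectors, attaches the downstream premature
#' stop to every frameshift record, sorts records by (exon order, location)
#' and tallies by class. Stop-introducing insertions are tallied with the
#' nonsense class; the frameshift tally covers frameshift insertions and
#' deletions; in-frame indels are reported but not inactivating.
#'
#' @param alns List of [exon_alignment()]s in model order, or a ready-made
#'   gene view from [concatenate_gene()].
#' @param model A [gene_model()] (ignored when `alns` is already a view).
#' @param target Target taxon name.
#' @return An object of class `lesion_report`: `taxon`, `gene`, `records`
#'   (mutation-record data frame) and `tally` (named counts:
#'   `nonsense_type`, `frameshift`, `inframe`, `inactivating`).
#' @export
scan_gene <- function(alns, model, target) {
  view <- if (inherits(alns, "gene_view")) alns else concatenate_gene(alns, model)
  rec <- rbind(detect_nonsense_substitutions(view, target),
               detect_indels(view, target))
  if (nrow(rec)) {
    fs <- which(rec$klass %in% c("frameshift_insertion", "frameshift_deletion"))
    for (i in fs) {
      ps <- locate_downstream_premature_stop(view, target, rec[i, ])
      if (!is.null(ps)) {
        rec$stop_triplet[i] <- ps$triplet
        rec$stop_from[i] <- ps$from
        rec$stop_to[i] <- ps$to
        rec$stop_exon[i] <- ps$exon
      }
    }
    rec <- rec[order(rec$exon_index, rec$pos_key), , drop = FALSE]
    rownames(rec) <- NULL
  }
  structure(
    list(taxon = target, gene = view$model$gene, records = rec,
         references = view$taxa[view$roles == "reference"],
         tally = tally_records(rec)),
    class = "lesion_report"
  )
}

tally_records <- function(rec) {
  c(nonsense_type = sum(rec$klass %in% c("nonsense_substitution",
                                         "stop_insertion")),
    frameshift = sum(rec$klass %in% c("frameshift_insertion",
                                      "frameshift_deletion")),
    inframe = sum(rec$klass == "inframe_indel"),
    inactivating = sum(rec$inactivating))
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf("<lesion_report %s / %s: %d nonsense-type, %d frameshift, %d in-frame>\n",
              x$taxon, x$gene, x$tally[["nonsense_type"]],
              x$tally[["frameshift"]], x$tally[["inframe"]]))
  if (nrow(x$records))
    print(x$records[, c("exon", "klass", "location", "alt", "zygosity",
                        "stop_triplet", "stop_from", "stop_to")])
  invisible(x)
}

# Flat table surface of one or more reports (TSV column order is fixed).
records_table <- function(reports) {
  if (inherits(reports, "lesion_report")) reports <- list(reports)
  rec <- do.call(rbind, c(lapply(reports, function(r) r$records),
                          list(empty_records())))
  data.frame(taxon = rec$taxon, gene = rec$gene, exon = rec$exon,
             class = rec$klass, location = rec$location,
             ref_alleles = rec$ref_alleles, alt = rec$alt,
             indel_length = rec$indel_length, zygosity = rec$zygosity,
             stop_triplet = rec$stop_triplet,
             stop_span = ifelse(is.na(rec$stop_from), NA_character_,
                                paste0(rec$stop_from, "-", rec$stop_to)),
             stringsAsFactors = FALSE)
}

#' Write mutation records as TSV / lesion reports as JSON
#'
#' @param reports A `lesion_report` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lesion_tsv <- function(reports, path) {
  write.table(records_table(reports), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_lesion_tsv
#' @export
write_lesion_json <- function(reports, path) {
  if (inherits(reports, "lesion_report")) reports <- list(reports)
  payload <- lapply(reports, function(r) {
    rec <- r$records
    rec$pos_key <- rec$col_start <- rec$col_end <- NULL
    list(taxon = r$taxon, gene = r$gene,
         references = as.list(r$references), tally = as.list(r$tally),
         records = rec)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}

#' Read lesion reports back from JSON
#' @param path Path written by [write_lesion_json()].
#' @return A list of `lesion_report` objects.
#' @export
read_lesion_json <- function(path) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    rec <- if (!length(p$records)) empty_records() else {
      tmpl <- empty_records()
      do.call(rbind, lapply(p$records, function(row) {
        out <- tmpl[0, ]
        one <- as.list(tmpl[NA_integer_, ])   # one row of typed NAs
        for (nm in names(one))
          if (!is.null(row[[nm]])) one[[nm]] <- row[[nm]]
        one$pos_key <- one$pos_key %||% NA_real_
        as.data.frame(one, stringsAsFactors = FALSE)
      }))
    }
    structure(list(taxon = p$taxon, gene = p$gene, records = rec,
                   references = unlist(p$references),
                   tally = tally_records(rec)),
              class = "lesion_report")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
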