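#' Construct an exon alignment
#'
#' An `exon_alignment` holds one exon's multiple alignment as a character
#' matrix (rows = taxa, columns = alignment columns) together with a role for
#' every taxon: `"reference"` rows define the coordinate system (they are the
#' functional species the target is numbered against), `"target"` rows are the
#' taxa scanned for lesions.
#'
#' Residues are restricted to `A C G T`, IUPAC ambiguity codes and the gap
#' character `-`; lower case is normalised to upper; `.` is rejected.
#'
#' @param exon_id Label of the exon (e.g. `"exon3"`).
#' @param seqs Named character vector of aligned sequences (equal lengths).
#' @param roles Named character vector mapping every taxon to
#'   `"reference"` or `"target"`.
#' @return An object of class `exon_alignment` with elements `exon_id`,
#'   `taxa`, `roles`, `mat` (character matrix) and `n_col`.
#' @examples
#' aln <- exon_alignment("exon1",
#'   c(ref = "ATGGCA", tgt = "ATGGTA"),
#'   roles = c(ref = "reference", tgt = "target"))
#' aln$n_col
#' @export
exon_alignment <- function(exon_id, seqs, roles) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_format("alignment sequences must have unique names")
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop_format("ragged alignment in %s: row widths %s", exon_id,
                paste(unique(widths), collapse = ", "))
  taxa <- names(seqs)
  missing_role <- setdiff(taxa, names(roles))
  if (length(missing_role))
    stop_label("no role given for taxa: %s", paste(missing_role, collapse = ", "))
  roles <- roles[taxa]
  if (!all(roles %in% c("reference", "target")))
    stop_label("roles must be 'reference' or 'target'")
  if (!any(roles == "reference") || !any(roles == "target"))
    stop_label("%s: need at least one reference and one target row", exon_id)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- taxa
  bad <- setdiff(unique(as.vector(mat)), VALID_RESIDUES)
  if (length(bad))
    stop_format("%s: invalid residue symbol(s): %s", exon_id,
                paste(bad, collapse = " "))
  structure(
    list(exon_id = exon_id, taxa = taxa, roles = roles,
         mat = mat, n_col = ncol(mat)),
    class = "exon_alignment"
  )
}

#' Read one exon's aligned FASTA
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @param exon_id Exon label.
#' @param roles Named character vector mapping taxon to role
#'   (`"reference"`/`"target"`); every record in the file must appear.
#' @return An [exon_alignment()].
#' @export
read_exon_alignment <- function(path, exon_id, roles) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop_format("cannot parse FASTA %s: %s",
                                                 path, conditionMessage(e)))
  seqs <- setNames(as.character(ss), names(ss))
  exon_alignment(exon_id, seqs, roles)
}

#' Write an exon alignment to FASTA
#' @param aln An [exon_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exon_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Define a gene model
#'
#' A gene model lists the exons of a coding sequence in order, with their
#' reference lengths in bp. The frame offset at each exon start (`phase_in`,
#' the number of bases of the straddling codon already consumed by upstream
#' exons) is derived from cumulative length; the terminal three reference
#' positions are the native stop codon.
#'
#' @param gene Gene name.
#' @param exon_ids Character vector of exon labels, 5' to 3'.
#' @param lengths Integer vector of reference exon lengths (bp); the total
#'   must be divisible by 3.
#' @return An object of class `gene_model` with `gene`, `exon_id`, `length`,
#'   `phase_in`, `cum_before` (reference bp upstream of each exon),
#'   `cds_length` and `native_stop` (global positions of the last codon).
#' @export
gene_model <- function(gene, exon_ids, lengths) {
  lengths <- as.integer(lengths)
  if (length(exon_ids) != length(lengths))
    stop_model("exon_ids and lengths differ in length")
  if (anyDuplicated(exon_ids)) stop_model("duplicate exon ids")
  if (any(lengths <= 0L)) stop_model("exon lengths must be positive")
  total <- sum(lengths)
  if (total %% 3L != 0L)
    stop_model("total reference CDS length %d is not divisible by 3", total)
  cum_before <- c(0L, cumsum(lengths))[seq_along(lengths)]
  structure(
    list(gene = gene, exon_id = as.character(exon_ids), length = lengths,
         phase_in = cum_before %% 3L, cum_before = cum_before,
         cds_length = total, native_stop = (total - 2L):total),
    class = "gene_model"
  )
}

#' Read or write a gene model as JSON
#'
#' The JSON layout is `{"gene": ..., "exons": [{"id": ..., "length": ...,
#' "phase_in": ...}, ...]}`; `phase_in` is recomputed and checked on read.
#'
#' @param path File path.
#' @return `read_gene_model()` returns a [gene_model()].
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop_format("bad gene-model JSON: %s",
                                                conditionMessage(e)))
  if (is.null(j$gene) || is.null(j$exons))
    stop_format("gene model JSON must have 'gene' and 'exons'")
  gm <- gene_model(j$gene, j$exons$id, j$exons$length)
  if (!is.null(j$exons$phase_in) &&
      !all(as.integer(j$exons$phase_in) == gm$phase_in))
    stop_model("declared phase_in inconsistent with exon lengths")
  gm
}

#' @rdname read_gene_model
#' @param model A [gene_model()].
#' @export
write_gene_model <- function(model, path) {
  jsonlite::write_json(
    list(gene = model$gene,
         exons = data.frame(id = model$exon_id, length = model$length,
                            phase_in = model$phase_in)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Reference-anchored coordinate map of an exon alignment
#'
#' Numbers alignment columns in reference coordinates: a column is a reference
#' position (1-based from the exon's 5' end, left to right) if at least one
#' reference-role row is ungapped there; columns gapped in all reference rows
#' are insertion slots "between p and p+1", attached to the nearest preceding
#' reference position `p` (0 if none precedes) with ordinal offsets 1, 2, ...
#'
#' @param aln An [exon_alignment()].
#' @return A data frame with one row per column: `column`, `ref_pos` (NA for
#'   slots), `anchor` (preceding reference position, for slots), `offset`
#'   (ordinal within a slot run). Attribute `ref_length` gives the exon's
#'   reference length.
#' @export
coordinate_map <- function(aln) {
  ref_rows <- aln$mat[aln$roles == "reference", , drop = FALSE]
  is_ref_col <- apply(ref_rows != "-", 2L, any)
  n <- aln$n_col
  ref_pos <- anchor <- offset <- rep(NA_integer_, n)
  ref_pos[is_ref_col] <- seq_len(sum(is_ref_col))
  p <- 0L; k <- 0L
  for (j in seq_len(n)) {
    if (is_ref_col[j]) {
      p <- ref_pos[j]; k <- 0L
    } else {
      k <- k + 1L
      anchor[j] <- p
      offset[j] <- k
    }
  }
  out <- data.frame(column = seq_len(n), ref_pos = ref_pos,
                    anchor = anchor, offset = offset)
  attr(out, "ref_length") <- sum(is_ref_col)
  out
}

#' Concatenate exon alignments into a gene view
#'
#' Joins the per-exon alignments in model order into one matrix with a global
#' column table carrying, for every column, its exon, per-exon reference
#' position or insertion slot, and (for reference positions) the global CDS
#' coordinate. The reading frame is continuous across exon junctions; codons
#' may span junctions.
#'
#' @param alns List of [exon_alignment()] objects in model order (names or
#'   `exon_id`s must match the model).
#' @param model A [gene_model()].
#' @return An object of class `gene_view`: `model`, `taxa`, `roles`, `mat`
#'   (full concatenated matrix), `col` (column table with `exon`,
#'   `exon_index`, `ref_pos`, `anchor`, `offset`, `global_ref`), and
#'   `ref_col` (column index of each global reference position).
#' @export
concatenate_gene <- function(alns, model) {
  ids <- vapply(alns, function(a) a$exon_id, character(1))
  if (!identical(ids, model$exon_id))
    stop_model("exon alignments (%s) do not match model exons (%s)",
               paste(ids, collapse = ","), paste(model$exon_id, collapse = ","))
  taxa <- alns[[1]]$taxa
  roles <- alns[[1]]$roles
  cols <- list(); mats <- list()
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    if (!setequal(a$taxa, taxa))
      stop_model("exon %s has a different taxon set", a$exon_id)
    cmap <- coordinate_map(a)
    if (attr(cmap, "ref_length") != model$length[i])
      stop_model("exon %s: reference span %d, model says %d",
                 a$exon_id, attr(cmap, "ref_length"), model$length[i])
    cmap$exon <- a$exon_id
    cmap$exon_index <- i
    cmap$global_ref <- ifelse(is.na(cmap$ref_pos), NA_integer_,
                              model$cum_before[i] + cmap$ref_pos)
    cols[[i]] <- cmap
    mats[[i]] <- a$mat[taxa, , drop = FALSE]
  }
  col <- do.call(rbind, cols)
  col$column <- seq_len(nrow(col))
  rownames(col) <- NULL
  mat <- do.call(cbind, mats)
  ref_col <- rep(NA_integer_, model$cds_length)
  ref_col[col$global_ref[!is.na(col$global_ref)]] <-
    col$column[!is.na(col$global_ref)]
  structure(
    list(model = model, taxa = taxa, roles = roles, mat = mat,
         col = col, ref_col = ref_col),
    class = "gene_view"
  )
}

# Per-exon location of a global reference position: list(exon, pos).
global_to_exon <- function(model, g) {
  i <- findInterval(g - 1L, c(model$cum_before, model$cds_length),
                    rightmost.closed = FALSE)
  list(exon = model$exon_id[i], exon_index = i, pos = g - model$cum_before[i])
}

#' Extract a taxon's gap-stripped CDS from a gene view
#'
#' @param view A gene view from [concatenate_gene()].
#' @param taxon Taxon name.
#' @return A list with `seq` (character vector of bases), `column` (alignment
#'   column of each base) and `global_ref` (global reference position of each
#'   base, NA for inserted bases).
#' @export
taxon_cds <- function(view, taxon) {
  if (!taxon %in% view$taxa) stop_label("taxon not in alignment: %s", taxon)
  x <- view$mat[taxon, ]
  keep <- x != "-"
  list(seq = unname(x[keep]), column = view$col$column[keep],
       global_ref = view$col$global_ref[keep])
}

#' @export
print.exon_alignment <- function(x, ...) {
  cat(sprintf("<exon_alignment %s: %d taxa x %d columns (%d reference rows)>\n",
              x$exon_id, length(x$taxa), x$n_col, sum(x$roles == "reference")))
  invisible(x)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s: %d exons, %d bp CDS>\n",
              x$gene, length(x$exon_id), x$cds_length))
  print(data.frame(exon = x$exon_id, length = x$length, phase_in = x$phase_in))
  invisible(x)
}

#' @export
print.gene_view <- function(x, ...) {
  cat(sprintf("<gene_view %s: %d taxa, %d columns, %d bp reference CDS>\n",
              x$model$gene, length(x$taxa), nrow(x$col), x$model$cds_length))
  invisible(x)
}
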