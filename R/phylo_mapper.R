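#' Parse a rooted, time-calibrated tree
#'
#' Reads a Newick tree with branch lengths in millions of years, checks that
#' it is rooted and ultrametric (relative root-to-tip deviation at most
#' `tol`), and computes node ages as root height minus root-to-node path
#' length. Tip ages are snapped to 0.
#'
#' @param source Newick text (if it contains a `(`/`;`) or a file path.
#' @param tol Relative ultrametricity tolerance (default `1e-6`).
#' @return An object of class `time_tree`: `phy` (an [ape::read.tree()]
#'   `phylo`), `ages` (node ages in Mya, indexed by ape node number),
#'   `labels` (tip and internal node labels), `root` (root node number),
#'   `root_age`.
#' @examples
#' tr <- read_time_tree("((A:3,B:3):6.5,(C:5,D:5):4.5);")
#' tr$root_age
#' @export
read_time_tree <- function(source, tol = 1e-6) {
  phy <- if (grepl("[(;]", source)) {
    tryCatch(ape::read.tree(text = source),
             error = function(e) stop_tree("cannot parse Newick: %s",
                                           conditionMessage(e)))
  } else {
    if (!file.exists(source)) stop_io("no such file: %s", source)
    tryCatch(ape::read.tree(source),
             error = function(e) stop_tree("cannot parse Newick: %s",
                                           conditionMessage(e)))
  }
  if (is.null(phy)) stop_tree("cannot parse Newick input")
  n <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label))
    stop_tree("duplicate tip labels: %s",
              paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                    collapse = ", "))
  if (n == 1L) {
    ages <- setNames(0, phy$tip.label)
    return(structure(list(phy = phy, ages = 0, labels = phy$tip.label,
                          root = 1L, root_age = 0),
                     class = "time_tree"))
  }
  if (is.null(phy$edge.length))
    stop_tree("tree has no branch lengths")
  if (!ape::is.rooted(phy)) stop_tree("tree is not rooted")
  if (any(phy$edge.length <= 0))
    stop_tree("all branch lengths must be positive")
  depth <- ape::node.depth.edgelength(phy)
  tip_depth <- depth[seq_len(n)]
  root_age <- max(tip_depth)
  if (root_age <= 0) stop_tree("tree has zero height")
  if ((max(tip_depth) - min(tip_depth)) / root_age > tol)
    stop_tree("tree is not ultrametric (relative deviation %.3g > %.3g)",
              (max(tip_depth) - min(tip_depth)) / root_age, tol)
  ages <- root_age - depth
  ages[seq_len(n)] <- 0
  m <- phy$Nnode
  internal_labels <- if (!is.null(phy$node.label) &&
                         all(nzchar(phy$node.label))) phy$node.label
                     else paste0("node", (n + 1L):(n + m))
  structure(
    list(phy = phy, ages = ages,
         labels = c(phy$tip.label, internal_labels),
         root = n + 1L, root_age = root_age),
    class = "time_tree"
  )
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("<time_tree: %d tips, root age %.4g Mya>\n",
              length(x$phy$tip.label), x$root_age))
  invisible(x)
}

# Tip-label sets of every node (tips included), indexed by ape node number.
node_tip_sets <- function(phy) {
  n <- length(phy$tip.label)
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    sets[[eo[k, 1L]]] <- c(sets[[eo[k, 1L]]], sets[[eo[k, 2L]]])
  sets
}

# Parent node number of each node (NA for root).
node_parents <- function(phy) {
  n_all <- length(phy$tip.label) + phy$Nnode
  par <- rep(NA_integer_, n_all)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

#' Group identical lesions across taxa
#'
#' Records from several taxa are merged when they share the identity key
#' (gene, exon, location, class, alternate allele, indel length); the taxa
#' carrying each lesion form its carrier set. Shared lesions are candidate
#' synapomorphies for a single ancestral origin.
#'
#' @param reports List of `lesion_report`s (typically one per taxon and
#'   gene). Reports with zero records still register their taxon as sampled
#'   for that gene, and the reference taxa of every report count as sampled
#'   too (they were sequenced and shown lesion-free).
#' @return An object of class `lesion_groups`: a data frame with the key
#'   fields, `inactivating`, `carriers` (list column) and `n_carriers`,
#'   plus attribute `sampled_by_gene` (taxa scanned per gene).
#' @export
group_shared_lesions <- function(reports) {
  if (inherits(reports, "lesion_report")) reports <- list(reports)
  sampled <- list()
  for (r in reports)
    sampled[[r$gene]] <- sort(unique(c(sampled[[r$gene]], r$taxon,
                                       r$references)))
  rec <- do.call(rbind, c(lapply(reports, `[[`, "records"),
                          list(empty_records())))
  if (!nrow(rec)) {
    out <- data.frame(key = character(0), gene = character(0),
                      exon = character(0), exon_index = integer(0),
                      location = character(0), klass = character(0),
                      alt = character(0), indel_length = integer(0),
                      pos_key = numeric(0), inactivating = logical(0),
                      n_carriers = integer(0))
    out$carriers <- list()
    attr(out, "sampled_by_gene") <- sampled
    class(out) <- c("lesion_groups", class(out))
    return(out)
  }
  key <- paste(rec$gene, rec$exon, rec$location, rec$klass, rec$alt,
               rec$indel_length, sep = "|")
  idx <- split(seq_len(nrow(rec)), key)
  rows <- lapply(idx, function(i) {
    first <- rec[i[1], ]
    data.frame(key = paste(first$gene, first$exon, first$location,
                           first$klass, first$alt, first$indel_length,
                           sep = "|"),
               gene = first$gene, exon = first$exon,
               exon_index = first$exon_index, location = first$location,
               klass = first$klass, alt = first$alt,
               indel_length = first$indel_length, pos_key = first$pos_key,
               inactivating = first$inactivating,
               n_carriers = length(unique(rec$taxon[i])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$carriers <- lapply(idx, function(i) sort(unique(rec$taxon[i])))
  out <- out[order(out$gene, out$exon_index, out$pos_key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sampled_by_gene") <- sampled
  class(out) <- c("lesion_groups", class(out))
  out
}

#' Assign Dollo origin branches to lesion groups
#'
#' Under the Dollo assumption an inactivating lesion arises once and is
#' never reverted, so a lesion shared by all sampled members of a clade is
#' placed on that clade's stem branch. Formally, each group's carriers are
#' covered by the minimal set of maximal clades whose sampled descendants
#' all carry the lesion; a singleton carrier maps to its terminal branch,
#' and a carrier set that is not a sampled clade yields several origins and
#' a homoplasy flag. Tips without a lesion report for the gene are treated
#' as unsampled: they never contradict a clade assignment.
#'
#' @param groups A [group_shared_lesions()] result.
#' @param tree A [read_time_tree()] result.
#' @param sampled Optional named list (gene -> character vector of sampled
#'   taxa); defaults to the groups' `sampled_by_gene` attribute.
#' @return An object of class `origin_assignments`: a list with one element
#'   per group (`key`, `gene`, `inactivating`, `carriers`, `origin_nodes`,
#'   `branches` as a list of `c(parent_label, child_label)`, `n_origins`,
#'   `homoplasy`), plus the `tree`.
#' @export
assign_origin_branches <- function(groups, tree, sampled = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  if (is.null(sampled)) sampled <- attr(groups, "sampled_by_gene")
  phy <- tree$phy
  tips <- phy$tip.label
  sets <- node_tip_sets(phy)
  parents <- node_parents(phy)
  per_group <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    carriers <- groups$carriers[[i]]
    missing <- setdiff(carriers, tips)
    if (length(missing))
      stop_label("carrier(s) not in tree: %s", paste(missing, collapse = ", "))
    samp <- intersect(sampled[[g$gene]] %||% carriers, tips)
    samp <- union(samp, carriers)
    # candidate nodes: >=1 sampled descendant, all sampled descendants carry
    cand <- vapply(sets, function(s) {
      sd <- intersect(s, samp)
      length(sd) > 0 && all(sd %in% carriers)
    }, logical(1))
    origins <- integer(0)
    for (tip in carriers) {
      v <- match(tip, tips)
      while (!is.na(parents[v]) && cand[parents[v]]) v <- parents[v]
      origins <- c(origins, v)
    }
    origins <- sort(unique(origins))
    branches <- lapply(origins, function(v) {
      p <- parents[v]
      c(parent = if (is.na(p)) NA_character_ else tree$labels[p],
        child = tree$labels[v])
    })
    list(key = g$key, gene = g$gene, inactivating = g$inactivating,
         carriers = carriers, origin_nodes = origins, branches = branches,
         n_origins = length(origins), homoplasy = length(origins) > 1L)
  })
  structure(list(groups = per_group, tree = tree, sampled = sampled),
            class = "origin_assignments")
}

#' @export
print.origin_assignments <- function(x, ...) {
  cat(sprintf("<origin_assignments: %d groups on %d-tip tree>\n",
              length(x$groups), length(x$tree$phy$tip.label)))
  for (g in x$groups)
    cat(sprintf("  %s: %d origin(s)%s on %s\n", g$key, g$n_origins,
                if (g$homoplasy) " [homoplasy]" else "",
                paste(vapply(g$branches, function(b)
                  sprintf("%s->%s", b[["parent"]], b[["child"]]), character(1)),
                  collapse = ", ")))
  invisible(x)
}

#' Date gene-loss events from origin assignments
#'
#' For each gene with at least one inactivating lesion group, the loss
#' branch is the assigned origin branch closest to the root whose sampled
#' descendant tips are all pseudogenes for that gene; independent origins
#' (homoplasy) yield one event per qualifying branch. The event's time
#' interval is `[age(child), age(parent)]` of the loss branch, in Mya, and
#' every tip descending from the branch's child — sampled or not — is
#' predicted nonfunctional. When nested branches qualify, the rootward one
#' is chosen; a warning is logged if that extension is supported only by
#' unsampled (unknown-status) tips.
#'
#' @param assignments An [assign_origin_branches()] result.
#' @param statuses List of [call_gene_status()] objects (or a named list
#'   gene -> named character vector taxon -> status).
#' @return A list of `loss_event` objects: `gene`, `branch`
#'   (`c(parent_label, child_label)`), `interval` (`c(lower, upper)` Mya),
#'   `causal_groups`, `predicted_tips`, `predicted_unsampled`, `tree_tips`.
#'   Genes with no inactivating groups produce no event.
#' @export
date_gene_loss <- function(assignments, statuses) {
  stopifnot(inherits(assignments, "origin_assignments"))
  tree <- assignments$tree
  phy <- tree$phy
  sets <- node_tip_sets(phy)
  parents <- node_parents(phy)
  status_map <- as_status_map(statuses)
  groups <- Filter(function(g) isTRUE(g$inactivating), assignments$groups)
  events <- list()
  for (gene in unique(vapply(groups, `[[`, character(1), "gene"))) {
    gg <- Filter(function(g) g$gene == gene, groups)
    st <- status_map[[gene]] %||% character(0)
    sampled_tips <- intersect(names(st), phy$tip.label)
    nodes <- sort(unique(unlist(lapply(gg, `[[`, "origin_nodes"))))
    qualifying <- nodes[vapply(nodes, function(v) {
      sd <- intersect(sets[[v]], sampled_tips)
      length(sd) > 0 && all(st[sd] == "pseudogene")
    }, logical(1))]
    if (!length(qualifying)) next
    keep <- qualifying[vapply(qualifying, function(v) {
      !any(vapply(qualifying, function(w)
        w != v && all(sets[[v]] %in% sets[[w]]), logical(1)))
    }, logical(1))]
    for (v in keep) {
      nested <- qualifying[vapply(qualifying, function(w)
        w != v && all(sets[[w]] %in% sets[[v]]), logical(1))]
      for (w in nested) {
        extra <- setdiff(sets[[v]], sets[[w]])
        if (length(extra) && !any(extra %in% sampled_tips))
          warning(sprintf(
            "%s: loss branch extended rootward past unsampled tips (%s)",
            gene, paste(extra, collapse = ", ")), call. = FALSE)
      }
      p <- parents[v]
      interval <- c(lower = unname(tree$ages[v]),
                    upper = if (is.na(p)) NA_real_ else unname(tree$ages[p]))
      causal <- vapply(Filter(function(g) v %in% g$origin_nodes, gg),
                       `[[`, character(1), "key")
      predicted <- sets[[v]]
      events[[length(events) + 1L]] <- structure(
        list(gene = gene,
             branch = c(parent = if (is.na(p)) NA_character_
                                 else tree$labels[p],
                        child = tree$labels[v]),
             interval = interval, causal_groups = causal,
             predicted_tips = predicted,
             predicted_unsampled = setdiff(predicted, sampled_tips),
             tree_tips = phy$tip.label),
        class = "loss_event")
    }
  }
  events
}

as_status_map <- function(statuses) {
  if (length(statuses) && all(vapply(statuses, inherits, logical(1),
                                     "gene_status"))) {
    out <- list()
    for (s in statuses) out[[s$gene]][s$taxon] <- s$status
    out
  } else statuses
}

#' Predict the status of a tip from a loss event
#'
#' Under Dollo irreversibility every descendant of the loss branch's child
#' inherits the pseudogene, so tips inside the clade — including taxa never
#' sequenced — are predicted nonfunctional; tips outside it get no
#' prediction (`NA`).
#'
#' @param event A `loss_event` from [date_gene_loss()].
#' @param tip Tip label.
#' @return `"pseudogene"` or `NA_character_`.
#' @export
predict_unsampled_status <- function(event, tip) {
  stopifnot(inherits(event, "loss_event"))
  if (!tip %in% event$tree_tips) stop_label("tip not in tree: %s", tip)
  if (tip %in% event$predicted_tips) "pseudogene" else NA_character_
}

#' @export
print.loss_event <- function(x, ...) {
  cat(sprintf("<loss_event %s: branch %s -> %s, %.4g to %.4g Mya, %d causal group(s)>\n",
              x$gene, x$branch[["parent"]], x$branch[["child"]],
              x$interval[["lower"]], x$interval[["upper"]],
              length(x$causal_groups)))
  invisible(x)
}

#' Tabulate or serialize loss events
#'
#' @param events List of `loss_event`s.
#' @return `loss_events_table()` returns a data frame (one row per event).
#' @export
loss_events_table <- function(events) {
  if (!length(events))
    return(data.frame(gene = character(0), parent = character(0),
                      child = character(0), lower_mya = numeric(0),
                      upper_mya = numeric(0), n_causal_groups = integer(0),
                      predicted_tips = character(0)))
  do.call(rbind, lapply(events, function(e)
    data.frame(gene = e$gene, parent = e$branch[["parent"]],
               child = e$branch[["child"]],
               lower_mya = e$interval[["lower"]],
               upper_mya = e$interval[["upper"]],
               n_causal_groups = length(e$causal_groups),
               predicted_tips = paste(e$predicted_tips, collapse = ","),
               stringsAsFactors = FALSE)))
}

#' @rdname loss_events_table
#' @param path Output path for JSON.
#' @return `write_loss_events_json()` returns `path`, invisibly.
#' @export
write_loss_events_json <- function(events, path) {
  payload <- lapply(events, function(e)
    list(gene = e$gene,
         branch = c(e$branch[["parent"]], e$branch[["child"]]),
         interval_mya = c(e$interval[["lower"]], e$interval[["upper"]]),
         causal_groups = as.list(e$causal_groups),
         predicted_tips = as.list(e$predicted_tips)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}
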