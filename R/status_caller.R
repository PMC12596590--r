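#' Call gene functional status from a lesion report
#'
#' A gene is a pseudogene if its scan found at least one inactivating record
#' (nonsense substitution, stop-introducing insertion, or frameshift indel);
#' otherwise it is intact. In-frame, stop-free indels do not inactivate.
#' Unscanned taxa are `unknown` — represent them by not calling a status.
#'
#' @param report A `lesion_report` from [scan_gene()].
#' @return An object of class `gene_status`: `taxon`, `gene`, `status`
#'   (`"intact"` or `"pseudogene"`), and `supporting` (the inactivating
#'   records).
#' @export
call_gene_status <- function(report) {
  stopifnot(inherits(report, "lesion_report"))
  supporting <- report$records[which(report$records$inactivating), ,
                               drop = FALSE]
  structure(
    list(taxon = report$taxon, gene = report$gene,
         status = if (nrow(supporting) > 0) "pseudogene" else "intact",
         supporting = supporting),
    class = "gene_status"
  )
}

#' Call heterodimeric receptor status from component-gene statuses
#'
#' A heterodimeric receptor (e.g. the TAS1R1+TAS1R3 umami or TAS1R2+TAS1R3
#' sweet taste receptor) requires the integrity of both component genes:
#' pseudogenization of either component makes the receptor nonfunctional.
#' The call is `nonfunctional` if any component is a pseudogene,
#' `functional` only if every component is intact, and `unknown` otherwise
#' (a missing or unknown component never improves the call).
#'
#' @param receptor Receptor name (e.g. `"TAS1R1-TAS1R3"`).
#' @param components Character vector of component gene names.
#' @param statuses A list of [call_gene_status()] results (or a named
#'   character vector of statuses, named by gene).
#' @return An object of class `receptor_status`: `receptor`, `components`,
#'   `component_status` (named character vector) and `functional`
#'   (`"functional"`, `"nonfunctional"` or `"unknown"`).
#' @export
call_receptor_status <- function(receptor, components, statuses) {
  if (is.list(statuses) && all(vapply(statuses, inherits, logical(1),
                                      "gene_status"))) {
    statuses <- setNames(vapply(statuses, `[[`, character(1), "status"),
                         vapply(statuses, `[[`, character(1), "gene"))
  }
  comp <- setNames(rep("unknown", length(components)), components)
  known <- intersect(components, names(statuses))
  comp[known] <- statuses[known]
  functional <-
    if (any(comp == "pseudogene")) "nonfunctional"
    else if (all(comp == "intact")) "functional"
    else "unknown"
  structure(
    list(receptor = receptor, components = components,
         component_status = comp, functional = functional),
    class = "receptor_status"
  )
}

#' @export
print.gene_status <- function(x, ...) {
  cat(sprintf("<gene_status %s / %s: %s (%d inactivating records)>\n",
              x$taxon, x$gene, x$status, nrow(x$supporting)))
  invisible(x)
}

#' @export
print.receptor_status <- function(x, ...) {
  cat(sprintf("<receptor_status %s: %s [%s]>\n", x$receptor, x$functional,
              paste(sprintf("%s=%s", names(x$component_status),
                            x$component_status), collapse = ", ")))
  invisible(x)
}

#' Write gene/receptor statuses as JSON
#' @param statuses List of `gene_status` and/or `receptor_status` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_status_json <- function(statuses, path) {
  payload <- lapply(statuses, function(s) {
    if (inherits(s, "gene_status"))
      list(kind = "gene", taxon = s$taxon, gene = s$gene, status = s$status,
           n_inactivating = nrow(s$supporting))
    else
      list(kind = "receptor", receptor = s$receptor,
           component_status = as.list(s$component_status),
           functional = s$functional)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
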