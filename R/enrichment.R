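# Gene-set overrepresentation of a mediator list, entity-level
# hypergeometric test with BH false-discovery-rate control.

#' Hypergeometric overrepresentation analysis
#'
#' For each set, tests whether the query list contains more of the set's
#' members than expected when drawing query_size genes from the universe:
#' p = P(X >= found) under Hypergeometric(universe_size, entities_total,
#' query_size). Sets are intersected with the universe first; query genes
#' absent from the universe are dropped with a warning. Rows are sorted by
#' p-value, ties broken by set name, and BH-adjusted FDR values are
#' attached.
#'
#' @param query_genes character vector of query symbols (case-insensitive).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character vector of background symbols; defaults to all
#'   genes appearing in the collection (a study-specific assay universe is
#'   preferable when available).
#' @return data.frame (set_name, description, entities_found,
#'   entities_total, universe_size, query_size, pval, fdr, mapped_members
#'   joined by ";"). Attribute "dropped_query" counts query genes outside
#'   the universe.
#' @export
hypergeomEnrich <- function(query_genes, collection, universe = NULL) {
  stopifnot(is(collection, "GeneSetCollection"))
  query <- unique(toupper(trimws(query_genes)))
  if (is.null(universe))
    universe <- sort(unique(unlist(collection@sets)))
  universe <- unique(toupper(trimws(universe)))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) absent from the universe, ",
            "dropped: ", paste(head(outside, 5), collapse = ", "))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(collection@sets), function(nm) {
    members <- intersect(collection@sets[[nm]], universe)
    hits <- intersect(query, members)
    m <- length(members)
    found <- length(hits)
    pval <- if (m == 0L) 1 else
      phyper(found - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(set_name = nm,
               description = collection@descriptions[[match(nm, names(collection@sets))]],
               entities_found = found, entities_total = m,
               universe_size = N, query_size = q, pval = pval,
               mapped_members = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhFdr(out$pval)
  out <- out[order(out$pval, out$set_name), , drop = FALSE]
  row.names(out) <- NULL
  out <- out[, c("set_name", "description", "entities_found",
                 "entities_total", "universe_size", "query_size", "pval",
                 "fdr", "mapped_members")]
  attr(out, "dropped_query") <- length(outside)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' preserving the input order.
#'
#' @param pvals numeric vector of raw p-values.
#' @return adjusted values, same order and length.
#' @export
bhFdr <- function(pvals) {
  p.adjust(pvals, method = "BH")
}
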