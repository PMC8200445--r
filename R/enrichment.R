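#' Over-representation analysis
#'
#' One-sided Fisher's exact (hypergeometric upper-tail) test of a query
#' gene list against each term of a GMT collection, BH-corrected across
#' the tested terms. Terms are intersected with the universe first; terms
#' with an empty intersection are skipped. The universe should be the
#' post-intersection analysis gene set, not the whole genome, to avoid
#' inflation from genes that were never testable.
#'
#' @param query character vector of genes (must be within `universe`).
#' @param universe character vector, the analysis gene universe.
#' @param collection a `gene_set_collection` from [read_gmt()].
#' @param config a [pipeline_config()]; `ora_alpha` sets the enrichment
#'   call threshold.
#' @return An `enrichment_result` data.frame: `term`, `description`,
#'   `overlap`, `term_size`, `query_size`, `universe_size`, `p`, `p_adj`,
#'   `enriched`, sorted by `p`.
#' @export
ora <- function(query, universe, collection, config = pipeline_config()) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes outside the universe")
  if (!length(query)) {
    warning("empty query: returning empty result")
    return(structure(data.frame(term = character(),
                                description = character(),
                                overlap = integer(), term_size = integer(),
                                query_size = integer(),
                                universe_size = integer(), p = numeric(),
                                p_adj = numeric(), enriched = logical()),
                     class = c("enrichment_result", "data.frame")))
  }
  N <- length(universe)
  nq <- length(query)
  rows <- lapply(names(collection), function(tm) {
    genes_t <- intersect(collection[[tm]]$genes, universe)
    if (!length(genes_t)) return(NULL)
    ov <- length(intersect(genes_t, query))
    p <- stats::phyper(ov - 1, length(genes_t), N - length(genes_t), nq,
                       lower.tail = FALSE)
    data.frame(term = tm, description = collection[[tm]]$description,
               overlap = ov, term_size = length(genes_t), query_size = nq,
               universe_size = N, p = p)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no term intersects the universe")
  tab$p_adj <- bh_adjust(tab$p)
  tab$enriched <- tab$p_adj < config$ora_alpha
  tab <- tab[order(tab$p), ]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_result", "data.frame")
  tab
}
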