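#' Quantile normalization
#'
#' Forces every column (array) of a log2 expression matrix onto the same
#' empirical distribution: the across-column mean of sorted values. Ties
#' within a column receive the mean of the reference values spanned by
#' their tied ranks. Delegates to [limma::normalizeQuantiles()] with
#' `ties = TRUE`, which implements exactly this convention.
#'
#' @param X numeric matrix with no missing values, genes x samples.
#' @return The normalized matrix, same dimnames and column order.
#' @export
quantile_normalize <- function(X) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (anyNA(X)) stop("missing values in matrix")
  if (ncol(X) < 2) {
    warning("single column: returned unchanged")
    return(X)
  }
  out <- limma::normalizeQuantiles(X, ties = TRUE)
  dimnames(out) <- dimnames(X)
  out
}

#' Collapse probes to genes
#'
#' Probes mapping to the same gene ID are averaged (arithmetic mean of
#' their rows); probes with no gene mapping are dropped and reported.
#' Output rows are sorted by gene ID.
#'
#' @param X probe-level matrix (rownames = probe IDs).
#' @param probe_map data frame with columns `probe_id`, `gene_id`; an
#'   empty/NA `gene_id` marks an unmapped probe.
#' @return The gene-level matrix with attribute `"unmapped"` listing
#'   dropped probes.
#' @export
collapse_probes <- function(X, probe_map) {
  stopifnot(is.matrix(X), all(c("probe_id", "gene_id") %in% names(probe_map)))
  pm <- probe_map
  pm$probe_id <- as.character(pm$probe_id)
  pm$gene_id <- as.character(pm$gene_id)
  pm <- pm[match(rownames(X), pm$probe_id), ]
  unmapped <- rownames(X)[is.na(pm$gene_id) | !nzchar(pm$gene_id) |
                            is.na(pm$probe_id)]
  keep <- setdiff(rownames(X), unmapped)
  if (!length(keep)) stop("no mapped probes left after dropping unmapped")
  Xk <- X[keep, , drop = FALSE]
  gene <- pm$gene_id[match(keep, pm$probe_id)]
  agg <- rowsum(Xk, group = gene, reorder = TRUE) /
    as.vector(table(factor(gene, levels = sort(unique(gene)))))
  attr(agg, "unmapped") <- unmapped
  agg
}

#' Intersect gene universes across datasets
#'
#' Restricts every dataset to the common set of gene IDs, in a shared
#' order, so that downstream meta-analysis and consensus networks operate
#' on one universe.
#'
#' @param datasets list of `expression_dataset`s (>= 2).
#' @return The datasets, each filtered to the identical ordered gene list.
#' @export
intersect_genes <- function(datasets) {
  stopifnot(length(datasets) >= 2)
  common <- Reduce(intersect, lapply(datasets, function(d) d$genes))
  if (!length(common)) stop("empty gene intersection")
  common <- sort(common)
  lapply(datasets, function(d) {
    d$X <- d$X[common, , drop = FALSE]
    d$genes <- common
    d
  })
}

#' Drop genes with zero variance in any dataset
#'
#' Pearson correlation (hence the co-expression stages) is undefined for a
#' constant gene, so any gene constant in at least one dataset is removed
#' from all of them.
#'
#' @param datasets list of `expression_dataset`s sharing a gene universe.
#' @return Filtered datasets with attribute `"dropped"` on the list.
#' @export
drop_zero_variance <- function(datasets) {
  bad <- unique(unlist(lapply(datasets, function(d) {
    v <- apply(d$X, 1, stats::var)
    d$genes[v <= 0 | !is.finite(v)]
  })))
  if (!length(bad)) return(datasets)
  out <- lapply(datasets, function(d) {
    keep <- setdiff(d$genes, bad)
    d$X <- d$X[keep, , drop = FALSE]
    d$genes <- keep
    d
  })
  attr(out, "dropped") <- bad
  out
}

#' Preprocess a group of datasets
#'
#' Applies the data-driven part of the published preprocessing to already
#' background-corrected inputs: optional `log2(x + 1)` transform for
#' raw-scale data, per-dataset quantile normalization, optional probe
#' collapse, cross-dataset gene intersection, and removal of zero-variance
#' genes.
#'
#' @param datasets list of `expression_dataset`s.
#' @param probe_map optional probe-to-gene map (see [collapse_probes()]).
#' @param log2_transform logical vector (recycled): apply `log2(x+1)` per
#'   dataset before normalization.
#' @param quantile logical vector (recycled): quantile-normalize per
#'   dataset (default TRUE).
#' @return The preprocessed datasets on a common gene universe.
#' @export
preprocess_group <- function(datasets, probe_map = NULL,
                             log2_transform = FALSE, quantile = TRUE) {
  log2_transform <- rep_len(log2_transform, length(datasets))
  quantile <- rep_len(quantile, length(datasets))
  datasets <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    if (log2_transform[i]) d$X <- log2(d$X + 1)
    if (quantile[i]) d$X <- quantile_normalize(d$X)
    if (!is.null(probe_map)) {
      d$X <- collapse_probes(d$X, probe_map)
      d$genes <- rownames(d$X)
    }
    d
  })
  if (length(datasets) >= 2) datasets <- intersect_genes(datasets)
  drop_zero_variance(datasets)
}
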