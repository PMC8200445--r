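#' Module membership (kME)
#'
#' For every assigned gene, the Pearson correlation between its expression
#' profile in one dataset and that dataset's eigengene of the gene's own
#' module, with a one-sided (upper-tail) correlation-test p value — one
#' sided because the networks are signed, so only positive membership is
#' meaningful.
#'
#' @param ds an `expression_dataset`.
#' @param eigengenes an `eigengene_set` containing `ds`.
#' @param partition a `module_partition`.
#' @return data.frame `gene_id`, `module`, `dataset_id`, `kME`, `p_right`.
#' @export
module_membership <- function(ds, eigengenes, partition) {
  mods <- names(eigengenes)
  n <- ncol(ds$X)
  rows <- lapply(mods, function(m) {
    genes_m <- names(partition)[partition == m]
    eg <- eigengenes[[m]][[ds$dataset_id]]$scores
    Xm <- ds$X[genes_m, names(eg), drop = FALSE]
    sds <- apply(Xm, 1, stats::sd)
    if (any(sds == 0)) {
      genes_m <- genes_m[sds > 0]
      Xm <- Xm[genes_m, , drop = FALSE]
    }
    kme <- as.vector(stats::cor(t(Xm), eg))
    t_stat <- kme * sqrt((n - 2) / pmax(1 - kme^2, .Machine$double.eps))
    p <- stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
    data.frame(gene_id = genes_m, module = m, dataset_id = ds$dataset_id,
               kME = kme, p_right = p)
  })
  do.call(rbind, rows)
}

#' Consensus module membership
#'
#' Aggregates a gene's one-sided kME p values across the group's datasets
#' with Stouffer's method into a single consensus membership Z score.
#'
#' @param kme_tables list of [module_membership()] tables (one per
#'   dataset).
#' @return data.frame `gene_id`, `module`, `Z_MM`, `n_datasets`.
#' @export
consensus_membership <- function(kme_tables) {
  all_tab <- do.call(rbind, kme_tables)
  k <- length(kme_tables)
  key <- paste(all_tab$gene_id, all_tab$module, sep = "\r")
  cnt <- table(key)
  complete <- names(cnt)[cnt == k]
  sub <- all_tab[key %in% complete, ]
  eps <- 1e-15
  p <- pmin(pmax(sub$p_right, eps), 1 - eps)
  z_by <- tapply(stats::qnorm(p, lower.tail = FALSE),
                 paste(sub$gene_id, sub$module, sep = "\r"), sum) / sqrt(k)
  parts <- strsplit(names(z_by), "\r", fixed = TRUE)
  data.frame(gene_id = vapply(parts, `[`, "", 1),
             module = vapply(parts, `[`, "", 2),
             Z_MM = as.vector(z_by),
             n_datasets = k, row.names = NULL)
}

#' Select consensus hub genes
#'
#' Within each module, genes whose consensus membership Z lies strictly
#' above the module's `hub_percentile` quantile (linear interpolation) are
#' flagged as hubs. With distinct Z values this yields the expected 15%
#' of module genes at the default percentile; ties at the threshold are
#' excluded.
#'
#' @param zmm a [consensus_membership()] table.
#' @param config a [pipeline_config()].
#' @return `zmm` with columns `threshold` and `hub`.
#' @export
select_hubs <- function(zmm, config = pipeline_config()) {
  out <- lapply(split(zmm, zmm$module), function(sub) {
    stopifnot(nrow(sub) >= 2)
    thr <- stats::quantile(sub$Z_MM, config$hub_percentile, names = FALSE,
                           type = 7)
    sub$threshold <- thr
    sub$hub <- sub$Z_MM > thr
    sub
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hub-overlap significance
#'
#' Hypergeometric upper-tail test of the overlap between two hub sets on a
#' shared gene universe (drawing `|hubsB|` genes from the universe with
#' `|hubsA|` successes).
#'
#' @param hubs_a,hubs_b character vectors of hub genes.
#' @param universe character vector, the shared module gene universe.
#' @return `list(overlap, p)`.
#' @export
hub_overlap_test <- function(hubs_a, hubs_b, universe) {
  if (!length(universe)) stop("empty universe")
  stopifnot(all(hubs_a %in% universe), all(hubs_b %in% universe))
  ov <- length(intersect(hubs_a, hubs_b))
  p <- stats::phyper(ov - 1, length(hubs_a),
                     length(universe) - length(hubs_a),
                     length(hubs_b), lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Compute the hub table for one network
#'
#' Runs kME, consensus membership and hub selection for every module of a
#' consensus network, restricted to the network's differentially regulated
#' modules if a `module_meta_table` is supplied.
#'
#' @param network a `consensus_network`.
#' @param datasets the group's `expression_dataset`s.
#' @param config a [pipeline_config()].
#' @param modules optional character vector restricting the modules
#'   scored (default: all).
#' @return A `hub_table` data.frame (see [select_hubs()]) with attribute
#'   `"kme"` holding the per-dataset kME table.
#' @export
hub_table <- function(network, datasets, config = pipeline_config(),
                      modules = NULL) {
  eg <- network$eigengenes
  if (!is.null(modules)) eg <- eg[intersect(names(eg), modules)]
  if (!length(eg))
    return(structure(data.frame(gene_id = character(), module = character(),
                                Z_MM = numeric(), n_datasets = integer(),
                                threshold = numeric(), hub = logical()),
                     class = c("hub_table", "data.frame")))
  kme <- lapply(datasets, module_membership, eigengenes = eg,
                partition = network$partition)
  zmm <- consensus_membership(kme)
  res <- select_hubs(zmm, config)
  attr(res, "kme") <- do.call(rbind, kme)
  class(res) <- c("hub_table", "data.frame")
  res
}

#' Overlay hub genes with RRHO/DE classes
#'
#' Annotates each hub with its cross-condition gene class when that class
#' is consistent with the module's differential-regulation scenario: for a
#' module up-regulated in condition A only, the matching class is
#' `unique-A-up`; for a module up in both, `common-concordant-up`; for a
#' module up in A and down in B, `common-discordant-A-up-B-down`; and the
#' sign-symmetric counterparts. Hubs whose class does not match (including
#' class `"none"`) are not annotated.
#'
#' @param hubs a `hub_table` (hub rows are considered).
#' @param gene_classes named vector from [classify_genes()].
#' @param module_scenarios named character vector module -> scenario, with
#'   scenario one of the class labels above (see
#'   [module_scenarios()]).
#' @return The hub rows with columns `gene_class`, `scenario`,
#'   `candidate`.
#' @export
overlay_hubs_rrho <- function(hubs, gene_classes, module_scenarios) {
  sub <- hubs[hubs$hub, , drop = FALSE]
  sub$gene_class <- unname(gene_classes[sub$gene_id])
  sub$gene_class[is.na(sub$gene_class)] <- "none"
  sub$scenario <- unname(module_scenarios[sub$module])
  sub$scenario[is.na(sub$scenario)] <- "none"
  sub$candidate <- sub$gene_class != "none" & sub$scenario != "none" &
    sub$gene_class == sub$scenario
  sub
}

#' Derive module regulation scenarios across two conditions
#'
#' Combines the module-level meta-analysis calls of two networks (after
#' label matching) into per-module cross-condition scenarios expressed in
#' the same vocabulary as [classify_genes()].
#'
#' @param meta_a module_meta_table of the reference (A) network.
#' @param meta_b module_meta_table of the source (B) network with labels
#'   already matched to A.
#' @return Named character vector module -> scenario.
#' @export
module_scenarios <- function(meta_a, meta_b) {
  dir_a <- stats::setNames(meta_a$direction, meta_a$module)
  dir_b <- stats::setNames(meta_b$direction, meta_b$module)
  mods <- union(names(dir_a), names(dir_b))
  da <- ifelse(mods %in% names(dir_a), dir_a[mods], "none")
  db <- ifelse(mods %in% names(dir_b), dir_b[mods], "none")
  sc <- rep("none", length(mods))
  sc[da == "up" & db == "up"] <- "common-concordant-up"
  sc[da == "down" & db == "down"] <- "common-concordant-down"
  sc[da == "up" & db == "down"] <- "common-discordant-A-up-B-down"
  sc[da == "down" & db == "up"] <- "common-discordant-A-down-B-up"
  sc[da == "up" & db == "none"] <- "unique-A-up"
  sc[da == "down" & db == "none"] <- "unique-A-down"
  sc[da == "none" & db == "up"] <- "unique-B-up"
  sc[da == "none" & db == "down"] <- "unique-B-down"
  stats::setNames(sc, mods)
}
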