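#' Run the full two-condition meta-analysis pipeline
#'
#' Executes every stage on two condition groups sharing a gene universe:
#' preprocessing (gene intersection and zero-variance filtering), per-group
#' gene-level meta-analysis, per-group consensus networks with module
#' detection and eigengene merging, module-level meta-analysis, module
#' label matching of B against the reference network A, RRHO
#' concordant/discordant gene sets, gene classification, consensus hub
#' selection restricted to differentially regulated modules, and the
#' hub-by-RRHO overlay. When `outdir` is given, every stage table and a
#' JSON run report (config, seed, per-stage summaries) are written.
#'
#' @param datasets_a,datasets_b lists of `expression_dataset`s for the two
#'   condition groups.
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for TSV tables and the run
#'   report.
#' @param preprocess quantile-normalize and re-intersect inputs first
#'   (default TRUE; set FALSE for already-normalized simulated data).
#' @return A `coexmeta_run` list: `gene_meta_a/b`, `network_a/b`,
#'   `module_meta_a/b`, `module_match`, `rrho`, `gene_classes`,
#'   `hubs_a/b`, `hub_overlap`, `overlay_a/b`, `config`.
#' @export
run_pipeline <- function(datasets_a, datasets_b,
                         config = pipeline_config(), outdir = NULL,
                         preprocess = TRUE) {
  if (preprocess) {
    datasets_a <- preprocess_group(datasets_a)
    datasets_b <- preprocess_group(datasets_b)
  }
  # shared universe across the two groups for RRHO/classification
  common <- sort(intersect(datasets_a[[1]]$genes, datasets_b[[1]]$genes))
  if (!length(common)) stop("empty gene intersection between groups")
  restrict <- function(ds) {
    ds$X <- ds$X[common, , drop = FALSE]
    ds$genes <- common
    ds
  }
  datasets_a <- lapply(datasets_a, restrict)
  datasets_b <- lapply(datasets_b, restrict)

  gm_a <- gene_meta(datasets_a, config)
  gm_b <- gene_meta(datasets_b, config)

  net_a <- consensus_network(datasets_a, config)
  net_b <- consensus_network(datasets_b, config)

  mm_a <- module_meta(net_a, datasets_a, config)
  mm_b <- module_meta(net_b, datasets_b, config)

  match <- match_labels(net_a$partition, net_b$partition)
  net_b$partition <- match$relabelled
  if (length(net_b$eigengenes)) {
    names(net_b$eigengenes) <- unname(match$relabel[names(net_b$eigengenes)])
    mm_b$module <- unname(match$relabel[mm_b$module])
    attr(mm_b, "per_dataset")$module <-
      unname(match$relabel[attr(mm_b, "per_dataset")$module])
  }

  rr <- rrho(gm_a, gm_b, config)
  classes <- classify_genes(gm_a, gm_b, rr)

  diff_a <- mm_a$module[mm_a$diff_flag]
  diff_b <- mm_b$module[mm_b$diff_flag]
  hubs_a <- hub_table(net_a, datasets_a, config, modules = diff_a)
  hubs_b <- hub_table(net_b, datasets_b, config, modules = diff_b)

  scen <- module_scenarios(mm_a, mm_b)
  overlay_a <- overlay_hubs_rrho(hubs_a, classes, scen)
  overlay_b <- overlay_hubs_rrho(hubs_b, classes, scen)

  shared_mods <- intersect(diff_a, diff_b)
  hub_overlap <- lapply(shared_mods, function(m) {
    ha <- hubs_a$gene_id[hubs_a$hub & hubs_a$module == m]
    hb <- hubs_b$gene_id[hubs_b$hub & hubs_b$module == m]
    uni <- union(names(net_a$partition)[net_a$partition == m],
                 names(net_b$partition)[net_b$partition == m])
    ht <- hub_overlap_test(ha, hb, uni)
    data.frame(module = m, hubs_a = length(ha), hubs_b = length(hb),
               universe = length(uni), overlap = ht$overlap, p = ht$p)
  })
  hub_overlap <- if (length(hub_overlap)) do.call(rbind, hub_overlap) else
    data.frame(module = character(), hubs_a = integer(), hubs_b = integer(),
               universe = integer(), overlap = integer(), p = numeric())

  run <- structure(list(gene_meta_a = gm_a, gene_meta_b = gm_b,
                        network_a = net_a, network_b = net_b,
                        module_meta_a = mm_a, module_meta_b = mm_b,
                        module_match = match, rrho = rr,
                        gene_classes = classes,
                        hubs_a = hubs_a, hubs_b = hubs_b,
                        hub_overlap = hub_overlap,
                        overlay_a = overlay_a, overlay_b = overlay_b,
                        config = config),
                   class = "coexmeta_run")
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_tsv(as.data.frame(df),
                                    file.path(outdir, name))
  w(run$gene_meta_a, "gene_meta_A.tsv")
  w(run$gene_meta_b, "gene_meta_B.tsv")
  part <- function(net) data.frame(gene_id = names(net$partition),
                                   module = as.character(net$partition))
  w(part(run$network_a), "module_assignment_A.tsv")
  w(part(run$network_b), "module_assignment_B.tsv")
  w(run$module_meta_a, "module_meta_A.tsv")
  w(run$module_meta_b, "module_meta_B.tsv")
  w(run$rrho$grid, "rrho_grid.tsv")
  opt <- do.call(rbind, lapply(names(run$rrho$optima), function(q) {
    o <- run$rrho$optima[[q]]
    if (!length(o$genes)) return(NULL)
    data.frame(quadrant = q, i = o$i, j = o$j, neglog10p = o$neglog10p,
               gene_id = o$genes)
  }))
  if (!is.null(opt)) w(opt, "optimal_sets.tsv")
  w(data.frame(gene_id = names(run$gene_classes),
               class = unname(run$gene_classes)), "gene_classes.tsv")
  mm <- run$module_match
  w(data.frame(source = names(mm$relabel), new_label = unname(mm$relabel)),
    "module_match.tsv")
  w(run$hubs_a, "hub_table_A.tsv")
  w(run$hubs_b, "hub_table_B.tsv")
  w(run$hub_overlap, "hub_overlap.tsv")
  report <- list(
    config = unclass(run$config),
    betas = list(A = run$network_a$betas, B = run$network_b$betas),
    calibration_scale_factors = list(A = run$network_a$scale_factors,
                                     B = run$network_b$scale_factors),
    n_modules = list(A = length(attr(run$network_a$partition, "sizes")),
                     B = length(attr(run$network_b$partition, "sizes"))),
    n_de = list(A = sum(run$gene_meta_a$de_flag),
                B = sum(run$gene_meta_b$de_flag)),
    n_diff_modules = list(A = sum(run$module_meta_a$diff_flag),
                          B = sum(run$module_meta_b$diff_flag)),
    n_hubs = list(A = sum(run$hubs_a$hub), B = sum(run$hubs_b$hub)))
  write_run_report(report, file.path(outdir, "run_report.json"))
  invisible(outdir)
}

#' @export
print.coexmeta_run <- function(x, ...) {
  cat("coexmeta two-condition meta-analysis run\n")
  cat(sprintf("  genes analysed: %d\n", nrow(x$gene_meta_a)))
  cat(sprintf("  DE genes: A %d (%d up / %d down), B %d (%d up / %d down)\n",
              sum(x$gene_meta_a$de_flag),
              sum(x$gene_meta_a$direction == "up"),
              sum(x$gene_meta_a$direction == "down"),
              sum(x$gene_meta_b$de_flag),
              sum(x$gene_meta_b$direction == "up"),
              sum(x$gene_meta_b$direction == "down")))
  cat(sprintf("  consensus modules: A %d, B %d (differential: A %d, B %d)\n",
              length(attr(x$network_a$partition, "sizes")),
              length(attr(x$network_b$partition, "sizes")),
              sum(x$module_meta_a$diff_flag), sum(x$module_meta_b$diff_flag)))
  cat(sprintf("  consensus hubs (differential modules): A %d, B %d\n",
              sum(x$hubs_a$hub), sum(x$hubs_b$hub)))
  invisible(x)
}
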