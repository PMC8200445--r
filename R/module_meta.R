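#' Per-dataset eigengene differential regulation
#'
#' Within each dataset, module eigengene scores are standardized to unit
#' variance and reduced to per-subject (post - pre) differences; a
#' classical one-sample paired t-test gives a right-tailed p value per
#' (module, dataset). The eigengene is a single series per module, so
#' there is no variance ensemble to moderate over and the ordinary t-test
#' is used.
#'
#' @param eigengenes an `eigengene_set`.
#' @param datasets the matching list of `expression_dataset`s.
#' @return data.frame with `module`, `dataset_id`, `delta` (mean paired
#'   difference in SD units), `t`, `p_right`, `n_pairs`.
#' @export
eigengene_paired_stats <- function(eigengenes, datasets) {
  res <- list()
  for (m in names(eigengenes)) {
    for (ds in datasets) {
      eg <- eigengenes[[m]][[ds$dataset_id]]$scores
      s <- ds$samples
      if (length(unique(s$subject_id)) < 3)
        stop("fewer than 3 subjects in dataset ", ds$dataset_id)
      eg <- eg / stats::sd(eg)
      subjects <- unique(s$subject_id)
      key <- paste0(s$subject_id, ".", s$timepoint)
      pre <- eg[s$sample_id[match(paste0(subjects, ".pre"), key)]]
      post <- eg[s$sample_id[match(paste0(subjects, ".post"), key)]]
      d <- post - pre
      n <- length(d)
      delta <- mean(d)
      sd_d <- stats::sd(d)
      t_stat <- if (sd_d > 0) delta / (sd_d / sqrt(n)) else
        ifelse(delta == 0, 0, sign(delta) * Inf)
      p_right <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
      res[[length(res) + 1]] <- data.frame(
        module = m, dataset_id = ds$dataset_id, delta = delta,
        t = t_stat, p_right = p_right, n_pairs = n)
    }
  }
  do.call(rbind, res)
}

#' Module-level meta-analysis call
#'
#' Mirrors the gene-level procedure at eigengene scale: Stouffer
#' combination of right-tailed per-dataset p values, two-sided meta p,
#' BH correction across the network's modules, and a three-part
#' differential-regulation call — q at most `alpha_meta`, absolute meta
#' mean eigengene change above `lfc_min` (in per-dataset SD units), and a
#' common direction of eigengene change across all datasets.
#'
#' @param stats_df output of [eigengene_paired_stats()].
#' @param config a [pipeline_config()].
#' @return A `module_meta_table`: one row per module with `Z`, `p_meta`,
#'   `q`, `mean_delta`, `common_direction`, `direction`, `diff_flag`.
#' @export
module_meta_call <- function(stats_df, config = pipeline_config()) {
  mods <- sort(unique(stats_df$module))
  rows <- lapply(mods, function(m) {
    sub <- stats_df[stats_df$module == m, ]
    st <- stouffer_combine(sub$p_right)
    s <- sign(sub$delta)
    data.frame(module = m,
               Z = st$Z,
               p_meta = 2 * stats::pnorm(abs(st$Z), lower.tail = FALSE),
               mean_delta = mean(sub$delta),
               common_direction = all(s == s[1]) && s[1] != 0)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p_meta)
  tab$diff_flag <- tab$q <= config$alpha_meta &
    abs(tab$mean_delta) > config$lfc_min &
    tab$common_direction
  tab$direction <- ifelse(!tab$diff_flag, "none",
                          ifelse(tab$mean_delta > 0, "up", "down"))
  class(tab) <- c("module_meta_table", "data.frame")
  tab
}

#' Module-level meta-analysis for a consensus network
#'
#' Convenience driver combining [eigengene_paired_stats()] and
#' [module_meta_call()].
#'
#' @param network a `consensus_network`.
#' @param datasets the group's `expression_dataset`s.
#' @param config a [pipeline_config()].
#' @return A `module_meta_table` with attribute `"per_dataset"`.
#' @export
module_meta <- function(network, datasets, config = pipeline_config()) {
  if (!length(network$eigengenes))
    return(structure(data.frame(module = character(), Z = numeric(),
                                p_meta = numeric(), mean_delta = numeric(),
                                common_direction = logical(), q = numeric(),
                                diff_flag = logical(),
                                direction = character()),
                     class = c("module_meta_table", "data.frame")))
  per_ds <- eigengene_paired_stats(network$eigengenes, datasets)
  tab <- module_meta_call(per_ds, config)
  attr(tab, "per_dataset") <- per_ds
  tab
}
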