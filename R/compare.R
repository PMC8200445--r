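#' Match module labels between two networks
#'
#' Compares module gene compositions between a reference and a source
#' partition with one-sided Fisher's exact (hypergeometric) tests on every
#' (reference, source) module pair, BH-corrects across all cells, and
#' greedily relabels source modules in ascending corrected p among
#' significant cells so that no two source modules take the same reference
#' label. Unmatched source modules receive fresh labels that do not occur
#' in the reference network.
#'
#' @param reference,source `module_partition`s over the same gene universe.
#' @param alpha BH threshold for a significant overlap (default 0.05).
#' @return A `module_match` list: `overlap` count table, `p` and `p_adj`
#'   matrices, `relabel` map (source -> new label), `unmatched` source
#'   labels, and `relabelled` partition of the source network.
#' @export
match_labels <- function(reference, source, alpha = 0.05) {
  if (!setequal(names(reference), names(source)))
    stop("reference and source partitions cover different gene universes")
  source <- source[names(reference)]
  ref_mods <- setdiff(sort(unique(as.character(reference))), "M0")
  src_mods <- setdiff(sort(unique(as.character(source))), "M0")
  N <- length(reference)
  ov <- p <- matrix(NA_real_, length(ref_mods), length(src_mods),
                    dimnames = list(ref_mods, src_mods))
  for (r in ref_mods) {
    in_r <- reference == r
    for (s in src_mods) {
      in_s <- source == s
      n11 <- sum(in_r & in_s)
      ov[r, s] <- n11
      p[r, s] <- stats::phyper(n11 - 1, sum(in_r), N - sum(in_r),
                               sum(in_s), lower.tail = FALSE)
    }
  }
  p_adj <- matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p),
                  dimnames = dimnames(p))
  cells <- which(p_adj < alpha, arr.ind = TRUE)
  relabel <- stats::setNames(character(0), character(0))
  if (nrow(cells)) {
    ord <- order(p_adj[cells])
    used_ref <- used_src <- character(0)
    for (i in ord) {
      r <- ref_mods[cells[i, 1]]
      s <- src_mods[cells[i, 2]]
      if (r %in% used_ref || s %in% used_src) next
      relabel[s] <- r
      used_ref <- c(used_ref, r)
      used_src <- c(used_src, s)
    }
  }
  unmatched <- setdiff(src_mods, names(relabel))
  if (length(unmatched)) {
    taken <- c(ref_mods, unname(relabel))
    fresh <- paste0("M", seq_len(length(taken) + length(unmatched) + 1))
    fresh <- setdiff(fresh, taken)[seq_along(unmatched)]
    relabel[unmatched] <- fresh
  }
  relabelled <- as.character(source)
  names(relabelled) <- names(source)
  keep <- relabelled != "M0"
  relabelled[keep] <- relabel[relabelled[keep]]
  attr(relabelled, "sizes") <- table(relabelled[keep])
  class(relabelled) <- "module_partition"
  list(overlap = ov, p = p, p_adj = p_adj, relabel = relabel,
       unmatched = unmatched, relabelled = relabelled)
}

#' Rank-rank hypergeometric overlap
#'
#' Ranks each condition's genes by the signed significance score
#' `sign(meta logFC) * (-log10 q)` and scans a grid of rank-threshold
#' pairs; at each grid point the hypergeometric upper-tail p value of the
#' overlap between the two rank prefixes is recorded as `-log10 p`. Four
#' quadrants are computed: up-up and down-down (concordant; top of both
#' lists / bottom of both lists) and up-down / down-up (discordant; top of
#' one against bottom of the other). Per quadrant the maximizing grid
#' point and its overlap gene set are returned; the maximum is searched
#' within the sign-consistent region of each ranked list (thresholds up to
#' the last positively-scored gene for an "up" axis and vice versa), since
#' beyond that point the hypergeometric complement symmetry merely mirrors
#' the opposite quadrant's signal.
#'
#' @param table_a,table_b `gene_meta_table`s over the same gene universe.
#' @param config a [pipeline_config()]; the grid step is
#'   `max(1, round(rrho_step_fraction * N))`.
#' @return An `rrho_result`: `scores` (per-condition signed scores),
#'   `step`, `grid` (long data.frame: quadrant, i, j, overlap,
#'   neglog10p), and `optima` (per quadrant: i, j, neglog10p, genes).
#' @export
rrho <- function(table_a, table_b, config = pipeline_config()) {
  genes <- table_a$gene_id
  if (!setequal(genes, table_b$gene_id))
    stop("gene universes differ between the two tables")
  N <- length(genes)
  if (N < 10) stop("need at least 10 genes for RRHO")
  table_b <- table_b[match(genes, table_b$gene_id), ]
  score <- function(tab)
    sign(tab$mean_logFC) * (-log10(pmax(tab$q, 1e-300)))
  sa <- stats::setNames(score(table_a), genes)
  sb <- stats::setNames(score(table_b), genes)
  s <- max(1L, as.integer(round(config$rrho_step_fraction * N)))
  n_steps <- N %/% s
  # rank 1 = strongest; ties broken by gene ID (lexicographic)
  rank_desc <- function(x) {
    ord <- order(-x, names(x))
    r <- integer(length(x))
    r[ord] <- seq_along(ord)
    stats::setNames(r, names(x))
  }
  ra_top <- rank_desc(sa)
  rb_top <- rank_desc(sb)
  ra_bot <- rank_desc(-sa)   # rank 1 = most negative score
  rb_bot <- rank_desc(-sb)

  quadrant <- function(ra, rb, max_i, max_j) {
    bin_a <- (ra + s - 1L) %/% s
    bin_b <- (rb + s - 1L) %/% s
    # genes beyond the last full grid step never enter a prefix
    keep <- bin_a <= n_steps & bin_b <= n_steps
    tab <- table(factor(bin_a[keep], levels = 1:n_steps),
                 factor(bin_b[keep], levels = 1:n_steps))
    cnt <- matrix(as.integer(tab), n_steps, n_steps)
    cum <- apply(apply(cnt, 2, cumsum), 1, cumsum)  # cum[j,i] after t()
    cum <- t(cum)
    ii <- matrix(seq_len(n_steps) * s, n_steps, n_steps)
    jj <- t(ii)
    p <- stats::phyper(cum - 1, ii, N - ii, jj, lower.tail = FALSE)
    neglog <- -log10(pmax(p, 1e-320))
    # the optimum is searched only within the sign-consistent part of each
    # ranked list: a top-list overlap at thresholds beyond the last
    # same-signed gene is the mirror image of the opposite quadrant's
    # signal (hypergeometric complement symmetry), not a signal here
    masked <- neglog
    masked[ii > max_i | jj > max_j] <- -Inf
    if (all(masked == -Inf)) {
      optimum <- list(i = 0L, j = 0L, neglog10p = 0,
                      genes = character(0))
    } else {
      best <- which.max(masked)
      bi <- ((best - 1) %% n_steps) + 1
      bj <- ((best - 1) %/% n_steps) + 1
      genes_i <- names(ra)[ra <= bi * s]
      genes_j <- names(rb)[rb <= bj * s]
      optimum <- list(i = bi * s, j = bj * s,
                      neglog10p = neglog[bi, bj],
                      genes = sort(intersect(genes_i, genes_j)))
    }
    list(grid = data.frame(i = as.vector(ii), j = as.vector(jj),
                           overlap = as.vector(cum),
                           neglog10p = as.vector(neglog)),
         optimum = optimum)
  }

  n_pos_a <- sum(sa > 0); n_neg_a <- sum(sa < 0)
  n_pos_b <- sum(sb > 0); n_neg_b <- sum(sb < 0)
  quads <- list(
    `up-up` = quadrant(ra_top, rb_top, n_pos_a, n_pos_b),
    `down-down` = quadrant(ra_bot, rb_bot, n_neg_a, n_neg_b),
    `up-down` = quadrant(ra_top, rb_bot, n_pos_a, n_neg_b),
    `down-up` = quadrant(ra_bot, rb_top, n_neg_a, n_pos_b))
  grid <- do.call(rbind, lapply(names(quads), function(q) {
    g <- quads[[q]]$grid
    g$quadrant <- q
    g[, c("quadrant", "i", "j", "overlap", "neglog10p")]
  }))
  structure(list(scores = data.frame(gene_id = genes, score_a = unname(sa),
                                     score_b = unname(sb)),
                 step = s,
                 grid = grid,
                 optima = lapply(quads, `[[`, "optimum")),
            class = "rrho_result")
}

#' Classify genes by cross-condition regulation
#'
#' Applies the published definitions: commonly regulated genes are
#' significantly DE in both conditions and present within the relevant
#' optimal overlap set; uniquely regulated genes are significantly DE in
#' one condition only and absent from every optimal overlap set. All
#' remaining genes are labelled `"none"`.
#'
#' @param table_a,table_b `gene_meta_table`s.
#' @param rrho_result an [rrho()] result.
#' @return Named character vector gene -> class, levels:
#'   `common-concordant-up`, `common-concordant-down`,
#'   `common-discordant-A-up-B-down`, `common-discordant-A-down-B-up`,
#'   `unique-A-up`, `unique-A-down`, `unique-B-up`, `unique-B-down`,
#'   `none`.
#' @export
classify_genes <- function(table_a, table_b, rrho_result) {
  genes <- table_a$gene_id
  table_b <- table_b[match(genes, table_b$gene_id), ]
  opt <- rrho_result$optima
  in_set <- function(q) genes %in% opt[[q]]$genes
  in_any <- in_set("up-up") | in_set("down-down") |
    in_set("up-down") | in_set("down-up")
  a_up <- table_a$de_flag & table_a$direction == "up"
  a_down <- table_a$de_flag & table_a$direction == "down"
  b_up <- table_b$de_flag & table_b$direction == "up"
  b_down <- table_b$de_flag & table_b$direction == "down"
  cls <- rep("none", length(genes))
  cls[a_up & b_up & in_set("up-up")] <- "common-concordant-up"
  cls[a_down & b_down & in_set("down-down")] <- "common-concordant-down"
  cls[a_up & b_down & in_set("up-down")] <- "common-discordant-A-up-B-down"
  cls[a_down & b_up & in_set("down-up")] <- "common-discordant-A-down-B-up"
  de_a_only <- table_a$de_flag & !table_b$de_flag
  de_b_only <- table_b$de_flag & !table_a$de_flag
  cls[de_a_only & a_up & !in_any] <- "unique-A-up"
  cls[de_a_only & a_down & !in_any] <- "unique-A-down"
  cls[de_b_only & b_up & !in_any] <- "unique-B-up"
  cls[de_b_only & b_down & !in_any] <- "unique-B-down"
  stats::setNames(cls, genes)
}
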