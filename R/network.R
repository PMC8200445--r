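#' Signed weighted adjacency
#'
#' `Adj_ij = (0.5 (1 + cor(x_i, x_j)))^beta`: a signed network in which
#' strong negative correlation maps to adjacency near 0 and strong positive
#' correlation to adjacency near 1, sharpened by the soft-threshold
#' exponent `beta`.
#'
#' @param X genes x samples matrix (>= 3 samples, no constant genes).
#' @param beta positive soft-threshold exponent.
#' @return Symmetric adjacency matrix with unit diagonal, entries in [0,1],
#'   attribute `"beta"`.
#' @export
signed_adjacency <- function(X, beta) {
  stopifnot(is.matrix(X), ncol(X) >= 3, beta >= 1)
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene: ",
         paste(rownames(X)[sds == 0], collapse = ", "))
  C <- stats::cor(t(X))
  A <- (0.5 * (1 + C))^beta
  diag(A) <- 1
  attr(A, "beta") <- beta
  A
}

#' Scale-free topology fit
#'
#' Connectivities `k_i = sum_{j != i} Adj_ij` are binned into `n_bins`
#' equal-width bins; the fit index is the R-squared of the regression of
#' `log10(frequency)` on `log10(mean k)` over non-empty bins. The slope is
#' returned as an attribute (scale-free topology requires it negative).
#'
#' @param A adjacency matrix (unit diagonal).
#' @param n_bins number of connectivity bins (default 10).
#' @return R-squared in [0,1] with attribute `"slope"`; 0 if all
#'   connectivities are equal.
#' @export
scale_free_fit <- function(A, n_bins = 10L) {
  k <- rowSums(A) - diag(A)
  if (max(k) - min(k) < .Machine$double.eps^0.5 * max(1, max(abs(k)))) {
    out <- 0
    attr(out, "slope") <- 0
    return(out)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  kmean <- tapply(k, bin, mean)
  keep <- freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(keep) < 2) {
    out <- 0
    attr(out, "slope") <- 0
    return(out)
  }
  x <- log10(kmean[keep])
  y <- log10(freq[keep] / length(k))
  fit <- stats::lm(y ~ x)
  out <- summary(fit)$r.squared
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  out
}

#' Select the soft-threshold exponent
#'
#' Scans integer exponents `1..beta_max` and returns the lowest one whose
#' scale-free fit reaches `scale_free_r2_min` with a negative log-log
#' slope. If no exponent qualifies (e.g. pure noise), returns the argmax of
#' the fit index with a warning flag.
#'
#' @param X genes x samples matrix.
#' @param config a [pipeline_config()].
#' @return `list(beta, fit_table, reached)`; `fit_table` has one row per
#'   candidate exponent with `r2` and `slope`.
#' @export
pick_beta <- function(X, config = pipeline_config()) {
  if (nrow(X) < 100)
    warning("fewer than 100 genes: scale-free fit is unstable")
  B <- 0.5 * (1 + stats::cor(t(X)))
  diag(B) <- 1
  betas <- seq_len(config$beta_max)
  r2 <- slope <- numeric(length(betas))
  for (i in seq_along(betas)) {
    A <- B^betas[i]
    diag(A) <- 1
    f <- scale_free_fit(A)
    r2[i] <- f
    slope[i] <- attr(f, "slope")
  }
  ok <- r2 >= config$scale_free_r2_min & slope < 0
  if (any(ok)) {
    beta <- betas[which(ok)[1]]
    reached <- TRUE
  } else {
    beta <- betas[which.max(r2)]
    reached <- FALSE
    warning("no exponent reached the scale-free fit threshold; ",
            "using argmax beta = ", beta)
  }
  list(beta = beta,
       fit_table = data.frame(beta = betas, r2 = r2, slope = slope),
       reached = reached)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + Adj_ij) / (min(k_i, k_j) + 1 - Adj_ij)` where
#' `l_ij = sum_{u != i,j} Adj_iu Adj_uj` counts shared neighbours and
#' `k_i` is connectivity; `TOM_ii = 1`. High overlap marks gene pairs that
#' are strongly connected to the same part of the network, not merely to
#' each other.
#'
#' @param A adjacency matrix (unit diagonal).
#' @return TOM, symmetric with unit diagonal, entries in [0,1].
#' @export
tom <- function(A) {
  A0 <- A
  diag(A0) <- 0
  L <- A0 %*% A0
  k <- rowSums(A0)
  kmin <- outer(k, k, pmin)
  TOM <- (L + A0) / (kmin + 1 - A0)
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Calibrate TOMs by single-quantile scaling
#'
#' Makes per-dataset TOMs comparable before taking the consensus: the
#' first TOM is the reference, and each other TOM is multiplied by the
#' ratio of the reference's off-diagonal `calibration_quantile` to its
#' own, then clipped to [0,1].
#'
#' @param toms list of >= 2 TOMs of identical shape.
#' @param calibration_quantile the quantile matched across TOMs.
#' @return List of calibrated TOMs with attribute `"scale_factors"`.
#' @export
calibrate_toms <- function(toms, calibration_quantile = 0.95) {
  stopifnot(length(toms) >= 2)
  off <- upper.tri(toms[[1]])
  qs <- vapply(toms, function(M) stats::quantile(M[off], calibration_quantile,
                                                 names = FALSE), 0)
  if (any(qs <= 0)) stop("zero calibration quantile in a TOM")
  fac <- qs[1] / qs
  out <- lapply(seq_along(toms), function(i) {
    M <- pmin(pmax(toms[[i]] * fac[i], 0), 1)
    diag(M) <- 1
    M
  })
  attr(out, "scale_factors") <- fac
  out
}

#' Consensus TOM
#'
#' Component-wise ("parallel") minimum of the calibrated TOMs: an edge is
#' only as strong as it is in its weakest dataset, so consensus modules
#' reflect co-expression reproduced in every dataset of the group.
#'
#' @param calibrated list of calibrated TOMs.
#' @return `list(cTOM, disTOM)` with `disTOM = 1 - cTOM` (zero diagonal).
#' @export
consensus_tom <- function(calibrated) {
  cTOM <- Reduce(pmin, calibrated)
  disTOM <- 1 - cTOM
  diag(disTOM) <- 0
  list(cTOM = cTOM, disTOM = disTOM)
}

#' Detect consensus modules
#'
#' Average-linkage hierarchical clustering of the consensus dissimilarity,
#' followed by a deterministic adaptive tree cut. A static cut at
#' `cut_fraction` of the maximum merge height defines candidate branches;
#' each branch is then recursively refined at its single largest internal
#' merge-height gap, accepting a split only when it retains a core
#' subcluster of at least `min_module_size` genes — this peels loosely
#' attached genes off a tight module core while refusing to tear apart a
#' homogeneous branch (whose largest gaps sit among its first, tightest
#' merges). If the static cut yields no module at all — which happens when
#' high soft-threshold exponents compress all dissimilarities into a
#' narrow band just below 1 — the cut is retried at `cut_fraction` of the
#' merge-height *range* above the minimum. Clusters below
#' `min_module_size` are discarded to the unassigned label "M0"; modules
#' are labelled "M1", "M2", ... in decreasing size order. Modules that
#' this cut splits too finely are re-joined downstream by the
#' eigengene-correlation merge step.
#'
#' @param disTOM consensus dissimilarity matrix (zero diagonal).
#' @param config a [pipeline_config()].
#' @param cut_fraction static cut height as a fraction of the maximum
#'   merge height (default 0.99).
#' @return A `module_partition`: named character vector gene -> label,
#'   with attributes `"sizes"` and `"dendrogram"` (the hclust object).
#' @export
detect_modules <- function(disTOM, config = pipeline_config(),
                           cut_fraction = 0.99) {
  genes <- rownames(disTOM)
  hc <- stats::hclust(stats::as.dist(disTOM), method = "average")
  # tied merges can leave float-level height inversions that cutree rejects
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  n <- length(hc$order)

  # representative leaf per merge node: clusters produced by height cuts are
  # subtrees, so a merge below the cluster's cut height is internal to the
  # cluster iff its representative leaf belongs to it
  node_rep <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m1 <- hc$merge[i, 1]
    node_rep[i] <- if (m1 < 0) -m1 else node_rep[m1]
  }

  split_rec <- function(members, cut_h) {
    if (length(members) < config$min_module_size + 1L)
      return(list(members))
    in_members <- logical(n)
    in_members[members] <- TRUE
    hts <- sort(hc$height[in_members[node_rep] & hc$height <= cut_h])
    if (length(hts) < 2) return(list(members))
    d <- diff(hts)
    j <- which.max(d)
    new_h <- (hts[j] + hts[j + 1]) / 2
    cl <- stats::cutree(hc, h = new_h)
    sub <- split(members, cl[members])
    sizes <- vapply(sub, length, 0L)
    if (length(sub) < 2 || max(sizes) < config$min_module_size)
      return(list(members))
    keep <- sub[sizes >= config$min_module_size]
    small <- sub[sizes < config$min_module_size]
    c(unlist(lapply(keep, split_rec, cut_h = new_h),
             recursive = FALSE, use.names = FALSE), small)
  }

  try_cut <- function(h0) {
    cl0 <- stats::cutree(hc, h = h0)
    clusters <- split(seq_len(n), cl0)
    clusters <- unlist(lapply(clusters, split_rec, cut_h = h0),
                       recursive = FALSE, use.names = FALSE)
    clusters[vapply(clusters, length, 0L) >= config$min_module_size]
  }
  clusters <- try_cut(cut_fraction * max(hc$height))
  if (!length(clusters))
    clusters <- try_cut(min(hc$height) +
                          cut_fraction * diff(range(hc$height)))

  labels <- rep("M0", n)
  if (length(clusters)) {
    ord <- order(vapply(clusters, length, 0L), decreasing = TRUE)
    for (i in seq_along(ord))
      labels[clusters[[ord[i]]]] <- paste0("M", i)
  } else {
    warning("no module of size >= ", config$min_module_size, " found")
  }
  partition <- stats::setNames(labels, genes)
  attr(partition, "sizes") <- table(partition[partition != "M0"])
  attr(partition, "dendrogram") <- hc
  class(partition) <- "module_partition"
  partition
}

#' Module eigengenes
#'
#' For each (module, dataset): genes are standardized across samples and
#' the eigengene is the first right-singular vector of the standardized
#' module submatrix (one unit-norm score per sample), oriented to
#' correlate positively with the module's mean expression profile. The
#' fraction of variance explained is recorded.
#'
#' @param partition a `module_partition`.
#' @param datasets list of `expression_dataset`s containing the module
#'   genes.
#' @return An `eigengene_set`: nested list `[[module]][[dataset_id]]` of
#'   `list(scores, var_explained)`.
#' @export
module_eigengenes <- function(partition, datasets) {
  mods <- setdiff(sort(unique(as.character(partition))), "M0")
  out <- list()
  for (m in mods) {
    genes_m <- names(partition)[partition == m]
    if (length(genes_m) < 2) stop("module ", m, " has fewer than 2 genes")
    out[[m]] <- list()
    for (ds in datasets) {
      Z <- t(scale(t(ds$X[genes_m, , drop = FALSE])))
      sv <- svd(Z, nu = 0, nv = 1)
      eg <- sv$v[, 1]
      if (stats::cor(eg, colMeans(Z)) < 0) eg <- -eg
      out[[m]][[ds$dataset_id]] <- list(
        scores = stats::setNames(eg, colnames(ds$X)),
        var_explained = sv$d[1]^2 / sum(sv$d^2))
    }
  }
  class(out) <- "eigengene_set"
  out
}

#' Merge highly correlated modules
#'
#' Iteratively merges the module pair whose minimum across-dataset
#' eigengene correlation is highest, provided it exceeds `merge_cor_min`;
#' eigengenes are recomputed after each merge until no pair qualifies.
#' Final labels are reassigned by decreasing size.
#'
#' @param partition a `module_partition`.
#' @param datasets list of `expression_dataset`s.
#' @param config a [pipeline_config()].
#' @return `list(partition, eigengenes, merge_history)`.
#' @export
merge_modules <- function(partition, datasets, config = pipeline_config()) {
  part <- as.character(partition)
  names(part) <- names(partition)
  history <- list()
  repeat {
    mods <- setdiff(sort(unique(part)), "M0")
    if (length(mods) < 2) break
    p_tmp <- structure(part, class = "module_partition")
    eg <- module_eigengenes(p_tmp, datasets)
    best <- NULL
    best_cor <- config$merge_cor_min
    for (i in seq_along(mods)) {
      for (j in seq_len(i - 1L)) {
        cors <- vapply(datasets, function(ds) {
          stats::cor(eg[[mods[i]]][[ds$dataset_id]]$scores,
                     eg[[mods[j]]][[ds$dataset_id]]$scores)
        }, 0)
        mc <- min(cors)
        if (mc > best_cor) {
          best_cor <- mc
          best <- c(mods[j], mods[i])
        }
      }
    }
    if (is.null(best)) break
    part[part == best[2]] <- best[1]
    history[[length(history) + 1]] <- list(merged = best, min_cor = best_cor)
  }
  # relabel by size, descending
  mods <- setdiff(unique(part), "M0")
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(part == m), 0L)
    relab <- stats::setNames(paste0("M", seq_along(mods)),
                             mods[order(sizes, decreasing = TRUE)])
    part[part != "M0"] <- relab[part[part != "M0"]]
  }
  partition_out <- structure(part, class = "module_partition",
                             sizes = table(part[part != "M0"]))
  eigengenes <- if (length(mods)) module_eigengenes(partition_out, datasets)
                else structure(list(), class = "eigengene_set")
  list(partition = partition_out, eigengenes = eigengenes,
       merge_history = history)
}

#' Build a consensus co-expression network
#'
#' End-to-end network stage for one condition group: per-dataset
#' soft-threshold selection, signed adjacency, TOM, single-quantile
#' calibration, parallel-minimum consensus, average-linkage module
#' detection, eigengenes, and eigengene-correlation merging.
#'
#' @param datasets list of `expression_dataset`s on a shared gene
#'   universe (>= 2).
#' @param config a [pipeline_config()].
#' @param beta optional integer vector of exponents to use per dataset
#'   (skips the scale-free scan).
#' @param keep_toms keep the consensus TOM in the result (memory-heavy for
#'   large gene sets; default FALSE).
#' @return A `consensus_network`: list with `partition`, `eigengenes`,
#'   `betas`, `beta_tables`, `scale_factors`, `merge_history`,
#'   `dataset_ids`, and optionally `cTOM`.
#' @export
consensus_network <- function(datasets, config = pipeline_config(),
                              beta = NULL, keep_toms = FALSE) {
  stopifnot(length(datasets) >= 2)
  genes <- datasets[[1]]$genes
  for (d in datasets) stopifnot(identical(d$genes, genes))
  k <- length(datasets)
  betas <- integer(k)
  beta_tables <- vector("list", k)
  toms <- vector("list", k)
  for (i in seq_len(k)) {
    X <- datasets[[i]]$X
    if (is.null(beta)) {
      pb <- pick_beta(X, config)
      betas[i] <- pb$beta
      beta_tables[[i]] <- pb$fit_table
    } else {
      betas[i] <- rep_len(as.integer(beta), k)[i]
    }
    A <- signed_adjacency(X, betas[i])
    toms[[i]] <- tom(A)
    rm(A)
  }
  calibrated <- calibrate_toms(toms, config$calibration_quantile)
  sf <- attr(calibrated, "scale_factors")
  rm(toms)
  cons <- consensus_tom(calibrated)
  rm(calibrated)
  partition0 <- detect_modules(cons$disTOM, config)
  merged <- merge_modules(partition0, datasets, config)
  out <- list(partition = merged$partition,
              eigengenes = merged$eigengenes,
              betas = betas,
              beta_tables = beta_tables,
              scale_factors = sf,
              merge_history = merged$merge_history,
              dataset_ids = vapply(datasets, `[[`, "", "dataset_id"))
  if (keep_toms) out$cTOM <- cons$cTOM
  class(out) <- "consensus_network"
  out
}

#' @export
print.consensus_network <- function(x, ...) {
  sizes <- attr(x$partition, "sizes")
  cat(sprintf("consensus_network: %d datasets (beta = %s), %d modules\n",
              length(x$dataset_ids), paste(x$betas, collapse = "/"),
              length(sizes)))
  if (length(sizes)) {
    s <- sort(as.integer(sizes), decreasing = TRUE)
    cat(sprintf("  module sizes: mean %.0f, range %d-%d\n",
                mean(s), min(s), max(s)))
  }
  invisible(x)
}
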