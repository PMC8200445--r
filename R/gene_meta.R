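#' Paired post-minus-pre differences
#'
#' Reduces a paired pre/post dataset to one column of log2 differences per
#' subject, the algebraic equivalent of the paired contrast.
#'
#' @param ds an `expression_dataset`.
#' @return genes x subjects matrix of (post - pre) differences.
#' @export
paired_differences <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  s <- ds$samples
  subjects <- unique(s$subject_id)
  pre <- s$sample_id[match(paste0(subjects, ".pre"),
                           paste0(s$subject_id, ".", s$timepoint))]
  post <- s$sample_id[match(paste0(subjects, ".post"),
                            paste0(s$subject_id, ".", s$timepoint))]
  D <- ds$X[, post, drop = FALSE] - ds$X[, pre, drop = FALSE]
  colnames(D) <- subjects
  D
}

#' Fit empirical-Bayes variance moderation
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2`
#' of the scaled inverse-chi-square prior on gene-wise variances by
#' matching the first two moments of `log(s_g^2)` to the theoretical
#' log-F model (digamma/trigamma moment equations). If the empirical
#' dispersion of `log(s_g^2)` does not exceed the sampling minimum
#' `trigamma(d/2)`, the variances are consistent with a single common
#' value and `d0 = Inf` with `s0^2 = mean(s_g^2)`.
#'
#' @param D genes x subjects matrix of paired differences (>= 3 subjects).
#' @return A `moderation_params` list: `d0`, `s02`, `df` (residual df),
#'   `n` (subjects), `low_confidence` flag for tiny gene sets.
#' @export
fit_moderation <- function(D) {
  stopifnot(is.matrix(D))
  n <- ncol(D)
  if (n < 3) stop("insufficient pairs: need >= 3 subjects")
  df <- n - 1
  s2 <- apply(D, 1, stats::var)
  ok <- is.finite(s2) & s2 > 0
  low_confidence <- sum(ok) < 10
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- if (length(e) > 1) stats::var(e) else 0
  excess <- evar - trigamma(df / 2)
  if (is.na(excess) || excess <= 0) {
    d0 <- Inf
    s02 <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s02 = s02, df = df, n = n,
                 low_confidence = low_confidence),
            class = "moderation_params")
}

# Invert trigamma by Newton iteration on 1/trigamma (nearly linear in x).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Moderated paired t-statistics
#'
#' Shrinks gene-wise variances toward the prior,
#' `s_tilde^2 = (d0 s0^2 + d s_g^2) / (d0 + d)`, and tests the mean paired
#' difference with `t = logFC / (s_tilde / sqrt(n))` on `d0 + d` degrees of
#' freedom (standard normal when `d0 = Inf`). P values are right-tailed:
#' down-shifted genes get p near 1, as required by the Stouffer
#' combination convention used downstream.
#'
#' @param D genes x subjects difference matrix.
#' @param params a `moderation_params` fit (use `d0 = 0` to recover the
#'   classical one-sample t-test).
#' @return data.frame with `gene_id`, `logFC`, `t`, `p_right`, `s2`.
#' @export
moderated_t <- function(D, params) {
  stopifnot(inherits(params, "moderation_params"))
  n <- ncol(D)
  df <- n - 1
  logFC <- rowMeans(D)
  s2 <- apply(D, 1, stats::var)
  d0 <- params$d0
  s02 <- params$s02
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  se <- sqrt(s2_post / n)
  t_stat <- ifelse(se > 0, logFC / se, 0)
  p_right <- if (is.infinite(df_total)) {
    stats::pnorm(t_stat, lower.tail = FALSE)
  } else {
    stats::pt(t_stat, df = df_total, lower.tail = FALSE)
  }
  # degenerate: zero posterior variance
  degen <- se <= 0
  if (any(degen)) {
    p_right[degen] <- ifelse(logFC[degen] == 0, 0.5,
                             ifelse(logFC[degen] > 0, 0, 1))
    t_stat[degen] <- ifelse(logFC[degen] == 0, 0,
                            sign(logFC[degen]) * Inf)
  }
  data.frame(gene_id = rownames(D), logFC = logFC, t = t_stat,
             p_right = p_right, s2 = s2, row.names = NULL)
}

#' Stouffer combination of right-tailed p values
#'
#' Unweighted Stouffer method: `Z = sum(qnorm(1 - p_i)) / sqrt(k)`,
#' `p_right = 1 - pnorm(Z)`. P values exactly 0 or 1 are clamped to
#' `[1e-15, 1 - 1e-15]` to keep the normal quantiles finite while
#' preserving ordering.
#'
#' @param p numeric vector of right-tailed p values (one per dataset).
#' @return `list(Z, p_right)`.
#' @export
stouffer_combine <- function(p) {
  stopifnot(length(p) >= 1, all(is.finite(p)), all(p >= 0), all(p <= 1))
  eps <- 1e-15
  p <- pmin(pmax(p, eps), 1 - eps)
  Z <- sum(stats::qnorm(p, lower.tail = FALSE)) / sqrt(length(p))
  list(Z = Z, p_right = stats::pnorm(Z, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1,
#' returned in the input order. Thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p values.
#' @return Vector of q values, same order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Gene-level meta-analysis across datasets
#'
#' Runs the full gene-level stage for one condition group: per-dataset
#' moderated paired t-tests (right-tailed), Stouffer combination across
#' datasets, and BH correction. The right-tailed Stouffer aggregation
#' makes down-regulation land near p = 1, so the reported meta
#' significance is the two-sided conversion `p_meta = 2 (1 - pnorm(|Z|))`
#' with direction read off `sign(Z)`; the right-tailed meta p is retained
#' per gene (`p_meta_right`) for rank-based overlap analyses.
#'
#' @param datasets list of `expression_dataset`s sharing a gene universe.
#' @param config a [pipeline_config()].
#' @return A `gene_meta_table`: data.frame with per-dataset `logFC_*`,
#'   `t_*`, `p_*` columns, and meta columns `Z`, `p_meta`, `p_meta_right`,
#'   `q`, `mean_logFC`, `common_direction`, `direction`, `de_flag`.
#' @export
gene_meta <- function(datasets, config = pipeline_config()) {
  stopifnot(length(datasets) >= 1)
  genes <- datasets[[1]]$genes
  for (d in datasets) stopifnot(identical(d$genes, genes))
  k <- length(datasets)
  logFC <- tmat <- pmat <- matrix(NA_real_, length(genes), k,
                                  dimnames = list(genes, NULL))
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    D <- paired_differences(datasets[[i]])
    fits[[i]] <- fit_moderation(D)
    res <- moderated_t(D, fits[[i]])
    logFC[, i] <- res$logFC
    tmat[, i] <- res$t
    pmat[, i] <- res$p_right
  }
  eps <- 1e-15
  pc <- pmin(pmax(pmat, eps), 1 - eps)
  Z <- rowSums(stats::qnorm(pc, lower.tail = FALSE)) / sqrt(k)
  p_meta_right <- stats::pnorm(Z, lower.tail = FALSE)
  p_meta <- 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
  q <- bh_adjust(p_meta)
  mean_logFC <- rowMeans(logFC)
  common_direction <- apply(logFC, 1, function(x) {
    s <- sign(x)
    all(s == s[1]) && s[1] != 0
  })
  tab <- data.frame(gene_id = genes, row.names = NULL)
  for (i in seq_len(k)) {
    id <- datasets[[i]]$dataset_id
    tab[[paste0("logFC_", id)]] <- logFC[, i]
    tab[[paste0("t_", id)]] <- tmat[, i]
    tab[[paste0("p_", id)]] <- pmat[, i]
  }
  tab$Z <- Z
  tab$p_meta <- p_meta
  tab$p_meta_right <- p_meta_right
  tab$q <- q
  tab$mean_logFC <- mean_logFC
  tab$common_direction <- common_direction
  tab <- call_de(tab, config)
  attr(tab, "moderation") <- fits
  attr(tab, "dataset_ids") <- vapply(datasets, `[[`, "", "dataset_id")
  class(tab) <- c("gene_meta_table", "data.frame")
  tab
}

#' Apply the three-part differential-expression call
#'
#' A gene is DE iff (i) BH-corrected meta P <= `alpha_meta`, (ii) absolute
#' meta mean log2 fold-change > `lfc_min`, and (iii) a common direction of
#' per-dataset log fold-change.
#'
#' @param tab a `gene_meta_table` with meta columns filled.
#' @param config a [pipeline_config()].
#' @return `tab` with `de_flag` and `direction` set.
#' @export
call_de <- function(tab, config = pipeline_config()) {
  stopifnot(all(c("q", "mean_logFC", "common_direction") %in% names(tab)))
  tab$de_flag <- tab$q <= config$alpha_meta &
    abs(tab$mean_logFC) > config$lfc_min &
    tab$common_direction
  tab$direction <- ifelse(!tab$de_flag, "none",
                          ifelse(tab$mean_logFC > 0, "up", "down"))
  tab
}

#' @export
print.gene_meta_table <- function(x, ...) {
  cat(sprintf("gene_meta_table: %d genes, %d datasets; %d DE (%d up, %d down)\n",
              nrow(x), length(attr(x, "dataset_ids")), sum(x$de_flag),
              sum(x$direction == "up"), sum(x$direction == "down")))
  invisible(x)
}
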