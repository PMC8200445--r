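fake_meta_table <- function(genes, mean_logFC, q, de_flag = NULL,
                            direction = NULL) {
  tab <- data.frame(gene_id = genes, mean_logFC = mean_logFC, q = q)
  tab$de_flag <- if (is.null(de_flag)) rep(FALSE, length(genes)) else de_flag
  tab$direction <- if (is.null(direction)) {
    ifelse(!tab$de_flag, "none", ifelse(mean_logFC > 0, "up", "down"))
  } else direction
  tab
}

test_that("identical partitions match one-to-one with identity relabelling", {
  genes <- sprintf("g%03d", 1:300)
  part <- structure(setNames(rep(c("M1", "M2", "M0"), each = 100), genes),
                    class = "module_partition")
  mm <- match_labels(part, part)
  expect_identical(unname(mm$relabel[c("M1", "M2")]), c("M1", "M2"))
  expect_length(mm$unmatched, 0)
  expect_identical(as.character(mm$relabelled), as.character(part))
})

test_that("disjoint source modules receive fresh labels", {
  genes <- sprintf("g%03d", 1:200)
  ref <- structure(setNames(rep(c("M1", "M0"), c(100, 100)), genes),
                   class = "module_partition")
  src <- structure(setNames(rep(c("M0", "M1"), c(100, 100)), genes),
                   class = "module_partition")
  mm <- match_labels(ref, src)
  expect_identical(mm$unmatched, "M1")
  expect_false(unname(mm$relabel["M1"]) == "M1")
  expect_error(match_labels(ref, src[1:100]), "different gene universes")
})

test_that("greedy assignment agrees with the exhaustive oracle on 3x3 case", {
  # construct overlaps with one ambiguous cell
  genes <- sprintf("g%03d", 1:240)
  ref <- rep(c("M1", "M2", "M3", "M0"), c(70, 70, 60, 40))
  src <- rep("M0", 240)
  src[1:60] <- "A"            # mostly M1
  src[61:70] <- "B"           # tail of M1 (ambiguous with A)
  src[71:130] <- "B"          # bulk of M2
  src[141:200] <- "C"         # bulk of M3
  ref_p <- structure(setNames(ref, genes), class = "module_partition")
  src_p <- structure(setNames(src, genes), class = "module_partition")
  mm <- match_labels(ref_p, src_p)
  # exhaustive oracle: over all one-to-one assignments of {A,B,C} to
  # reference labels, pick the one greedily by ascending corrected p
  p_adj <- mm$p_adj
  cells <- data.frame(ref = rep(rownames(p_adj), ncol(p_adj)),
                      src = rep(colnames(p_adj), each = nrow(p_adj)),
                      p = as.vector(p_adj))
  cells <- cells[cells$p < 0.05, ]
  cells <- cells[order(cells$p), ]
  used_r <- used_s <- character(0)
  oracle <- character(0)
  for (i in seq_len(nrow(cells))) {
    if (cells$ref[i] %in% used_r || cells$src[i] %in% used_s) next
    oracle[cells$src[i]] <- cells$ref[i]
    used_r <- c(used_r, cells$ref[i])
    used_s <- c(used_s, cells$src[i])
  }
  expect_identical(mm$relabel[names(oracle)], oracle)
  expect_identical(unname(mm$relabel["A"]), "M1")
  expect_identical(unname(mm$relabel["B"]), "M2")
  expect_identical(unname(mm$relabel["C"]), "M3")
})

test_that("RRHO p value matches the exact hypergeometric by hand", {
  # N = 10, step 1, identical top-3 lists: p = 1/C(10,3)
  genes <- sprintf("g%02d", 1:10)
  score <- seq(5, -4)   # descending scores, no ties
  ta <- fake_meta_table(genes, mean_logFC = score,
                        q = 10^(-abs(score)))
  cfg <- pipeline_config(rrho_step_fraction = 0.1)  # step = 1
  rr <- rrho(ta, ta, cfg)
  g <- rr$grid[rr$grid$quadrant == "up-up" & rr$grid$i == 3 & rr$grid$j == 3, ]
  expect_equal(g$overlap, 3)
  expect_equal(10^(-g$neglog10p), 1 / choose(10, 3), tolerance = 1e-9)
  expect_equal(g$neglog10p, 2.079, tolerance = 1e-3)
})

test_that("self-comparison puts concordant optima on the diagonal", {
  set.seed(6)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  lfc <- rnorm(n)
  q <- pmin(1, abs(rnorm(n, 0.3, 0.2)))
  ta <- fake_meta_table(genes, lfc, q)
  rr <- rrho(ta, ta, pipeline_config(rrho_step_fraction = 0.05))
  for (quad in c("up-up", "down-down")) {
    o <- rr$optima[[quad]]
    expect_equal(o$i, o$j)
    expect_length(o$genes, o$i)   # identical prefixes overlap fully
  }
  # discordant quadrants of a self-comparison stay unimpressive
  bonf <- -log10(0.05 / nrow(rr$grid))
  expect_lt(rr$optima[["up-down"]]$neglog10p, bonf)
  expect_lt(rr$optima[["down-up"]]$neglog10p, bonf)
})

test_that("RRHO grid equals a direct per-point hypergeometric oracle", {
  set.seed(31)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  for (rep_i in 1:3) {
    ta <- fake_meta_table(genes, rnorm(n), runif(n))
    tb <- fake_meta_table(genes, rnorm(n), runif(n))
    cfg <- pipeline_config(rrho_step_fraction = 0.05)  # step 10, 20x20 grid
    rr <- rrho(ta, tb, cfg)
    score <- function(tab) sign(tab$mean_logFC) * (-log10(pmax(tab$q, 1e-300)))
    sa <- setNames(score(ta), genes)
    sb <- setNames(score(tb), genes)
    top <- function(x, k) names(sort(x, decreasing = TRUE))[seq_len(k)]
    ord_desc <- function(x) genes[order(-x, genes)]
    oa <- ord_desc(sa); ob <- ord_desc(sb)
    g <- rr$grid[rr$grid$quadrant == "up-up", ]
    for (row in sample(nrow(g), 30)) {
      i <- g$i[row]; j <- g$j[row]
      ov <- length(intersect(oa[1:i], ob[1:j]))
      expect_identical(g$overlap[row], ov)
      expect_equal(g$neglog10p[row],
                   -log10(max(phyper(ov - 1, i, n - i, j, lower.tail = FALSE),
                              1e-320)),
                   tolerance = 1e-9)
    }
    # one discordant quadrant spot-check
    oa_bot <- genes[order(sa, genes)]
    gd <- rr$grid[rr$grid$quadrant == "down-up", ]
    row <- sample(nrow(gd), 1)
    i <- gd$i[row]; j <- gd$j[row]
    ov <- length(intersect(oa_bot[1:i], ob[1:j]))
    expect_identical(gd$overlap[row], ov)
  }
})

test_that("independent random scores rarely clear the Bonferroni line", {
  n <- 300
  genes <- sprintf("g%03d", 1:n)
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    ta <- fake_meta_table(genes, rnorm(n), runif(n))
    tb <- fake_meta_table(genes, rnorm(n), runif(n))
    rr <- rrho(ta, tb, pipeline_config(rrho_step_fraction = 0.05))
    bonf <- -log10(0.05 / nrow(rr$grid))
    if (max(rr$grid$neglog10p) >= bonf) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("gene classification follows the published definitions", {
  genes <- paste0("g", 1:8)
  ta <- fake_meta_table(genes, c(1, 1, 1, -1, 1, 0, 1, -1),
                        q = rep(0.01, 8),
                        de_flag = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                                    TRUE, TRUE),
                        direction = c("up", "up", "up", "down", "none",
                                      "none", "up", "down"))
  tb <- fake_meta_table(genes, c(1, 0, -1, -1, 1, 0, 1, 1),
                        q = rep(0.01, 8),
                        de_flag = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                                    TRUE, TRUE),
                        direction = c("up", "none", "down", "down", "up",
                                      "none", "up", "up"))
  rr <- list(optima = list(
    "up-up" = list(genes = c("g1")),
    "down-down" = list(genes = c("g4")),
    "up-down" = list(genes = c("g3")),
    "down-up" = list(genes = character(0))))
  cls <- classify_genes(ta, tb, rr)
  expect_identical(unname(cls["g1"]), "common-concordant-up")
  expect_identical(unname(cls["g2"]), "unique-A-up")     # DE in A only, no set
  expect_identical(unname(cls["g3"]), "common-discordant-A-up-B-down")
  expect_identical(unname(cls["g4"]), "common-concordant-down")
  expect_identical(unname(cls["g5"]), "unique-B-up")
  expect_identical(unname(cls["g6"]), "none")
  expect_identical(unname(cls["g7"]), "none")  # DE both, in no optimal set
  expect_identical(unname(cls["g8"]), "none")  # discordant but not in set
  # classes are exhaustive and mutually exclusive by construction
  expect_length(cls, length(genes))
  expect_true(all(cls %in% c("common-concordant-up", "common-concordant-down",
                             "common-discordant-A-up-B-down",
                             "common-discordant-A-down-B-up",
                             "unique-A-up", "unique-A-down", "unique-B-up",
                             "unique-B-down", "none")))
})

test_that("planted effect classes are recovered through RRHO end-to-end", {
  spec <- simulation_spec(n_datasets = 3, n_pairs = 20, n_genes = 1500,
                          module_sizes = integer(0))
  recov <- matrix(NA_real_, 3, 3,
                  dimnames = list(NULL, c("shared", "uniqueA", "inverted")))
  for (s in 1:3) {
    sim <- simulate_two_groups(spec, spec, n_shared = 100, n_unique_a = 100,
                               n_unique_b = 0, n_inverted = 50,
                               effect_size = 0.5, seed = 600 + s)
    gma <- gene_meta(sim$A$datasets)
    gmb <- gene_meta(sim$B$datasets)
    rr <- rrho(gma, gmb)
    cls <- classify_genes(gma, gmb, rr)
    truth <- sim$classes
    frac <- function(truth_prefix, pred_prefix) {
      idx <- startsWith(truth, truth_prefix)
      mean(startsWith(cls[names(truth)[idx]], pred_prefix))
    }
    recov[s, "shared"] <- frac("shared", "common-concordant")
    recov[s, "uniqueA"] <- frac("unique-A", "unique-A")
    recov[s, "inverted"] <- frac("inverted", "common-discordant")
  }
  expect_true(all(colMeans(recov) >= 0.7))
})
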