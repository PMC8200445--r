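test_that("signed adjacency matches its closed forms at cor -1, 0, 1", {
  base <- rnorm(6)
  X <- rbind(g1 = base, g2 = 2 * base + 1, g3 = -base)
  A <- signed_adjacency(X, beta = 6)
  expect_equal(unname(A["g1", "g2"]), 1)            # cor = 1
  expect_equal(unname(A["g1", "g3"]), 0)            # cor = -1
  set.seed(5)
  X2 <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("g", 1:3), NULL))
  A2 <- signed_adjacency(X2, beta = 6)
  C <- cor(t(X2))
  expect_equal(A2[1, 2], (0.5 * (1 + C[1, 2]))^6)
  # cor = 0 -> 0.5^6 by the formula
  expect_equal((0.5 * (1 + 0))^6, 0.015625)
  Xc <- rbind(g1 = rep(1, 5), g2 = rnorm(5))
  expect_error(signed_adjacency(Xc, 6), "zero-variance gene: g1")
})

test_that("adjacency and TOM stay symmetric with entries in [0,1]", {
  set.seed(9)
  for (i in 1:20) {
    X <- matrix(rnorm(15 * 8), 15, 8,
                dimnames = list(sprintf("g%02d", 1:15), NULL))
    A <- signed_adjacency(X, beta = sample(1:12, 1))
    expect_equal(A, t(A))
    expect_true(all(A >= 0 & A <= 1))
    TT <- tom(A)
    expect_equal(TT, t(TT), tolerance = 1e-12)
    expect_true(all(TT >= -1e-12 & TT <= 1 + 1e-12))
  }
})

test_that("scale-free fit is 1 on constructed power-law data, 0 when degenerate", {
  # prescribe the connectivity histogram: bin values 1..10 with counts
  # proportional to k^-2, realised through an expected-degree adjacency
  k_target <- rep(1:10, round(400 * (1:10)^-2)) / 400
  w <- k_target / sqrt(sum(k_target))       # k_i ~ w_i * sum(w), solve exactly
  for (iter in 1:200) {
    S <- sum(w)
    w <- S / 2 - sqrt(pmax(S^2 / 4 - k_target, 0))
  }
  A <- outer(w, w)
  diag(A) <- 1
  expect_lt(max(abs((rowSums(A) - 1) - k_target)) / max(k_target), 0.01)
  f <- scale_free_fit(A)
  expect_gte(f, 0.99)
  expect_lt(attr(f, "slope"), 0)
  # all-equal connectivities
  Aeq <- matrix(0.3, 20, 20)
  diag(Aeq) <- 1
  expect_equal(as.numeric(scale_free_fit(Aeq)), 0)
  # always in [0,1]
  for (i in 1:5) {
    f2 <- scale_free_fit(random_adjacency(30, i))
    expect_gte(as.numeric(f2), 0)
    expect_lte(as.numeric(f2), 1)
  }
})

test_that("beta selection follows the lowest-integer scale-free rule", {
  # strongly modular data: some beta reaches the threshold; result equals
  # an exhaustive scan oracle
  spec <- simulation_spec(n_datasets = 1, n_pairs = 30, n_genes = 300,
                          module_sizes = c(100L, 100L), module_cor = 0.8)
  sim <- simulate_group(spec, seed = 41)
  X <- sim$datasets[[1]]$X
  cfg <- pipeline_config()
  pb <- suppressWarnings(pick_beta(X, cfg))
  scan <- vapply(1:cfg$beta_max, function(b) {
    f <- scale_free_fit(signed_adjacency(X, b))
    as.numeric(f) >= cfg$scale_free_r2_min && attr(f, "slope") < 0
  }, TRUE)
  if (any(scan)) {
    expect_true(pb$reached)
    expect_identical(pb$beta, which(scan)[1])
  } else {
    expect_false(pb$reached)
    expect_identical(pb$beta, which.max(pb$fit_table$r2))
  }
  expect_identical(nrow(pb$fit_table), cfg$beta_max)
})

test_that("TOM matches closed forms and the brute-force triple loop", {
  # 2-gene network: TOM_12 = a
  a <- 0.37
  A2 <- matrix(c(1, a, a, 1), 2, 2)
  expect_equal(tom(A2)[1, 2], a)
  # all-ones adjacency
  A1 <- matrix(1, 6, 6)
  expect_true(all(tom(A1) == 1))
  # random 10-gene adjacencies vs O(n^3) oracle
  for (i in 1:5) {
    A <- random_adjacency(10, 50 + i)
    expect_equal(tom(A), tom_brute(A), tolerance = 1e-10)
  }
})

test_that("quantile calibration aligns TOMs and consensus is the minimum", {
  T1 <- tom(random_adjacency(12, 1))
  # identical TOMs unchanged
  cal_same <- calibrate_toms(list(T1, T1))
  expect_equal(cal_same[[1]], T1)
  expect_equal(cal_same[[2]], T1)
  # scaled TOM recovers the reference after calibration
  T2 <- T1 * 0.5
  diag(T2) <- 1
  cal <- calibrate_toms(list(T1, T2))
  off <- upper.tri(T1)
  expect_equal(cal[[2]][off], T1[off], tolerance = 1e-12)
  # calibrated TOMs share the calibration quantile
  T3 <- tom(random_adjacency(12, 2))
  cal2 <- calibrate_toms(list(T1, T3), calibration_quantile = 0.95)
  qs <- vapply(cal2, function(M) quantile(M[off], 0.95, names = FALSE), 0)
  expect_equal(qs[1], qs[2], tolerance = 1e-12)
  # consensus: element-wise minimum; all-zero input forces zero
  cons <- consensus_tom(cal2)
  expect_equal(cons$cTOM, pmin(cal2[[1]], cal2[[2]]))
  expect_true(all(cons$cTOM <= cal2[[1]] + 1e-15))
  expect_true(all(cons$cTOM <= cal2[[2]] + 1e-15))
  expect_true(all(diag(cons$disTOM) == 0))
  zero <- T1 * 0
  expect_true(all(consensus_tom(list(T1, zero))$cTOM == 0))
})

test_that("module detection separates forced blocks and drops small ones", {
  n <- 120
  ids <- sprintf("g%03d", 1:n)
  D <- matrix(0.95, n, n, dimnames = list(ids, ids))
  D[1:60, 1:60] <- 0.05
  D[61:120, 61:120] <- 0.05
  diag(D) <- 0
  part <- detect_modules(D, pipeline_config())
  sizes <- attr(part, "sizes")
  expect_length(sizes, 2)
  expect_true(all(sizes == 60))
  expect_length(unique(part[1:60]), 1)
  expect_length(unique(part[61:120]), 1)
  # a coherent 40-gene block stays unassigned under the 50-gene floor
  n2 <- 140
  ids2 <- sprintf("h%03d", 1:n2)
  set.seed(77)
  D2 <- matrix(runif(n2 * n2, 0.9, 1), n2, n2)
  D2 <- (D2 + t(D2)) / 2
  D2[1:40, 1:40] <- 0.05
  diag(D2) <- 0
  dimnames(D2) <- list(ids2, ids2)
  part2 <- suppressWarnings(detect_modules(D2, pipeline_config()))
  expect_true(all(part2[1:40] == "M0"))
})

test_that("planted consensus modules are recovered with high ARI", {
  spec <- simulation_spec(n_datasets = 3, n_pairs = 20, n_genes = 1000,
                          module_sizes = rep(80L, 5), module_cor = 0.6)
  aris <- vapply(1:3, function(seed) {
    sim <- simulate_group(spec, seed = seed)
    net <- suppressWarnings(consensus_network(sim$datasets))
    ari(sim$truth$module_assignment[names(net$partition)],
        as.character(net$partition))
  }, 0)
  expect_true(all(aris >= 0.8))
})

test_that("eigengenes are the oriented first principal component", {
  set.seed(13)
  v <- rnorm(10)
  X <- matrix(rep(v, each = 6), 6, 10) +
    matrix(rnorm(60, sd = 1e-6), 6, 10)
  rownames(X) <- paste0("g", 1:6)
  ds <- make_dataset(X, "d1")
  part <- structure(setNames(rep("M1", 6), rownames(X)),
                    class = "module_partition")
  eg <- module_eigengenes(part, list(ds))
  scores <- eg$M1$d1$scores
  vz <- (v - mean(v)) / sd(v)
  expect_gt(abs(cor(scores, v)), 0.999999)
  expect_gt(cor(scores, v), 0)                      # positive orientation
  expect_equal(sum(scores^2), 1)                    # unit norm
  expect_gt(eg$M1$d1$var_explained, 0.999)
  expect_lte(eg$M1$d1$var_explained, 1)
  # mixed-sign genes: orientation still positive vs the mean profile
  X2 <- rbind(X[1:3, ], -X[4:6, ] + 10)
  rownames(X2) <- paste0("g", 1:6)
  ds2 <- make_dataset(X2, "d1")
  eg2 <- module_eigengenes(part, list(ds2))
  Z2 <- t(scale(t(X2)))
  expect_gte(cor(eg2$M1$d1$scores, colMeans(Z2)), 0)
})

test_that("module merging applies the minimum-across-datasets rule", {
  # two modules tracking the same latent factor in every dataset: merged
  mk_group <- function(cor_second_ds) {
    lapply(1:2, function(d) {
      set.seed(200 + d)
      f <- rnorm(12)
      g <- if (d == 2 && cor_second_ds == 0) rnorm(12) else f
      X <- rbind(
        matrix(rep(f, each = 30), 30, 12) + matrix(rnorm(360, sd = 0.3), 30, 12),
        matrix(rep(g, each = 30), 30, 12) + matrix(rnorm(360, sd = 0.3), 30, 12))
      rownames(X) <- sprintf("g%03d", 1:60)
      make_dataset(X, paste0("d", d))
    })
  }
  part <- structure(setNames(rep(c("M1", "M2"), each = 30),
                             sprintf("g%03d", 1:60)),
                    class = "module_partition")
  cfg <- pipeline_config(min_module_size = 30)
  merged <- merge_modules(part, mk_group(1), cfg)
  expect_length(attr(merged$partition, "sizes"), 1)
  expect_length(merged$merge_history, 1)
  # correlation ~0 in one dataset blocks the merge (minimum rule)
  kept <- merge_modules(part, mk_group(0), cfg)
  expect_length(attr(kept$partition, "sizes"), 2)
  expect_length(kept$merge_history, 0)
})

test_that("chained merges reach the same single module as exhaustive order", {
  # A ~ B strongly, C correlates with the A+B mixture: expect one module
  set.seed(303)
  f <- rnorm(16)
  mk <- function(loading, n, noise) {
    matrix(rep(f, each = n) * loading, n, 16) +
      matrix(rnorm(16 * n, sd = noise), n, 16)
  }
  X <- rbind(mk(1, 20, 0.2), mk(1, 20, 0.2), mk(0.8, 20, 0.45))
  rownames(X) <- sprintf("g%03d", 1:60)
  ds <- make_dataset(X, "d1")
  part <- structure(setNames(rep(c("A", "B", "C"), each = 20),
                             rownames(X)), class = "module_partition")
  cfg <- pipeline_config(min_module_size = 20)
  merged <- merge_modules(part, list(ds), cfg)
  expect_length(attr(merged$partition, "sizes"), 1)
  # exhaustive merge-order oracle: any pair order must end in one module
  pair_orders <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  for (first in pair_orders) {
    p2 <- as.character(part)
    names(p2) <- names(part)
    p2[p2 == first[2]] <- first[1]
    p2 <- structure(p2, class = "module_partition")
    m2 <- merge_modules(p2, list(ds), cfg)
    expect_length(attr(m2$partition, "sizes"), 1)
  }
})
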