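# Independent oracles and small fixture builders shared across test files.

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  ex <- sum_a * sum_b / choose(n, 2)
  (sum_ij - ex) / ((sum_a + sum_b) / 2 - ex)
}

# O(m^2) brute-force BH step-up: q_i = min over {j : p_(j) >= p_i} of m p_(j)/j.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cands <- (m * ps / seq_len(m))[seq(i, m)]
    q[ord[i]] <- min(1, min(cands))
  }
  q
}

# O(n^3) triple-loop TOM oracle.
tom_brute <- function(A) {
  n <- nrow(A)
  A0 <- A
  diag(A0) <- 0
  TOM <- diag(n)
  k <- rowSums(A0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A0[i, u] * A0[u, j]
    TOM[i, j] <- (l + A0[i, j]) / (min(k[i], k[j]) + 1 - A0[i, j])
  }
  dimnames(TOM) <- dimnames(A)
  TOM
}

# Exhaustive hypergeometric upper tail by enumerating all draws of size nb
# from a universe of size N containing na successes (N <= ~15).
hyper_enum <- function(ov, na, N, nb) {
  num <- 0
  for (x in seq(ov, min(na, nb))) {
    num <- num + choose(na, x) * choose(N - na, nb - x)
  }
  num / choose(N, nb)
}

# Paired pre/post dataset with explicit values.
make_dataset <- function(X, dataset_id = "d1", condition = "other") {
  n_pairs <- ncol(X) / 2
  subj <- paste0("S", seq_len(n_pairs))
  samples <- data.frame(
    sample_id = c(paste0(subj, "_pre"), paste0(subj, "_post")),
    subject_id = rep(subj, 2),
    timepoint = rep(c("pre", "post"), each = n_pairs))
  colnames(X) <- samples$sample_id
  if (is.null(rownames(X))) rownames(X) <- sprintf("g%03d", seq_len(nrow(X)))
  expression_dataset(dataset_id, condition, X, samples)
}

# Random valid adjacency: symmetric, unit diagonal, entries in [0,1].
random_adjacency <- function(n, seed) {
  set.seed(seed)
  M <- matrix(runif(n * n), n, n)
  A <- (M + t(M)) / 2
  diag(A) <- 1
  dimnames(A) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  A
}
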