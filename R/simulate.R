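#' Simulation specification
#'
#' Describes one condition group's synthetic multi-study design: number of
#' independent datasets, paired subjects per dataset, gene universe, planted
#' co-expression modules, per-gene additive log2 effects applied at the
#' post timepoint, per-module eigengene shifts, and dataset noise scales.
#'
#' Defaults mirror the published study design this package re-implements:
#' three independent datasets per condition group (five for the older-RET
#' analogue), paired pre/post biopsies per subject, a shared gene universe
#' of a few thousand genes, and module sizes comfortably above the
#' 50-gene module-detection floor.
#'
#' @param n_datasets number of independent datasets in the group.
#' @param n_pairs integer vector (recycled) of subject pairs per dataset.
#' @param n_genes size of the shared gene universe.
#' @param module_sizes integer vector of planted module sizes; remaining
#'   genes are uncorrelated background.
#' @param module_cor target within-module Pearson correlation.
#' @param noise_sd numeric vector (recycled) of per-dataset residual SDs on
#'   the log2 scale.
#' @param gene_effects named numeric vector of planted log2 fold-changes
#'   (post minus pre), names are gene IDs (`g0001`, ...); may be `NULL`.
#' @param module_shifts numeric vector (recycled over modules) of eigengene
#'   shifts in subject-factor SD units applied at the post timepoint.
#' @param condition condition label for the generated datasets.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_datasets = 3L,
                            n_pairs = 20L,
                            n_genes = 4000L,
                            module_sizes = c(80L, 80L, 80L, 80L, 80L),
                            module_cor = 0.6,
                            noise_sd = 0.5,
                            gene_effects = NULL,
                            module_shifts = 0,
                            condition = "other") {
  spec <- list(n_datasets = as.integer(n_datasets),
               n_pairs = rep_len(as.integer(n_pairs), n_datasets),
               n_genes = as.integer(n_genes),
               module_sizes = as.integer(module_sizes),
               module_cor = as.numeric(module_cor),
               noise_sd = rep_len(as.numeric(noise_sd), n_datasets),
               gene_effects = gene_effects,
               module_shifts = rep_len(as.numeric(module_shifts),
                                       max(1L, length(module_sizes))),
               condition = condition)
  if (sum(spec$module_sizes) > spec$n_genes)
    stop("module sizes sum to more than n_genes")
  if (any(spec$noise_sd <= 0)) stop("noise_sd must be positive")
  if (spec$module_cor < 0 || spec$module_cor >= 1)
    stop("module_cor must be in [0,1)")
  class(spec) <- "simulation_spec"
  spec
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate one condition group
#'
#' Generates `n_datasets` independent paired pre/post expression datasets
#' from a common generative model. Per dataset `d`: baseline gene means
#' `mu_g ~ N(8, 1.5^2)` on the log2 scale; each planted module `m` has a
#' latent per-subject factor `f_{s,d} ~ N(0,1)` shared between a subject's
#' pre and post samples (this is what makes the within-person design pay
#' off downstream); a module gene's value is
#' `mu_g + lambda_g * f + effect_g * 1[post] + eps`,
#' `eps ~ N(0, noise_sd_d^2)`. Module eigengene shifts are planted by
#' using `f` at pre and `f + shift_m` at post. Loadings `lambda_g` are set
#' around `noise_sd * sqrt(rho/(1-rho))` so the expected within-module
#' Pearson correlation equals the target `rho`, with mild per-gene jitter
#' so that genes differ in how strongly they carry the module signal
#' (the basis of hub-gene recovery checks). Module membership is identical
#' across the group's datasets.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed; the run is fully reproducible.
#' @param dataset_prefix prefix for dataset IDs.
#' @return `list(datasets = <list of expression_dataset>, truth = <list>)`.
#'   `truth` records module assignment, planted gene effects, module
#'   shifts, per-dataset noise SDs and per-gene loadings.
#' @export
simulate_group <- function(spec, seed = 17L, dataset_prefix = spec$condition) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(as.integer(seed))
  n_genes <- spec$n_genes
  ids <- gene_ids(n_genes)
  n_mod <- length(spec$module_sizes)
  assignment <- rep("background", n_genes)
  names(assignment) <- ids
  idx <- 0L
  module_genes <- list()
  for (m in seq_len(n_mod)) {
    gidx <- idx + seq_len(spec$module_sizes[m])
    assignment[gidx] <- sprintf("sim%02d", m)
    module_genes[[sprintf("sim%02d", m)]] <- ids[gidx]
    idx <- idx + spec$module_sizes[m]
  }

  effects <- rep(0, n_genes)
  names(effects) <- ids
  if (!is.null(spec$gene_effects)) {
    unknown <- setdiff(names(spec$gene_effects), ids)
    if (length(unknown)) stop("gene_effects name genes outside the universe")
    effects[names(spec$gene_effects)] <- spec$gene_effects
  }

  rho <- spec$module_cor
  lambda_base <- sqrt(rho / (1 - rho))  # in units of noise_sd
  # per-gene jitter keeps mean pairwise correlation on target while ranking
  # genes by module-signal strength
  loading_jitter <- stats::runif(n_genes, 0.8, 1.2)

  datasets <- vector("list", spec$n_datasets)
  loadings <- matrix(NA_real_, n_genes, spec$n_datasets,
                     dimnames = list(ids, NULL))
  for (d in seq_len(spec$n_datasets)) {
    n_pairs <- spec$n_pairs[d]
    sd_d <- spec$noise_sd[d]
    mu <- stats::rnorm(n_genes, mean = 8, sd = 1.5)
    lambda <- ifelse(assignment == "background", 0,
                     lambda_base * sd_d * loading_jitter)
    loadings[, d] <- lambda
    n_samp <- 2L * n_pairs
    subj <- sprintf("%s%d_S%02d", dataset_prefix, d, seq_len(n_pairs))
    sample_id <- c(paste0(subj, "_pre"), paste0(subj, "_post"))
    timepoint <- rep(c("pre", "post"), each = n_pairs)
    X <- matrix(mu, n_genes, n_samp)
    for (m in seq_len(n_mod)) {
      lab <- sprintf("sim%02d", m)
      rows <- which(assignment == lab)
      f <- stats::rnorm(n_pairs)
      f_mat <- c(f, f + spec$module_shifts[m])  # pre then post
      X[rows, ] <- X[rows, ] + outer(lambda[rows], f_mat)
    }
    post_cols <- which(timepoint == "post")
    X[, post_cols] <- X[, post_cols] + effects
    X <- X + matrix(stats::rnorm(n_genes * n_samp, sd = sd_d), n_genes, n_samp)
    rownames(X) <- ids
    colnames(X) <- sample_id
    datasets[[d]] <- expression_dataset(
      dataset_id = sprintf("%s%d", dataset_prefix, d),
      condition = spec$condition,
      X = X,
      samples = data.frame(sample_id = sample_id,
                           subject_id = rep(subj, 2),
                           timepoint = timepoint,
                           stringsAsFactors = FALSE))
  }
  truth <- list(module_assignment = assignment,
                module_genes = module_genes,
                gene_effects = effects,
                module_shifts = stats::setNames(
                  spec$module_shifts[seq_len(max(n_mod, 0))],
                  if (n_mod) sprintf("sim%02d", seq_len(n_mod)) else NULL),
                noise_sd = spec$noise_sd,
                loadings = loadings,
                seed = as.integer(seed))
  list(datasets = datasets, truth = truth)
}

#' Simulate a two-condition study
#'
#' Builds two condition groups (A and B) on a shared gene universe with
#' disjoint planted effect classes: genes shifted in a shared direction in
#' both conditions, genes shifted in one condition only, and genes with
#' inverted (opposite-sign) shifts across conditions — the classes the
#' rank-rank overlap stage is designed to separate.
#'
#' @param spec_a,spec_b [simulation_spec()]s for the two groups; they must
#'   agree on `n_genes` and `module_sizes`.
#' @param n_shared,n_unique_a,n_unique_b,n_inverted number of genes per
#'   effect class (each split evenly between up and down variants except
#'   `n_inverted`, which is A-up/B-down for the first half and the reverse
#'   for the rest).
#' @param effect_size absolute planted log2 fold-change.
#' @param seed integer seed.
#' @return `list(A = <group>, B = <group>, classes = <named character>)`
#'   where each group is a [simulate_group()] result and `classes` labels
#'   every gene with its planted class.
#' @export
simulate_two_groups <- function(spec_a, spec_b,
                                n_shared = 100L, n_unique_a = 100L,
                                n_unique_b = 100L, n_inverted = 50L,
                                effect_size = 0.5, seed = 17L) {
  stopifnot(spec_a$n_genes == spec_b$n_genes)
  n_genes <- spec_a$n_genes
  ids <- gene_ids(n_genes)
  n_eff <- n_shared + n_unique_a + n_unique_b + n_inverted
  if (n_eff > n_genes) stop("effect classes exceed gene universe")
  set.seed(as.integer(seed))
  pick <- sample(ids, n_eff)
  classes <- rep("none", n_genes)
  names(classes) <- ids
  halves <- function(n) c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2)))
  eff_a <- eff_b <- stats::setNames(numeric(0), character(0))
  take <- function(n) {
    out <- pick[seq_len(n)]
    pick <<- pick[-seq_len(n)]
    out
  }
  if (n_shared) {
    g <- take(n_shared); s <- halves(n_shared)
    classes[g] <- ifelse(s > 0, "shared-up", "shared-down")
    eff_a <- c(eff_a, stats::setNames(s * effect_size, g))
    eff_b <- c(eff_b, stats::setNames(s * effect_size, g))
  }
  if (n_unique_a) {
    g <- take(n_unique_a); s <- halves(n_unique_a)
    classes[g] <- ifelse(s > 0, "unique-A-up", "unique-A-down")
    eff_a <- c(eff_a, stats::setNames(s * effect_size, g))
  }
  if (n_unique_b) {
    g <- take(n_unique_b); s <- halves(n_unique_b)
    classes[g] <- ifelse(s > 0, "unique-B-up", "unique-B-down")
    eff_b <- c(eff_b, stats::setNames(s * effect_size, g))
  }
  if (n_inverted) {
    g <- take(n_inverted); s <- halves(n_inverted)
    classes[g] <- ifelse(s > 0, "inverted-A-up", "inverted-A-down")
    eff_a <- c(eff_a, stats::setNames(s * effect_size, g))
    eff_b <- c(eff_b, stats::setNames(-s * effect_size, g))
  }
  spec_a$gene_effects <- eff_a
  spec_b$gene_effects <- eff_b
  seeds <- sample.int(2^31 - 1, 2)
  list(A = simulate_group(spec_a, seed = seeds[1], dataset_prefix = "A"),
       B = simulate_group(spec_b, seed = seeds[2], dataset_prefix = "B"),
       classes = classes)
}

#' Write a simulated group to disk
#'
#' One matrix + sample-sheet TSV pair per dataset, plus a ground-truth TSV.
#'
#' @param sim a [simulate_group()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (ds in sim$datasets) {
    write_expression(ds,
                     file.path(outdir, paste0(ds$dataset_id, "_matrix.tsv")),
                     file.path(outdir, paste0(ds$dataset_id, "_samples.tsv")))
  }
  truth <- data.frame(gene_id = names(sim$truth$module_assignment),
                      module = unname(sim$truth$module_assignment),
                      effect = unname(sim$truth$gene_effects))
  write_tsv(truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
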