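#' Pipeline configuration
#'
#' Creates the configuration object holding every analysis threshold used by
#' the pipeline. Defaults reproduce the published criteria: differential
#' expression requires a BH-corrected meta P value at or below `alpha_meta`,
#' an absolute meta mean log2 fold-change above `lfc_min`, and a common
#' per-dataset direction; consensus modules contain at least
#' `min_module_size` genes and are merged when their minimum across-dataset
#' eigengene correlation exceeds `merge_cor_min`; consensus hub genes sit
#' strictly above the `hub_percentile` quantile of consensus module
#' membership; the soft-threshold exponent is the lowest integer whose
#' scale-free topology fit reaches `scale_free_r2_min`.
#'
#' @param alpha_meta FDR threshold for meta P values (default 0.1).
#' @param lfc_min absolute meta mean log2 fold-change threshold (default 0.1).
#' @param min_module_size minimum genes per consensus module (default 50).
#' @param merge_cor_min minimum across-dataset eigengene correlation above
#'   which two modules are merged (default 0.75).
#' @param hub_percentile quantile of consensus module membership defining
#'   hub genes (default 0.85).
#' @param scale_free_r2_min scale-free topology fit threshold (default 0.8).
#' @param beta_max largest soft-threshold exponent scanned (default 20).
#' @param calibration_quantile off-diagonal TOM quantile used for
#'   single-quantile calibration (default 0.95).
#' @param rrho_step_fraction RRHO grid step as a fraction of the ranked list
#'   length (default 0.01).
#' @param ora_alpha BH threshold for over-representation calls (default 0.05).
#' @param seed integer RNG seed recorded in run reports (default 17).
#' @return An object of class `coexmeta_config` (a named list).
#' @export
pipeline_config <- function(alpha_meta = 0.1,
                            lfc_min = 0.1,
                            min_module_size = 50L,
                            merge_cor_min = 0.75,
                            hub_percentile = 0.85,
                            scale_free_r2_min = 0.8,
                            beta_max = 20L,
                            calibration_quantile = 0.95,
                            rrho_step_fraction = 0.01,
                            ora_alpha = 0.05,
                            seed = 17L) {
  cfg <- list(
    alpha_meta = as.numeric(alpha_meta),
    lfc_min = as.numeric(lfc_min),
    min_module_size = as.integer(min_module_size),
    merge_cor_min = as.numeric(merge_cor_min),
    hub_percentile = as.numeric(hub_percentile),
    scale_free_r2_min = as.numeric(scale_free_r2_min),
    beta_max = as.integer(beta_max),
    calibration_quantile = as.numeric(calibration_quantile),
    rrho_step_fraction = as.numeric(rrho_step_fraction),
    ora_alpha = as.numeric(ora_alpha),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "coexmeta_config"
  cfg
}

validate_config <- function(cfg) {
  in01 <- function(x) is.finite(x) && x > 0 && x <= 1
  stopifnot(
    "alpha_meta must be in (0,1]" = in01(cfg$alpha_meta),
    "lfc_min must be non-negative" = is.finite(cfg$lfc_min) && cfg$lfc_min >= 0,
    "min_module_size must be >= 2" = cfg$min_module_size >= 2L,
    "merge_cor_min must be in (0,1]" = in01(cfg$merge_cor_min),
    "hub_percentile must be in (0,1]" = in01(cfg$hub_percentile),
    "scale_free_r2_min must be in (0,1]" = in01(cfg$scale_free_r2_min),
    "beta_max must be >= 1" = cfg$beta_max >= 1L,
    "calibration_quantile must be in (0,1]" = in01(cfg$calibration_quantile),
    "rrho_step_fraction must be in (0,1]" = in01(cfg$rrho_step_fraction),
    "ora_alpha must be in (0,1]" = in01(cfg$ora_alpha)
  )
  invisible(cfg)
}

#' Read a configuration file
#'
#' The configuration file is a flat `key: value` text file; keys match the
#' arguments of [pipeline_config()]. Values passed through `...` override
#' values from the file, which in turn override the defaults.
#'
#' @param path path to the config file, or `NULL` for defaults only.
#' @param ... named overrides applied on top of file values.
#' @return A `coexmeta_config` object.
#' @export
read_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(kv) < 2) stop("malformed config line: ", ln)
      key <- trimws(kv[1])
      if (!key %in% names(formals(pipeline_config)))
        stop("unknown config key: ", key)
      vals[[key]] <- as.numeric(trimws(paste(kv[-1], collapse = ":")))
    }
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Write a configuration file
#'
#' @param cfg a `coexmeta_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "coexmeta_config"))
  writeLines(sprintf("%s: %.15g", names(cfg), unlist(cfg)), path)
  invisible(path)
}

#' @export
print.coexmeta_config <- function(x, ...) {
  cat("coexmeta pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-22s %g\n", k, x[[k]]))
  invisible(x)
}
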