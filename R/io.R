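#' Expression dataset constructor
#'
#' Bundles one study's log2 expression matrix with its paired pre/post
#' design. Every subject must contribute exactly one pre and one post
#' sample; column order of `X` follows the sample sheet.
#'
#' @param dataset_id study identifier.
#' @param condition one of `"disuse"`, `"young_RET"`, `"older_RET"`,
#'   `"other"`.
#' @param X numeric matrix, genes in rows (rownames = gene IDs), samples in
#'   columns (colnames = sample IDs), log2 scale.
#' @param samples data frame with columns `sample_id`, `subject_id`,
#'   `timepoint` (`"pre"`/`"post"`).
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, condition, X, samples) {
  condition <- match.arg(condition, c("disuse", "young_RET", "older_RET", "other"))
  stopifnot(is.matrix(X), is.numeric(X),
            !is.null(rownames(X)), !is.null(colnames(X)),
            all(c("sample_id", "subject_id", "timepoint") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  samples$subject_id <- as.character(samples$subject_id)
  samples$timepoint <- as.character(samples$timepoint)
  if (anyDuplicated(rownames(X)))
    stop("duplicate gene ID: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  if (!all(samples$timepoint %in% c("pre", "post")))
    stop("timepoint must be 'pre' or 'post'")
  missing_in_matrix <- setdiff(samples$sample_id, colnames(X))
  if (length(missing_in_matrix))
    stop("samples in sheet missing from matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  extra_in_matrix <- setdiff(colnames(X), samples$sample_id)
  if (length(extra_in_matrix))
    stop("samples in matrix missing from sheet: ",
         paste(extra_in_matrix, collapse = ", "))
  tab <- table(samples$subject_id, samples$timepoint)
  bad <- rownames(tab)[tab[, "pre", drop = TRUE] != 1 | tab[, "post", drop = TRUE] != 1]
  if (length(bad)) stop("unpaired subject ", paste(bad, collapse = ", "))
  if (anyNA(X)) stop("missing values in expression matrix")
  X <- X[, samples$sample_id, drop = FALSE]
  structure(list(dataset_id = as.character(dataset_id),
                 condition = condition,
                 genes = rownames(X),
                 X = X,
                 samples = samples),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s' (%s): %d genes x %d samples, %d subject pairs\n",
              x$dataset_id, x$condition, nrow(x$X), ncol(x$X),
              length(unique(x$samples$subject_id))))
  invisible(x)
}

#' Read an expression dataset from TSV files
#'
#' The matrix file is tab-delimited with gene IDs in the first column and a
#' header row of sample IDs. The sample sheet has columns `sample_id`,
#' `subject_id`, `timepoint`, `dataset_id`, `condition`.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param samplesheet_path path to the sample sheet TSV.
#' @return An `expression_dataset`.
#' @export
read_expression <- function(matrix_path, samplesheet_path) {
  sheet <- utils::read.delim(samplesheet_path, sep = "\t",
                             colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "subject_id", "timepoint", "dataset_id", "condition")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  tab <- utils::read.delim(matrix_path, sep = "\t", check.names = FALSE,
                           colClasses = c("character"), header = TRUE)
  gene_ids <- tab[[1]]
  X <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- gene_ids
  expression_dataset(dataset_id = sheet$dataset_id[1],
                     condition = sheet$condition[1],
                     X = X, samples = sheet)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]; the round trip preserves values to full
#' double precision (`%.17g`).
#'
#' @param ds an `expression_dataset`.
#' @param matrix_path output path for the matrix TSV.
#' @param samplesheet_path output path for the sample sheet TSV.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(ds, matrix_path, samplesheet_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene_id = rownames(ds$X),
                   format(as.data.frame(ds$X), digits = 17, trim = TRUE,
                          scientific = NA),
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- ds$samples
  sheet$dataset_id <- ds$dataset_id
  sheet$condition <- ds$condition
  utils::write.table(sheet, samplesheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-delimited as
#' `term<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are collapsed.
#'
#' @param path path to the GMT file.
#' @return A `gene_set_collection`: named list of `list(description, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    sets[[fields[1]]] <- list(description = fields[2],
                              genes = unique(fields[-(1:2)]))
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a run report
#'
#' Records the configuration, seed and per-stage summaries as JSON for
#' provenance.
#'
#' @param report named list of report entries.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Write a data.frame as TSV with full precision; round-trips to 12+ sig digits.
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
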