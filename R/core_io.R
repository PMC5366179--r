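#' Validate an expression matrix
#'
#' The package-wide convention is genes in rows and samples in columns, with
#' unique identifiers as dimnames, numeric values on the log2 scale (after
#' preprocessing) and no missing values.
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
  }
  invisible(x)
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample ids and gene ids
#' in the first column ('.' decimal separator, UTF-8, no quoting). Duplicate
#' ids and non-numeric cells are errors; the offending location is named.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (genes x samples) with dimnames.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("expression TSV must have gene ids plus >=1 sample column")
  gene_ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 gene_ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  rownames(num) <- gene_ids
  validate_expression_matrix(num)
  message(sprintf("read expression matrix: %d genes x %d samples",
                  nrow(num), ncol(num)))
  num
}

#' Write an expression matrix to TSV
#'
#' @param x Expression matrix (genes x samples).
#' @param path Output path.
#' @param digits Significant digits retained (default 10; round-trips through
#'   [read_expression_matrix()] reproduce values to this precision).
#' @export
write_expression_matrix <- function(x, path, digits = 10) {
  validate_expression_matrix(x)
  out <- data.frame(gene_id = rownames(x),
                    signif(x, digits = digits),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' Columns `sample_id`, `subtype`, `batch` are required; `main_class` is
#' derived (never stored) via [merge_to_main_classes()].
#'
#' @param path Path to the TSV file.
#' @return Data frame with character columns `sample_id`, `subtype`, `batch`.
#' @export
read_sample_annotation <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "subtype", "batch")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicated sample_id in annotation: ",
         ann$sample_id[duplicated(ann$sample_id)][1L])
  ann[need]
}

#' Write a sample annotation table to TSV
#' @param annotation Data frame with `sample_id`, `subtype`, `batch`.
#' @param path Output path.
#' @export
write_sample_annotation <- function(annotation, path) {
  write.table(annotation[c("sample_id", "subtype", "batch")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Merge subtypes into main disease classes
#'
#' Adds (or recomputes) a `main_class` column as the deterministic function
#' of `subtype` given by `class_map`. The number of rows is preserved and
#' the operation is idempotent.
#'
#' @param annotation Sample annotation data frame with a `subtype` column.
#' @param class_map Named character vector mapping subtype to main class;
#'   defaults to the 18-subtype leukaemia mapping of [main_class_map()].
#' @return `annotation` with a `main_class` column.
#' @export
#' @examples
#' ann <- data.frame(sample_id = c("s1", "s2"),
#'                   subtype = c("T-ALL", "CML"), batch = "b1")
#' merge_to_main_classes(ann)$main_class
merge_to_main_classes <- function(annotation, class_map = main_class_map()) {
  if (!"subtype" %in% names(annotation)) stop("annotation lacks a 'subtype' column")
  unknown <- setdiff(unique(annotation$subtype), names(class_map))
  if (length(unknown))
    stop("unknown subtype label(s): ", paste(unknown, collapse = ", "))
  annotation$main_class <- unname(class_map[annotation$subtype])
  annotation
}

#' Check that matrix and annotation describe the same samples
#' @param x Expression matrix.
#' @param annotation Sample annotation data frame.
#' @return Annotation reordered to the matrix column order.
#' @export
align_annotation <- function(x, annotation) {
  if (!setequal(colnames(x), annotation$sample_id))
    stop("matrix sample ids and annotation sample_id do not match")
  annotation[match(colnames(x), annotation$sample_id), , drop = FALSE]
}

#' Analysis configuration
#'
#' Bundles the significance level, the master seed and per-stage options used
#' by [run_pipeline()].
#'
#' @param alpha Per-gene significance level in (0, 1); default 0.05.
#' @param seed Master integer seed.
#' @param filter List: `k_range` for mixture order selection, `n_keep`
#'   highest-amplitude components retained.
#' @param test List: `branch` one of "auto", "parametric", "nonparametric";
#'   `control` label of the reference class.
#' @param cv List: `k` folds, `reps` repetitions, `n_top` for the t-test
#'   baseline, `r_threshold` decorrelation cutoff.
#' @return List of class `"analysis_config"`.
#' @export
analysis_config <- function(alpha = 0.05, seed = 1L,
                            filter = list(k_range = 1:6, n_keep = 3L),
                            test = list(branch = "auto", control = "CTR"),
                            cv = list(k = 30L, reps = 3L, n_top = 100L,
                                      r_threshold = 0.5)) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  structure(list(alpha = alpha, seed = as.integer(seed),
                 filter = filter, test = test, cv = cv),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#' @param path Path to a YAML file whose top-level keys match the arguments
#'   of [analysis_config()].
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- analysis_config()
  for (nm in intersect(names(y), c("filter", "test", "cv")))
    defaults[[nm]][names(y[[nm]])] <- y[[nm]]
  do.call(analysis_config, c(y[intersect(names(y), c("alpha", "seed"))],
                             defaults[c("filter", "test", "cv")]))
}
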