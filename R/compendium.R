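# Shared data model: an expression compendium is a nonnegative gene x sample
# matrix of normalized expression plus one annotation row per sample.

#' Construct an expression compendium
#'
#' An expression compendium holds normalized expression values (nonnegative,
#' unitless "normalized fluorescence units") for a set of genes (or probe
#' sets) across annotated samples. It is the substrate of all screening and
#' profiling operations in this package. Values live on their native linear
#' scale; any log transform happens inside consuming operations.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty row and column names. All values must be finite and
#'   `>= 0`. A data frame whose first column is `gene_id` is also accepted.
#' @param annotations Data frame with one row per sample and columns
#'   `sample_id`, `tissue`, `condition`, `genotype`, `timepoint_h`,
#'   `replicate`. Every column of `values` must have exactly one matching
#'   annotation row; annotation rows for samples absent from the matrix are
#'   an error.
#' @param scale_tag Single string identifying the measurement scale of the
#'   compendium (e.g. the source platform). Anchor thresholds carry the same
#'   tag and classification refuses to mix scales.
#'
#' @return An object of class `expression_compendium`: a list with elements
#'   `values` (the matrix), `annotations` (a tibble, ordered as the matrix
#'   columns) and `scale_tag`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ann <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "seedling",
#'                       condition = c("control", "heat"), genotype = "wt",
#'                       timepoint_h = c(0, 2), replicate = 1L)
#' expression_compendium(m, ann)
#' @export
expression_compendium <- function(values, annotations, scale_tag = "unspecified") {
  if (is.data.frame(values)) {
    if (!identical(names(values)[1], "gene_id")) {
      abort("first column of a data-frame `values` must be 'gene_id'",
            class = "promscreen_format_error")
    }
    m <- as.matrix(values[-1])
    rownames(m) <- as.character(values[[1]])
    storage.mode(m) <- "double"
    values <- m
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix", class = "promscreen_format_error")
  }
  annotations <- as_tibble(annotations)
  x <- structure(
    list(values = values, annotations = annotations,
         scale_tag = as.character(scale_tag)[1]),
    class = "expression_compendium"
  )
  validate_compendium(x)
}

#' Validate an expression compendium
#'
#' Checks every invariant of the data model: nonnegative finite values, no
#' duplicate gene or sample identifiers, at least one sample, and a
#' one-to-one correspondence between matrix columns and annotation rows.
#' Annotations are reordered to follow the matrix column order.
#'
#' @param x An `expression_compendium`.
#' @return `x`, invisibly validated (annotations ordered as matrix columns).
#' @export
validate_compendium <- function(x) {
  v <- x$values
  ann <- x$annotations
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    abort("matrix must carry gene and sample identifiers",
          class = "promscreen_format_error")
  }
  if (ncol(v) < 1L) {
    abort("a compendium needs at least one sample",
          class = "promscreen_format_error")
  }
  if (anyDuplicated(rownames(v))) {
    abort(paste0("duplicate gene identifiers: ",
                 paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")),
          class = "promscreen_format_error")
  }
  if (anyDuplicated(colnames(v))) {
    abort(paste0("duplicate sample identifiers: ",
                 paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")),
          class = "promscreen_format_error")
  }
  bad <- which(!is.finite(v) | v < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(v))
    abort(sprintf("invalid expression value at gene '%s', sample '%s' (%s)",
                  rownames(v)[i[1]], colnames(v)[i[2]],
                  format(v[bad[1]])),
          class = "promscreen_format_error")
  }
  req <- c("sample_id", "tissue", "condition", "genotype", "timepoint_h", "replicate")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    abort(paste0("annotation table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "promscreen_format_error")
  }
  if (anyDuplicated(ann$sample_id)) {
    abort("duplicate sample_id in annotations", class = "promscreen_format_error")
  }
  unannotated <- setdiff(colnames(v), ann$sample_id)
  if (length(unannotated)) {
    abort(paste0("sample(s) without annotation: ", paste(unannotated, collapse = ", ")),
          class = "promscreen_consistency_error")
  }
  orphan <- setdiff(ann$sample_id, colnames(v))
  if (length(orphan)) {
    abort(paste0("annotation row(s) for unknown sample(s): ",
                 paste(orphan, collapse = ", ")),
          class = "promscreen_consistency_error")
  }
  if (any(!nzchar(ann$tissue)) || any(!nzchar(ann$condition))) {
    abort("tissue and condition labels must be nonempty",
          class = "promscreen_format_error")
  }
  if (any(ann$timepoint_h < 0)) {
    abort("timepoint_h must be >= 0", class = "promscreen_format_error")
  }
  if (any(ann$replicate < 1)) {
    abort("replicate must be a positive integer", class = "promscreen_format_error")
  }
  x$annotations <- ann[match(colnames(v), ann$sample_id), , drop = FALSE]
  x
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("<expression_compendium> %d genes x %d samples (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  cat("conditions:", paste(unique(x$annotations$condition), collapse = ", "), "\n")
  cat("tissues:   ", paste(utils::head(unique(x$annotations$tissue), 8), collapse = ", "),
      if (length(unique(x$annotations$tissue)) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.expression_compendium <- function(x) dim(x$values)

#' Long-format view of a compendium
#'
#' @param x An `expression_compendium`.
#' @param ... Unused.
#' @return A tibble with one row per (gene, sample) cell, joined with the
#'   sample annotations.
#' @export
as_tibble.expression_compendium <- function(x, ...) {
  long <- tibble(
    gene_id   = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    expression = as.vector(x$values)
  )
  left_join(long, x$annotations, by = "sample_id")
}

# ---------------------------------------------------------------------------
# Readers / writers

#' Read a tab-separated expression matrix
#'
#' Low-level tolerant reader used by [read_compendium()]. Expects a UTF-8,
#' tab-delimited table whose first column (named `gene_id`) holds gene or
#' probe identifiers and whose header row holds sample identifiers. With
#' `geo_style = TRUE`, comment lines starting with `!` (as in GEO
#' series-matrix exports) are skipped.
#'
#' @param path Path to the TSV file.
#' @param geo_style Skip `!`-prefixed metadata lines before parsing.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path, geo_style = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "promscreen_io_error")
  }
  df <- readr::read_tsv(path, comment = if (geo_style) "!" else "",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2L) {
    abort("matrix file needs a gene_id column plus at least one sample",
          class = "promscreen_format_error")
  }
  gene_ids <- df[[1]]
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(gene_ids, names(df)[-1]))
  for (j in seq_len(ncol(df) - 1L)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num))
    if (length(bad)) {
      abort(sprintf("non-numeric or missing value at gene '%s', sample '%s': '%s'",
                    gene_ids[bad[1]], names(df)[j + 1L],
                    ifelse(is.na(raw[bad[1]]), "NA", raw[bad[1]])),
            class = "promscreen_format_error")
    }
    m[, j] <- num
  }
  m
}

#' Read an expression compendium from matrix + annotation files
#'
#' The matrix file is tab-separated with gene identifiers in the first
#' column (header `gene_id`) and sample identifiers in the header row. The
#' annotation file is tab-separated with columns `sample_id`, `tissue`,
#' `condition`, `genotype`, `timepoint_h`, `replicate`. Sample order follows
#' the matrix header. Missing values are rejected, not imputed.
#'
#' @inheritParams read_matrix_tsv
#' @param matrix_path Path to the expression matrix TSV.
#' @param annotation_path Path to the sample annotation TSV.
#' @param scale_tag Scale identifier recorded on the compendium.
#' @return A validated [expression_compendium()].
#' @examples
#' td <- tempfile(); dir.create(td)
#' m <- matrix(c(0.1, 5, 0.2, 6), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ann <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "seedling",
#'                       condition = c("control", "heat"), genotype = "wt",
#'                       timepoint_h = c(0, 2), replicate = 1L)
#' cc <- expression_compendium(m, ann)
#' write_compendium(cc, file.path(td, "m.tsv"), file.path(td, "ann.tsv"))
#' read_compendium(file.path(td, "m.tsv"), file.path(td, "ann.tsv"))
#' @export
read_compendium <- function(matrix_path, annotation_path, geo_style = FALSE,
                            scale_tag = "unspecified") {
  m <- read_matrix_tsv(matrix_path, geo_style = geo_style)
  ann <- readr::read_tsv(annotation_path, progress = FALSE, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           tissue = readr::col_character(),
                           condition = readr::col_character(),
                           genotype = readr::col_character(),
                           timepoint_h = readr::col_double(),
                           replicate = readr::col_integer()
                         ))
  expression_compendium(m, ann, scale_tag = scale_tag)
}

# Fixed rendering used by all writers so reruns are byte-identical.
# 15 significant digits round-trips doubles in practice for this data.
format_num <- function(x, digits = 15L) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- format(v, digits = digits, scientific = FALSE, trim = TRUE)
    s
  }, character(1))
  out
}

#' Write a tabular report as TSV
#'
#' Tab-separated, UTF-8, LF line endings, header row always present.
#' Floating-point columns are rendered with a fixed precision (15
#' significant digits, no scientific notation) so that repeated runs on the
#' same records produce byte-identical files.
#'
#' @param records Data frame with named columns (may have zero rows).
#' @param path Output path.
#' @param digits Significant digits used for numeric columns.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, digits = 15L) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rendered <- records
  for (j in seq_along(rendered)) {
    if (is.double(rendered[[j]])) rendered[[j]] <- format_num(rendered[[j]], digits)
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    abort(paste0("cannot open for writing: ", path), class = "promscreen_io_error")
  })
  on.exit(close(con))
  lines <- c(paste(names(rendered), collapse = "\t"))
  if (nrow(rendered)) {
    body <- do.call(paste, c(lapply(rendered, as.character), sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write an expression compendium to matrix + annotation TSV files
#'
#' Inverse of [read_compendium()]: `read(write(x))` reproduces `x` field by
#' field at the rendered precision.
#'
#' @param x An `expression_compendium`.
#' @param matrix_path,annotation_path Output paths.
#' @param digits Significant digits for expression values.
#' @return `x`, invisibly.
#' @export
write_compendium <- function(x, matrix_path, annotation_path, digits = 15L) {
  df <- data.frame(gene_id = rownames(x$values),
                   as.data.frame(x$values, check.names = FALSE),
                   check.names = FALSE)
  write_report(df, matrix_path, digits = digits)
  write_report(x$annotations, annotation_path, digits = digits)
  invisible(x)
}
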