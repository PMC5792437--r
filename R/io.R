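#' Construct a validated expression matrix
#'
#' Container for a genes x samples FPKM matrix together with its progression
#' design: every sample belongs to exactly one cell line and the cell lines
#' form an explicit ordered series (parental first).
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names. All values must be finite and non-negative.
#' @param design `data.frame` with columns `sample_id`, `cell_line`,
#'   `replicate`; one row per sample column of `values`.
#' @param line_order Character vector giving the total order of the cell
#'   lines. Defaults to order of first appearance in `design`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `design` and `line_order`.
#' @export
expression_matrix <- function(values, design, line_order = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate or missing gene ids",
         if (length(dup)) paste0(": ", paste(utils::head(dup, 3L), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate or missing sample ids", call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("negative or non-finite FPKM at gene '%s', sample '%s'",
                 rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]),
         call. = FALSE)
  }
  req <- c("sample_id", "cell_line", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design))) {
    stop("`design` must have columns sample_id, cell_line, replicate",
         call. = FALSE)
  }
  design <- design[, req]
  design$sample_id <- as.character(design$sample_id)
  design$cell_line <- as.character(design$cell_line)
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample ids in the sample sheet", call. = FALSE)
  }
  missing_in_matrix <- setdiff(design$sample_id, colnames(values))
  if (length(missing_in_matrix)) {
    stop("sample sheet references samples absent from the matrix: ",
         paste(missing_in_matrix, collapse = ", "), call. = FALSE)
  }
  missing_in_sheet <- setdiff(colnames(values), design$sample_id)
  if (length(missing_in_sheet)) {
    stop("matrix samples missing from the sample sheet: ",
         paste(missing_in_sheet, collapse = ", "), call. = FALSE)
  }
  if (is.null(line_order)) line_order <- unique(design$cell_line)
  if (!setequal(line_order, unique(design$cell_line)) ||
      anyDuplicated(line_order)) {
    stop("`line_order` must be a permutation of the cell lines in the design",
         call. = FALSE)
  }
  design <- design[match(colnames(values), design$sample_id), ]
  rownames(design) <- NULL
  structure(list(values = values, design = design,
                 line_order = as.character(line_order)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  reps <- table(x$design$cell_line)[x$line_order]
  cat("Line order:", paste(sprintf("%s (n=%d)", x$line_order, reps),
                           collapse = " -> "), "\n")
  invisible(x)
}

#' Samples belonging to one cell line
#' @param expr An [expression_matrix()].
#' @param line Cell line name.
#' @return Character vector of sample ids.
#' @keywords internal
line_samples <- function(expr, line) {
  if (!line %in% expr$line_order) {
    stop(sprintf("cell line '%s' not present in the design", line),
         call. = FALSE)
  }
  expr$design$sample_id[expr$design$cell_line == line]
}

# Accept decimal commas ("0,4972") in expression tables; reject anything
# else that does not parse as a plain non-scientific-or-scientific numeric.
parse_fpkm <- function(x, what = "value") {
  x0 <- trimws(as.character(x))
  x1 <- sub(",", ".", x0, fixed = TRUE)
  out <- suppressWarnings(as.numeric(x1))
  bad <- which(is.na(out) & !is.na(x0) & nzchar(x0))
  if (length(bad)) {
    stop(sprintf("malformed numeric %s: '%s'", what, x0[bad[1L]]),
         call. = FALSE)
  }
  if (anyNA(out)) {
    stop(sprintf("missing %s in expression table", what), call. = FALSE)
  }
  out
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix file is a TSV whose first column is `gene_id`, followed by one
#' column per sample. Decimal commas (as printed in some publication tables,
#' e.g. `0,4972`) are accepted in expression cells and normalized to dot
#' decimals. The sample sheet is a TSV with columns `sample_id`, `cell_line`,
#' `replicate` and optionally `line_order` (an integer rank per cell line);
#' without it, lines are ordered by first appearance.
#'
#' @param path_matrix Path to the expression TSV.
#' @param path_sample_sheet Path to the sample-sheet TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path_matrix, path_sample_sheet) {
  mat <- utils::read.delim(path_matrix, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(mat) < 2L || names(mat)[1L] != "gene_id") {
    stop("expression matrix must start with a 'gene_id' column followed by samples",
         call. = FALSE)
  }
  if (nrow(mat) == 0L) stop("expression matrix is empty", call. = FALSE)
  genes <- mat$gene_id
  values <- vapply(mat[-1L], parse_fpkm, numeric(nrow(mat)))
  values <- matrix(values, nrow = nrow(mat),
                   dimnames = list(genes, names(mat)[-1L]))
  sheet <- utils::read.delim(path_sample_sheet, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  req <- c("sample_id", "cell_line", "replicate")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns sample_id, cell_line, replicate",
         call. = FALSE)
  }
  line_order <- NULL
  if ("line_order" %in% names(sheet)) {
    ord <- unique(sheet[, c("cell_line", "line_order")])
    if (anyDuplicated(ord$cell_line)) {
      stop("inconsistent line_order for a cell line in the sample sheet",
           call. = FALSE)
    }
    line_order <- ord$cell_line[order(ord$line_order)]
  }
  expression_matrix(values, sheet, line_order)
}

#' Write an expression matrix and its sample sheet
#'
#' Inverse of [read_expression()]; output is deterministic (genes and samples
#' in stored order, dot decimals).
#'
#' @param expr An [expression_matrix()].
#' @param path_matrix,path_sample_sheet Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(expr, path_matrix, path_sample_sheet) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path_matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- expr$design
  sheet$line_order <- match(sheet$cell_line, expr$line_order)
  utils::write.table(sheet, path_sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path_matrix, path_sample_sheet))
}

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, `name TAB description TAB gene ...`.
#' Duplicate genes within one set are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (pathway id -> gene ids). The
#'   descriptions are kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("GMT parse error at line %d: fewer than 3 fields",
                 which(nf < 3L)[1L]), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id in GMT: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, character(1L), 2L), ids)
  sets
}

#' Write pathway gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions;
#'   defaults to the pathway id.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions)) {
      descriptions[[id]]
    } else id
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pathway-to-hallmark map
#'
#' TSV with columns `pathway_id` and `hallmark`. A pathway may map to several
#' hallmarks; repeated pairs are collapsed.
#'
#' @param path Path to the TSV.
#' @param vocabulary Allowed hallmark names; defaults to [cogex_hallmarks()].
#' @param allow_unknown If `TRUE`, hallmark names outside the vocabulary are
#'   accepted instead of raising an error.
#' @return `data.frame` with columns `pathway_id`, `hallmark` (unique pairs).
#' @export
read_hallmark_map <- function(path, vocabulary = cogex_hallmarks(),
                              allow_unknown = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "hallmark") %in% names(df))) {
    stop("hallmark map must have columns pathway_id, hallmark", call. = FALSE)
  }
  df <- df[, c("pathway_id", "hallmark")]
  if (!allow_unknown) {
    unknown <- setdiff(unique(df$hallmark), vocabulary)
    if (length(unknown)) {
      stop("unknown hallmark name(s): ", paste(unknown, collapse = ", "),
           "; pass allow_unknown = TRUE to override", call. = FALSE)
    }
  }
  df <- unique(df)
  df <- df[order(df$pathway_id, df$hallmark), ]
  rownames(df) <- NULL
  df
}

#' Write a pathway-to-hallmark map
#' @param map `data.frame` with columns `pathway_id`, `hallmark`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hallmark_map <- function(map, path) {
  utils::write.table(map[, c("pathway_id", "hallmark")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle pathways and their hallmark map
#'
#' @param pathways Named list of gene sets (as from [read_gmt()]).
#' @param hallmark_map `data.frame` with columns `pathway_id`, `hallmark`
#'   (as from [read_hallmark_map()]).
#' @param vocabulary Allowed hallmark names.
#' @return Object of class `HallmarkAnnotation`: list with elements
#'   `pathways`, `map`, `vocabulary`.
#' @export
hallmark_annotation <- function(pathways, hallmark_map,
                                vocabulary = cogex_hallmarks()) {
  if (!all(c("pathway_id", "hallmark") %in% names(hallmark_map))) {
    stop("hallmark_map must have columns pathway_id, hallmark", call. = FALSE)
  }
  orphan <- setdiff(unique(hallmark_map$pathway_id), names(pathways))
  if (length(orphan)) {
    stop("hallmark map references unknown pathway(s): ",
         paste(utils::head(orphan, 3L), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(hallmark_map$hallmark), vocabulary)
  if (length(unknown)) {
    stop("hallmark name(s) outside vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  map <- unique(hallmark_map[, c("pathway_id", "hallmark")])
  map <- map[order(map$pathway_id, map$hallmark), ]
  rownames(map) <- NULL
  structure(list(pathways = pathways, map = map, vocabulary = vocabulary),
            class = "HallmarkAnnotation")
}

#' @export
print.HallmarkAnnotation <- function(x, ...) {
  cat(sprintf("HallmarkAnnotation: %d pathways, %d pathway-hallmark pairs, %d hallmarks\n",
              length(x$pathways), nrow(x$map),
              length(unique(x$map$hallmark))))
  invisible(x)
}
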