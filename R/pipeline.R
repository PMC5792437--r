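#' Run the full progression analysis
#'
#' Executes the pipeline over an ordered series of cell lines: (1) one
#' [compare_lines()] per successive transition; (2) one [assign_coge()] table
#' per focal transition (every transition that has a predecessor — the first
#' transition only serves as the reference for the second); (3)
#' [find_consistent_genes()] over the focal transitions; (4) when an
#' annotation is supplied, per-comparison hallmark gene sets on the CoGE gene
#' universe, [relative_contribution()] tables, their [aggregate_and_rank()]
#' summary, and a genome-wide [absolute_contribution()] table.
#'
#' @param expr An [expression_matrix()] with >= 3 cell lines.
#' @param annotation Optional [hallmark_annotation()].
#' @param alpha Significance level (default 0.05).
#' @param mode `"p"` or `"q"` DEG calling.
#' @param ratio_low,ratio_high Fold-change thresholds (defaults 0.8, 1.2).
#' @param reference Reference hallmark.
#' @param continuum_requires_prev Passed to [assign_coge()].
#' @param welch,min_expression Passed to [compare_lines()].
#' @return Object of class `cogex_results`: list with `comparisons`, `coge`,
#'   `consistent`, `absolute`, `relative`, `contribution_summary`, `params`.
#' @export
run_pipeline <- function(expr, annotation = NULL, alpha = 0.05,
                         mode = c("p", "q"), ratio_low = 0.8,
                         ratio_high = 1.2,
                         reference = "invasion and metastasis",
                         continuum_requires_prev = FALSE, welch = FALSE,
                         min_expression = NULL) {
  mode <- match.arg(mode)
  lines <- expr$line_order
  if (length(lines) < 3L) {
    stop("the progression series needs at least 3 cell lines", call. = FALSE)
  }
  comparisons <- lapply(seq_len(length(lines) - 1L), function(i) {
    compare_lines(expr, lines[i], lines[i + 1L], alpha = alpha, mode = mode,
                  ratio_low = ratio_low, ratio_high = ratio_high,
                  welch = welch, min_expression = min_expression)
  })
  names(comparisons) <- paste(lines[-length(lines)], "vs", lines[-1L])

  coge <- lapply(seq_along(comparisons)[-1L], function(i) {
    assign_coge(comparisons[[i - 1L]], comparisons[[i]],
                continuum_requires_prev = continuum_requires_prev)
  })
  names(coge) <- names(comparisons)[-1L]

  focal <- comparisons[-1L]
  consistent <- if (length(focal) >= 2L) {
    find_consistent_genes(focal, mode = mode)
  } else {
    find_consistent_genes(comparisons, mode = mode)
  }

  absolute <- relative <- contribution_summary <- NULL
  if (!is.null(annotation)) {
    genome_sets <- build_hallmark_sets(annotation,
                                       universe = rownames(expr$values),
                                       reference = reference)
    absolute <- absolute_contribution(genome_sets)
    relative <- lapply(coge, function(ct) {
      universe <- ct$gene_id[!is.na(ct$cluster)]
      sets <- build_hallmark_sets(annotation, universe = universe,
                                  reference = reference)
      relative_contribution(sets, ct)
    })
    contribution_summary <- aggregate_and_rank(relative)
  }

  structure(list(comparisons = comparisons, coge = coge,
                 consistent = consistent, absolute = absolute,
                 relative = relative,
                 contribution_summary = contribution_summary,
                 params = list(alpha = alpha, mode = mode,
                               ratio_low = ratio_low,
                               ratio_high = ratio_high,
                               reference = reference,
                               continuum_requires_prev = continuum_requires_prev,
                               welch = welch,
                               min_expression = min_expression,
                               line_order = lines)),
            class = "cogex_results")
}

#' Write pipeline results to a directory
#'
#' Writes the standard result files with deterministic column order and row
#' sort (by pair then gene id / hallmark): `deg_table.tsv`, `coge_table.tsv`,
#' `consistent_genes.tsv`, and when hallmark results are present
#' `contributions_absolute.csv`, `contributions_relative.csv`,
#' `contributions_summary.csv`, plus a `summary.json` run summary (parameter
#' echo, package version, per-stage counts). Two calls on the same results
#' produce byte-identical files.
#'
#' @param results A [run_pipeline()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, character vector of written paths.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }

  deg <- do.call(rbind, lapply(results$comparisons, function(cmp) {
    df <- as.data.frame(cmp)
    df <- data.frame(gene_id = df$gene_id,
                     parental = attr(cmp, "parental"),
                     derived = attr(cmp, "derived"),
                     df[, c("mean_parental", "mean_derived", "ratio",
                            "p_value", "q_value", "deg_p", "deg_q", "label")],
                     stringsAsFactors = FALSE)
    df[order(df$gene_id), ]
  }))
  rownames(deg) <- NULL
  paths <- c(paths, wtsv(deg, "deg_table.tsv"))

  coge <- do.call(rbind, lapply(names(results$coge), function(nm) {
    ct <- results$coge[[nm]]
    df <- data.frame(gene_id = ct$gene_id, focal_pair = nm,
                     cluster = ifelse(is.na(ct$cluster), "", ct$cluster),
                     stringsAsFactors = FALSE)
    df[order(df$gene_id), ]
  }))
  rownames(coge) <- NULL
  paths <- c(paths, wtsv(coge, "coge_table.tsv"))

  paths <- c(paths, wtsv(as.data.frame(results$consistent),
                         "consistent_genes.tsv"))

  if (!is.null(results$absolute)) {
    paths <- c(paths, wcsv(results$absolute, "contributions_absolute.csv"))
    rel <- do.call(rbind, lapply(names(results$relative), function(nm) {
      tab <- results$relative[[nm]]
      data.frame(comparison = nm, tab, stringsAsFactors = FALSE)
    }))
    rownames(rel) <- NULL
    paths <- c(paths, wcsv(rel, "contributions_relative.csv"))
    cs <- results$contribution_summary
    summary_df <- merge(cs$per_comparison, cs$overall, by = "hallmark")
    summary_df <- summary_df[order(summary_df$hallmark,
                                   summary_df$comparison), ]
    rownames(summary_df) <- NULL
    paths <- c(paths, wcsv(summary_df, "contributions_summary.csv"))
  }

  meta <- list(
    package = "cogex",
    version = as.character(utils::packageVersion("cogex")),
    params = results$params,
    counts = list(
      genes = nrow(results$comparisons[[1L]]),
      comparisons = length(results$comparisons),
      deg_p = vapply(results$comparisons, function(x) sum(x$deg_p),
                     integer(1L)),
      deg_q = vapply(results$comparisons, function(x) sum(x$deg_q),
                     integer(1L)),
      coge_assigned = vapply(results$coge,
                             function(x) sum(!is.na(x$cluster)), integer(1L)),
      consistent_genes = nrow(results$consistent)
    )
  )
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
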