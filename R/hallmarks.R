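#' Build per-hallmark pathway and gene sets
#'
#' For each hallmark `h`, `P(h)` is the set of pathways annotated to it and
#' `G(h)` the union of those pathways' gene sets, optionally intersected with
#' a gene universe (all genes for a genome-wide analysis, the DEG set of a
#' comparison for per-comparison analyses). A gene belonging to pathways of
#' several hallmarks counts in each of them.
#'
#' @param annotation A [hallmark_annotation()].
#' @param universe Optional character vector restricting `G(h)`.
#' @param reference Reference hallmark name (default
#'   `"invasion and metastasis"`); must be in the annotation vocabulary.
#' @return Object of class `HallmarkGeneSets`: list with `pathways` and
#'   `genes` (named lists per hallmark, empty sets for hallmarks with no
#'   pathways), `hallmarks`, `reference`.
#' @export
build_hallmark_sets <- function(annotation, universe = NULL,
                                reference = "invasion and metastasis") {
  if (!inherits(annotation, "HallmarkAnnotation")) {
    stop("annotation must be a HallmarkAnnotation", call. = FALSE)
  }
  vocab <- annotation$vocabulary
  if (!reference %in% vocab) {
    stop(sprintf("unknown reference hallmark '%s'", reference), call. = FALSE)
  }
  paths <- lapply(stats::setNames(vocab, vocab), function(h) {
    sort(unique(annotation$map$pathway_id[annotation$map$hallmark == h]))
  })
  genes <- lapply(paths, function(ps) {
    g <- sort(unique(unlist(annotation$pathways[ps], use.names = FALSE)))
    if (is.null(g)) g <- character(0)
    if (!is.null(universe)) g <- intersect(g, universe)
    g
  })
  structure(list(pathways = paths, genes = genes, hallmarks = vocab,
                 reference = reference),
            class = "HallmarkGeneSets")
}

#' Absolute contribution of each hallmark to the reference hallmark
#'
#' Counts the pathways and genes each hallmark shares with the reference
#' hallmark (the intersections of a Venn diagram against the reference). The
#' reference's own row reports its totals.
#'
#' @param sets A [build_hallmark_sets()] result.
#' @return `data.frame` with columns `hallmark`, `n_pathways`, `n_genes`,
#'   `shared_pathways`, `shared_genes`.
#' @export
absolute_contribution <- function(sets) {
  ref_p <- sets$pathways[[sets$reference]]
  ref_g <- sets$genes[[sets$reference]]
  out <- data.frame(
    hallmark = sets$hallmarks,
    n_pathways = vapply(sets$pathways, length, integer(1L))[sets$hallmarks],
    n_genes = vapply(sets$genes, length, integer(1L))[sets$hallmarks],
    shared_pathways = vapply(sets$hallmarks, function(h) {
      length(intersect(sets$pathways[[h]], ref_p))
    }, integer(1L)),
    shared_genes = vapply(sets$hallmarks, function(h) {
      length(intersect(sets$genes[[h]], ref_g))
    }, integer(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Relative contribution of each hallmark per CoGE cluster
#'
#' For hallmark `h` and cluster `c`, `n(h, c)` is the number of the hallmark's
#' genes assigned to the cluster, and the percentage is the share of those
#' genes that also belong to the reference hallmark's gene set:
#' `pct = 100 * |G(h) & G(ref) & C(c)| / n(h, c)`; empty denominators give
#' `0.0` (not `NA`), so means over the 11 clusters are always defined. The
#' reference hallmark therefore scores 100 in every cluster where it has
#' genes.
#'
#' @param sets A [build_hallmark_sets()] result, built on the same gene
#'   universe as `coge`.
#' @param coge A [assign_coge()] table.
#' @return `data.frame` with columns `hallmark`, `cluster`, `n_genes`, `pct`
#'   (one row per hallmark x cluster, all 11 clusters always present);
#'   attribute `comparison` copies the focal pair name.
#' @export
relative_contribution <- function(sets, coge) {
  if (!inherits(coge, "CoGETable")) {
    stop("coge must be a CoGETable", call. = FALSE)
  }
  ref_g <- sets$genes[[sets$reference]]
  clusters <- coge_clusters()
  grid <- expand.grid(cluster = clusters, hallmark = sets$hallmarks,
                      stringsAsFactors = FALSE)[, c(2L, 1L)]
  cluster_genes <- lapply(stats::setNames(clusters, clusters), function(cl) {
    coge$gene_id[!is.na(coge$cluster) & coge$cluster == cl]
  })
  n <- integer(nrow(grid)); pct <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gh <- sets$genes[[grid$hallmark[i]]]
    gc <- intersect(gh, cluster_genes[[grid$cluster[i]]])
    n[i] <- length(gc)
    pct[i] <- if (n[i] > 0L) 100 * length(intersect(gc, ref_g)) / n[i] else 0
  }
  structure(
    data.frame(hallmark = grid$hallmark, cluster = grid$cluster,
               n_genes = n, pct = pct, stringsAsFactors = FALSE),
    comparison = attr(coge, "focal_pair"),
    reference = sets$reference
  )
}

#' Aggregate relative contributions and rank the hallmarks
#'
#' Per comparison, each hallmark's total percentage is the unweighted
#' arithmetic mean of its 11 cluster percentages; the overall figure is the
#' mean of the per-comparison totals. Hallmarks are ranked descending by the
#' overall mean, with the reference hallmark excluded from the ranking.
#'
#' @param relative_tables List of [relative_contribution()] tables, one per
#'   comparison, optionally named (names default to each table's
#'   `comparison` attribute).
#' @return Object of class `ContributionSummary`: list with `per_comparison`
#'   (`data.frame` comparison x hallmark mean pct) and `overall`
#'   (`data.frame` with `hallmark`, `overall_mean`, `rank`; rank `NA` for the
#'   reference).
#' @export
aggregate_and_rank <- function(relative_tables) {
  if (!length(relative_tables)) {
    stop("need at least one relative-contribution table", call. = FALSE)
  }
  if (is.null(names(relative_tables)) || any(!nzchar(names(relative_tables)))) {
    names(relative_tables) <- vapply(relative_tables, function(x) {
      cmp <- attr(x, "comparison")
      if (is.null(cmp)) "" else cmp
    }, character(1L))
  }
  reference <- attr(relative_tables[[1L]], "reference")
  hallmarks <- unique(relative_tables[[1L]]$hallmark)
  per_comp <- do.call(rbind, lapply(names(relative_tables), function(nm) {
    tab <- relative_tables[[nm]]
    agg <- tapply(tab$pct, tab$hallmark, mean)
    data.frame(comparison = nm, hallmark = hallmarks,
               mean_pct = as.numeric(agg[hallmarks]),
               stringsAsFactors = FALSE)
  }))
  overall_mean <- tapply(per_comp$mean_pct, per_comp$hallmark, mean)
  overall <- data.frame(hallmark = hallmarks,
                        overall_mean = as.numeric(overall_mean[hallmarks]),
                        stringsAsFactors = FALSE)
  rankable <- overall$hallmark != reference
  overall$rank <- NA_integer_
  overall$rank[rankable] <- rank(-overall$overall_mean[rankable],
                                 ties.method = "min")
  structure(list(per_comparison = per_comp, overall = overall,
                 reference = reference),
            class = "ContributionSummary")
}

#' @export
print.ContributionSummary <- function(x, ...) {
  cat(sprintf("ContributionSummary (reference: %s)\n", x$reference))
  ord <- order(x$overall$rank, na.last = FALSE)
  print(x$overall[ord, ], row.names = FALSE)
  invisible(x)
}
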