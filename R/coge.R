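#' Assign genes to the 11 clusters of gene expression
#'
#' Combines the direction labels of a gene in a predecessor comparison
#' (`prev`, e.g. SCC9 vs ZsG) and the focal comparison (`focal`, e.g. ZsG vs
#' LN1) into one of the 11 CoGE patterns. The two comparisons must be chained:
#' the derived line of `prev` is the parental line of `focal`.
#'
#' Precedence:
#' 1. focal label `EXCLUSIVE_PARENTAL` -> cluster `EXCLUSIVE_PARENTAL`;
#' 2. focal label `EXCLUSIVE_DERIVED` -> cluster `EXCLUSIVE_DERIVED`;
#' 3. focal label `CONTINUUM` -> cluster `CONTINUUM` (when
#'    `continuum_requires_prev = TRUE`, additionally only if the gene is
#'    regulated in `prev`);
#' 4. cross rules on the regulated labels `DOWN` / `UP`, where "not regulated"
#'    means any other label: (DOWN, not-reg) -> `EXCL_PARENTAL_DOWN`;
#'    (UP, not-reg) -> `EXCL_PARENTAL_UP`; (not-reg, DOWN) ->
#'    `EXCL_DERIVED_DOWN`; (not-reg, UP) -> `EXCL_DERIVED_UP`; (DOWN, DOWN) ->
#'    `COMMON_DOWN`; (UP, UP) -> `COMMON_UP`; (DOWN, UP) ->
#'    `COMMON_PDOWN_DUP`; (UP, DOWN) -> `COMMON_PUP_DDOWN`.
#'
#' Genes that are DEGs in neither comparison stay unassigned (`NA`), as do the
#' residual combinations the rules do not cover (a gene regulated only in
#' `prev` with an exclusive or continuum label there).
#'
#' @param prev,focal `ComparisonResult` objects sharing the middle cell line
#'   and computed in the same mode.
#' @param continuum_requires_prev Require predecessor DEG status for the
#'   `CONTINUUM` cluster (default `FALSE`).
#' @return `data.frame` of class `CoGETable` with columns `gene_id`,
#'   `cluster` (one of [coge_clusters()] or `NA`); attributes `focal_pair`,
#'   `prev_pair`, `mode`.
#' @export
assign_coge <- function(prev, focal, continuum_requires_prev = FALSE) {
  if (!inherits(prev, "ComparisonResult") || !inherits(focal, "ComparisonResult")) {
    stop("prev and focal must be ComparisonResult objects", call. = FALSE)
  }
  if (!identical(attr(prev, "derived"), attr(focal, "parental"))) {
    stop(sprintf("comparisons are not chained: prev derived '%s' != focal parental '%s'",
                 attr(prev, "derived"), attr(focal, "parental")), call. = FALSE)
  }
  if (!identical(attr(prev, "mode"), attr(focal, "mode"))) {
    stop("prev and focal were computed in different modes (p vs q)",
         call. = FALSE)
  }
  genes <- intersect(prev$gene_id, focal$gene_id)
  if (length(genes) == 0L) stop("no shared genes between comparisons",
                                call. = FALSE)
  lp <- prev$label[match(genes, prev$gene_id)]
  lf <- focal$label[match(genes, focal$gene_id)]
  cluster <- coge_decide(lp, lf, continuum_requires_prev)
  structure(
    data.frame(gene_id = genes, cluster = cluster, stringsAsFactors = FALSE),
    class = c("CoGETable", "data.frame"),
    focal_pair = paste(attr(focal, "parental"), "vs", attr(focal, "derived")),
    prev_pair = paste(attr(prev, "parental"), "vs", attr(prev, "derived")),
    mode = attr(focal, "mode")
  )
}

# Vectorized CoGE decision on a pair of direction-label vectors.
coge_decide <- function(lp, lf, continuum_requires_prev = FALSE) {
  stopifnot(length(lp) == length(lf))
  cluster <- rep.int(NA_character_, length(lp))
  prev_reg <- lp == "DOWN" | lp == "UP"
  focal_reg <- lf == "DOWN" | lf == "UP"
  cluster[prev_reg & !focal_reg & lp == "DOWN"] <- "EXCL_PARENTAL_DOWN"
  cluster[prev_reg & !focal_reg & lp == "UP"] <- "EXCL_PARENTAL_UP"
  cluster[!prev_reg & focal_reg & lf == "DOWN"] <- "EXCL_DERIVED_DOWN"
  cluster[!prev_reg & focal_reg & lf == "UP"] <- "EXCL_DERIVED_UP"
  cluster[lp == "DOWN" & lf == "DOWN"] <- "COMMON_DOWN"
  cluster[lp == "UP" & lf == "UP"] <- "COMMON_UP"
  cluster[lp == "DOWN" & lf == "UP"] <- "COMMON_PDOWN_DUP"
  cluster[lp == "UP" & lf == "DOWN"] <- "COMMON_PUP_DDOWN"
  cont <- lf == "CONTINUUM"
  if (continuum_requires_prev) cont <- cont & lp != "NOT_DEG"
  cluster[cont] <- "CONTINUUM"
  cluster[lf == "EXCLUSIVE_PARENTAL"] <- "EXCLUSIVE_PARENTAL"
  cluster[lf == "EXCLUSIVE_DERIVED"] <- "EXCLUSIVE_DERIVED"
  cluster
}

#' @export
print.CoGETable <- function(x, ...) {
  cat(sprintf("CoGETable for %s (predecessor %s, mode %s): %d genes, %d assigned\n",
              attr(x, "focal_pair"), attr(x, "prev_pair"), attr(x, "mode"),
              nrow(x), sum(!is.na(x$cluster))))
  print(table(factor(x$cluster, levels = coge_clusters())))
  invisible(x)
}

#' Genes with consistent regulation along the whole progression
#'
#' Filters for candidate progression biomarkers: genes that are DEGs in every
#' comparison of a chained series and carry the identical direction label
#' (`DOWN`, `CONTINUUM`, `UP`, `EXCLUSIVE_PARENTAL` or `EXCLUSIVE_DERIVED`)
#' in all of them.
#'
#' @param comparisons List of >= 2 chained `ComparisonResult` objects (the
#'   derived line of each is the parental line of the next).
#' @param mode `"p"` or `"q"`: which DEG flag to require. Defaults to the mode
#'   the comparisons were computed in.
#' @return `data.frame` with columns `gene_id`, `label` and one
#'   `ratio_<i>` column per comparison; attribute `comparisons` names the
#'   pairs. Zero rows when no gene is consistent.
#' @export
find_consistent_genes <- function(comparisons, mode = NULL) {
  if (length(comparisons) < 2L) {
    stop("need at least two comparisons", call. = FALSE)
  }
  for (i in seq_len(length(comparisons) - 1L)) {
    if (!identical(attr(comparisons[[i]], "derived"),
                   attr(comparisons[[i + 1L]], "parental"))) {
      stop(sprintf("comparisons %d and %d are not chained", i, i + 1L),
           call. = FALSE)
    }
  }
  if (is.null(mode)) mode <- attr(comparisons[[1L]], "mode")
  mode <- match.arg(mode, c("p", "q"))
  genes <- Reduce(intersect, lapply(comparisons, `[[`, "gene_id"))
  deg_col <- if (mode == "p") "deg_p" else "deg_q"
  labs <- vapply(comparisons, function(cmp) {
    i <- match(genes, cmp$gene_id)
    ifelse(cmp[[deg_col]][i], cmp$label[i], "NOT_DEG")
  }, character(length(genes)))
  labs <- matrix(labs, nrow = length(genes))
  ratios <- vapply(comparisons, function(cmp) {
    cmp$ratio[match(genes, cmp$gene_id)]
  }, numeric(length(genes)))
  ratios <- matrix(ratios, nrow = length(genes))
  same <- labs[, 1L] != "NOT_DEG" &
    rowSums(labs == labs[, 1L]) == ncol(labs)
  out <- data.frame(gene_id = genes[same], label = labs[same, 1L],
                    stringsAsFactors = FALSE)
  rt <- as.data.frame(ratios[same, , drop = FALSE])
  names(rt) <- paste0("ratio_", seq_along(comparisons))
  out <- cbind(out, rt)
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  pair_names <- vapply(comparisons, function(cmp) {
    paste(attr(cmp, "parental"), "vs", attr(cmp, "derived"))
  }, character(1L))
  structure(out, comparisons = pair_names)
}
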