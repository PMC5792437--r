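#' Per-gene two-sample t-test between two cell lines
#'
#' Runs a two-sided two-sample t-test on the replicate FPKM values of every
#' gene, comparing a parental line against its derived line. The default is
#' the textbook Student test (pooled variance); `welch = TRUE` switches to the
#' Welch unequal-variance form.
#'
#' Degenerate conventions (FPKM ties, in particular ties at zero, are common):
#' a gene whose replicate values have zero pooled variance gets `p = 1` when
#' the two group means are equal (e.g. an all-zero gene) and `p = 0` when they
#' differ (two distinct constants).
#'
#' @param expr An [expression_matrix()].
#' @param parental,derived Cell line names; each needs >= 2 replicates.
#' @param welch Use the Welch test instead of the pooled-variance Student test.
#' @return Named numeric vector of two-sided p-values, one per gene.
#' @export
t_test_per_gene <- function(expr, parental, derived, welch = FALSE) {
  x <- expr$values[, line_samples(expr, parental), drop = FALSE]
  y <- expr$values[, line_samples(expr, derived), drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2L || ny < 2L) {
    stop(sprintf("need >= 2 replicates per line (got %d for '%s', %d for '%s')",
                 nx, parental, ny, derived), call. = FALSE)
  }
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1L)
  vy <- rowSums((y - my)^2) / (ny - 1L)
  if (welch) {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  } else {
    sp2 <- ((nx - 1L) * vx + (ny - 1L) * vy) / (nx + ny - 2L)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- rep.int(nx + ny - 2L, length(se2))
  }
  p <- rep.int(NA_real_, nrow(expr$values))
  degen <- se2 == 0
  p[degen] <- ifelse(mx[degen] == my[degen], 1, 0)
  ok <- !degen
  tstat <- (my[ok] - mx[ok]) / sqrt(se2[ok])
  p[ok] <- 2 * stats::pt(abs(tstat), df[ok], lower.tail = FALSE)
  stats::setNames(p, rownames(expr$values))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure: with the m p-values sorted ascending,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, and returned in the
#' original input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (names preserved).
#' @return Vector of q-values, `q >= p` elementwise.
#' @export
fdr_correct <- function(p) {
  if (length(p) == 0L) return(p)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  # multiply by m/j (not (p*m)/j): keeps q >= p exact in floating point
  q_sorted <- pmin(1, rev(cummin(rev(m / seq_len(m) * ps))))
  q <- numeric(m)
  q[ord] <- q_sorted
  names(q) <- names(p)
  q
}

#' Direction label for one gene in one comparison
#'
#' Classifies genes by the derived/parental mean-FPKM ratio, applying the
#' exclusive-expression rules first:
#' non-significant genes are `NOT_DEG`; genes expressed only in the parental
#' (derived mean exactly 0) are `EXCLUSIVE_PARENTAL`; only in the derived,
#' `EXCLUSIVE_DERIVED`; otherwise a ratio below `ratio_low` is `DOWN`, inside
#' the closed interval `[ratio_low, ratio_high]` it is `CONTINUUM`
#' (significant but negligible fold change) and above `ratio_high` it is `UP`.
#'
#' @param mean_parental,mean_derived Non-negative mean FPKM vectors.
#' @param is_deg Logical vector: did the gene pass the significance test?
#' @param ratio_low,ratio_high Fold-change thresholds (defaults 0.8 and 1.2).
#' @return Character vector of labels from [direction_labels()].
#' @export
label_direction <- function(mean_parental, mean_derived, is_deg,
                            ratio_low = 0.8, ratio_high = 1.2) {
  if (any(mean_parental < 0) || any(mean_derived < 0)) {
    stop("mean FPKM must be non-negative", call. = FALSE)
  }
  if (ratio_low >= 1 || ratio_high <= 1) {
    stop("need ratio_low < 1 < ratio_high", call. = FALSE)
  }
  n <- length(mean_parental)
  stopifnot(length(mean_derived) == n, length(is_deg) == n)
  both_zero <- mean_parental == 0 & mean_derived == 0
  if (any(both_zero & is_deg)) {
    stop("invalid state: gene flagged significant with zero FPKM in both lines",
         call. = FALSE)
  }
  lab <- rep.int("NOT_DEG", n)
  r <- mean_derived / mean_parental
  lab[is_deg & r < ratio_low] <- "DOWN"
  lab[is_deg & r >= ratio_low & r <= ratio_high] <- "CONTINUUM"
  lab[is_deg & r > ratio_high] <- "UP"
  lab[is_deg & mean_parental > 0 & mean_derived == 0] <- "EXCLUSIVE_PARENTAL"
  lab[is_deg & mean_parental == 0 & mean_derived > 0] <- "EXCLUSIVE_DERIVED"
  names(lab) <- names(mean_parental)
  lab
}

#' Compare a parental line against its derived line
#'
#' Composes [t_test_per_gene()], [fdr_correct()] and [label_direction()]:
#' per-gene means, derived/parental ratio, p- and q-values, DEG flags at
#' `alpha` for both, and the direction label (using the p- or q-based flag
#' according to `mode`).
#'
#' @param expr An [expression_matrix()].
#' @param parental,derived Cell line names.
#' @param alpha Significance threshold, default 0.05.
#' @param mode `"p"` (uncorrected t-test) or `"q"` (BH-corrected) DEG calling
#'   for the direction label.
#' @param ratio_low,ratio_high Fold-change thresholds for [label_direction()].
#' @param welch Use the Welch test.
#' @param min_expression Optional filter: genes whose mean FPKM is below this
#'   value in both lines are excluded from testing (they get `NA` p/q values
#'   and label `NOT_DEG`), which reduces the multiple-testing burden `m`.
#'   `NULL` (default) tests every gene.
#' @return `data.frame` of class `ComparisonResult` with columns `gene_id`,
#'   `mean_parental`, `mean_derived`, `ratio` (`NA` when the parental mean is
#'   zero), `p_value`, `q_value`, `deg_p`, `deg_q`, `label`; attributes
#'   `parental`, `derived`, `alpha`, `mode`.
#' @export
compare_lines <- function(expr, parental, derived, alpha = 0.05,
                          mode = c("p", "q"), ratio_low = 0.8,
                          ratio_high = 1.2, welch = FALSE,
                          min_expression = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  mp <- rowMeans(expr$values[, line_samples(expr, parental), drop = FALSE])
  md <- rowMeans(expr$values[, line_samples(expr, derived), drop = FALSE])
  p <- t_test_per_gene(expr, parental, derived, welch = welch)
  tested <- rep.int(TRUE, length(p))
  if (!is.null(min_expression)) {
    tested <- mp >= min_expression | md >= min_expression
    p[!tested] <- NA_real_
  }
  q <- rep.int(NA_real_, length(p))
  q[tested] <- fdr_correct(p[tested])
  deg_p <- !is.na(p) & p < alpha
  deg_q <- !is.na(q) & q < alpha
  is_deg <- if (mode == "p") deg_p else deg_q
  lab <- label_direction(mp, md, is_deg, ratio_low, ratio_high)
  res <- data.frame(
    gene_id = rownames(expr$values),
    mean_parental = unname(mp),
    mean_derived = unname(md),
    ratio = ifelse(mp > 0, md / mp, NA_real_),
    p_value = unname(p),
    q_value = unname(q),
    deg_p = unname(deg_p),
    deg_q = unname(deg_q),
    label = unname(lab),
    stringsAsFactors = FALSE
  )
  structure(res, class = c("ComparisonResult", "data.frame"),
            parental = parental, derived = derived, alpha = alpha,
            mode = mode)
}

#' Build ComparisonResult objects directly from a table of per-line means
#'
#' Demo/fixture mode: when only per-line mean FPKM values are available (for
#' example a published table of means), this constructs the chain of
#' successive comparisons with every gene treated as a significant DEG, so the
#' ratio-based direction labels and downstream CoGE logic can be applied.
#'
#' @param means Numeric matrix of mean FPKM, genes x cell lines, columns in
#'   progression order.
#' @param ratio_low,ratio_high Fold-change thresholds.
#' @return List of `ComparisonResult` objects, one per successive transition.
#' @export
comparisons_from_means <- function(means, ratio_low = 0.8, ratio_high = 1.2) {
  if (ncol(means) < 2L) stop("need at least two cell lines", call. = FALSE)
  lines <- colnames(means)
  out <- vector("list", ncol(means) - 1L)
  for (i in seq_len(ncol(means) - 1L)) {
    mp <- means[, i]; md <- means[, i + 1L]
    lab <- label_direction(mp, md, is_deg = rep.int(TRUE, nrow(means)),
                           ratio_low, ratio_high)
    res <- data.frame(
      gene_id = rownames(means),
      mean_parental = unname(mp),
      mean_derived = unname(md),
      ratio = ifelse(mp > 0, md / mp, NA_real_),
      p_value = rep.int(0, nrow(means)),
      q_value = rep.int(0, nrow(means)),
      deg_p = rep.int(TRUE, nrow(means)),
      deg_q = rep.int(TRUE, nrow(means)),
      label = unname(lab),
      stringsAsFactors = FALSE
    )
    out[[i]] <- structure(res, class = c("ComparisonResult", "data.frame"),
                          parental = lines[i], derived = lines[i + 1L],
                          alpha = 0.05, mode = "p")
  }
  names(out) <- paste(lines[-length(lines)], "vs", lines[-1L])
  out
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("ComparisonResult %s vs %s (alpha = %g, mode = %s): %d genes, %d deg_p, %d deg_q\n",
              attr(x, "parental"), attr(x, "derived"), attr(x, "alpha"),
              attr(x, "mode"), nrow(x), sum(x$deg_p), sum(x$deg_q)))
  NextMethod()
}
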