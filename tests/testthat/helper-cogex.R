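# Shared builders and independent oracles for the test suite.

# Tiny expression matrix: `reps` named list cell_line -> list of replicate
# vectors per gene (matrix genes x replicates).
make_expr <- function(values_by_line, gene_ids = NULL) {
  lines <- names(values_by_line)
  mats <- lapply(values_by_line, as.matrix)
  n_genes <- nrow(mats[[1L]])
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(n_genes))
  cols <- list(); design <- list()
  for (ln in lines) {
    m <- mats[[ln]]
    colnames(m) <- paste0(ln, "_r", seq_len(ncol(m)))
    cols[[ln]] <- m
    design[[ln]] <- data.frame(sample_id = colnames(m), cell_line = ln,
                               replicate = seq_len(ncol(m)),
                               stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, cols)
  rownames(values) <- gene_ids
  expression_matrix(values, do.call(rbind, design), lines)
}

# Hand-built ComparisonResult with given labels (ratios filled from means).
make_comparison <- function(gene_id, mean_parental, mean_derived, label,
                            parental = "A", derived = "B", mode = "p") {
  deg <- label != "NOT_DEG"
  res <- data.frame(gene_id = gene_id, mean_parental = mean_parental,
                    mean_derived = mean_derived,
                    ratio = ifelse(mean_parental > 0,
                                   mean_derived / mean_parental, NA_real_),
                    p_value = ifelse(deg, 0, 1), q_value = ifelse(deg, 0, 1),
                    deg_p = deg, deg_q = deg, label = label,
                    stringsAsFactors = FALSE)
  structure(res, class = c("ComparisonResult", "data.frame"),
            parental = parental, derived = derived, alpha = 0.05, mode = mode)
}

# Independent Benjamini-Hochberg oracle: literal min-over-suffix definition,
# no sorting tricks.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)              # position of p[i] in the sort
    suffix <- ord[rank_i:m]
    q[i] <- min(1, min(p[suffix] * m / match(suffix, ord)))
  }
  q
}

# Independent CoGE decision table: one explicit if/else per label pair.
coge_brute <- function(lp, lf, continuum_requires_prev = FALSE) {
  one <- function(a, b) {
    if (b == "EXCLUSIVE_PARENTAL") return("EXCLUSIVE_PARENTAL")
    if (b == "EXCLUSIVE_DERIVED") return("EXCLUSIVE_DERIVED")
    if (b == "CONTINUUM" && (!continuum_requires_prev || a != "NOT_DEG")) {
      return("CONTINUUM")
    }
    areg <- a %in% c("DOWN", "UP"); breg <- b %in% c("DOWN", "UP")
    if (areg && !breg) return(if (a == "DOWN") "EXCL_PARENTAL_DOWN" else "EXCL_PARENTAL_UP")
    if (!areg && breg) return(if (b == "DOWN") "EXCL_DERIVED_DOWN" else "EXCL_DERIVED_UP")
    if (areg && breg) {
      if (a == "DOWN" && b == "DOWN") return("COMMON_DOWN")
      if (a == "UP" && b == "UP") return("COMMON_UP")
      if (a == "DOWN" && b == "UP") return("COMMON_PDOWN_DUP")
      return("COMMON_PUP_DDOWN")
    }
    NA_character_
  }
  mapply(one, lp, lf, USE.NAMES = FALSE)
}

# Exhaustive contribution oracle: loops over every (hallmark, cluster, gene).
contrib_brute <- function(annotation, universe, coge_df, reference) {
  hallmarks <- annotation$vocabulary
  gene_sets <- lapply(hallmarks, function(h) {
    ps <- annotation$map$pathway_id[annotation$map$hallmark == h]
    g <- character(0)
    for (p in ps) g <- union(g, annotation$pathways[[p]])
    intersect(g, universe)
  })
  names(gene_sets) <- hallmarks
  ref_genes <- gene_sets[[reference]]
  rows <- list()
  for (h in hallmarks) {
    for (cl in coge_clusters()) {
      in_cluster <- coge_df$gene_id[!is.na(coge_df$cluster) &
                                      coge_df$cluster == cl]
      n <- 0L; shared <- 0L
      for (g in gene_sets[[h]]) {
        if (g %in% in_cluster) {
          n <- n + 1L
          if (g %in% ref_genes) shared <- shared + 1L
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        hallmark = h, cluster = cl, n_genes = n,
        pct = if (n > 0L) 100 * shared / n else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
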