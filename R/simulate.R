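#' Configuration for the synthetic progression-series generator
#'
#' Describes a simulated stepwise tumor-progression experiment: an ordered
#' series of cell lines measured with replicate FPKM profiles, containing
#' planted genes for every direction pattern plus unregulated null genes.
#' Defaults mirror the study design the package targets: 5 lines with 7
#' replicates each (three biological experiments pooled into seven flat
#' technical datasets per line) and multiplicative replicate noise with a
#' coefficient of variation of 0.10.
#'
#' @param n_lines Number of cell lines in the series (>= 3).
#' @param replicates_per_line Replicates per line (>= 2).
#' @param n_null_genes Number of unregulated genes (one mean shared by all
#'   lines).
#' @param genes_per_pattern Named integer vector: how many genes to plant per
#'   pattern; names from `DOWN`, `UP`, `CONTINUUM`, `EXCLUSIVE_PARENTAL`,
#'   `EXCLUSIVE_DERIVED`.
#' @param cv Coefficient of variation of the lognormal replicate noise
#'   (> 0).
#' @param continuum_cv Noise level for planted `CONTINUUM` genes. These genes
#'   must stay statistically significant while their fold change is confined
#'   to `[0.8, 1.2]`, so they are generated with much tighter replicates
#'   (default 0.001).
#' @param ratio_ranges Named list of `(low, high)` multiplicative steps per
#'   transition for the ratio-driven patterns. `DOWN` ranges must lie below
#'   0.8, `CONTINUUM` within `[0.8, 1.2]`, `UP` above 1.2.
#' @param base_expression_range `(min, max)` FPKM for first-line means.
#' @param seed Integer random seed; identical seeds give identical output.
#' @return Object of class `SimulationConfig` (a validated list).
#' @export
simulation_config <- function(n_lines = 5L,
                              replicates_per_line = 7L,
                              n_null_genes = 200L,
                              genes_per_pattern = c(DOWN = 60L, UP = 60L,
                                                    CONTINUUM = 60L,
                                                    EXCLUSIVE_PARENTAL = 20L,
                                                    EXCLUSIVE_DERIVED = 20L),
                              cv = 0.10,
                              continuum_cv = 0.001,
                              ratio_ranges = list(DOWN = c(0.2, 0.6),
                                                  UP = c(1.5, 3.0),
                                                  CONTINUUM = c(0.95, 1.05)),
                              base_expression_range = c(5, 200),
                              seed = 1L) {
  fail <- function(field, msg) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(n_lines) || n_lines < 3) fail("n_lines", "must be >= 3")
  if (!is.numeric(replicates_per_line) || replicates_per_line < 2) {
    fail("replicates_per_line", "must be >= 2")
  }
  if (!is.numeric(n_null_genes) || n_null_genes < 0) {
    fail("n_null_genes", "must be >= 0")
  }
  if (!is.numeric(cv) || cv <= 0) fail("cv", "must be > 0")
  if (!is.numeric(continuum_cv) || continuum_cv <= 0) {
    fail("continuum_cv", "must be > 0")
  }
  known <- c("DOWN", "UP", "CONTINUUM", "EXCLUSIVE_PARENTAL",
             "EXCLUSIVE_DERIVED")
  if (length(genes_per_pattern)) {
    if (is.null(names(genes_per_pattern)) ||
        !all(names(genes_per_pattern) %in% known)) {
      fail("genes_per_pattern",
           paste("names must be among", paste(known, collapse = ", ")))
    }
    if (any(genes_per_pattern < 0)) fail("genes_per_pattern", "must be >= 0")
  }
  for (pat in intersect(names(ratio_ranges), c("DOWN", "UP", "CONTINUUM"))) {
    rr <- ratio_ranges[[pat]]
    if (length(rr) != 2L || rr[1L] > rr[2L] || any(rr <= 0)) {
      fail("ratio_ranges", sprintf("(%s) must be a positive (low, high) pair", pat))
    }
    ok <- switch(pat,
                 DOWN = rr[2L] < 0.8,
                 CONTINUUM = rr[1L] >= 0.8 && rr[2L] <= 1.2,
                 UP = rr[1L] > 1.2)
    if (!ok) {
      fail("ratio_ranges",
           sprintf("(%s) must respect the 0.8 / 1.2 direction thresholds", pat))
    }
  }
  for (pat in setdiff(c("DOWN", "UP", "CONTINUUM"),
                      names(ratio_ranges))) {
    if (pat %in% names(genes_per_pattern) && genes_per_pattern[[pat]] > 0) {
      fail("ratio_ranges", sprintf("missing range for planted pattern %s", pat))
    }
  }
  if (length(base_expression_range) != 2L ||
      base_expression_range[1L] <= 0 ||
      base_expression_range[1L] > base_expression_range[2L]) {
    fail("base_expression_range", "must be a positive (min, max) pair")
  }
  if (!is.numeric(seed) || is.na(seed)) fail("seed", "must be an integer")
  structure(list(n_lines = as.integer(n_lines),
                 replicates_per_line = as.integer(replicates_per_line),
                 n_null_genes = as.integer(n_null_genes),
                 genes_per_pattern = genes_per_pattern,
                 cv = cv, continuum_cv = continuum_cv,
                 ratio_ranges = ratio_ranges,
                 base_expression_range = base_expression_range,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Lognormal replicates with E[X] = mean and sd/mean = cv.
rlnorm_cv <- function(n, mean, cv) {
  sdlog2 <- log1p(cv^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic progression-series expression matrix
#'
#' Plants genes whose per-line true means follow each configured pattern:
#' `DOWN` / `UP` / `CONTINUUM` genes step by a ratio drawn uniformly from the
#' pattern's range at every transition; `EXCLUSIVE_PARENTAL` genes are
#' expressed up to a random cutoff line and exactly zero afterwards;
#' `EXCLUSIVE_DERIVED` genes are exactly zero before a random onset line;
#' null genes share one mean across all lines. Replicates are lognormal
#' around the line mean with coefficient of variation `cv` (`continuum_cv`
#' for planted continuum genes); designated zero cells are exact zeros.
#'
#' @param config A [simulation_config()].
#' @return List with elements `expr` (an [expression_matrix()]) and `truth`
#'   (class `SyntheticTruth`: `genes` data.frame with `gene_id`, `pattern`,
#'   `base_mean`; `labels` data.frame with the intended direction label per
#'   gene and transition; `line_order`).
#' @export
generate_expression <- function(config) {
  if (!inherits(config, "SimulationConfig")) {
    stop("config must come from simulation_config()", call. = FALSE)
  }
  set.seed(config$seed)
  lines <- paste0("line", seq_len(config$n_lines))
  n_rep <- config$replicates_per_line
  samples <- as.vector(t(outer(lines, seq_len(n_rep),
                               function(l, r) paste0(l, "_r", r))))
  design <- data.frame(sample_id = samples,
                       cell_line = rep(lines, each = n_rep),
                       replicate = rep(seq_len(n_rep), times = length(lines)),
                       stringsAsFactors = FALSE)

  pats <- config$genes_per_pattern
  gene_pattern <- c(rep(names(pats), times = pats),
                    rep("NULL", config$n_null_genes))
  n_genes <- length(gene_pattern)
  if (n_genes == 0L) stop("config generates no genes", call. = FALSE)
  gene_id <- sprintf("g%05d", seq_len(n_genes))

  base <- stats::runif(n_genes, config$base_expression_range[1L],
                       config$base_expression_range[2L])
  n_trans <- config$n_lines - 1L
  means <- matrix(0, n_genes, config$n_lines,
                  dimnames = list(gene_id, lines))
  intended <- matrix("NOT_DEG", n_genes, n_trans)
  for (i in seq_len(n_genes)) {
    pat <- gene_pattern[i]
    if (pat %in% c("DOWN", "UP", "CONTINUUM")) {
      rr <- config$ratio_ranges[[pat]]
      steps <- stats::runif(n_trans, rr[1L], rr[2L])
      means[i, ] <- base[i] * cumprod(c(1, steps))
      intended[i, ] <- pat
    } else if (pat == "EXCLUSIVE_DERIVED") {
      onset <- sample(2:config$n_lines, 1L)
      means[i, onset:config$n_lines] <- base[i]
      intended[i, onset - 1L] <- "EXCLUSIVE_DERIVED"
    } else if (pat == "EXCLUSIVE_PARENTAL") {
      cutoff <- sample(2:config$n_lines, 1L)
      means[i, seq_len(cutoff - 1L)] <- base[i]
      intended[i, cutoff - 1L] <- "EXCLUSIVE_PARENTAL"
    } else {
      means[i, ] <- base[i]
    }
  }

  values <- matrix(0, n_genes, length(samples),
                   dimnames = list(gene_id, samples))
  gene_cv <- ifelse(gene_pattern == "CONTINUUM", config$continuum_cv,
                    config$cv)
  for (j in seq_along(lines)) {
    cols <- design$sample_id[design$cell_line == lines[j]]
    m <- means[, j]
    nz <- m > 0
    if (any(nz)) {
      values[nz, cols] <- rlnorm_cv(sum(nz) * n_rep, rep(m[nz], n_rep),
                                    rep(gene_cv[nz], n_rep))
    }
  }

  labels <- data.frame(
    gene_id = rep(gene_id, each = n_trans),
    parental = rep(lines[-config$n_lines], times = n_genes),
    derived = rep(lines[-1L], times = n_genes),
    label = as.vector(t(intended)),
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    genes = data.frame(gene_id = gene_id, pattern = gene_pattern,
                       base_mean = base, stringsAsFactors = FALSE),
    labels = labels,
    line_means = means,
    line_order = lines
  ), class = "SyntheticTruth")
  list(expr = expression_matrix(values, design, lines), truth = truth)
}

#' Generate a synthetic pathway/hallmark annotation with known overlaps
#'
#' Partitions the simulated genes into pathways and annotates each hallmark of
#' the 8 + 2 vocabulary with two pathways. For every hallmark except
#' `"chronic diseases"`, one of its pathways is also annotated to the
#' reference hallmark (`"invasion and metastasis"`), giving a known planted
#' pathway overlap of 1; the chronic-diseases analog shares none. The planted
#' per-hallmark overlap is recorded in the `"planted_shared_pathways"`
#' attribute.
#'
#' @param config A [simulation_config()] (its seed, offset by one, makes the
#'   annotation deterministic).
#' @param truth The `truth` component of [generate_expression()].
#' @return A [hallmark_annotation()] with attributes
#'   `planted_shared_pathways` (named integer vector) and `gene_pathways`.
#' @export
generate_annotation <- function(config, truth) {
  if (!inherits(truth, "SyntheticTruth")) {
    stop("truth must come from generate_expression()", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  genes <- sample(truth$genes$gene_id)
  vocab <- cogex_hallmarks()
  reference <- "invasion and metastasis"
  n_pathways <- 2L * length(vocab)
  chunk <- split(genes, rep_len(seq_len(n_pathways), length(genes)))
  ids <- sprintf("pw%03d", seq_len(n_pathways))
  pathways <- stats::setNames(lapply(chunk, sort), ids)

  map <- data.frame(pathway_id = rep(ids[seq(1L, by = 2L, length.out = length(vocab))],
                                     each = 1L),
                    hallmark = vocab, stringsAsFactors = FALSE)
  map <- rbind(map,
               data.frame(pathway_id = ids[seq(2L, by = 2L, length.out = length(vocab))],
                          hallmark = vocab, stringsAsFactors = FALSE))
  shared <- vocab[vocab != reference & vocab != "chronic diseases"]
  own_first <- stats::setNames(ids[seq(1L, by = 2L, length.out = length(vocab))], vocab)
  map <- rbind(map, data.frame(pathway_id = unname(own_first[shared]),
                               hallmark = reference, stringsAsFactors = FALSE))
  ann <- hallmark_annotation(pathways, map, vocab)
  planted <- stats::setNames(ifelse(vocab %in% shared, 1L, 0L), vocab)
  planted[reference] <- length(unique(map$pathway_id[map$hallmark == reference]))
  attr(ann, "planted_shared_pathways") <- planted
  gp <- data.frame(
    gene_id = unlist(pathways, use.names = FALSE),
    pathway_id = rep(names(pathways), times = lengths(pathways)),
    stringsAsFactors = FALSE
  )
  attr(ann, "gene_pathways") <- gp[order(gp$gene_id), ]
  ann
}

#' Write a simulated dataset to disk
#'
#' Materializes everything the pipeline consumes: expression matrix TSV,
#' sample sheet TSV, pathway GMT, hallmark-map TSV, plus the ground-truth
#' table (gene, pattern, per-transition intended label).
#'
#' @param sim Result of [generate_expression()].
#' @param annotation Result of [generate_annotation()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, named character vector of the written paths.
#' @export
write_simulation <- function(sim, annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    hallmarks = file.path(dir, "hallmark_map.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression(sim$expr, paths[["expression"]], paths[["samples"]])
  write_gmt(annotation$pathways, paths[["gmt"]])
  write_hallmark_map(annotation$map, paths[["hallmarks"]])
  lab <- sim$truth$labels
  lab$pattern <- sim$truth$genes$pattern[match(lab$gene_id,
                                               sim$truth$genes$gene_id)]
  lab$transition <- paste(lab$parental, "vs", lab$derived)
  utils::write.table(lab[, c("gene_id", "pattern", "transition", "label")],
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
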