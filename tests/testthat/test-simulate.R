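test_that("config validation names the offending field", {
  expect_error(simulation_config(n_lines = 2), "n_lines")
  expect_error(simulation_config(replicates_per_line = 1),
               "replicates_per_line")
  expect_error(simulation_config(cv = 0), "'cv'")
  expect_error(simulation_config(ratio_ranges = list(DOWN = c(0.5, 0.9),
                                                     UP = c(1.5, 3),
                                                     CONTINUUM = c(0.95, 1.05))),
               "ratio_ranges")
  expect_error(simulation_config(ratio_ranges = list(DOWN = c(0.2, 0.6),
                                                     UP = c(1.1, 3),
                                                     CONTINUUM = c(0.95, 1.05))),
               "ratio_ranges")
  expect_error(simulation_config(genes_per_pattern = c(BOGUS = 5L)),
               "genes_per_pattern")
})

test_that("noise-free limit: successive ratios match the planted pattern", {
  cfg <- simulation_config(cv = 1e-10, continuum_cv = 1e-10, seed = 4,
                           n_null_genes = 5,
                           ratio_ranges = list(DOWN = c(0.5, 0.5),
                                               UP = c(2, 2),
                                               CONTINUUM = c(1, 1)),
                           genes_per_pattern = c(DOWN = 3L, UP = 3L,
                                                 CONTINUUM = 3L),
                           base_expression_range = c(10, 10))
  sim <- generate_expression(cfg)
  means <- sapply(sim$truth$line_order, function(ln) {
    rowMeans(sim$expr$values[, cogex:::line_samples(sim$expr, ln),
                             drop = FALSE])
  })
  down <- sim$truth$genes$gene_id[sim$truth$genes$pattern == "DOWN"]
  # step ratio 0.5 from base 10: 10, 5, 2.5, 1.25, 0.625
  expect_equal(unname(means[down[1], ]), c(10, 5, 2.5, 1.25, 0.625),
               tolerance = 1e-6)
  for (pat in c("DOWN", "UP", "CONTINUUM")) {
    ids <- sim$truth$genes$gene_id[sim$truth$genes$pattern == pat]
    r <- means[ids, -1, drop = FALSE] / means[ids, -ncol(means), drop = FALSE]
    ok <- switch(pat, DOWN = all(r < 0.8), UP = all(r > 1.2),
                 CONTINUUM = all(r >= 0.8 & r <= 1.2))
    expect_true(ok, label = pat)
  }
  nulls <- sim$truth$genes$gene_id[sim$truth$genes$pattern == "NULL"]
  expect_equal(apply(means[nulls, ], 1, function(x) diff(range(x))),
               setNames(rep(0, length(nulls)), nulls), tolerance = 1e-6)
})

test_that("exclusive patterns produce exact zeros on the designated side", {
  cfg <- simulation_config(seed = 8, n_null_genes = 0,
                           genes_per_pattern = c(EXCLUSIVE_PARENTAL = 10L,
                                                 EXCLUSIVE_DERIVED = 10L))
  sim <- generate_expression(cfg)
  lab <- sim$truth$labels
  for (i in seq_len(nrow(lab))) {
    if (lab$label[i] == "EXCLUSIVE_DERIVED") {
      par_cols <- cogex:::line_samples(sim$expr, lab$parental[i])
      der_cols <- cogex:::line_samples(sim$expr, lab$derived[i])
      expect_true(all(sim$expr$values[lab$gene_id[i], par_cols] == 0))
      expect_true(all(sim$expr$values[lab$gene_id[i], der_cols] > 0))
    }
    if (lab$label[i] == "EXCLUSIVE_PARENTAL") {
      der_cols <- cogex:::line_samples(sim$expr, lab$derived[i])
      expect_true(all(sim$expr$values[lab$gene_id[i], der_cols] == 0))
    }
  }
  # every gene has exactly one truth row per transition
  expect_equal(nrow(lab), nrow(sim$truth$genes) * 4L)
})

test_that("identical seeds give identical outputs, different seeds differ", {
  cfg <- simulation_config(seed = 1)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth$labels, b$truth$labels)
  ann_a <- generate_annotation(cfg, a$truth)
  ann_b <- generate_annotation(cfg, b$truth)
  expect_identical(ann_a$pathways, ann_b$pathways)
  expect_identical(ann_a$map, ann_b$map)
  c_ <- generate_expression(simulation_config(seed = 2))
  expect_false(identical(a$expr$values, c_$expr$values))
})

test_that("written simulation files are byte-identical across runs and re-read", {
  cfg <- simulation_config(seed = 7, n_null_genes = 10,
                           genes_per_pattern = c(DOWN = 5L, UP = 5L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim1 <- generate_expression(cfg)
  write_simulation(sim1, generate_annotation(cfg, sim1$truth), d1)
  sim2 <- generate_expression(cfg)
  write_simulation(sim2, generate_annotation(cfg, sim2$truth), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  back <- read_expression(file.path(d1, "expression.tsv"),
                          file.path(d1, "samples.tsv"))
  expect_equal(back$values, sim1$expr$values, tolerance = 1e-12)
  expect_identical(back$line_order, sim1$expr$line_order)
  ann <- hallmark_annotation(read_gmt(file.path(d1, "pathways.gmt")),
                             read_hallmark_map(file.path(d1, "hallmark_map.tsv")))
  expect_s3_class(ann, "HallmarkAnnotation")
})

test_that("replicate noise has the configured coefficient of variation", {
  cfg <- simulation_config(seed = 19, n_lines = 3, replicates_per_line = 500,
                           n_null_genes = 200,
                           genes_per_pattern = c(DOWN = 0L))
  sim <- generate_expression(cfg)
  vals <- sim$expr$values[, cogex:::line_samples(sim$expr, "line1")]
  cv_hat <- apply(vals, 1, function(x) sd(x) / mean(x))
  expect_equal(median(cv_hat), 0.10, tolerance = 0.05)
  # lognormal noise is mean-unbiased
  m_hat <- rowMeans(vals)
  expect_equal(unname(m_hat / sim$truth$line_means[, "line1"]),
               rep(1, 200), tolerance = 0.05)
})

test_that("null genes control type I error at the nominal level", {
  cfg <- simulation_config(seed = 101, n_lines = 3,
                           genes_per_pattern = c(DOWN = 0L),
                           n_null_genes = 2000)
  sim <- generate_expression(cfg)
  p <- t_test_per_gene(sim$expr, "line1", "line2")
  rate <- mean(p < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rate - 0.05), 3 * mc_se)
})

test_that("planted direction labels are recovered at >= 95% under defaults", {
  cfg <- simulation_config(seed = 55)
  sim <- generate_expression(cfg)
  truth <- sim$truth
  planted <- truth$genes$gene_id[truth$genes$pattern %in%
                                   c("DOWN", "UP", "CONTINUUM",
                                     "EXCLUSIVE_PARENTAL",
                                     "EXCLUSIVE_DERIVED")]
  hits <- 0L; total <- 0L
  for (i in seq_len(length(truth$line_order) - 1L)) {
    cmp <- compare_lines(sim$expr, truth$line_order[i],
                         truth$line_order[i + 1L])
    lab <- setNames(cmp$label, cmp$gene_id)
    tl <- truth$labels[truth$labels$parental == truth$line_order[i] &
                         truth$labels$gene_id %in% planted, ]
    # skip NOT_DEG truth rows (flat stretches of exclusive genes)
    tl <- tl[tl$label != "NOT_DEG", ]
    hits <- hits + sum(lab[tl$gene_id] == tl$label)
    total <- total + nrow(tl)
  }
  expect_gte(hits / total, 0.95)
})
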