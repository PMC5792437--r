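make_ann <- function() {
  hallmark_annotation(
    pathways = list(p1 = c("g1", "g2"), p2 = "g3", p3 = c("g4", "g5")),
    hallmark_map = data.frame(
      pathway_id = c("p1", "p1", "p2", "p3"),
      hallmark = c("angiogenesis", "invasion and metastasis",
                   "invasion and metastasis", "energy metabolism"),
      stringsAsFactors = FALSE))
}

test_that("hallmark sets: pathway union, universe intersection, empty sets", {
  ann <- make_ann()
  sets <- build_hallmark_sets(ann)
  expect_setequal(sets$genes[["angiogenesis"]], c("g1", "g2"))
  expect_setequal(sets$genes[["invasion and metastasis"]],
                  c("g1", "g2", "g3"))
  expect_length(sets$genes[["chronic diseases"]], 0)  # no pathways
  restricted <- build_hallmark_sets(ann, universe = "g1")
  expect_equal(restricted$genes[["invasion and metastasis"]], "g1")
  expect_error(build_hallmark_sets(ann, reference = "nope"),
               "unknown reference")
})

test_that("absolute contributions count shared pathways and genes", {
  sets <- build_hallmark_sets(make_ann())
  abs_tab <- absolute_contribution(sets)
  row <- abs_tab[abs_tab$hallmark == "angiogenesis", ]
  expect_equal(row$shared_pathways, 1L)  # p1 annotated to both
  expect_equal(row$shared_genes, 2L)
  em <- abs_tab[abs_tab$hallmark == "energy metabolism", ]
  expect_equal(c(em$shared_pathways, em$shared_genes), c(0L, 0L))
  cd <- abs_tab[abs_tab$hallmark == "chronic diseases", ]
  expect_equal(c(cd$n_pathways, cd$shared_genes), c(0L, 0L))
  ref <- abs_tab[abs_tab$hallmark == "invasion and metastasis", ]
  expect_equal(ref$shared_pathways, ref$n_pathways)
})

test_that("planted pathway overlaps are recovered from the generator", {
  cfg <- simulation_config(seed = 2)
  sim <- generate_expression(cfg)
  ann <- generate_annotation(cfg, sim$truth)
  sets <- build_hallmark_sets(ann)
  abs_tab <- absolute_contribution(sets)
  planted <- attr(ann, "planted_shared_pathways")
  got <- setNames(abs_tab$shared_pathways, abs_tab$hallmark)
  expect_equal(got[names(planted)], planted)
  expect_equal(unname(got["chronic diseases"]), 0L)
})

test_that("relative contributions: reference 100, constructed 50, 0/0 -> 0", {
  ann <- hallmark_annotation(
    pathways = list(pa = c("a", "b", "c", "d"), pr = c("a", "b")),
    hallmark_map = data.frame(
      pathway_id = c("pa", "pr"),
      hallmark = c("angiogenesis", "invasion and metastasis")))
  sets <- build_hallmark_sets(ann)
  coge <- structure(
    data.frame(gene_id = c("a", "b", "c", "d"),
               cluster = rep("COMMON_DOWN", 4), stringsAsFactors = FALSE),
    class = c("CoGETable", "data.frame"), focal_pair = "B vs C",
    prev_pair = "A vs B", mode = "p")
  rel <- relative_contribution(sets, coge)
  ang <- rel[rel$hallmark == "angiogenesis" & rel$cluster == "COMMON_DOWN", ]
  expect_equal(ang$n_genes, 4L)
  expect_equal(ang$pct, 50)  # {a,b} of {a,b,c,d} in the reference
  ref <- rel[rel$hallmark == "invasion and metastasis", ]
  expect_true(all(ref$pct[ref$n_genes > 0] == 100))
  expect_true(all(rel$pct[rel$n_genes == 0] == 0))
  expect_equal(nrow(rel), length(cogex_hallmarks()) * 11)
})

test_that("contributions match the exhaustive oracle on small annotations", {
  set.seed(41)
  genes <- sprintf("g%02d", 1:20)
  for (rep in 1:5) {
    n_path <- sample(3:6, 1)
    pathways <- lapply(seq_len(n_path), function(i) {
      sample(genes, sample(2:8, 1))
    })
    names(pathways) <- paste0("p", seq_len(n_path))
    vocab <- cogex_hallmarks()
    map <- data.frame(
      pathway_id = sample(names(pathways), 8, replace = TRUE),
      hallmark = sample(vocab, 8, replace = TRUE),
      stringsAsFactors = FALSE)
    # make sure the reference exists
    map <- rbind(map, data.frame(pathway_id = "p1",
                                 hallmark = "invasion and metastasis"))
    ann <- hallmark_annotation(pathways, map)
    coge_df <- data.frame(
      gene_id = genes,
      cluster = sample(c(coge_clusters(), NA), 20, replace = TRUE),
      stringsAsFactors = FALSE)
    coge <- structure(coge_df, class = c("CoGETable", "data.frame"),
                      focal_pair = "B vs C", prev_pair = "A vs B", mode = "p")
    sets <- build_hallmark_sets(ann, universe = genes)
    rel <- relative_contribution(sets, coge)
    want <- contrib_brute(ann, genes, coge_df, "invasion and metastasis")
    got <- rel[order(rel$hallmark, rel$cluster), ]
    want <- want[order(want$hallmark, want$cluster), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, c("hallmark", "cluster", "n_genes", "pct")], want,
                 tolerance = 1e-12)
    # absolute/relative coherence: no shared genes -> all pct zero
    abs_tab <- absolute_contribution(sets)
    for (h in vocab) {
      if (abs_tab$shared_genes[abs_tab$hallmark == h] == 0) {
        expect_true(all(rel$pct[rel$hallmark == h] == 0))
      }
    }
  }
})

test_that("enlarging the reference gene set never decreases a percentage", {
  ann_small <- hallmark_annotation(
    pathways = list(pa = c("a", "b", "c", "d"), pr = c("a", "b"),
                    pr2 = c("c")),
    hallmark_map = data.frame(
      pathway_id = c("pa", "pr"),
      hallmark = c("angiogenesis", "invasion and metastasis")))
  ann_big <- hallmark_annotation(
    pathways = ann_small$pathways,
    hallmark_map = rbind(ann_small$map,
                         data.frame(pathway_id = "pr2",
                                    hallmark = "invasion and metastasis")))
  coge <- structure(
    data.frame(gene_id = c("a", "b", "c", "d"),
               cluster = rep("COMMON_UP", 4), stringsAsFactors = FALSE),
    class = c("CoGETable", "data.frame"), focal_pair = "B vs C",
    prev_pair = "A vs B", mode = "p")
  rel_small <- relative_contribution(build_hallmark_sets(ann_small), coge)
  rel_big <- relative_contribution(build_hallmark_sets(ann_big), coge)
  expect_true(all(rel_big$pct >= rel_small$pct))
})

test_that("aggregation is the plain mean over 11 clusters then comparisons", {
  # one hallmark with all 11 percentages at 100 keeps mean 100
  tab1 <- data.frame(hallmark = rep(c("angiogenesis", "energy metabolism"),
                                    each = 11),
                     cluster = rep(coge_clusters(), 2),
                     n_genes = 1L, pct = rep(c(100, 50), each = 11),
                     stringsAsFactors = FALSE)
  attr(tab1, "comparison") <- "A vs B"
  attr(tab1, "reference") <- "invasion and metastasis"
  tab2 <- tab1
  tab2$pct <- rep(c(80, 100), each = 11)
  attr(tab2, "comparison") <- "B vs C"
  agg <- aggregate_and_rank(list(tab1, tab2))
  ov <- setNames(agg$overall$overall_mean, agg$overall$hallmark)
  expect_equal(unname(ov["angiogenesis"]), 90)
  expect_equal(unname(ov["energy metabolism"]), 75)
  expect_equal(agg$overall$rank[agg$overall$hallmark == "angiogenesis"], 1L)
  pc <- agg$per_comparison
  expect_equal(pc$mean_pct[pc$comparison == "A vs B" &
                             pc$hallmark == "angiogenesis"], 100)
})

test_that("published worked row: 11-cluster mean of the angiogenesis column", {
  tab2 <- load_table2("p")
  vals <- tab2$pct[tab2$hallmark == "Angiogenesis" &
                     tab2$comparison == "ZsG vs LN1"]
  expect_length(vals, 11)
  expect_equal(mean(vals), 85.781818, tolerance = 1e-6)
})
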