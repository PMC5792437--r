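# Packaged worked-example tables. Checksums guard against accidental edits of
# the shipped files; the values are transcriptions of published tables (comma
# decimals normalized on load).
.fixture_md5 <- c(
  table3_fpkm.tsv = "141c2e84e812e162c73f0765749f9d7c",
  table2_contributions.tsv = "15f395a7f8fc29f042d67393d1a5aaeb"
)

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "cogex")
  if (!nzchar(path)) stop("fixture not found: ", name, call. = FALSE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[name]]))) {
    stop(sprintf("fixture integrity error: %s has md5 %s (expected %s)",
                 name, sum, .fixture_md5[[name]]), call. = FALSE)
  }
  path
}

#' The 26-gene progression-consistent FPKM fixture
#'
#' Mean FPKM of the 26 genes found consistently regulated along the ZsG ->
#' LN1 -> LN2 -> LN3 progression, with their published grouping (15 common
#' down-regulated, 10 continuum, 1 common up-regulated). Values are stored as
#' printed (comma decimals) and normalized on load; the file checksum is
#' verified.
#'
#' @return `data.frame` of class `Table3Fixture` with columns `gene_id`,
#'   `group` (`common_down` / `continuum` / `common_up`) and numeric `ZsG`,
#'   `LN1`, `LN2`, `LN3`.
#' @export
load_table3 <- function() {
  path <- fixture_path("table3_fpkm.tsv")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  for (col in c("ZsG", "LN1", "LN2", "LN3")) {
    df[[col]] <- parse_fpkm(df[[col]], col)
  }
  if (nrow(df) != 26L || any(df$ZsG < 0)) {
    stop("fixture integrity error: unexpected table3 content", call. = FALSE)
  }
  class(df) <- c("Table3Fixture", "data.frame")
  df
}

#' Mean-FPKM matrix of the 26-gene fixture
#'
#' Convenience accessor: the [load_table3()] values as a numeric matrix
#' (genes x cell lines, progression order), ready for
#' [comparisons_from_means()].
#'
#' @return 26 x 4 numeric matrix.
#' @export
table3_means <- function() {
  df <- load_table3()
  m <- as.matrix(df[, c("ZsG", "LN1", "LN2", "LN3")])
  rownames(m) <- df$gene_id
  m
}

#' The hallmark-contribution percentage fixture
#'
#' Published per-(hallmark, CoGE cluster, comparison) DEG counts and
#' percentage contributions to the invasion-and-metastasis hallmark, for the
#' uncorrected (`p`) and FDR-corrected (`q`) panels of the source table.
#'
#' @param mode `"p"` or `"q"`: which panel to return.
#' @return `data.frame` of class `Table2Fixture` with columns `hallmark`,
#'   `cluster`, `comparison`, `n_genes`, `pct`.
#' @export
load_table2 <- function(mode = c("p", "q")) {
  mode <- match.arg(mode)
  path <- fixture_path("table2_contributions.tsv")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- df[, c("hallmark", "cluster", "comparison")]
  out$n_genes <- if (mode == "p") df$n_genes_p else df$n_genes_q
  out$pct <- if (mode == "p") df$pct_p else df$pct_q
  if (any(out$pct < 0 | out$pct > 100)) {
    stop("fixture integrity error: percentage outside [0, 100]", call. = FALSE)
  }
  class(out) <- c("Table2Fixture", "data.frame")
  out
}
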