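.crosstab_classes <- c("neural", "ubiq_high", "ubiq_low", "ubiq_med", "other")
.crosstab_features <- c("five_utr", "recoding", "synonymous",
                        "splice_junction", "intron", "three_utr")

#' Marginal totals of a robustness-by-class-by-feature cross-tabulation
#'
#' The aggregation behind [tabulate_sites()]: given the per-class,
#' per-feature site counts of the robust and non-robust blocks, computes
#' every marginal by summation - per-row (class) totals, per-column
#' (feature) totals within each block and overall, block totals, and the
#' grand total. Feeding published cell values through this function
#' reproduces the published marginals exactly.
#'
#' @param robust,nonrobust numeric matrices with classes as rows and the
#'   six genic features as columns.
#' @return A list with `robust_row_totals`, `nonrobust_row_totals`,
#'   `robust_col_totals`, `nonrobust_col_totals`, `col_totals`,
#'   `robust_total`, `nonrobust_total`, `grand_total`.
#' @export
#' @examples
#' rb <- matrix(1:12, 2, 6,
#'              dimnames = list(c("neural", "other"), NULL))
#' crosstab_totals(rb, rb)$grand_total  # 2 * sum(1:12)
crosstab_totals <- function(robust, nonrobust) {
  stopifnot(is.matrix(robust), is.matrix(nonrobust),
            ncol(robust) == ncol(nonrobust))
  if (any(robust < 0) || any(nonrobust < 0))
    stop("cell counts must be non-negative")
  storage.mode(robust) <- storage.mode(nonrobust) <- "double"
  out <- list(robust_row_totals = rowSums(robust),
              nonrobust_row_totals = rowSums(nonrobust),
              robust_col_totals = colSums(robust),
              nonrobust_col_totals = colSums(nonrobust),
              col_totals = colSums(robust) + colSums(nonrobust),
              robust_total = sum(robust),
              nonrobust_total = sum(nonrobust))
  out$grand_total <- out$robust_total + out$nonrobust_total
  stopifnot(sum(out$robust_row_totals) == out$robust_total,
            sum(out$nonrobust_row_totals) == out$nonrobust_total)
  out
}

#' Cross-tabulate classified, annotated edit sites
#'
#' Builds the robustness-block by class by genic-feature table of site
#' counts. Unclassified sites (insufficient pooled depth) are excluded from
#' the blocks and reported separately; sites without a genic feature
#' (intergenic or invalid annotation) go to a logged `unassigned` bucket
#' rather than disappearing silently.
#'
#' @param records data frame with `class`, `robust` and `feature` columns.
#' @return An object of class `edit_crosstab`: `robust` and `nonrobust`
#'   cell matrices, `totals` (see [crosstab_totals()]), `n_unclassified`,
#'   `n_unassigned`.
#' @export
tabulate_sites <- function(records) {
  stopifnot(all(c("class", "robust", "feature") %in% names(records)))
  uncl <- records$class == "unclassified"
  rec <- records[!uncl, , drop = FALSE]
  genic <- rec$feature %in% .crosstab_features
  n_unassigned <- sum(!genic)
  if (n_unassigned > 0)
    message(n_unassigned,
            " classified sites without genic feature set aside")
  rec <- rec[genic, , drop = FALSE]
  cells <- function(block) {
    b <- rec[block, , drop = FALSE]
    t <- table(factor(b$class, levels = .crosstab_classes),
               factor(b$feature, levels = .crosstab_features))
    m <- matrix(as.integer(t), nrow(t), ncol(t),
                dimnames = dimnames(t))
    m
  }
  robust <- cells(rec$robust)
  nonrobust <- cells(!rec$robust)
  structure(list(robust = robust, nonrobust = nonrobust,
                 totals = crosstab_totals(robust, nonrobust),
                 n_unclassified = sum(uncl),
                 n_unassigned = n_unassigned),
            class = "edit_crosstab")
}

#' @export
print.edit_crosstab <- function(x, ...) {
  show_block <- function(m, label, row_tot, tot) {
    cat(label, "\n")
    disp <- cbind(m, Total = row_tot)
    print(disp)
    cat("  block total:", tot, "\n")
  }
  show_block(x$robust, "Robust (>25% editing in some sample)",
             x$totals$robust_row_totals, x$totals$robust_total)
  show_block(x$nonrobust, "Not robust",
             x$totals$nonrobust_row_totals, x$totals$nonrobust_total)
  cat("Grand total:", x$totals$grand_total,
      "| unclassified:", x$n_unclassified,
      "| unassigned:", x$n_unassigned, "\n")
  invisible(x)
}

#' Write a cross-tabulation as TSV
#' @param x an `edit_crosstab`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(x, path) {
  stopifnot(inherits(x, "edit_crosstab"))
  block <- function(m, lab, rt)
    data.frame(robustness = lab, class = rownames(m), m,
               total = rt, row.names = NULL, check.names = FALSE)
  df <- rbind(block(x$robust, "robust", x$totals$robust_row_totals),
              block(x$nonrobust, "not_robust",
                    x$totals$nonrobust_row_totals))
  write_tsv(df, path)
  invisible(path)
}

#' Edit-frequency histogram for one sample group
#'
#' Bins the pooled group frequency (WN for the neural group, WNN for the
#' non-neural group) of the supplied records and reports per-bin fractions
#' together with the fraction of sites edited below 1%. Restrict `records`
#' to a consequence of interest (e.g. recoding sites) before calling.
#'
#' @param records data frame with `wn` and `wnn` columns.
#' @param group `"neural"` or `"non_neural"`.
#' @param breaks histogram break points on \[0, 1\].
#' @return A list with `breaks`, `fractions` (summing to 1),
#'   `frac_below_1pct`, `n`.
#' @export
frequency_histogram <- function(records, group = c("neural", "non_neural"),
                                breaks = seq(0, 1, by = 0.01)) {
  group <- match.arg(group)
  f <- if (group == "neural") records$wn else records$wnn
  f <- f[!is.na(f)]
  if (!length(f))
    stop("no sites with a defined pooled frequency in this selection")
  h <- graphics::hist(f, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(breaks = h$breaks, fractions = h$counts / length(f),
       frac_below_1pct = mean(f < 0.01), n = length(f))
}

#' Tissue correlation and clustering over constitutive sites
#'
#' Computes the sample-by-sample correlation of edit frequencies over
#' constitutively covered sites (pairwise-complete cells) and clusters the
#' samples hierarchically on the distance 1 - correlation.
#'
#' @param f sites-by-samples frequency matrix (typically `freqs$f` rows
#'   restricted to [constitutive_sites()]).
#' @param method correlation coefficient (`"pearson"` or `"spearman"`).
#' @param linkage hierarchical-clustering linkage (default `"average"`).
#' @return An object of class `tissue_clustering`: `correlation` matrix,
#'   `hclust` object and the dendrogram `order` of sample labels.
#' @export
tissue_clustering <- function(f, method = "pearson", linkage = "average") {
  if (is.null(dim(f)) || ncol(f) < 2L)
    stop("tissue clustering needs at least two samples")
  if (nrow(f) < 1L)
    stop("constitutive site set is empty")
  cc <- stats::cor(f, use = "pairwise.complete.obs", method = method)
  hc <- stats::hclust(stats::as.dist(1 - cc), method = linkage)
  structure(list(correlation = cc, hclust = hc,
                 order = colnames(cc)[hc$order]),
            class = "tissue_clustering")
}

#' @export
print.tissue_clustering <- function(x, ...) {
  cat(sprintf("tissue_clustering over %d samples\n", ncol(x$correlation)))
  cat("order:", paste(x$order, collapse = " "), "\n")
  invisible(x)
}

#' Write a tissue clustering as correlation TSV plus Newick tree
#' @param x a `tissue_clustering`.
#' @param cor_path TSV output for the correlation matrix.
#' @param newick_path Newick output for the dendrogram (via `ape`).
#' @return Invisibly, the paths written.
#' @export
write_clustering <- function(x, cor_path, newick_path = NULL) {
  stopifnot(inherits(x, "tissue_clustering"))
  write_tsv(data.frame(sample = rownames(x$correlation), x$correlation,
                       check.names = FALSE), cor_path)
  if (!is.null(newick_path))
    ape::write.tree(ape::as.phylo(x$hclust), newick_path)
  invisible(c(cor_path, newick_path))
}

#' Per-site, per-tissue editing profile of one gene
#'
#' @param gene_id gene identifier.
#' @param records data frame with `site_id` and `gene_id` columns (e.g.
#'   classified+annotated records).
#' @param freqs list with `f` matrix as from [frequency_matrix()].
#' @return Sites-by-samples frequency matrix ordered by genomic position;
#'   cells with no coverage are `NA`, never zero-filled.
#' @export
gene_profile <- function(gene_id, records, freqs) {
  stopifnot(all(c("site_id", "gene_id", "pos") %in% names(records)))
  rows <- records[!is.na(records$gene_id) & records$gene_id == gene_id, ,
                  drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no edited sites recorded for gene ", gene_id)
  rows <- rows[order(rows$pos), , drop = FALSE]
  m <- freqs$f[rows$site_id, , drop = FALSE]
  rownames(m) <- rows$site_id
  m
}
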