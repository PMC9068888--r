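#' Depth-weighted pooled edit frequency
#'
#' Pools allele counts over a group of samples and returns the edit frequency
#' of the pooled counts, `sum(g) / sum(a + g)`. Pooling the reads weights
#' each sample by its depth; this is not the mean of per-sample ratios.
#'
#' @param a,g vectors of unedited (A-state) and edited (G-state) read counts,
#'   one element per sample in the group. `NA` counts are treated as zero
#'   depth for that sample.
#' @return A single frequency in \[0, 1\], or `NA` when the pooled depth is
#'   zero.
#' @export
#' @examples
#' pooled_frequency(c(9, 7), c(1, 3))     # 4/20 = 0.2
#' pooled_frequency(c(100, 0), c(0, 10))  # 10/110, not the mean 0.5
pooled_frequency <- function(a, g) {
  if (length(a) == 0L || length(g) == 0L)
    stop("cannot pool over an empty sample group")
  if (length(a) != length(g))
    stop("'a' and 'g' must have the same length")
  if (any(a < 0, na.rm = TRUE) || any(g < 0, na.rm = TRUE))
    stop("allele counts must be non-negative")
  a[is.na(a)] <- 0
  g[is.na(g)] <- 0
  depth <- sum(a) + sum(g)
  if (depth == 0) return(NA_real_)
  sum(g) / depth
}

#' Robust-editing flag
#'
#' A site is robustly edited when at least one sample shows an edit frequency
#' strictly above `robust_min` (default 0.25). A frequency of exactly 0.25
#' does not qualify.
#'
#' @param f per-sample edit frequencies for one site; `NA` marks samples
#'   with no coverage.
#' @param robust_min strict lower bound, default 0.25.
#' @return `TRUE` or `FALSE`.
#' @export
is_robust <- function(f, robust_min = 0.25) {
  if (all(is.na(f)))
    stop("all per-sample frequencies are missing")
  any(f > robust_min, na.rm = TRUE)
}

#' Classify edit sites in the (WN, WNN) plane
#'
#' Assigns each site one of the classes `neural`, `ubiq_high`, `ubiq_low`,
#' `ubiq_med`, `other` or `unclassified` from its pooled neural (WN) and
#' non-neural (WNN) edit frequencies and its cumulative pooled read depth.
#' Sites with pooled depth below `thresholds$min_pooled_depth`, or with an
#' undefined WN or WNN (no covered sample in one group), are `unclassified`.
#' Otherwise the class predicates (see [edit_thresholds()]) are evaluated in
#' the configured precedence order and the first match wins; a site matching
#' none is `other`. A WNN of exactly zero with positive WN is treated as an
#' infinite ratio and satisfies the neural predicate; WN = WNN = 0 does not
#' (such sites fall in the ubiquitous-low band).
#'
#' @param wn,wnn pooled neural and non-neural edit frequencies in \[0, 1\]
#'   (vectors are recycled to a common length).
#' @param pooled_depth cumulative read depth over all pooled samples.
#' @param thresholds an [edit_thresholds()] object.
#' @return Character vector of class labels.
#' @export
#' @examples
#' th <- edit_thresholds()
#' classify_site(c(0.30, 0.70, 0.20, 0.50), c(0.10, 0.50, 0.30, 0.30),
#'               100, th)
classify_site <- function(wn, wnn, pooled_depth,
                          thresholds = edit_thresholds()) {
  stopifnot(inherits(thresholds, "edit_thresholds"))
  n <- max(length(wn), length(wnn), length(pooled_depth))
  wn <- rep_len(wn, n); wnn <- rep_len(wnn, n)
  pooled_depth <- rep_len(pooled_depth, n)
  bad <- function(x) !is.na(x) & (x < 0 | x > 1)
  if (any(bad(wn)) || any(bad(wnn)))
    stop("WN and WNN must lie in [0, 1]")
  th <- thresholds
  ok <- !is.na(wn) & !is.na(wnn) & pooled_depth >= th$min_pooled_depth

  ratio_fires <- ifelse(wnn > 0, wn / wnn > th$neural_ratio, wn > 0)
  pred <- list(
    neural    = ratio_fires,
    ubiq_high = wn > th$high_wn_min & wnn > th$high_wnn_min,
    ubiq_low  = wn < th$low_max & wnn < th$low_max,
    ubiq_med  = wn >= th$low_max & wn <= th$med_wn_max &
                wnn >= th$low_max & wnn <= th$med_wnn_max
  )
  cls <- rep("other", n)
  for (nm in rev(th$precedence)) cls[ok & pred[[nm]]] <- nm
  cls[!ok] <- "unclassified"
  cls
}

#' Pool counts and classify every site of an allele-count matrix
#'
#' Computes, for each site, the depth-weighted pooled frequencies WN (over
#' samples in the `neural` group) and WNN (over `non_neural`), the cumulative
#' pooled depth, the robust flag, and the site class. Samples in the `mixed`
#' group are excluded from WN/WNN pooling (their heterogeneous composition
#' would blur the contrast) but still count towards the robust flag; samples
#' in the `excluded` group, and samples not from the reference individual,
#' take no part at all.
#'
#' @param counts an [allele_counts()] object.
#' @param tissues tissue panel data frame with columns `sample_id`, `group`
#'   (one of `neural`, `non_neural`, `mixed`, `excluded`) and optionally
#'   `reference_individual` (logical, default `TRUE`).
#' @param thresholds an [edit_thresholds()] object.
#' @return A data frame with one row per site: coordinates, `wn`, `wnn`,
#'   `pooled_depth`, `max_freq`, `robust`, `class`.
#' @export
classify_sites <- function(counts, tissues,
                           thresholds = edit_thresholds()) {
  stopifnot(inherits(counts, "allele_counts"))
  tissues <- validate_tissue_panel(tissues, require_groups = TRUE)
  use <- tissues$reference_individual & tissues$group != "excluded"
  tissues <- tissues[use, , drop = FALSE]
  missing_samples <- setdiff(tissues$sample_id, counts$samples)
  if (length(missing_samples))
    stop("tissue panel samples absent from counts: ",
         paste(missing_samples, collapse = ", "))

  grp <- function(g) tissues$sample_id[tissues$group == g]
  neural <- grp("neural"); non_neural <- grp("non_neural")
  if (length(neural) == 0L || length(non_neural) == 0L)
    stop("classification needs at least one neural and one non-neural sample")

  A <- counts$A; G <- counts$G
  pool <- function(samples) {
    ga <- rowSums(G[, samples, drop = FALSE], na.rm = TRUE)
    da <- ga + rowSums(A[, samples, drop = FALSE], na.rm = TRUE)
    list(f = ifelse(da > 0, ga / da, NA_real_), depth = da)
  }
  pn <- pool(neural); pnn <- pool(non_neural)
  pooled_depth <- pn$depth + pnn$depth

  all_samp <- tissues$sample_id
  Dall <- A[, all_samp, drop = FALSE] + G[, all_samp, drop = FALSE]
  Fall <- ifelse(Dall > 0, G[, all_samp, drop = FALSE] / Dall, NA_real_)
  max_freq <- suppressWarnings(apply(Fall, 1L, max, na.rm = TRUE))
  max_freq[!is.finite(max_freq)] <- NA_real_
  robust <- !is.na(max_freq) & max_freq > thresholds$robust_min

  data.frame(counts$sites,
             wn = pn$f, wnn = pnn$f, pooled_depth = pooled_depth,
             max_freq = max_freq, robust = robust,
             class = classify_site(pn$f, pnn$f, pooled_depth, thresholds),
             row.names = NULL, stringsAsFactors = FALSE)
}
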