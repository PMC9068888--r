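#' Per-site, per-sample allele counts on the transcribed strand
#'
#' Container for unedited (A-state) and edited (G-state) read counts at
#' candidate adenosines. Counts are always expressed on the transcribed
#' strand: for a gene on the minus strand the genomic reference base is a T
#' and edited reads appear as C in genomic orientation, but they enter this
#' container as A and G. Positions are 1-based, matching GFF3 and VCF.
#'
#' @param sites data frame with columns `chrom`, `pos`, `strand`
#'   (`"+"`, `"-"`, or `"*"` when no gene model assigns a strand).
#' @param A,G integer matrices, sites by samples, of A-state and G-state
#'   read counts. Column names are sample identifiers.
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(sites, A, G) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "strand") %in% names(sites)),
            nrow(A) == nrow(sites), nrow(G) == nrow(sites),
            identical(dim(A), dim(G)),
            !is.null(colnames(A)), identical(colnames(A), colnames(G)))
  if (any(A < 0, na.rm = TRUE) || any(G < 0, na.rm = TRUE))
    stop("allele counts must be non-negative")
  sites <- sites[, c("chrom", "pos", "strand")]
  sites$site_id <- site_key(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(sites$site_id))
    stop("duplicated site coordinates")
  rownames(A) <- rownames(G) <- sites$site_id
  structure(list(sites = sites, samples = colnames(A),
                 A = A, G = G),
            class = "allele_counts")
}

site_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = ":")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Subset an allele_counts object by site
#' @param x an `allele_counts` object.
#' @param i logical or integer index over sites.
#' @param ... unused.
#' @export
`[.allele_counts` <- function(x, i, ...) {
  allele_counts(x$sites[i, , drop = FALSE],
                x$A[i, , drop = FALSE], x$G[i, , drop = FALSE])
}

#' Build an allele_counts object from a long count table
#'
#' @param df data frame with columns `chrom`, `pos`, `strand`, `sample`,
#'   `a_count`, `g_count` (one row per site/sample pair; absent pairs are
#'   zero-depth).
#' @return An [allele_counts()] object.
#' @export
allele_counts_from_long <- function(df) {
  stopifnot(all(c("chrom", "pos", "strand", "sample",
                  "a_count", "g_count") %in% names(df)))
  key <- site_key(df$chrom, df$pos, df$strand)
  sites <- df[!duplicated(key), c("chrom", "pos", "strand")]
  ukey <- unique(key)
  samples <- unique(as.character(df$sample))
  ii <- match(key, ukey)
  jj <- match(df$sample, samples)
  A <- G <- matrix(0L, length(ukey), length(samples),
                   dimnames = list(ukey, samples))
  A[cbind(ii, jj)] <- as.integer(df$a_count)
  G[cbind(ii, jj)] <- as.integer(df$g_count)
  allele_counts(sites, A, G)
}

#' Edit frequency of one site in one sample
#'
#' The fraction of reads supporting the edited state,
#' `g / (a + g)`. With zero depth the frequency is undefined and `NA` is
#' returned - never 0, since absence of data is not absence of editing.
#'
#' @param a_count,g_count non-negative read counts (vectorised).
#' @return Numeric vector of frequencies in \[0, 1\] with `NA` at zero depth.
#' @export
#' @examples
#' edit_frequency(10, 0)   # 0
#' edit_frequency(12, 4)   # 0.25
#' edit_frequency(0, 0)    # NA
edit_frequency <- function(a_count, g_count) {
  if (any(a_count < 0, na.rm = TRUE) || any(g_count < 0, na.rm = TRUE))
    stop("allele counts must be non-negative")
  depth <- a_count + g_count
  ifelse(!is.na(depth) & depth > 0, g_count / depth, NA_real_)
}

#' Per-site, per-sample frequency and depth matrices
#'
#' @param counts an [allele_counts()] object.
#' @return A list with matrices `f` (edit frequency, `NA` where depth is
#'   zero) and `depth` (`a + g`), both sites by samples.
#' @export
frequency_matrix <- function(counts) {
  stopifnot(inherits(counts, "allele_counts"))
  depth <- counts$A + counts$G
  f <- ifelse(depth > 0, counts$G / depth, NA_real_)
  list(f = f, depth = depth)
}

#' Call candidate A-to-I edit sites
#'
#' A site is a candidate edit site when (i) the same-individual genomic
#' genotype is homozygous A on the transcribed strand, (ii) at least one
#' sample has an edit frequency strictly above `min_site_freq`, and (iii) at
#' least one sample carries at least one edited read. Heterozygous (AG)
#' genotypes are the signature of a genomic polymorphism masquerading as
#' editing and are excluded, as are GG/other/missing genotypes; the reason
#' for every exclusion is recorded.
#'
#' @param counts an [allele_counts()] object.
#' @param genotypes data frame with columns `chrom`, `pos`, `genotype`
#'   (one of `"AA"`, `"AG"`, `"GG"`, `"other"`; expressed on the transcribed
#'   strand), and optionally `dna_depth`, `mq`. Sites absent from the table
#'   are treated as genotype missing.
#' @param min_site_freq strict per-sample frequency threshold (default
#'   0.001, i.e. 0.1%); a site passes when any sample exceeds it.
#' @return A data frame with one row per site of `counts`: coordinates,
#'   `candidate` (logical) and `reason` (`NA` for candidates, otherwise one
#'   of `het_genotype`, `non_A_genotype`, `genotype_missing`,
#'   `ambiguous_strand`, `no_edited_reads`, `below_min_freq`).
#' @export
call_candidate_sites <- function(counts, genotypes, min_site_freq = 0.001) {
  stopifnot(inherits(counts, "allele_counts"))
  stopifnot(all(c("chrom", "pos", "genotype") %in% names(genotypes)))
  if (min_site_freq < 0 || min_site_freq >= 1)
    stop("'min_site_freq' must lie in [0, 1)")
  fm <- frequency_matrix(counts)
  sites <- counts$sites

  gkey <- paste(genotypes$chrom, genotypes$pos, sep = ":")
  skey <- paste(sites$chrom, sites$pos, sep = ":")
  gt <- genotypes$genotype[match(skey, gkey)]
  gt[is.na(gt)] <- "missing"

  max_f <- suppressWarnings(apply(fm$f, 1L, max, na.rm = TRUE))
  max_f[!is.finite(max_f)] <- NA_real_
  any_g <- rowSums(counts$G, na.rm = TRUE) > 0

  reason <- rep(NA_character_, nrow(sites))
  reason[gt == "missing"] <- "genotype_missing"
  reason[gt %in% c("GG", "other")] <- "non_A_genotype"
  reason[gt == "AG"] <- "het_genotype"
  ambiguous <- is.na(reason) & sites$strand == "*" & dual_orientation(counts)
  reason[ambiguous] <- "ambiguous_strand"
  reason[is.na(reason) & !any_g] <- "no_edited_reads"
  reason[is.na(reason) & !(!is.na(max_f) & max_f > min_site_freq)] <-
    "below_min_freq"

  data.frame(sites, candidate = is.na(reason), reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

# A strand-unknown site with edited reads attributable to both orientations
# cannot be interpreted; counts carry only transcribed-strand A/G states, so
# ambiguity here means the same chrom:pos appears under more than one strand.
dual_orientation <- function(counts) {
  cp <- paste(counts$sites$chrom, counts$sites$pos, sep = ":")
  cp %in% cp[duplicated(cp)]
}

#' Constitutively covered edit sites
#'
#' Sites usable for tissue-correlation analysis: covered by more than
#' `min_depth_all - 1` reads (default: more than 3) in *every* sample of the
#' panel, and reaching an edit frequency of at least `min_max_freq`
#' (default 5%) in at least one sample.
#'
#' @param freqs a list with matrices `f` and `depth` as returned by
#'   [frequency_matrix()].
#' @param min_depth_all minimum per-sample depth; the retention condition is
#'   `depth >= min_depth_all`, i.e. strictly more than `min_depth_all - 1`
#'   reads.
#' @param min_max_freq inclusive threshold on the maximum per-sample
#'   frequency.
#' @param samples optional character vector restricting the panel.
#' @return Character vector of retained site identifiers (rownames of `f`).
#' @export
constitutive_sites <- function(freqs, min_depth_all = 4, min_max_freq = 0.05,
                               samples = NULL) {
  stopifnot(is.list(freqs), !is.null(freqs$f), !is.null(freqs$depth))
  f <- freqs$f; depth <- freqs$depth
  if (!is.null(samples)) {
    f <- f[, samples, drop = FALSE]
    depth <- depth[, samples, drop = FALSE]
  }
  if (ncol(f) == 0L)
    stop("empty sample panel")
  covered <- rowSums(depth >= min_depth_all) == ncol(depth)
  max_f <- suppressWarnings(apply(f, 1L, max, na.rm = TRUE))
  keep <- covered & is.finite(max_f) & max_f >= min_max_freq
  rownames(f)[keep]
}
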