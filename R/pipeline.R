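#' Run the full editing-landscape analysis
#'
#' Chains the pipeline stages: per-sample edit frequencies, candidate-site
#' calling against the same-individual genomic genotypes, WN/WNN pooling
#' and classification, feature annotation with recoding consequences,
#' repeat/domain overlap, the constitutive site set and the class-by-feature
#' cross-tabulation.
#'
#' @param counts an [allele_counts()] object (transcribed-strand A/G reads).
#' @param genotypes genomic genotype data frame (see
#'   [call_candidate_sites()]).
#' @param tissues tissue panel data frame.
#' @param models optional [read_gene_models()] object; enables annotation.
#' @param genome optional `DNAStringSet` or FASTA path (required with
#'   `models`).
#' @param repeats,domains,tm optional overlap tracks (see
#'   [overlap_flags()]).
#' @param thresholds an [edit_thresholds()] object.
#' @param min_site_freq candidate-site frequency filter (default 0.001).
#' @return An object of class `editing_landscape`: `candidates` (all input
#'   sites with exclusion reasons), `records` (classified candidate sites,
#'   with annotation columns when models are given), `freqs`,
#'   `constitutive` (site ids), `crosstab` (when annotated), plus the
#'   inputs `tissues` and `thresholds`.
#' @export
analyze_editing <- function(counts, genotypes, tissues,
                            models = NULL, genome = NULL,
                            repeats = NULL, domains = NULL, tm = NULL,
                            thresholds = edit_thresholds(),
                            min_site_freq = 0.001) {
  tissues <- validate_tissue_panel(tissues, require_groups = TRUE)
  use <- tissues$sample_id[tissues$reference_individual &
                            tissues$group != "excluded"]
  counts_use <- counts
  counts_use$A <- counts_use$A[, use, drop = FALSE]
  counts_use$G <- counts_use$G[, use, drop = FALSE]
  counts_use$samples <- use

  freqs <- frequency_matrix(counts_use)
  candidates <- call_candidate_sites(counts_use, genotypes, min_site_freq)
  cand <- counts_use[candidates$candidate]
  records <- classify_sites(cand, tissues, thresholds)
  records$site_id <- site_key(records$chrom, records$pos, records$strand)

  crosstab <- NULL
  if (!is.null(models)) {
    if (is.null(genome))
      stop("annotation needs the genome sequence")
    ann <- annotate_sites(records, models, genome)
    flags <- overlap_flags(records, ann, repeats = repeats,
                           domains = domains, tm = tm, models = models)
    records <- cbind(records, ann, flags)
    crosstab <- tabulate_sites(records)
  }

  cand_freqs <- list(f = freqs$f[candidates$candidate, , drop = FALSE],
                     depth = freqs$depth[candidates$candidate, , drop = FALSE])
  constitutive <- constitutive_sites(cand_freqs)
  structure(list(candidates = candidates, records = records,
                 freqs = freqs, constitutive = constitutive,
                 crosstab = crosstab, tissues = tissues,
                 thresholds = thresholds),
            class = "editing_landscape")
}

#' @export
print.editing_landscape <- function(x, ...) {
  cat(sprintf("editing_landscape: %d sites in, %d candidates\n",
              nrow(x$candidates), nrow(x$records)))
  cat("class counts:\n")
  print(table(x$records$class))
  invisible(x)
}

#' @method summary editing_landscape
#' @export
summary.editing_landscape <- function(object, ...) {
  cat(sprintf("Sites examined:      %d\n", nrow(object$candidates)))
  excl <- table(object$candidates$reason)
  if (length(excl)) {
    cat("Exclusions:\n")
    for (r in names(excl)) cat(sprintf("  %-18s %d\n", r, excl[[r]]))
  }
  cat(sprintf("Candidate sites:     %d\n", nrow(object$records)))
  cat(sprintf("Robust sites:        %d\n", sum(object$records$robust)))
  cat(sprintf("Constitutive sites:  %d\n", length(object$constitutive)))
  cat("Classes:\n")
  print(table(object$records$class))
  if (!is.null(object$crosstab)) print(object$crosstab)
  invisible(object)
}

#' Confusion matrix and per-class recall against planted truth
#'
#' Compares pipeline output with the generator's ground truth. Every
#' planted site receives a called label: its class when it was classified;
#' `excluded` when candidate calling rejected it (e.g. a heterozygous
#' genotype); `not_called` when it passed no filter at all or is absent
#' from the calls. Rows of the confusion matrix are true classes, columns
#' called labels; cells sum to the number of planted sites. Recall for an
#' edited class is the fraction of its planted sites called as that class;
#' for `het_artifact`, the fraction excluded; for `unedited`, the fraction
#' not called.
#'
#' @param truth the `truth` element of an `edit_sim` (list with `sites`),
#'   or its `sites` data frame.
#' @param called an `editing_landscape`, or a data frame with `site_id` and
#'   `class` columns (exclusions may be encoded as class `excluded`).
#' @return An object of class `recovery_eval`: `confusion` matrix and
#'   `recall` named vector.
#' @export
evaluate_recovery <- function(truth, called) {
  ts <- if (is.data.frame(truth)) truth else truth$sites
  stopifnot(all(c("site_id", "true_class") %in% names(ts)))

  if (inherits(called, "editing_landscape")) {
    cand <- called$candidates
    cand_id <- site_key(cand$chrom, cand$pos, cand$strand)
    if (!all(ts$site_id %in% cand_id))
      stop("truth and calls disagree on site coordinates")
    lab <- rep("not_called", nrow(ts))
    i <- match(ts$site_id, cand_id)
    geno_excluded <- !cand$candidate[i] &
      cand$reason[i] %in% c("het_genotype", "non_A_genotype",
                            "ambiguous_strand")
    lab[geno_excluded] <- "excluded"
    j <- match(ts$site_id, called$records$site_id)
    lab[!is.na(j)] <- called$records$class[stats::na.omit(j)]
  } else {
    stopifnot(all(c("site_id", "class") %in% names(called)))
    lab <- called$class[match(ts$site_id, called$site_id)]
    lab[is.na(lab)] <- "not_called"
  }

  true_levels <- unique(ts$true_class)
  call_levels <- c("neural", "ubiq_high", "ubiq_low", "ubiq_med", "other",
                   "unclassified", "excluded", "not_called")
  lab[!lab %in% call_levels] <- "other"
  confusion <- table(true = factor(ts$true_class, levels = true_levels),
                     called = factor(lab, levels = call_levels))
  target <- c(neural = "neural", ubiq_low = "ubiq_low",
              ubiq_med = "ubiq_med", ubiq_high = "ubiq_high",
              het_artifact = "excluded", unedited = "not_called")
  recall <- vapply(true_levels, function(cl) {
    want <- if (cl %in% names(target)) target[[cl]] else cl
    n <- sum(confusion[cl, ])
    if (n == 0) NA_real_ else confusion[cl, want] / n
  }, numeric(1))
  structure(list(confusion = confusion, recall = recall),
            class = "recovery_eval")
}

#' @export
print.recovery_eval <- function(x, ...) {
  print(x$confusion)
  cat("recall:\n")
  print(round(x$recall, 4))
  invisible(x)
}
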