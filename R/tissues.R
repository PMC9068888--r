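#' Validate a tissue panel
#'
#' A tissue panel maps each RNA sample to a group: `neural`, `non_neural`,
#' `mixed` (tissues of heterogeneous composition, excluded from WN/WNN
#' pooling) or `excluded`. The optional logical column
#' `reference_individual` marks samples taken from the same individual as
#' the genomic reference; only those take part in site discovery and
#' classification (defaults to `TRUE` for all samples).
#'
#' @param tissues data frame with columns `sample_id`, `group` and
#'   optionally `reference_individual`.
#' @param require_groups when `TRUE`, require at least one neural and one
#'   non-neural reference-individual sample.
#' @return The validated (and completed) data frame.
#' @export
validate_tissue_panel <- function(tissues, require_groups = FALSE) {
  stopifnot(is.data.frame(tissues),
            all(c("sample_id", "group") %in% names(tissues)))
  tissues$sample_id <- as.character(tissues$sample_id)
  tissues$group <- as.character(tissues$group)
  ok <- c("neural", "non_neural", "mixed", "excluded")
  if (!all(tissues$group %in% ok))
    stop("tissue groups must be one of: ", paste(ok, collapse = ", "))
  if (anyDuplicated(tissues$sample_id))
    stop("duplicated sample_id in tissue panel")
  if (is.null(tissues$reference_individual))
    tissues$reference_individual <- TRUE
  tissues$reference_individual <- as.logical(tissues$reference_individual)
  if (require_groups) {
    use <- tissues$reference_individual & tissues$group != "excluded"
    if (!any(tissues$group[use] == "neural") ||
        !any(tissues$group[use] == "non_neural"))
      stop("panel needs at least one neural and one non-neural sample")
  }
  tissues
}
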