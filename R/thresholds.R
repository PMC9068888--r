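#' Classification thresholds for edit-site classes
#'
#' Bundles the numeric thresholds that define the edit-site classes in the
#' (WN, WNN) plane, where WN and WNN are the depth-weighted pooled edit
#' frequencies over neural and non-neural samples. The defaults are:
#' a site is *neural* when WN/WNN exceeds `neural_ratio`; *ubiquitous-high*
#' when WN exceeds `high_wn_min` and WNN exceeds `high_wnn_min`;
#' *ubiquitous-low* when both WN and WNN are below `low_max`;
#' *ubiquitous-medium* when WN lies in [`low_max`, `med_wn_max`] and WNN in
#' [`low_max`, `med_wnn_max`]; anything else is *other*. Sites whose pooled
#' read depth falls below `min_pooled_depth` are not classified at all.
#'
#' Class predicates overlap at low frequencies, so class assignment follows
#' the `precedence` order: the first predicate that fires wins. The default
#' tests the ubiquitous-low band before the neural ratio because the ratio
#' of two near-zero pooled frequencies is dominated by sampling noise; see
#' the methods vignette for the analysis behind this choice. The neural and
#' ubiquitous-high predicates can never fire together: they would require
#' WN > `neural_ratio` * `high_wnn_min` = 1.1 > 1.
#'
#' @param neural_ratio minimum WN/WNN ratio for the neural class.
#' @param low_max exclusive upper bound on both WN and WNN for the
#'   ubiquitous-low class (also the inclusive lower edge of the medium band).
#' @param med_wn_max,med_wnn_max inclusive upper bounds on WN and WNN for
#'   the ubiquitous-medium class.
#' @param high_wn_min,high_wnn_min exclusive lower bounds on WN and WNN for
#'   the ubiquitous-high class.
#' @param robust_min a site is robust when at least one sample has edit
#'   frequency strictly above this value.
#' @param min_pooled_depth minimum cumulative read depth (reads summed over
#'   all pooled neural and non-neural samples) for a site to be classified.
#' @param precedence character vector giving the order in which the class
#'   predicates are tested; must be a permutation of
#'   `c("neural", "ubiq_high", "ubiq_low", "ubiq_med")`.
#'
#' @return An object of class `edit_thresholds`.
#' @seealso [classify_site()], [classify_sites()]
#' @export
#' @examples
#' th <- edit_thresholds()
#' classify_site(0.30, 0.10, 100, th)  # ratio 3 > 2.75 -> neural
edit_thresholds <- function(neural_ratio = 2.75,
                            low_max = 0.05,
                            med_wn_max = 0.40,
                            med_wnn_max = 0.60,
                            high_wn_min = 0.60,
                            high_wnn_min = 0.40,
                            robust_min = 0.25,
                            min_pooled_depth = 10,
                            precedence = c("ubiq_low", "neural",
                                           "ubiq_high", "ubiq_med")) {
  freqs <- c(low_max = low_max, med_wn_max = med_wn_max,
             med_wnn_max = med_wnn_max, high_wn_min = high_wn_min,
             high_wnn_min = high_wnn_min, robust_min = robust_min)
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > 1))
    stop("frequency thresholds must lie in [0, 1]")
  if (!is.finite(neural_ratio) || neural_ratio <= 1)
    stop("'neural_ratio' must be > 1")
  if (min_pooled_depth < 0)
    stop("'min_pooled_depth' must be non-negative")
  if (!setequal(precedence, c("neural", "ubiq_high", "ubiq_low", "ubiq_med")) ||
      anyDuplicated(precedence))
    stop("'precedence' must be a permutation of the four class names")
  structure(list(neural_ratio = neural_ratio, low_max = low_max,
                 med_wn_max = med_wn_max, med_wnn_max = med_wnn_max,
                 high_wn_min = high_wn_min, high_wnn_min = high_wnn_min,
                 robust_min = robust_min, min_pooled_depth = min_pooled_depth,
                 precedence = precedence),
            class = "edit_thresholds")
}

#' @export
print.edit_thresholds <- function(x, ...) {
  cat("Edit-site classification thresholds\n")
  cat(sprintf("  neural:    WN/WNN > %.3g\n", x$neural_ratio))
  cat(sprintf("  ubiq_high: WN > %.3g and WNN > %.3g\n",
              x$high_wn_min, x$high_wnn_min))
  cat(sprintf("  ubiq_low:  WN < %.3g and WNN < %.3g\n",
              x$low_max, x$low_max))
  cat(sprintf("  ubiq_med:  %.3g <= WN <= %.3g and %.3g <= WNN <= %.3g\n",
              x$low_max, x$med_wn_max, x$low_max, x$med_wnn_max))
  cat(sprintf("  robust:    any sample frequency > %.3g\n", x$robust_min))
  cat(sprintf("  classified only at pooled depth >= %d reads\n",
              as.integer(x$min_pooled_depth)))
  cat("  precedence:", paste(x$precedence, collapse = " > "), "\n")
  invisible(x)
}
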