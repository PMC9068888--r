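#' Outgroup genotype track with coverage window
#'
#' Wraps one outgroup species' genomic genotype calls together with its CDS
#' shotgun-coverage summary. Calls are trusted only inside the expected
#' coverage window, mean plus or minus two standard deviations (floored at
#' one read).
#'
#' @param species_id species identifier.
#' @param calls data frame with `chrom`, `pos`, `allele1`, `allele2`
#'   (genomic alleles), `depth`, `mq` (e.g. from [read_outgroup_vcf()]).
#' @param depth_mean,depth_sd mean and standard deviation of shotgun
#'   coverage over CDS regions.
#' @param min_depth minimum depth for a confident homozygous call.
#' @return An object of class `outgroup_track`.
#' @export
outgroup_track <- function(species_id, calls, depth_mean, depth_sd,
                           min_depth = 5) {
  stopifnot(all(c("chrom", "pos", "allele1", "allele2", "depth", "mq")
                %in% names(calls)))
  if (depth_mean <= 0 || depth_sd < 0)
    stop("invalid depth statistics")
  structure(list(species_id = species_id, calls = calls,
                 depth_window = c(max(1, depth_mean - 2 * depth_sd),
                                  depth_mean + 2 * depth_sd),
                 min_depth = min_depth),
            class = "outgroup_track")
}

#' @export
print.outgroup_track <- function(x, ...) {
  cat(sprintf("outgroup_track '%s': %d sites, depth window [%.1f, %.1f]\n",
              x$species_id, nrow(x$calls),
              x$depth_window[1], x$depth_window[2]))
  invisible(x)
}

#' Conservation status of edit sites against one outgroup
#'
#' For each focal-species site, looks up the orthologous outgroup genotype
#' and classifies it as `conserved_A` (confident homozygous adenosine on the
#' transcribed strand), `derived_in_focal` (confident homozygous
#' non-adenosine: the editable A arose on the focal lineage) or `no_call`.
#' A call is confident only when mapping quality reaches `min_mq`, depth
#' lies inside the species' expected coverage window and reaches the
#' track's minimum, and the genotype is homozygous.
#'
#' @param sites data frame with `chrom`, `pos`, `strand`.
#' @param track an [outgroup_track()].
#' @param min_mq minimum mapping quality (default 20).
#' @param ortho_map optional data frame with `chrom`, `pos`,
#'   `target_chrom`, `target_pos` mapping focal coordinates to outgroup
#'   coordinates; by default the identity map is used (outgroup reads
#'   mapped directly to the focal genome).
#' @return Data frame with `site_id`, `status`, `reason` (reason `NA` for
#'   confident calls).
#' @export
conservation_status <- function(sites, track, min_mq = 20,
                                ortho_map = NULL) {
  stopifnot(inherits(track, "outgroup_track"))
  chrom <- sites$chrom; pos <- sites$pos
  if (!is.null(ortho_map)) {
    mk <- paste(ortho_map$chrom, ortho_map$pos, sep = ":")
    i <- match(paste(chrom, pos, sep = ":"), mk)
    chrom <- ortho_map$target_chrom[i]
    pos <- ortho_map$target_pos[i]
  }
  calls <- track$calls
  idx <- match(paste(chrom, pos, sep = ":"),
               paste(calls$chrom, calls$pos, sep = ":"))

  n <- nrow(sites)
  status <- rep("no_call", n)
  reason <- rep(NA_character_, n)
  unmapped <- is.na(chrom) | is.na(pos)
  reason[unmapped] <- "no_orthologous_position"
  nohit <- !unmapped & is.na(idx)
  reason[nohit] <- "no_genotype"

  ok <- !unmapped & !nohit
  a1 <- calls$allele1[idx]; a2 <- calls$allele2[idx]
  depth <- calls$depth[idx]; mq <- calls$mq[idx]
  low_mq <- ok & (is.na(mq) | mq < min_mq)
  reason[low_mq] <- "low_mapping_quality"; ok <- ok & !low_mq
  outside <- ok & (is.na(depth) | depth < track$depth_window[1] |
                     depth > track$depth_window[2])
  reason[outside] <- "depth_outside_window"; ok <- ok & !outside
  thin <- ok & depth < track$min_depth
  reason[thin] <- "insufficient_depth"; ok <- ok & !thin
  het <- ok & (is.na(a1) | is.na(a2) | a1 != a2)
  reason[het] <- "not_homozygous"; ok <- ok & !het

  tx_allele <- ifelse(sites$strand == "-", unname(.complement[a1]), a1)
  status[ok & tx_allele == "A"] <- "conserved_A"
  status[ok & tx_allele != "A"] <- "derived_in_focal"
  data.frame(site_id = site_key(sites$chrom, sites$pos, sites$strand),
             status = status, reason = reason, stringsAsFactors = FALSE)
}

#' Flag lineage-specific ("new") edits across outgroups
#'
#' A focal edited site counts as a new edit only when *every* supplied
#' outgroup yields a confident homozygous non-adenosine call
#' (`derived_in_focal`); a `no_call` in any outgroup withholds the flag.
#'
#' @param statuses list of [conservation_status()] results, one per
#'   outgroup, over the same sites.
#' @return Data frame with `site_id`, `new_edit` (logical) and per-species
#'   status columns.
#' @export
new_edit_calls <- function(statuses) {
  stopifnot(length(statuses) >= 1L)
  ids <- statuses[[1L]]$site_id
  for (s in statuses)
    if (!identical(s$site_id, ids))
      stop("conservation status tables cover different sites")
  st <- do.call(cbind, lapply(statuses, `[[`, "status"))
  out <- data.frame(site_id = ids,
                    new_edit = rowSums(st == "derived_in_focal") == ncol(st),
                    stringsAsFactors = FALSE)
  for (i in seq_along(statuses))
    out[[paste0("status_", i)]] <- statuses[[i]]$status
  out
}

#' Count lineage-specific edits by class and consequence
#'
#' Joins new-edit flags to classified, annotated edit-site records and
#' tallies new edits in total, per class, and for the recoding subset.
#' Sites present in the conservation calls but absent from the records (or
#' vice versa) are excluded from the tallies; their number is reported.
#'
#' @param new_edits output of [new_edit_calls()].
#' @param records data frame with `site_id`, `class` and `feature` columns
#'   (classified, annotated sites).
#' @return A list with `total` (count of new edits), `by_class` (data frame
#'   `class`, `n`, `n_recoding`) and `n_unjoined`.
#' @export
count_new_edits <- function(new_edits, records) {
  stopifnot(all(c("site_id", "new_edit") %in% names(new_edits)),
            all(c("site_id", "class", "feature") %in% names(records)))
  idx <- match(new_edits$site_id, records$site_id)
  joined <- !is.na(idx)
  n_unjoined <- sum(!joined)
  if (n_unjoined > 0)
    message(n_unjoined, " conservation calls without a matching record ",
            "were excluded")
  ne <- new_edits$new_edit[joined]
  cls <- records$class[idx[joined]]
  feat <- records$feature[idx[joined]]
  classes <- c("neural", "ubiq_high", "ubiq_low", "ubiq_med", "other",
               "unclassified")
  by_class <- data.frame(
    class = classes,
    n = vapply(classes, function(k) sum(ne & cls == k), integer(1)),
    n_recoding = vapply(classes, function(k)
      sum(ne & cls == k & feat == "recoding"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(total = sum(ne), by_class = by_class, n_unjoined = n_unjoined)
}
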