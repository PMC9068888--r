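#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS records into per-transcript interval structures
#' and selects one *primary* transcript per gene: the longest isoform by
#' summed exon length, ties broken by lexicographic transcript identifier.
#'
#' @param x path to a GFF3 file, or a `GRanges` as returned by
#'   `rtracklayer::import` with `type`, `ID` and `Parent` metadata columns.
#' @return An object of class `gene_models`: a list with `transcripts`
#'   (named list; each element has `tx_id`, `gene_id`, `chrom`, `strand`,
#'   `exons` and `cds` interval matrices ordered by genomic start, `tx_len`,
#'   `cds_len`) and `primary` (named character vector, gene to transcript).
#' @export
read_gene_models <- function(x) {
  gr <- if (is.character(x)) rtracklayer::import(x, format = "gff3") else x
  stopifnot(methods::is(gr, "GRanges"))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  id <- as.character(mc$ID)
  parent <- vapply(as.list(mc$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))

  is_tx <- type %in% c("mRNA", "transcript")
  tx_ids <- id[is_tx]
  tx_parent <- parent[is_tx]
  tx_chrom <- as.character(GenomeInfoDb::seqnames(gr))[is_tx]
  tx_strand <- as.character(BiocGenerics::strand(gr))[is_tx]

  part <- type %in% c("exon", "CDS")
  part_tx <- parent[part]
  part_df <- data.frame(tx = part_tx, type = type[part],
                        start = BiocGenerics::start(gr)[part],
                        end = BiocGenerics::end(gr)[part])

  transcripts <- vector("list", length(tx_ids))
  names(transcripts) <- tx_ids
  for (i in seq_along(tx_ids)) {
    p <- part_df[part_df$tx == tx_ids[i], , drop = FALSE]
    ex <- p[p$type == "exon", c("start", "end"), drop = FALSE]
    cd <- p[p$type == "CDS", c("start", "end"), drop = FALSE]
    ex <- as.matrix(ex[order(ex$start), , drop = FALSE])
    cd <- as.matrix(cd[order(cd$start), , drop = FALSE])
    if (nrow(ex) == 0L) ex <- cd   # CDS-only annotations
    if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
      stop("overlapping exons in transcript ", tx_ids[i])
    transcripts[[i]] <- list(
      tx_id = tx_ids[i], gene_id = tx_parent[i],
      chrom = tx_chrom[i], strand = tx_strand[i],
      exons = ex, cds = cd,
      tx_len = sum(ex[, 2L] - ex[, 1L] + 1L),
      cds_len = if (nrow(cd)) sum(cd[, 2L] - cd[, 1L] + 1L) else 0L)
  }

  genes <- split(tx_ids, tx_parent)
  primary <- vapply(genes, function(txs) {
    lens <- vapply(transcripts[txs], `[[`, numeric(1), "tx_len")
    txs[order(-lens, txs)][1L]
  }, character(1))
  structure(list(transcripts = transcripts, primary = primary),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d transcripts, %d genes\n",
              length(x$transcripts), length(x$primary)))
  invisible(x)
}

# Transcript-relative coordinate of a genomic position over an interval
# matrix laid out in genomic order; 5'->3' on the given strand. NA when the
# position falls outside the intervals.
.walk_coord <- function(intervals, strand, pos) {
  if (nrow(intervals) == 0L) return(NA_real_)
  w <- intervals[, 2L] - intervals[, 1L] + 1L
  hit <- which(pos >= intervals[, 1L] & pos <= intervals[, 2L])
  if (length(hit) != 1L) return(NA_real_)
  if (strand == "-") {
    after <- if (hit < nrow(intervals))
      sum(w[(hit + 1L):nrow(intervals)]) else 0L
    after + (intervals[hit, 2L] - pos) + 1L
  } else {
    before <- if (hit > 1L) sum(w[1L:(hit - 1L)]) else 0L
    before + (pos - intervals[hit, 1L]) + 1L
  }
}

# Genomic positions of transcript-relative coordinates (inverse walk).
.walk_genome <- function(intervals, strand, coords) {
  w <- intervals[, 2L] - intervals[, 1L] + 1L
  if (strand == "-") {
    ord <- rev(seq_len(nrow(intervals)))
  } else ord <- seq_len(nrow(intervals))
  offs <- cumsum(c(0L, w[ord]))[seq_along(ord)]
  vapply(coords, function(cc) {
    k <- findInterval(cc - 1L, offs)
    i <- ord[k]
    within <- cc - offs[k] - 1L
    if (strand == "-") intervals[i, 2L] - within else intervals[i, 1L] + within
  }, numeric(1))
}

# Genomic positions inside the splice-junction window of a transcript:
# `intron_bases` at each intron end plus `exon_bases` terminal exonic bases
# flanking each intron.
.splice_window <- function(tx, intron_bases = 2L, exon_bases = 1L) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(integer(0))
  out <- integer(0)
  for (i in seq_len(nrow(ex) - 1L)) {
    istart <- ex[i, 2L] + 1L
    iend <- ex[i + 1L, 1L] - 1L
    if (iend < istart) next
    donor <- istart:min(iend, istart + intron_bases - 1L)
    accept <- max(istart, iend - intron_bases + 1L):iend
    exl <- if (exon_bases > 0)
      (ex[i, 2L] - exon_bases + 1L):ex[i, 2L] else integer(0)
    exr <- if (exon_bases > 0)
      ex[i + 1L, 1L]:(ex[i + 1L, 1L] + exon_bases - 1L) else integer(0)
    out <- c(out, donor, accept, exl, exr)
  }
  unique(out)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.genome_bases <- function(genome, chrom, pos) {
  seq <- genome[[chrom]]
  vapply(pos, function(p) as.character(Biostrings::subseq(seq, p, p)),
         character(1))
}

#' Annotate edit sites against gene models
#'
#' Assigns each site a genic feature and, for coding sites, the reference
#' and edited codons with their translations. The feature is one of
#' `five_utr`, `recoding`, `synonymous`, `splice_junction`, `intron`,
#' `three_utr`, `intergenic`, or `invalid` for a coding site whose codon is
#' truncated. The splice-junction window (the first/last `splice_intron_bases`
#' of each intron plus `splice_exon_bases` terminal exonic bases) takes
#' precedence over exonic and intronic assignment. Only the primary (longest)
#' transcript of each gene is consulted, and a site inside a gene is
#' annotated only against transcripts on its own strand; a site overlapping
#' genes on the opposite strand only is reported `intergenic`.
#'
#' Codons are read on the coding strand with the A-to-G substitution applied
#' at the edited position, so a minus-strand gene with genomic T>C variant
#' is handled transparently (counts and sites are already expressed on the
#' transcribed strand).
#'
#' @param sites data frame with `chrom`, `pos`, `strand`.
#' @param models a [read_gene_models()] object.
#' @param genome a `Biostrings::DNAStringSet` (or path to a FASTA file).
#' @param splice_intron_bases,splice_exon_bases extent of the
#'   splice-junction window.
#' @return A data frame aligned with `sites`: `feature`, `gene_id`, `tx_id`,
#'   `cds_pos`, `aa_pos`, `codon_pos`, `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `blosum62`.
#' @export
annotate_sites <- function(sites, models, genome,
                           splice_intron_bases = 2L, splice_exon_bases = 1L) {
  stopifnot(inherits(models, "gene_models"))
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))

  prim <- models$transcripts[models$primary]
  spans <- GenomicRanges::GRanges(
    vapply(prim, `[[`, character(1), "chrom"),
    IRanges::IRanges(
      vapply(prim, function(t) min(t$exons[, 1L]), numeric(1)),
      vapply(prim, function(t) max(t$exons[, 2L]), numeric(1))),
    strand = vapply(prim, `[[`, character(1), "strand"))
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, width = 1L),
                                strand = sites$strand)
  hits <- GenomicRanges::findOverlaps(sgr, spans)  # strand-aware; '*' matches

  n <- nrow(sites)
  out <- data.frame(feature = rep("intergenic", n),
                    gene_id = NA_character_, tx_id = NA_character_,
                    cds_pos = NA_real_, aa_pos = NA_real_,
                    codon_pos = NA_real_,
                    ref_codon = NA_character_, alt_codon = NA_character_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    blosum62 = NA_integer_, stringsAsFactors = FALSE)

  hit_tx <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  sj_cache <- new.env(parent = emptyenv())
  gcode <- Biostrings::GENETIC_CODE

  for (qi in as.integer(names(hit_tx))) {
    txs <- hit_tx[[as.character(qi)]]
    tx <- prim[[sort(txs)[1L]]]
    pos <- sites$pos[qi]

    key <- tx$tx_id
    sj <- if (!is.null(sj_cache[[key]])) sj_cache[[key]] else {
      sj_cache[[key]] <- .splice_window(tx, splice_intron_bases,
                                        splice_exon_bases)
    }
    if (pos %in% sj) {
      out$feature[qi] <- "splice_junction"
      out$gene_id[qi] <- tx$gene_id; out$tx_id[qi] <- tx$tx_id
      next
    }
    cpos <- .walk_coord(tx$cds, tx$strand, pos)
    if (!is.na(cpos)) {
      out$gene_id[qi] <- tx$gene_id; out$tx_id[qi] <- tx$tx_id
      off <- (cpos - 1) %% 3
      cstart <- cpos - off
      if (cstart + 2 > tx$cds_len) {
        out$feature[qi] <- "invalid"   # incomplete terminal codon
        next
      }
      gpos <- .walk_genome(tx$cds, tx$strand, cstart:(cstart + 2))
      bases <- .genome_bases(genome, tx$chrom, gpos)
      if (tx$strand == "-") bases <- unname(.complement[bases])
      alt <- bases
      alt[off + 1] <- "G"
      ref_codon <- paste(bases, collapse = "")
      alt_codon <- paste(alt, collapse = "")
      ref_aa <- unname(gcode[ref_codon])
      alt_aa <- unname(gcode[alt_codon])
      out$cds_pos[qi] <- cpos
      out$aa_pos[qi] <- (cpos - 1) %/% 3 + 1
      out$codon_pos[qi] <- off + 1
      out$ref_codon[qi] <- ref_codon; out$alt_codon[qi] <- alt_codon
      out$ref_aa[qi] <- ref_aa; out$alt_aa[qi] <- alt_aa
      out$blosum62[qi] <- blosum62_score(ref_aa, alt_aa)
      out$feature[qi] <- if (identical(ref_aa, alt_aa))
        "synonymous" else "recoding"
      next
    }
    tpos <- .walk_coord(tx$exons, tx$strand, pos)
    if (!is.na(tpos)) {
      out$gene_id[qi] <- tx$gene_id; out$tx_id[qi] <- tx$tx_id
      if (tx$cds_len == 0L) {
        out$feature[qi] <- "invalid"   # exon of a non-coding model
      } else {
        cds_tx_start <- .walk_coord(tx$exons, tx$strand,
                                    .walk_genome(tx$cds, tx$strand, 1))
        out$feature[qi] <- if (tpos < cds_tx_start) "five_utr" else "three_utr"
      }
      next
    }
    out$feature[qi] <- "intron"
    out$gene_id[qi] <- tx$gene_id; out$tx_id[qi] <- tx$tx_id
  }
  out
}

#' Repeat, protein-domain and transmembrane overlap flags
#'
#' Repeat intervals are intersected in genomic coordinates; domain and
#' transmembrane intervals are given in protein coordinates (half-open
#' `[start_aa, end_aa)`) and mapped through the gene models via the residue
#' index of each coding site.
#'
#' @param sites data frame with `chrom`, `pos`, `strand`.
#' @param annotations the matching [annotate_sites()] result (required for
#'   domain/TM flags; supplies `tx_id` and `aa_pos`).
#' @param repeats `GRanges` of repeat intervals (e.g. from
#'   [read_repeats()]), or `NULL`.
#' @param domains,tm data frames with columns `transcript_id`, `start_aa`,
#'   `end_aa` (half-open) and `label`, or `NULL`.
#' @param models a [read_gene_models()] object; every `transcript_id` in
#'   `domains`/`tm` must exist in it.
#' @return A data frame with logical columns `in_repeat`, `in_domain`,
#'   `in_tm` aligned with `sites`.
#' @export
overlap_flags <- function(sites, annotations = NULL, repeats = NULL,
                          domains = NULL, tm = NULL, models = NULL) {
  n <- nrow(sites)
  out <- data.frame(in_repeat = rep(FALSE, n), in_domain = FALSE,
                    in_tm = FALSE)
  if (!is.null(repeats)) {
    sgr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos, width = 1L))
    out$in_repeat <- GenomicRanges::countOverlaps(
      sgr, repeats, ignore.strand = TRUE) > 0L
  }
  flag_protein <- function(tab) {
    stopifnot(all(c("transcript_id", "start_aa", "end_aa") %in% names(tab)))
    if (is.null(annotations))
      stop("protein-coordinate overlap needs 'annotations'")
    if (!is.null(models)) {
      missing_tx <- setdiff(tab$transcript_id, names(models$transcripts))
      if (length(missing_tx))
        stop("domain intervals on unknown transcripts: ",
             paste(missing_tx, collapse = ", "))
    }
    f <- rep(FALSE, n)
    idx <- which(!is.na(annotations$aa_pos))
    for (i in idx) {
      rows <- tab$transcript_id == annotations$tx_id[i] &
        tab$start_aa <= annotations$aa_pos[i] &
        annotations$aa_pos[i] < tab$end_aa
      f[i] <- any(rows)
    }
    f
  }
  if (!is.null(domains)) out$in_domain <- flag_protein(domains)
  if (!is.null(tm)) out$in_tm <- flag_protein(tm)
  out
}

#' Editable-adenosine background per genic feature
#'
#' Counts, per genic feature, the transcribed-strand adenosines that are
#' well covered (pooled depth strictly above `min_depth`) yet show no edited
#' read at all - the denominator for editing enrichment. Each such position
#' is annotated with the consequence a hypothetical A-to-G edit would have,
#' so CDS positions split into `recoding`/`synonymous`. When a table of
#' observed edited sites is supplied, the per-feature enrichment ratio
#' (edited fraction over editable fraction) is reported alongside.
#'
#' @param counts an [allele_counts()] object covering transcribed positions
#'   (edited or not).
#' @param models a [read_gene_models()] object.
#' @param genome a `DNAStringSet` or FASTA path.
#' @param edited optional data frame of edited sites with a `feature`
#'   column.
#' @param min_depth strict pooled-depth threshold (default 10: keep depth
#'   > 10).
#' @return Data frame with one row per feature: `editable_a`,
#'   `edited_sites`, `enrichment` (`NA` where no editable adenosine exists;
#'   0 when there are no edited sites).
#' @export
editable_background <- function(counts, models, genome, edited = NULL,
                                min_depth = 10) {
  stopifnot(inherits(counts, "allele_counts"))
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  sites <- counts$sites
  depth <- rowSums(counts$A, na.rm = TRUE) + rowSums(counts$G, na.rm = TRUE)
  no_alt <- rowSums(counts$G, na.rm = TRUE) == 0L
  base <- mapply(function(ch, p) .genome_bases(genome, ch, p),
                 sites$chrom, sites$pos)
  on_tx <- ifelse(sites$strand == "-", unname(.complement[base]), base)
  editable <- depth > min_depth & no_alt & on_tx == "A"

  feats <- c("five_utr", "recoding", "synonymous", "splice_junction",
             "intron", "three_utr")
  ann <- annotate_sites(sites[editable, , drop = FALSE], models, genome)
  editable_a <- table(factor(ann$feature, levels = feats))

  edited_n <- if (is.null(edited)) rep(0L, length(feats)) else
    as.integer(table(factor(edited$feature, levels = feats)))
  tot_ed <- sum(edited_n); tot_ea <- sum(editable_a)
  enr <- rep(NA_real_, length(feats))
  nz <- editable_a > 0 & tot_ea > 0
  if (tot_ed > 0) {
    enr[nz] <- (edited_n[nz] / tot_ed) / (as.integer(editable_a)[nz] / tot_ea)
  } else enr[nz] <- 0
  data.frame(feature = feats, editable_a = as.integer(editable_a),
             edited_sites = edited_n, enrichment = enr,
             stringsAsFactors = FALSE)
}
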