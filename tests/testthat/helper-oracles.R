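# Independent oracles, written as plain enumerations so they share no code
# path with the implementation they check.

# Scalar classifier: evaluates every region predicate literally, then walks
# the precedence list with early return.
oracle_classify <- function(wn, wnn, depth, th = edit_thresholds()) {
  if (is.na(wn) || is.na(wnn) || depth < th$min_pooled_depth)
    return("unclassified")
  regions <- list(
    neural = if (wnn == 0) wn > 0 else (wn / wnn) > th$neural_ratio,
    ubiq_high = (wn > th$high_wn_min) && (wnn > th$high_wnn_min),
    ubiq_low = (wn < th$low_max) && (wnn < th$low_max),
    ubiq_med = (wn >= th$low_max) && (wn <= th$med_wn_max) &&
      (wnn >= th$low_max) && (wnn <= th$med_wnn_max))
  for (nm in th$precedence)
    if (isTRUE(regions[[nm]])) return(nm)
  "other"
}

# Per-base feature map built directly from the GFF intervals: every genomic
# position of every chromosome gets a label, by layered painting
# (intron, then UTRs/CDS from enumerated exonic positions, then the
# splice-junction window on top). CDS positions are labelled with the
# consequence of a hypothetical A-to-G edit at that position.
oracle_feature_map <- function(models, genome,
                               splice_intron = 2L, splice_exon = 1L) {
  gc <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  maps <- lapply(names(genome), function(ch)
    rep("intergenic", Biostrings::width(genome)[match(ch, names(genome))]))
  names(maps) <- names(genome)
  for (tx in models$transcripts[models$primary]) {
    lab <- maps[[tx$chrom]]
    span <- min(tx$exons[, 1]):max(tx$exons[, 2])
    lab[span] <- "intron"
    expos <- unlist(lapply(seq_len(nrow(tx$exons)), function(i)
      tx$exons[i, 1]:tx$exons[i, 2]))
    if (tx$strand == "-") expos <- rev(expos)
    cdspos <- unlist(lapply(seq_len(nrow(tx$cds)), function(i)
      tx$cds[i, 1]:tx$cds[i, 2]))
    ctx <- sort(match(cdspos, expos))
    if (min(ctx) > 1) lab[expos[1:(min(ctx) - 1)]] <- "five_utr"
    if (max(ctx) < length(expos))
      lab[expos[(max(ctx) + 1):length(expos)]] <- "three_utr"

    chars <- strsplit(as.character(genome[[tx$chrom]]), "")[[1]]
    coding <- chars[expos[ctx]]
    if (tx$strand == "-") coding <- unname(comp[coding])
    for (k in seq_along(ctx)) {
      ci <- (k - 1) %/% 3
      if ((ci + 1) * 3 > length(coding)) {
        lab[expos[ctx[k]]] <- "invalid"
        next
      }
      codon <- coding[(ci * 3 + 1):(ci * 3 + 3)]
      alt <- codon
      alt[(k - 1) %% 3 + 1] <- "G"
      same <- unname(gc[paste(codon, collapse = "")]) ==
        unname(gc[paste(alt, collapse = "")])
      lab[expos[ctx[k]]] <- if (same) "synonymous" else "recoding"
    }
    if (nrow(tx$exons) > 1) {
      for (i in seq_len(nrow(tx$exons) - 1)) {
        istart <- tx$exons[i, 2] + 1
        iend <- tx$exons[i + 1, 1] - 1
        win <- c(istart:min(iend, istart + splice_intron - 1),
                 max(istart, iend - splice_intron + 1):iend,
                 (tx$exons[i, 2] - splice_exon + 1):tx$exons[i, 2],
                 tx$exons[i + 1, 1]:(tx$exons[i + 1, 1] + splice_exon - 1))
        lab[unique(win)] <- "splice_junction"
      }
    }
    maps[[tx$chrom]] <- lab
  }
  maps
}
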