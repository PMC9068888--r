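#' Write a synthetic dataset bundle to standard file formats
#'
#' Emits `genome.fa`, `genes.gff3`, `repeats.bed`, `counts.tsv` (long
#' format: chrom, pos, strand, sample, a_count, g_count), `tissues.tsv`,
#' `dna_genotypes.vcf`, one `outgroup_<species>.vcf` per outgroup plus
#' `outgroup_depth_stats.tsv`, `domains.tsv`, `tm.tsv` and `truth.tsv`.
#' Output is deterministic: the same bundle always yields byte-identical
#' files (no timestamps are written).
#'
#' @param sim an `edit_sim` bundle from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "edit_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)

  Biostrings::writeXStringSet(sim$genome, fp("genome.fa"))
  rtracklayer::export(sim$gff, fp("genes.gff3"), format = "gff3")
  rtracklayer::export(sim$repeats, fp("repeats.bed"), format = "bed")

  cs <- sim$counts$sites
  long <- data.frame(
    chrom = rep(cs$chrom, ncol(sim$counts$A)),
    pos = rep(cs$pos, ncol(sim$counts$A)),
    strand = rep(cs$strand, ncol(sim$counts$A)),
    sample = rep(sim$counts$samples, each = nrow(cs)),
    a_count = as.vector(sim$counts$A),
    g_count = as.vector(sim$counts$G), stringsAsFactors = FALSE)
  write_tsv(long, fp("counts.tsv"))
  write_tsv(sim$tissues, fp("tissues.tsv"))
  write_tsv(sim$domains, fp("domains.tsv"))
  write_tsv(sim$tm, fp("tm.tsv"))
  write_tsv(sim$outgroups$depth_stats, fp("outgroup_depth_stats.tsv"))

  truth <- cbind(sim$truth$sites,
                 stats::setNames(as.data.frame(sim$truth$freq),
                                 paste0("freq_", colnames(sim$truth$freq))))
  write_tsv(truth, fp("truth.tsv"))

  .write_genotype_vcf(sim$genotypes, sim$genome, fp("dna_genotypes.vcf"),
                      sample_name = "reference_individual")
  for (sp in names(sim$outgroups$tracks))
    .write_outgroup_vcf(sim$outgroups$tracks[[sp]], sim$genome,
                        fp(paste0("outgroup_", sp, ".vcf")), sp)
  invisible(dir)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# Minimal VCF text writer. Output validates against VariantAnnotation's
# parser; no file date is emitted so identical inputs give identical bytes.
.write_vcf <- function(path, contigs, header_extra, sample_name, body) {
  lines <- c("##fileformat=VCFv4.2",
             header_extra,
             paste0("##contig=<ID=", names(contigs),
                    ",length=", unname(contigs), ">"),
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_name, sep = "\t"),
             body)
  writeLines(lines, path)
}

# Genotypes are stored on the transcribed strand; the VCF stores genomic
# alleles, so AG sites on minus-strand genes are written as T/C.
.write_genotype_vcf <- function(genotypes, genome, path, sample_name) {
  g <- genotypes[order(genotypes$chrom, genotypes$pos), , drop = FALSE]
  minus <- g$strand == "-"
  ref <- ifelse(minus, "T", "A")
  alt_allele <- ifelse(minus, "C", "G")
  alt <- ifelse(g$genotype == "AA", ".",
         ifelse(g$genotype %in% c("AG", "GG"), alt_allele, "N"))
  gt <- c(AA = "0/0", AG = "0/1", GG = "1/1", other = "./.",
          missing = "./.")[g$genotype]
  body <- paste(g$chrom, g$pos, ".", ref, alt, 99, "PASS",
                paste0("MQ=", g$mq), "GT:DP",
                paste0(gt, ":", g$dna_depth), sep = "\t")
  contigs <- stats::setNames(Biostrings::width(genome), names(genome))
  .write_vcf(path, contigs,
             c(paste0("##INFO=<ID=MQ,Number=1,Type=Integer,",
                      "Description=\"RMS mapping quality\">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                      "Description=\"Read depth\">")),
             sample_name, body)
}

.write_outgroup_vcf <- function(track, genome, path, species) {
  tr <- track[order(track$chrom, track$pos), , drop = FALSE]
  ref <- vapply(seq_len(nrow(tr)), function(i)
    as.character(Biostrings::subseq(genome[[tr$chrom[i]]],
                                    tr$pos[i], tr$pos[i])), character(1))
  hom_ref <- tr$allele1 == ref & tr$allele2 == ref
  het <- tr$allele1 != tr$allele2
  alt <- ifelse(hom_ref, ".",
         ifelse(tr$allele1 != ref, tr$allele1, tr$allele2))
  gt <- ifelse(hom_ref, "0/0", ifelse(het, "0/1", "1/1"))
  body <- paste(tr$chrom, tr$pos, ".", ref, alt, 99, "PASS",
                paste0("MQ=", tr$mq), "GT:DP",
                paste0(gt, ":", tr$depth), sep = "\t")
  contigs <- stats::setNames(Biostrings::width(genome), names(genome))
  .write_vcf(path, contigs,
             c(paste0("##INFO=<ID=MQ,Number=1,Type=Integer,",
                      "Description=\"RMS mapping quality\">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                      "Description=\"Read depth\">")),
             species, body)
}

#' Read a long-format allele-count table
#' @param path TSV with columns `chrom`, `pos`, `strand`, `sample`,
#'   `a_count`, `g_count`.
#' @return An [allele_counts()] object.
#' @export
read_allele_counts <- function(path) {
  allele_counts_from_long(read_tsv(path))
}

#' Read a tissue panel table
#' @param path TSV with columns `sample_id`, `group` and optionally
#'   `reference_individual`.
#' @return Validated tissue panel data frame.
#' @export
read_tissue_panel <- function(path) {
  validate_tissue_panel(read_tsv(path))
}

#' Read repeat intervals from BED
#'
#' BED uses 0-based half-open intervals; the returned `GRanges` is 1-based
#' inclusive (the conversion is done by the importer).
#' @param path BED file path.
#' @return A `GRanges`.
#' @export
read_repeats <- function(path) {
  rtracklayer::import(path, format = "bed")
}

# Convert the two genomic alleles of a genotype call to a transcribed-strand
# genotype label (AA / AG / GG / other).
.alleles_to_label <- function(a1, a2, strand) {
  minus <- strand == "-"
  a1 <- ifelse(minus, unname(.complement[a1]), a1)
  a2 <- ifelse(minus, unname(.complement[a2]), a2)
  lab <- rep("other", length(a1))
  lab[a1 == "A" & a2 == "A"] <- "AA"
  lab[a1 == "G" & a2 == "G"] <- "GG"
  lab[(a1 == "A" & a2 == "G") | (a1 == "G" & a2 == "A")] <- "AG"
  lab[is.na(a1) | is.na(a2)] <- "missing"
  lab
}

# Expand GT strings like "0/1" against REF/ALT into two allele characters.
.gt_alleles <- function(gt, ref, alt_list) {
  parts <- strsplit(gt, "[/|]")
  t(vapply(seq_along(parts), function(i) {
    idx <- suppressWarnings(as.integer(parts[[i]]))
    if (length(idx) != 2L || anyNA(idx))
      return(c(NA_character_, NA_character_))
    alleles <- c(ref[i], alt_list[[i]])
    vapply(idx + 1L, function(k)
      if (k <= length(alleles)) alleles[k] else NA_character_, character(1))
  }, character(2)))
}

#' Read same-individual genomic genotypes from a VCF
#'
#' Genotypes are re-expressed on the transcribed strand of the overlapping
#' gene (supplied through `strand_of`), so a homozygous T on a minus-strand
#' gene reads as genotype AA.
#'
#' @param path VCF file with a GT (and optionally DP) FORMAT field for one
#'   individual.
#' @param strand_of data frame with `chrom`, `pos`, `strand` giving the
#'   transcribed strand at each queried site (e.g. the `sites` table of an
#'   [allele_counts()] object). Sites absent from the VCF are reported with
#'   genotype `missing`.
#' @return Data frame with `chrom`, `pos`, `strand`, `genotype`,
#'   `dna_depth`, `mq`.
#' @export
read_genotypes_vcf <- function(path, strand_of) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(strand_of)))
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  vchrom <- as.character(GenomeInfoDb::seqnames(rr))
  vpos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- lapply(as.list(VariantAnnotation::alt(vcf)), as.character)
  gt <- as.character(VariantAnnotation::geno(vcf)$GT[, 1L])
  dp <- if ("DP" %in% names(VariantAnnotation::geno(vcf)))
    as.integer(VariantAnnotation::geno(vcf)$DP[, 1L]) else NA_integer_
  mq <- if ("MQ" %in% names(VariantAnnotation::info(vcf)))
    as.numeric(VariantAnnotation::info(vcf)$MQ) else NA_real_

  al <- .gt_alleles(gt, ref, alt_list)
  key <- paste(vchrom, vpos, sep = ":")
  skey <- paste(strand_of$chrom, strand_of$pos, sep = ":")
  idx <- match(skey, key)
  lab <- rep("missing", length(skey))
  hit <- !is.na(idx)
  lab[hit] <- .alleles_to_label(al[idx[hit], 1L], al[idx[hit], 2L],
                                strand_of$strand[hit])
  data.frame(chrom = strand_of$chrom, pos = strand_of$pos,
             strand = strand_of$strand, genotype = lab,
             dna_depth = if (length(dp) > 1) dp[idx] else NA_integer_,
             mq = if (length(mq) > 1) mq[idx] else NA_real_,
             stringsAsFactors = FALSE)
}

#' Read an outgroup genotype track from a VCF
#'
#' @param path single-sample VCF with GT and DP fields and an MQ INFO tag.
#' @return Data frame with `chrom`, `pos`, `allele1`, `allele2` (genomic
#'   alleles), `depth`, `mq`.
#' @export
read_outgroup_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- lapply(as.list(VariantAnnotation::alt(vcf)), as.character)
  gt <- as.character(VariantAnnotation::geno(vcf)$GT[, 1L])
  al <- .gt_alleles(gt, ref, alt_list)
  dp <- if ("DP" %in% names(VariantAnnotation::geno(vcf)))
    as.integer(VariantAnnotation::geno(vcf)$DP[, 1L]) else NA_integer_
  mq <- if ("MQ" %in% names(VariantAnnotation::info(vcf)))
    as.numeric(VariantAnnotation::info(vcf)$MQ) else NA_real_
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(rr)),
             pos = BiocGenerics::start(rr),
             allele1 = al[, 1L], allele2 = al[, 2L],
             depth = dp, mq = mq, stringsAsFactors = FALSE)
}

#' Read transcriptome allele counts from a multi-sample VCF
#'
#' Accepts a VCF with per-sample allele depths (`AD`). Only records that
#' read as A-to-G on the transcribed strand are kept: REF A with a G
#' alternate on plus-strand genes, REF T with a C alternate on minus-strand
#' genes. The transcribed strand is taken from the primary transcript
#' overlapping each record; records outside annotated genes keep the
#' orientation of the VCF record (REF A) and are flagged by strand `"*"`.
#'
#' @param path VCF file path.
#' @param models a [read_gene_models()] object used to assign strands.
#' @return An [allele_counts()] object.
#' @export
read_allele_counts_vcf <- function(path, models = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- lapply(as.list(VariantAnnotation::alt(vcf)), as.character)

  strand <- rep("*", length(pos))
  if (!is.null(models)) {
    prim <- models$transcripts[models$primary]
    spans <- GenomicRanges::GRanges(
      vapply(prim, `[[`, character(1), "chrom"),
      IRanges::IRanges(
        vapply(prim, function(t) min(t$exons[, 1L]), numeric(1)),
        vapply(prim, function(t) max(t$exons[, 2L]), numeric(1))))
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L)),
      spans, ignore.strand = TRUE)
    strand[S4Vectors::queryHits(hits)] <- vapply(
      prim[S4Vectors::subjectHits(hits)], `[[`, character(1), "strand")
  }

  want_ref <- ifelse(strand == "-", "T", "A")
  want_alt <- ifelse(strand == "-", "C", "G")
  alt_idx <- vapply(seq_along(alt_list), function(i)
    match(want_alt[i], alt_list[[i]]), integer(1))
  keep <- ref == want_ref & !is.na(alt_idx)

  ad <- VariantAnnotation::geno(vcf)$AD
  samples <- colnames(ad)
  n <- sum(keep)
  A <- G <- matrix(0L, n, length(samples),
                   dimnames = list(NULL, samples))
  ki <- which(keep)
  for (r in seq_len(n)) {
    for (s in seq_along(samples)) {
      depths <- if (length(dim(ad)) == 3L) ad[ki[r], s, ] else ad[ki[r], s]
      if (is.list(depths)) depths <- depths[[1L]]
      if (is.null(depths) || all(is.na(depths))) next
      A[r, s] <- depths[1L]
      G[r, s] <- depths[alt_idx[ki[r]] + 1L]
    }
  }
  allele_counts(data.frame(chrom = chrom[keep], pos = pos[keep],
                           strand = strand[keep], stringsAsFactors = FALSE),
                A, G)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir directory containing the bundle files.
#' @return A list shaped like the output of [simulate_dataset()] (class
#'   `edit_sim`), with gene models parsed from the GFF3 rather than the
#'   generator's internal structures.
#' @export
read_dataset <- function(dir) {
  fp <- function(f) file.path(dir, f)
  genome <- Biostrings::readDNAStringSet(fp("genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  counts <- read_allele_counts(fp("counts.tsv"))
  tissues <- read_tissue_panel(fp("tissues.tsv"))
  genotypes <- read_genotypes_vcf(fp("dna_genotypes.vcf"), counts$sites)
  stats <- read_tsv(fp("outgroup_depth_stats.tsv"))
  tracks <- lapply(stats$species, function(sp)
    read_outgroup_vcf(fp(paste0("outgroup_", sp, ".vcf"))))
  names(tracks) <- stats$species
  truth_df <- read_tsv(fp("truth.tsv"))
  fcols <- grep("^freq_", names(truth_df))
  freq <- as.matrix(truth_df[, fcols, drop = FALSE])
  colnames(freq) <- sub("^freq_", "", colnames(freq))
  rownames(freq) <- truth_df$site_id
  structure(list(config = NULL, genome = genome,
                 gff = rtracklayer::import(fp("genes.gff3"),
                                           format = "gff3"),
                 repeats = read_repeats(fp("repeats.bed")),
                 counts = counts, tissues = tissues, genotypes = genotypes,
                 domains = read_tsv(fp("domains.tsv")),
                 tm = read_tsv(fp("tm.tsv")),
                 outgroups = list(tracks = tracks, depth_stats = stats),
                 truth = list(sites = truth_df[, -fcols], freq = freq)),
            class = "edit_sim")
}
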