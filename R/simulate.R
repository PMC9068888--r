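#' Configuration for the synthetic editing dataset generator
#'
#' Defines the study conditions the generator emulates: a small annotated
#' genome, a tissue panel with neural, non-neural and mixed members,
#' heterozygous A/G genomic sites, and per-tissue allele counts at sites of
#' known class. Per-site, per-tissue true edit frequencies follow a Beta
#' model parameterised by a neural-group mean, a non-neural-group mean and a
#' concentration; read depths are negative-binomial and edited-read counts
#' binomial given depth and frequency. Mixed tissues draw 50/50 mixtures of
#' a neural and a non-neural frequency, emulating tissues of heterogeneous
#' composition.
#'
#' @param seed integer seed; a fixed seed makes the generated bundle (and
#'   the files written from it) byte-identical across runs.
#' @param n_chromosomes,chromosome_length genome shape (bases).
#' @param n_genes number of gene models to place.
#' @param tissue_panel data frame with `sample_id` and `group` columns; the
#'   default has 10 neural, 10 non-neural and 2 mixed samples.
#' @param site_counts named integer vector: planted sites per class, over
#'   `neural`, `ubiq_low`, `ubiq_med`, `ubiq_high`, `het_artifact`,
#'   `unedited`.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   (mean and size; variance is `mu + mu^2/size`).
#' @param class_frequency_params data frame with columns `class`,
#'   `mean_neural`, `mean_non_neural`, `concentration`.
#' @param feature_weights named sampling weights over planted genic
#'   features (`five_utr`, `cds`, `splice_junction`, `intron`, `three_utr`).
#' @param fraction_sites_in_repeats fraction of planted sites guaranteed to
#'   lie inside a repeat interval.
#' @param outgroup_divergence_rate per-site probability that an edited-class
#'   site is lineage-specific, i.e. a non-adenosine in both outgroup
#'   genomes.
#' @param outgroup_species identifiers of the outgroup genotype tracks.
#' @param outgroup_depth_mean,outgroup_depth_sd shotgun-coverage summary per
#'   outgroup species (CDS depth mean and SD defining the accepted window).
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chromosome_length = 500000L,
                              n_genes = 200L,
                              tissue_panel = default_tissue_panel(),
                              site_counts = c(neural = 500L, ubiq_low = 500L,
                                              ubiq_med = 500L,
                                              ubiq_high = 500L,
                                              het_artifact = 500L,
                                              unedited = 500L),
                              depth_mean = 50,
                              depth_dispersion = 5,
                              class_frequency_params =
                                default_class_frequency_params(),
                              feature_weights = c(five_utr = 0.06,
                                                  cds = 0.40,
                                                  splice_junction = 0.04,
                                                  intron = 0.25,
                                                  three_utr = 0.25),
                              fraction_sites_in_repeats = 0.25,
                              outgroup_divergence_rate = 0.05,
                              outgroup_species = c("outgroup1", "outgroup2"),
                              outgroup_depth_mean = 40,
                              outgroup_depth_sd = 8) {
  tissue_panel <- validate_tissue_panel(tissue_panel)
  if (!any(tissue_panel$group == "neural") ||
      !any(tissue_panel$group == "non_neural"))
    stop("tissue panel must contain at least one neural and one ",
         "non-neural sample")
  known <- c("neural", "ubiq_low", "ubiq_med", "ubiq_high",
             "het_artifact", "unedited")
  if (is.null(names(site_counts)) || !all(names(site_counts) %in% known))
    stop("site_counts must be named with classes from: ",
         paste(known, collapse = ", "))
  if (any(site_counts < 0) || any(site_counts != round(site_counts)))
    stop("site_counts must be non-negative integers")
  if (depth_mean <= 0 || depth_dispersion <= 0)
    stop("depth model parameters must be positive")
  if (n_chromosomes < 1 || chromosome_length < 10000 || n_genes < 1)
    stop("genome configuration out of range")
  if (fraction_sites_in_repeats < 0 || fraction_sites_in_repeats > 1)
    stop("'fraction_sites_in_repeats' must lie in [0, 1]")
  if (outgroup_divergence_rate < 0 || outgroup_divergence_rate > 1)
    stop("'outgroup_divergence_rate' must lie in [0, 1]")
  p <- class_frequency_params
  stopifnot(all(c("class", "mean_neural", "mean_non_neural",
                  "concentration") %in% names(p)))
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chromosome_length = chromosome_length, n_genes = n_genes,
                 tissue_panel = tissue_panel,
                 site_counts = site_counts[site_counts > 0],
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 class_frequency_params = p,
                 feature_weights = feature_weights,
                 fraction_sites_in_repeats = fraction_sites_in_repeats,
                 outgroup_divergence_rate = outgroup_divergence_rate,
                 outgroup_species = outgroup_species,
                 outgroup_depth_mean = outgroup_depth_mean,
                 outgroup_depth_sd = outgroup_depth_sd),
            class = "sim_config")
}

#' Default tissue panel: 10 neural, 10 non-neural, 2 mixed samples
#' @return Tissue panel data frame.
#' @export
default_tissue_panel <- function() {
  data.frame(
    sample_id = c(paste0("neural_", sprintf("%02d", 1:10)),
                  paste0("nonneural_", sprintf("%02d", 1:10)),
                  "mixed_01", "mixed_02"),
    group = c(rep("neural", 10), rep("non_neural", 10), rep("mixed", 2)),
    reference_individual = TRUE,
    stringsAsFactors = FALSE)
}

#' Default Beta frequency parameters per planted class
#'
#' Neural sites are strongly edited in neural tissues only; ubiquitous sites
#' are edited at comparable rates everywhere within a low, medium or high
#' band; heterozygous artifacts sit near 0.5 in all tissues.
#' @return Data frame with `class`, `mean_neural`, `mean_non_neural`,
#'   `concentration`.
#' @export
default_class_frequency_params <- function() {
  data.frame(
    class = c("neural", "ubiq_low", "ubiq_med", "ubiq_high",
              "het_artifact", "unedited"),
    mean_neural = c(0.40, 0.02, 0.20, 0.70, 0.50, 0),
    mean_non_neural = c(0.01, 0.02, 0.20, 0.55, 0.50, 0),
    concentration = c(30, 30, 30, 30, 50, NA),
    stringsAsFactors = FALSE)
}

.pos_to_intervals <- function(pos) {
  pos <- sort(unique(pos))
  if (!length(pos)) return(matrix(numeric(0), 0, 2))
  brk <- c(0, which(diff(pos) > 1), length(pos))
  t(vapply(seq_len(length(brk) - 1L), function(i)
    c(pos[brk[i] + 1L], pos[brk[i + 1L]]), numeric(2)))
}

# Lay out one gene model starting no earlier than `cursor`; returns NULL when
# the chromosome has no room left.
.place_gene <- function(gene_id, chrom, chrom_len, cursor) {
  gap <- sample(300:1500, 1L)
  start <- cursor + gap
  n_ex <- sample(2:5, 1L)
  exw <- sample(150:400, n_ex, replace = TRUE)
  inw <- sample(80:300, n_ex - 1L, replace = TRUE)
  u5 <- sample(40:120, 1L)
  u3 <- sample(60:200, 1L)
  cds_len <- sum(exw) - u5 - u3
  u3 <- u3 + cds_len %% 3
  cds_len <- sum(exw) - u5 - u3
  if (cds_len < 60) {
    delta <- ceiling((60 - cds_len) / 3) * 3
    exw[n_ex] <- exw[n_ex] + delta
    cds_len <- cds_len + delta
  }
  ex <- matrix(0, n_ex, 2)
  s <- start
  for (i in seq_len(n_ex)) {
    ex[i, ] <- c(s, s + exw[i] - 1L)
    if (i < n_ex) s <- ex[i, 2L] + inw[i] + 1L
  }
  if (ex[n_ex, 2L] > chrom_len - 500L) return(NULL)
  strand <- sample(c("+", "-"), 1L)
  tx_len <- sum(exw)
  cds_pos <- .walk_genome(ex, strand, (u5 + 1L):(u5 + cds_len))
  list(gene_id = gene_id, tx_id = paste0(gene_id, ".t1"),
       chrom = chrom, strand = strand, exons = ex,
       cds = .pos_to_intervals(cds_pos),
       u5 = u5, u3 = u3, tx_len = tx_len, cds_len = cds_len)
}

# Genomic position pools per feature for one gene, splice-junction window
# removed from the exonic/intronic pools.
.feature_pools <- function(g) {
  sj <- .splice_window(g, 2L, 1L)
  exonic <- unlist(mapply(seq, g$exons[, 1L], g$exons[, 2L],
                          SIMPLIFY = FALSE))
  cds <- unlist(mapply(seq, g$cds[, 1L], g$cds[, 2L], SIMPLIFY = FALSE))
  span <- g$exons[1L, 1L]:g$exons[nrow(g$exons), 2L]
  intron <- setdiff(span, exonic)
  u5 <- .walk_genome(g$exons, g$strand, seq_len(g$u5))
  u3 <- .walk_genome(g$exons, g$strand,
                     (g$u5 + g$cds_len + 1L):g$tx_len)
  list(five_utr = setdiff(u5, sj), cds = setdiff(cds, sj),
       splice_junction = sj, intron = setdiff(intron, sj),
       three_utr = setdiff(u3, sj))
}

#' Simulate a fully labeled synthetic editing dataset
#'
#' Generates a genome with gene models, plants edit sites of the configured
#' classes at known positions, and emits everything the analysis pipeline
#' consumes: per-tissue allele counts, same-individual genomic genotypes
#' (heterozygous AG at the planted artifact sites), repeat intervals,
#' protein-domain and transmembrane tables, outgroup genotype tracks, and a
#' ground-truth table. Planted positions are forced to adenosine on the
#' transcribed strand. With a fixed seed the returned bundle is
#' reproducible bit for bit.
#'
#' @param config a [simulation_config()] object.
#' @return An object of class `edit_sim`: a list with elements `config`,
#'   `genome` (`DNAStringSet`), `gff` (`GRanges`), `repeats` (`GRanges`),
#'   `counts` ([allele_counts()]), `tissues`, `genotypes`, `domains`, `tm`,
#'   `outgroups` (`tracks` per species plus `depth_stats`), and `truth`
#'   (`sites` data frame and per-tissue `freq` matrix).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- stats::setNames(rep(config$chromosome_length, length(chroms)), chroms)

  ## -- gene models ---------------------------------------------------------
  genes <- list(); cursor <- stats::setNames(rep(0L, length(chroms)), chroms)
  ci <- 1L
  for (gi in seq_len(config$n_genes)) {
    placed <- FALSE
    for (try in seq_along(chroms)) {
      ch <- chroms[ci]
      g <- .place_gene(sprintf("gene%03d", gi), ch, L[ch], cursor[ch])
      if (!is.null(g)) {
        genes[[g$gene_id]] <- g
        cursor[ch] <- g$exons[nrow(g$exons), 2L]
        placed <- TRUE
        ci <- ci %% length(chroms) + 1L
        break
      }
      ci <- ci %% length(chroms) + 1L
    }
    if (!placed) break
  }
  if (!length(genes)) stop("no gene fits the configured chromosome length")

  ## -- plant sites ---------------------------------------------------------
  classes <- rep(names(config$site_counts), config$site_counts)
  n_sites <- length(classes)
  pools <- lapply(genes, .feature_pools)
  has_feature <- function(feat)
    names(genes)[vapply(pools, function(p) length(p[[feat]]) > 0, logical(1))]
  fw <- config$feature_weights
  fw <- fw[fw > 0]

  used <- lapply(L, function(l) logical(l))
  site_chrom <- character(n_sites); site_pos <- integer(n_sites)
  site_strand <- character(n_sites); site_gene <- character(n_sites)
  site_feat <- character(n_sites)
  for (i in seq_len(n_sites)) {
    repeat {
      feat <- names(fw)[sample.int(length(fw), 1L, prob = fw)]
      cand_genes <- has_feature(feat)
      g <- genes[[cand_genes[sample.int(length(cand_genes), 1L)]]]
      pool <- pools[[g$gene_id]][[feat]]
      pos <- pool[sample.int(length(pool), 1L)]
      lo <- max(1L, pos - 2L); hi <- min(L[g$chrom], pos + 2L)
      if (!any(used[[g$chrom]][lo:hi])) {
        used[[g$chrom]][lo:hi] <- TRUE
        site_chrom[i] <- g$chrom; site_pos[i] <- pos
        site_strand[i] <- g$strand; site_gene[i] <- g$gene_id
        site_feat[i] <- feat
        break
      }
    }
  }

  ## -- genome sequence with forced adenosines ------------------------------
  seqs <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), L[ch], replace = TRUE))
  names(seqs) <- chroms
  for (i in seq_len(n_sites)) {
    seqs[[site_chrom[i]]][site_pos[i]] <-
      if (site_strand[i] == "-") "T" else "A"
  }
  genome <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- chroms

  ## -- true feature (CDS sites resolve to recoding/synonymous) -------------
  true_feature <- site_feat
  gcode <- Biostrings::GENETIC_CODE
  for (i in which(site_feat == "cds")) {
    g <- genes[[site_gene[i]]]
    cpos <- .walk_coord(g$cds, g$strand, site_pos[i])
    off <- (cpos - 1) %% 3
    gpos <- .walk_genome(g$cds, g$strand, (cpos - off):(cpos - off + 2))
    bases <- vapply(gpos, function(p) seqs[[g$chrom]][p], character(1))
    if (g$strand == "-") bases <- unname(.complement[bases])
    alt <- bases; alt[off + 1] <- "G"
    ref_aa <- unname(gcode[paste(bases, collapse = "")])
    alt_aa <- unname(gcode[paste(alt, collapse = "")])
    true_feature[i] <- if (identical(ref_aa, alt_aa))
      "synonymous" else "recoding"
  }

  ## -- per-tissue true frequencies -----------------------------------------
  tissues <- config$tissue_panel
  ns <- nrow(tissues)
  pars <- config$class_frequency_params
  freq <- matrix(0, n_sites, ns,
                 dimnames = list(NULL, tissues$sample_id))
  for (i in seq_len(n_sites)) {
    p <- pars[pars$class == classes[i], ]
    draw <- function(mu) {
      if (is.na(p$concentration) || mu <= 0) return(0)
      stats::rbeta(1L, mu * p$concentration, (1 - mu) * p$concentration)
    }
    for (j in seq_len(ns)) {
      freq[i, j] <- switch(tissues$group[j],
        neural = draw(p$mean_neural),
        non_neural = draw(p$mean_non_neural),
        mixed = 0.5 * (draw(p$mean_neural) + draw(p$mean_non_neural)),
        excluded = draw(p$mean_non_neural))
    }
  }

  ## -- allele counts -------------------------------------------------------
  depth <- matrix(stats::rnbinom(n_sites * ns, size = config$depth_dispersion,
                                 mu = config$depth_mean), n_sites, ns)
  G <- matrix(stats::rbinom(n_sites * ns, as.vector(depth), as.vector(freq)),
              n_sites, ns)
  A <- depth - G
  storage.mode(A) <- storage.mode(G) <- "integer"
  colnames(A) <- colnames(G) <- tissues$sample_id
  sites_df <- data.frame(chrom = site_chrom, pos = site_pos,
                         strand = site_strand, stringsAsFactors = FALSE)
  counts <- allele_counts(sites_df, A, G)

  ## -- genomic genotypes ---------------------------------------------------
  genotypes <- data.frame(
    chrom = site_chrom, pos = site_pos, strand = site_strand,
    genotype = ifelse(classes == "het_artifact", "AG", "AA"),
    dna_depth = sample(30:50, n_sites, replace = TRUE),
    mq = 60L, stringsAsFactors = FALSE)

  ## -- repeats -------------------------------------------------------------
  rep_start <- integer(0); rep_end <- integer(0); rep_chrom <- character(0)
  for (ch in chroms) {
    s <- sample.int(L[ch] - 2000L, 20L)
    w <- sample(200:2000, 20L, replace = TRUE)
    rep_chrom <- c(rep_chrom, rep(ch, 20L))
    rep_start <- c(rep_start, s); rep_end <- c(rep_end, pmin(s + w, L[ch]))
  }
  n_anch <- round(config$fraction_sites_in_repeats * n_sites)
  if (n_anch > 0) {
    anch <- sample.int(n_sites, n_anch)
    rep_chrom <- c(rep_chrom, site_chrom[anch])
    rep_start <- c(rep_start, pmax(1L, site_pos[anch] - 50L))
    rep_end <- c(rep_end, pmin(L[site_chrom[anch]], site_pos[anch] + 149L))
  }
  repeats <- GenomicRanges::reduce(GenomicRanges::GRanges(
    rep_chrom, IRanges::IRanges(rep_start, rep_end)))
  in_repeat <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(site_chrom, IRanges::IRanges(site_pos, width = 1L)),
    repeats, ignore.strand = TRUE) > 0L

  ## -- protein domains and TM segments -------------------------------------
  dom <- list(); tml <- list()
  for (g in genes) {
    plen <- g$cds_len / 3
    if (plen >= 40 && stats::runif(1) < 0.30) {
      s <- sample.int(plen - 25L, 1L)
      dom[[length(dom) + 1L]] <- data.frame(
        transcript_id = g$tx_id, start_aa = s,
        end_aa = min(s + sample(10:40, 1L), plen + 1L),
        label = paste0("DOM_", g$gene_id), stringsAsFactors = FALSE)
    }
    if (plen >= 40 && stats::runif(1) < 0.10) {
      s <- sample.int(plen - 10L, 1L)
      tml[[length(tml) + 1L]] <- data.frame(
        transcript_id = g$tx_id, start_aa = s, end_aa = s + 7L,
        label = paste0("TM_", g$gene_id), stringsAsFactors = FALSE)
    }
  }
  domains <- if (length(dom)) do.call(rbind, dom) else
    data.frame(transcript_id = character(0), start_aa = numeric(0),
               end_aa = numeric(0), label = character(0))
  tm <- if (length(tml)) do.call(rbind, tml) else
    data.frame(transcript_id = character(0), start_aa = numeric(0),
               end_aa = numeric(0), label = character(0))

  ## -- outgroup genotype tracks --------------------------------------------
  edited_classes <- c("neural", "ubiq_low", "ubiq_med", "ubiq_high")
  lineage_specific <- classes %in% edited_classes &
    stats::runif(n_sites) < config$outgroup_divergence_rate
  tracks <- list()
  for (sp in config$outgroup_species) {
    allele_tx <- ifelse(lineage_specific, "G", "A")
    allele_gen <- ifelse(site_strand == "-",
                         unname(.complement[allele_tx]), allele_tx)
    dmin <- config$outgroup_depth_mean - 1.5 * config$outgroup_depth_sd
    dmax <- config$outgroup_depth_mean + 1.5 * config$outgroup_depth_sd
    tracks[[sp]] <- data.frame(
      chrom = site_chrom, pos = site_pos,
      allele1 = allele_gen, allele2 = allele_gen,
      depth = as.integer(round(stats::runif(n_sites, dmin, dmax))),
      mq = 60L, stringsAsFactors = FALSE)
  }
  depth_stats <- data.frame(species = config$outgroup_species,
                            depth_mean = config$outgroup_depth_mean,
                            depth_sd = config$outgroup_depth_sd,
                            stringsAsFactors = FALSE)

  ## -- truth and gene annotation -------------------------------------------
  truth_sites <- data.frame(
    site_id = site_key(site_chrom, site_pos, site_strand),
    chrom = site_chrom, pos = site_pos, strand = site_strand,
    gene_id = site_gene,
    tx_id = vapply(genes[site_gene], `[[`, character(1), "tx_id"),
    true_class = classes, true_feature = true_feature,
    in_repeat = in_repeat, lineage_specific = lineage_specific,
    row.names = NULL, stringsAsFactors = FALSE)
  rownames(freq) <- truth_sites$site_id

  structure(list(config = config, genome = genome,
                 gff = .genes_to_gff(genes), repeats = repeats,
                 counts = counts, tissues = tissues, genotypes = genotypes,
                 domains = domains, tm = tm,
                 outgroups = list(tracks = tracks, depth_stats = depth_stats),
                 truth = list(sites = truth_sites, freq = freq)),
            class = "edit_sim")
}

.genes_to_gff <- function(genes) {
  rows <- list()
  for (g in genes) {
    span <- c(g$exons[1L, 1L], g$exons[nrow(g$exons), 2L])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = span[1L], end = span[2L], strand = g$strand,
      type = c("gene", "mRNA"), ID = c(g$gene_id, g$tx_id),
      parent = c(NA, g$gene_id), phase = NA_integer_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = g$exons[, 1L], end = g$exons[, 2L],
      strand = g$strand, type = "exon", ID = NA_character_,
      parent = g$tx_id, phase = NA_integer_, stringsAsFactors = FALSE)
    cd <- g$cds
    ord <- if (g$strand == "-") rev(seq_len(nrow(cd))) else seq_len(nrow(cd))
    w <- cd[, 2L] - cd[, 1L] + 1L
    before <- cumsum(c(0L, w[ord]))[seq_along(ord)]
    phase <- (3L - before %% 3L) %% 3L
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = cd[ord, 1L], end = cd[ord, 2L],
      strand = g$strand, type = "CDS", ID = NA_character_,
      parent = g$tx_id, phase = phase, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$phase <- df$phase
  gr
}

#' @export
print.edit_sim <- function(x, ...) {
  cat(sprintf(paste0("edit_sim: %d planted sites (%s) on %d chromosomes, ",
                     "%d samples\n"),
              nrow(x$truth$sites),
              paste(names(table(x$truth$sites$true_class)), collapse = "/"),
              length(x$genome), nrow(x$tissues)))
  invisible(x)
}

#' Mirror a synthetic dataset onto the opposite strand
#'
#' Reverse-complements the genome and rewrites every coordinate-bearing
#' component accordingly: positions are mirrored (`pos' = L - pos + 1`),
#' gene and site strands flip, genomic alleles are complemented, and
#' transcribed-strand quantities (allele counts, genotype labels) are left
#' untouched, since the transcribed strand itself is preserved. Running the
#' pipeline on the mirrored bundle must reproduce the original candidate
#' set and classifications at mirrored coordinates.
#'
#' @param sim an `edit_sim` bundle.
#' @return A new `edit_sim` bundle.
#' @seealso [mirror_position()]
#' @export
reverse_complement_dataset <- function(sim) {
  stopifnot(inherits(sim, "edit_sim"))
  L <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
  mirror <- function(chrom, pos) L[chrom] - pos + 1L
  flip <- function(s) ifelse(s == "+", "-", ifelse(s == "-", "+", s))

  out <- sim
  out$genome <- Biostrings::reverseComplement(sim$genome)
  names(out$genome) <- names(sim$genome)

  gr <- sim$gff
  st <- as.character(GenomeInfoDb::seqnames(gr))
  newr <- IRanges::IRanges(L[st] - BiocGenerics::end(gr) + 1L,
                           L[st] - BiocGenerics::start(gr) + 1L)
  out$gff <- GenomicRanges::GRanges(st, newr,
    strand = flip(as.character(BiocGenerics::strand(gr))))
  S4Vectors::mcols(out$gff) <- S4Vectors::mcols(gr)

  rst <- as.character(GenomeInfoDb::seqnames(sim$repeats))
  out$repeats <- GenomicRanges::GRanges(rst,
    IRanges::IRanges(L[rst] - BiocGenerics::end(sim$repeats) + 1L,
                     L[rst] - BiocGenerics::start(sim$repeats) + 1L))

  cs <- sim$counts$sites
  out$counts <- allele_counts(
    data.frame(chrom = cs$chrom, pos = unname(mirror(cs$chrom, cs$pos)),
               strand = flip(cs$strand), stringsAsFactors = FALSE),
    sim$counts$A, sim$counts$G)

  out$genotypes <- transform(sim$genotypes,
                             pos = unname(mirror(chrom, pos)),
                             strand = flip(strand))
  out$outgroups$tracks <- lapply(sim$outgroups$tracks, function(tr)
    transform(tr, pos = unname(mirror(chrom, pos)),
              allele1 = unname(.complement[allele1]),
              allele2 = unname(.complement[allele2])))
  ts <- sim$truth$sites
  ts$pos <- unname(mirror(ts$chrom, ts$pos))
  ts$strand <- flip(ts$strand)
  ts$site_id <- site_key(ts$chrom, ts$pos, ts$strand)
  out$truth$sites <- ts
  fr <- sim$truth$freq
  rownames(fr) <- ts$site_id
  out$truth$freq <- fr
  out
}

#' Mirror a position onto the reverse-complemented genome
#' @param chrom,pos coordinates on the original genome.
#' @param genome the original `DNAStringSet` (supplies chromosome lengths).
#' @return Mirrored 1-based positions.
#' @export
mirror_position <- function(chrom, pos, genome) {
  L <- stats::setNames(Biostrings::width(genome), names(genome))
  unname(L[chrom] - pos + 1L)
}
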