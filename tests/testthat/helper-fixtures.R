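# Shared fixtures, built once per run and cached.
.fixtures <- new.env(parent = emptyenv())

# Default study conditions: 3000 sites (500 per class), 10+10+2 tissues,
# depth mean 50, seed 1.
default_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulate_dataset(simulation_config(seed = 1))
  .fixtures$sim
}

default_landscape <- function() {
  if (is.null(.fixtures$land)) {
    sim <- default_sim()
    models <- read_gene_models(sim$gff)
    .fixtures$land <- analyze_editing(
      sim$counts, sim$genotypes, sim$tissues,
      models = models, genome = sim$genome,
      repeats = sim$repeats, domains = sim$domains, tm = sim$tm)
  }
  .fixtures$land
}

# Reduced bundle for cheap per-module tests.
small_config <- function(seed = 7,
                         site_counts = c(neural = 60L, ubiq_low = 60L,
                                         ubiq_med = 60L, ubiq_high = 60L,
                                         het_artifact = 60L,
                                         unedited = 60L),
                         ...) {
  simulation_config(seed = seed, n_chromosomes = 2,
                    chromosome_length = 60000, n_genes = 30,
                    site_counts = site_counts, ...)
}

small_sim <- function() {
  if (is.null(.fixtures$small_sim))
    .fixtures$small_sim <- simulate_dataset(small_config())
  .fixtures$small_sim
}

default_small_landscape <- function() {
  if (is.null(.fixtures$small_land)) {
    sim <- small_sim()
    models <- read_gene_models(sim$gff)
    .fixtures$small_land <- analyze_editing(
      sim$counts, sim$genotypes, sim$tissues,
      models = models, genome = sim$genome,
      repeats = sim$repeats, domains = sim$domains, tm = sim$tm)
  }
  .fixtures$small_land
}

# Tiny hand-built gene models: one plus-strand and one minus-strand gene
# with known structure, on a fully scripted genome.
#   gplus:  chr1:101-400 (+): exons 101-220, 301-400; CDS 151-220 + 301-341
#   gminus: chr2:101-400 (-): exons 101-200, 301-400; CDS 161-200 + 301-362
toy_gene_set <- function() {
  gff <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t101\t400\t.\t+\t.\tID=gplus",
    "chr1\ttoy\tmRNA\t101\t400\t.\t+\t.\tID=gplus.t1;Parent=gplus",
    "chr1\ttoy\texon\t101\t220\t.\t+\t.\tParent=gplus.t1",
    "chr1\ttoy\texon\t301\t400\t.\t+\t.\tParent=gplus.t1",
    "chr1\ttoy\tCDS\t151\t220\t.\t+\t0\tParent=gplus.t1",
    "chr1\ttoy\tCDS\t301\t341\t.\t+\t2\tParent=gplus.t1",
    "chr2\ttoy\tgene\t101\t400\t.\t-\t.\tID=gminus",
    "chr2\ttoy\tmRNA\t101\t400\t.\t-\t.\tID=gminus.t1;Parent=gminus",
    "chr2\ttoy\texon\t101\t200\t.\t-\t.\tParent=gminus.t1",
    "chr2\ttoy\texon\t301\t400\t.\t-\t.\tParent=gminus.t1",
    "chr2\ttoy\tCDS\t161\t200\t.\t-\t1\tParent=gminus.t1",
    "chr2\ttoy\tCDS\t301\t362\t.\t-\t0\tParent=gminus.t1")
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep("ACGT", 125), collapse = ""),
    chr2 = paste(rep("ACGT", 125), collapse = "")))
  list(models = read_gene_models(path), genome = genome, gff_path = path)
}

# Toy genome where codons are fully controlled: a single-exon plus-strand
# gene whose CDS is given literally.
toy_cds_gene <- function(cds_seq, utr5 = "GGGGG", utr3 = "CCCCC") {
  seq <- paste0(utr5, cds_seq, utr3)
  pad <- paste(rep("A", 20), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrT = paste0(pad, seq, pad)))
  off <- nchar(pad)
  gff <- c(
    "##gff-version 3",
    sprintf("chrT\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=g1",
            off + 1, off + nchar(seq)),
    sprintf("chrT\ttoy\tmRNA\t%d\t%d\t.\t+\t.\tID=g1.t1;Parent=g1",
            off + 1, off + nchar(seq)),
    sprintf("chrT\ttoy\texon\t%d\t%d\t.\t+\t.\tParent=g1.t1",
            off + 1, off + nchar(seq)),
    sprintf("chrT\ttoy\tCDS\t%d\t%d\t.\t+\t0\tParent=g1.t1",
            off + nchar(utr5) + 1, off + nchar(utr5) + nchar(cds_seq)))
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  list(models = read_gene_models(path), genome = genome,
       cds_start = off + nchar(utr5) + 1)
}
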