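test_that("edit frequency is g/(a+g), undefined at zero depth", {
  expect_equal(edit_frequency(10, 0), 0)
  expect_equal(edit_frequency(12, 4), 0.25)
  expect_true(is.na(edit_frequency(0, 0)))
  expect_equal(edit_frequency(c(10, 12, 0), c(0, 4, 0)),
               c(0, 0.25, NA))
  expect_error(edit_frequency(-1, 2), "non-negative")
})

make_counts <- function(a, g, strand = "+") {
  n <- nrow(a)
  allele_counts(data.frame(chrom = "chr1", pos = seq_len(n) * 10,
                           strand = strand, stringsAsFactors = FALSE), a, g)
}

test_that("candidate calling separates edits from genomic artifacts", {
  a <- matrix(c(9, 10, 5, 100, 9), 5, 2,
              dimnames = list(NULL, c("s1", "s2")))
  g <- matrix(c(1, 10, 5, 0, 0), 5, 2,
              dimnames = list(NULL, c("s1", "s2")))
  counts <- make_counts(a, g)
  geno <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40),
                     genotype = c("AA", "AG", "GG", "AA"))
  cand <- call_candidate_sites(counts, geno)
  # AA genotype, f = 0.1 > 0.001
  expect_true(cand$candidate[1])
  # heterozygous genomic site with RNA f ~ 0.5: excluded, reasoned
  expect_false(cand$candidate[2])
  expect_equal(cand$reason[2], "het_genotype")
  expect_equal(cand$reason[3], "non_A_genotype")
  # AA but no edited read anywhere
  expect_false(cand$candidate[4])
  expect_equal(cand$reason[4], "no_edited_reads")
  # no genotype record at all
  expect_equal(cand$reason[5], "genotype_missing")
})

test_that("candidate set shrinks monotonically as the frequency filter rises", {
  set.seed(11)
  n <- 200
  a <- matrix(rpois(n * 4, 40), n, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  g <- matrix(rbinom(n * 4, 10, 0.15), n, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  counts <- make_counts(a, g)
  geno <- data.frame(chrom = "chr1", pos = counts$sites$pos,
                     genotype = "AA")
  sizes <- vapply(c(0, 0.001, 0.05, 0.2, 0.5),
                  function(t) sum(call_candidate_sites(counts, geno,
                                                       t)$candidate),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("constitutive sites need depth in every sample and 5% somewhere", {
  f <- matrix(c(0.05, 0.04, 0.10,
                0.00, 0.00, 0.00), 3, 2,
              dimnames = list(c("x", "y", "z"), c("s1", "s2")))
  depth <- matrix(10, 3, 2, dimnames = dimnames(f))
  expect_setequal(constitutive_sites(list(f = f, depth = depth)),
                  c("x", "z"))
  # one sample at depth 3 (not more than 3 reads) drops the site
  depth["z", 2] <- 3
  expect_setequal(constitutive_sites(list(f = f, depth = depth)), "x")
  # max frequency below 5% drops the site even at depth 100
  depth[] <- 100
  f["x", ] <- c(0.04, 0.049)
  expect_setequal(constitutive_sites(list(f = f, depth = depth)), "z")
  expect_error(constitutive_sites(list(f = f[, 0], depth = depth[, 0])),
               "empty")
})

test_that("allele counts round-trip through the long TSV format", {
  sim <- small_sim()
  path <- tempfile(fileext = ".tsv")
  dir <- tempfile()
  write_dataset(sim, dir)
  rt <- read_allele_counts(file.path(dir, "counts.tsv"))
  expect_identical(rt$A, sim$counts$A)
  expect_identical(rt$G, sim$counts$G)
  expect_identical(rt$sites$site_id, sim$counts$sites$site_id)
})

test_that("minus-strand T/C variants read from VCF become A/G candidates", {
  toy <- toy_gene_set()
  dir <- tempfile(); dir.create(dir)
  # gminus covers chr2:101-400; genomic T>C inside its CDS at 310
  rna <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=500>",
    "##contig=<ID=chr2,length=500>",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr2\t310\t.\tT\tC\t99\tPASS\t.\tAD\t18,2\t9,1",
    "chr2\t320\t.\tG\tA\t99\tPASS\t.\tAD\t10,5\t10,5",   # not A>G on strand
    "chr1\t160\t.\tA\tG\t99\tPASS\t.\tAD\t12,4\t16,0")
  writeLines(rna, file.path(dir, "rna.vcf"))
  counts <- read_allele_counts_vcf(file.path(dir, "rna.vcf"), toy$models)
  expect_equal(nrow(counts$sites), 2L)  # the G>A record is dropped
  m <- counts$sites$pos == 310
  expect_equal(counts$sites$strand[m], "-")
  expect_equal(unname(counts$A[m, ]), c(18L, 9L))
  expect_equal(unname(counts$G[m, ]), c(2L, 1L))

  dna <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=500>",
    "##contig=<ID=chr2,length=500>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tind",
    "chr2\t310\t.\tT\t.\t99\tPASS\t.\tGT\t0/0",
    "chr1\t160\t.\tA\tG\t99\tPASS\t.\tGT\t0/1")
  writeLines(dna, file.path(dir, "dna.vcf"))
  geno <- read_genotypes_vcf(file.path(dir, "dna.vcf"), counts$sites)
  # homozygous T on a minus-strand gene is homozygous A on the transcript
  expect_equal(geno$genotype[geno$pos == 310], "AA")
  expect_equal(geno$genotype[geno$pos == 160], "AG")

  cand <- call_candidate_sites(counts, geno)
  expect_true(cand$candidate[cand$pos == 310])
  expect_false(cand$candidate[cand$pos == 160])
  expect_equal(cand$reason[cand$pos == 160], "het_genotype")
})
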